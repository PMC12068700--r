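# Per-column phylogenetic generalized least squares of a trait on RES,
# significance screening, joint-model information criteria, and mapping of
# significant columns onto a reference sequence's residue numbering.

# Whitened 2-column GLS fit. Xw = [1, x] and yw already multiplied by the
# inverse Cholesky factor of V; returns slope/intercept/se/t/p with n-2 df.
.gls_fit_whitened <- function(Xw, yw) {
  n <- nrow(Xw)
  fit <- lm.fit(Xw, yw)
  beta <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  df <- n - 2
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  if (se[2] <= .Machine$double.eps^0.75 * max(1, abs(beta[2]))) {
    # exact fit: a degenerate (e.g. constant) response
    t_stat <- if (abs(beta[2]) <= 1e-12) 0 else sign(beta[2]) * Inf
  } else {
    t_stat <- beta[2] / se[2]
  }
  p <- 2 * pt(-abs(t_stat), df)
  list(slope = unname(beta[2]), intercept = unname(beta[1]),
       se_slope = unname(se[2]), t_stat = unname(t_stat), p_value = p,
       rss = rss, n = n)
}

#' Phylogenetic generalized least squares of a trait on one predictor
#'
#' Fits `y = b0 + b1 * x + e`, `e ~ N(0, sigma2 * V)`, by Cholesky
#' whitening: both sides are premultiplied by the inverse transpose Cholesky
#' factor of `V` and solved by ordinary least squares (the covariance is
#' never inverted explicitly). The slope is tested two-sided against a t
#' distribution with `n - 2` degrees of freedom, with
#' `sigma2_hat = r' V^-1 r / (n - 2)`.
#'
#' @param x predictor vector (per-taxon RES at one column).
#' @param y response vector (per-taxon lifespan, years).
#' @param V phylogenetic covariance (positive definite), rows/cols in the
#'   same taxon order as `x` and `y`.
#' @return object of class `res_sitefit`: list with `slope`, `intercept`,
#'   `se_slope`, `t_stat`, `p_value`, `n_used`, `status` (`"ok"` or
#'   `"constant_predictor"`).
#' @export
pgls_fit <- function(x, y, V) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(V) == n, ncol(V) == n)
  if (n < 3) stop("PGLS needs at least 3 taxa")
  if (var(x) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          se_slope = NA_real_, t_stat = NA_real_,
                          p_value = NA_real_, n_used = n,
                          status = "constant_predictor"),
                     class = "res_sitefit"))
  }
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is singular (condition number ",
         format(kappa(V), digits = 3), ")"))
  Xw <- backsolve(ch, cbind(1, x), transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  out <- .gls_fit_whitened(Xw, yw)
  structure(list(slope = out$slope, intercept = out$intercept,
                 se_slope = out$se_slope, t_stat = out$t_stat,
                 p_value = out$p_value, n_used = n, status = "ok"),
            class = "res_sitefit")
}

#' @export
print.res_sitefit <- function(x, ...) {
  if (x$status != "ok") {
    cat("res_sitefit:", x$status, "\n")
  } else {
    cat(sprintf(
      "res_sitefit: slope = %.4f (se %.4f), t = %.3f, p = %.4g, n = %d\n",
      x$slope, x$se_slope, x$t_stat, x$p_value, x$n_used))
  }
  invisible(x)
}

#' Screen every alignment column for trait association
#'
#' Runs [pgls_fit()] of the trait on the RES values of each column under the
#' lambda-transformed Brownian covariance, and collects the columns with
#' `status = "ok"` and `p < alpha_screen` as the significant set. No
#' multiple-testing correction is applied by default; Benjamini-Hochberg is
#' available via `correction = "bh"` (screening then uses the adjusted p).
#'
#' @param res score matrix from [score_alignment()] (rownames = taxa).
#' @param traits trait data.frame covering all score rows.
#' @param V Brownian covariance with dimnames covering the score rows.
#' @param alpha_screen significance level (default 0.05).
#' @param lambda Pagel's lambda applied to `V` before fitting (default 1,
#'   i.e. the untransformed Brownian covariance).
#' @param trait_col trait column used as response (default `"L_avg"`).
#' @param correction `"none"` (default) or `"bh"`.
#' @return object of class `res_screen`: list with `sites` (one row per
#'   column: `column`, `slope`, `intercept`, `se_slope`, `t_stat`,
#'   `p_value`, optional `p_adj`, `loglik`, `aic`, `n_used`, `status`),
#'   `rplars` (the significant subset), `alpha_screen`, `lambda`.
#' @export
site_screen <- function(res, traits, V, alpha_screen = 0.05, lambda = 1,
                        trait_col = "L_avg", correction = c("none", "bh")) {
  correction <- match.arg(correction)
  ids <- rownames(res)
  if (!all(ids %in% traits$species))
    stop("traits are missing species: ",
         paste(setdiff(ids, traits$species), collapse = ", "))
  if (!all(ids %in% rownames(V)))
    stop("covariance matrix is missing taxa")
  y <- traits[[trait_col]][match(ids, traits$species)]
  if (anyNA(y)) stop("missing trait values for some species in '", trait_col, "'")
  Vl <- lambda_transform(V[ids, ids], lambda)
  n <- length(y)
  L <- ncol(res)
  ch <- tryCatch(chol(Vl), error = function(e)
    stop("covariance matrix is singular (condition number ",
         format(kappa(Vl), digits = 3),
         "); zero-distance (identical) taxa produce duplicate rows -- ",
         "drop duplicates or supply a tree with distinct tip positions"))
  yw <- backsolve(ch, y, transpose = TRUE)
  ones_w <- backsolve(ch, rep(1, n), transpose = TRUE)
  Sw <- backsolve(ch, res, transpose = TRUE)
  logdet <- 2 * sum(log(diag(ch)))
  rows <- vector("list", L)
  for (j in seq_len(L)) {
    if (var(res[, j]) == 0) {
      rows[[j]] <- data.frame(column = j, slope = NA_real_,
                              intercept = NA_real_, se_slope = NA_real_,
                              t_stat = NA_real_, p_value = NA_real_,
                              loglik = NA_real_, aic = NA_real_,
                              n_used = n, status = "constant_predictor")
      next
    }
    out <- .gls_fit_whitened(cbind(ones_w, Sw[, j]), yw)
    # per-site ML log-likelihood and AIC (k = 3: intercept, slope, sigma2)
    s2_ml <- out$rss / n
    ll <- -0.5 * n * log(2 * pi * s2_ml) - 0.5 * logdet - 0.5 * n
    rows[[j]] <- data.frame(column = j, slope = out$slope,
                            intercept = out$intercept,
                            se_slope = out$se_slope, t_stat = out$t_stat,
                            p_value = out$p_value,
                            loglik = ll, aic = 2 * 3 - 2 * ll,
                            n_used = n, status = "ok")
  }
  sites <- do.call(rbind, rows)
  p_screen <- sites$p_value
  if (correction == "bh") {
    sites$p_adj <- NA_real_
    okr <- sites$status == "ok"
    sites$p_adj[okr] <- p.adjust(sites$p_value[okr], method = "BH")
    p_screen <- sites$p_adj
  }
  sig <- sites$status == "ok" & !is.na(p_screen) & p_screen < alpha_screen
  structure(list(sites = sites, rplars = sites[sig, , drop = FALSE],
                 alpha_screen = alpha_screen, lambda = lambda),
            class = "res_screen")
}

#' @export
print.res_screen <- function(x, ...) {
  cat(sprintf(
    "res_screen: %d columns (%d ok, %d constant), %d significant at p < %g (lambda = %g)\n",
    nrow(x$sites), sum(x$sites$status == "ok"),
    sum(x$sites$status == "constant_predictor"),
    nrow(x$rplars), x$alpha_screen, x$lambda))
  invisible(x)
}

#' Joint GLS fit of the trait on a set of columns
#'
#' A single generalized least squares fit of the trait on the RES values of
#' all selected columns jointly, reported as ML log-likelihood and AIC with
#' `k = |columns| + 2` parameters (slopes, intercept, sigma2).
#'
#' @param res score matrix from [score_alignment()].
#' @param traits trait data.frame covering all score rows.
#' @param V Brownian covariance with dimnames covering the score rows.
#' @param columns 1-based alignment columns to include as predictors.
#' @param lambda Pagel's lambda applied to `V` (default 1).
#' @param trait_col trait column used as response (default `"L_avg"`).
#' @return object of class `res_modelfit`: list with `aic`, `loglik`, `k`,
#'   `predictors`, `coefficients`, `n`.
#' @export
joint_model_fit <- function(res, traits, V, columns, lambda = 1,
                            trait_col = "L_avg") {
  columns <- as.integer(columns)
  if (length(columns) < 1) stop("at least one column must be selected")
  if (min(columns) < 1 || max(columns) > ncol(res))
    stop("column index out of range 1..", ncol(res))
  ids <- rownames(res)
  y <- traits[[trait_col]][match(ids, traits$species)]
  n <- length(y)
  if (n <= length(columns) + 2)
    stop("need more taxa (", n, ") than predictors + 2 (",
         length(columns) + 2, ")")
  Vl <- lambda_transform(V[ids, ids], lambda)
  ch <- chol(Vl)
  X <- cbind(`(Intercept)` = 1, res[, columns, drop = FALSE])
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(Xw)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yw)
  rss <- sum(qr.resid(qx, yw)^2)
  s2_ml <- rss / n
  ll <- -0.5 * n * log(2 * pi * s2_ml) - sum(log(diag(ch))) - 0.5 * n
  k <- length(columns) + 2
  structure(list(aic = 2 * k - 2 * ll, loglik = ll, k = k,
                 predictors = columns, coefficients = beta, n = n),
            class = "res_modelfit")
}

#' @export
print.res_modelfit <- function(x, ...) {
  cat(sprintf(
    "res_modelfit: %d predictors, logLik = %.4f, AIC = %.4f (k = %d, n = %d)\n",
    length(x$predictors), x$loglik, x$aic, x$k, x$n))
  invisible(x)
}

#' Map screened columns onto a reference sequence's residue numbering
#'
#' For each row of a site table, the reference residue number is the count
#' of non-gap reference symbols in alignment columns `1..j` when the
#' reference is non-gap at column `j`, and absent (`NA`) when the reference
#' has a gap there. Residue numbering is 1-based and ungapped, as in
#' standard protein coordinates.
#'
#' @param sites data.frame with a `column` field (e.g. the `rplars` element
#'   of [site_screen()]).
#' @param alignment the source `res_alignment`.
#' @param reference_id id of the reference sequence in the alignment.
#' @return `sites` with added `ref_residue` (integer or `NA`) and
#'   `ref_symbol` columns.
#' @export
map_to_reference <- function(sites, alignment, reference_id) {
  stopifnot(inherits(alignment, "res_alignment"))
  reference_id <- normalize_taxon(reference_id)
  if (!reference_id %in% alignment$ids)
    stop("reference sequence '", reference_id, "' not in alignment")
  ref <- alignment$rows[reference_id, ]
  cum <- cumsum(ref != "-")
  j <- sites$column
  if (any(j < 1 | j > length(ref))) stop("column index out of range")
  sites$ref_residue <- ifelse(ref[j] == "-", NA_integer_, cum[j])
  sites$ref_symbol <- ref[j]
  sites
}
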