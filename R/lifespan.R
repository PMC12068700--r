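# Max-to-average lifespan regression and normalization.
#
# Average lifespan is missing for many species in broad ortholog panels
# while maximum lifespan is widely recorded; a simple linear model
# L_avg = alpha * L_max + beta trained on species with both values lets us
# estimate the missing averages, and the learned slope also drives a
# normalized lifespan that interpolates between the estimated average and
# the maximum: L_norm = L_avg_est + (L_max - L_avg_est) * alpha.

#' Fit the max-to-average lifespan regression
#'
#' Ordinary least squares of observed average lifespan on maximum lifespan,
#' using only species for which both values are present.
#'
#' @param traits trait data.frame with `L_avg` and `L_max` columns (years).
#' @return object of class `lifespan_model`: list with `alpha` (slope),
#'   `beta` (intercept, years) and `n_train`.
#' @export
fit_lifespan_regression <- function(traits) {
  ok <- !is.na(traits$L_avg) & !is.na(traits$L_max)
  if (sum(ok) < 2)
    stop("need at least 2 species with both L_avg and L_max (found ",
         sum(ok), ")")
  x <- traits$L_max[ok]
  y <- traits$L_avg[ok]
  if (var(x) == 0) stop("degenerate design: all training L_max values equal")
  fit <- lm(y ~ x)
  structure(list(alpha = unname(coef(fit)[2]),
                 beta = unname(coef(fit)[1]),
                 n_train = sum(ok)),
            class = "lifespan_model")
}

#' @export
print.lifespan_model <- function(x, ...) {
  cat(sprintf("lifespan_model: L_avg = %.4f * L_max + %.4f  (n_train = %d)\n",
              x$alpha, x$beta, x$n_train))
  invisible(x)
}

#' Compute normalized lifespans
#'
#' For species without an observed average lifespan, the model predicts
#' `L_avg_est = alpha * L_max + beta`; observed averages are used directly.
#' The normalized lifespan is then
#' `L_norm = L_avg_est + (L_max - L_avg_est) * alpha` (only the slope enters
#' the correction term). Species with an observed average but no recorded
#' maximum keep `L_norm = L_avg` since the correction term is undefined.
#'
#' @param traits trait data.frame (see [read_traits()]).
#' @param model a [fit_lifespan_regression()] model.
#' @return the trait table with added columns `L_avg_est`, `L_norm` and
#'   `source` (`"observed"` or `"estimated"`).
#' @export
normalize_lifespans <- function(traits, model) {
  stopifnot(inherits(model, "lifespan_model"))
  none <- is.na(traits$L_avg) & is.na(traits$L_max)
  if (any(none)) {
    warning("dropping ", sum(none), " species with neither L_avg nor L_max")
    traits <- traits[!none, , drop = FALSE]
  }
  est <- is.na(traits$L_avg)
  traits$L_avg_est <- ifelse(est,
                             model$alpha * traits$L_max + model$beta,
                             traits$L_avg)
  traits$L_norm <- ifelse(is.na(traits$L_max),
                          traits$L_avg_est,
                          traits$L_avg_est +
                            (traits$L_max - traits$L_avg_est) * model$alpha)
  traits$source <- ifelse(est, "estimated", "observed")
  rownames(traits) <- NULL
  traits
}
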