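# Relative evolutionary scoring: position weight matrix with additive
# pseudocounts, alignment-wide background frequencies, and per-sequence
# per-column log-odds scores.

#' Build a position weight matrix with pseudocounts
#'
#' Column probabilities are `p(a, j) = (c(a, j) + kappa) / (n + kappa * 21)`
#' where `c(a, j)` counts symbol `a` (one of the 20 amino acids or the gap)
#' in column `j` of an `n`-sequence alignment. Background frequencies receive
#' the same pseudocount: `q(a) = (C(a) + kappa) / (n * L + kappa * 21)` with
#' `C(a)` the total count of `a`. The pseudocount keeps all probabilities
#' strictly positive so log-odds scores stay finite.
#'
#' @param alignment a `res_alignment`.
#' @param pseudocount additive count `kappa > 0` (default 1, Laplace).
#' @param log_base base used later by [score_alignment()]; 2 (bits, default)
#'   or `exp(1)` (nats).
#' @return object of class `res_pwm`: list with `probs` (21 x L matrix,
#'   rows in [RES_ALPHABET] order), `background` (length-21 vector),
#'   `pseudocount`, `log_base`, `n`, `L`.
#' @export
build_pwm <- function(alignment, pseudocount = 1, log_base = 2) {
  stopifnot(inherits(alignment, "res_alignment"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  if (!log_base %in% c(2, exp(1)))
    stop("log_base must be 2 or exp(1)")
  m <- alignment$rows
  n <- nrow(m)
  L <- ncol(m)
  S <- length(RES_ALPHABET)
  idx <- matrix(match(m, RES_ALPHABET), nrow = n)
  counts <- vapply(seq_len(L),
                   function(j) tabulate(idx[, j], nbins = S),
                   integer(S))
  probs <- (counts + pseudocount) / (n + pseudocount * S)
  background <- (rowSums(counts) + pseudocount) / (n * L + pseudocount * S)
  rownames(probs) <- RES_ALPHABET
  colnames(probs) <- paste0("pos", seq_len(L))
  names(background) <- RES_ALPHABET
  structure(list(probs = probs, background = background,
                 pseudocount = pseudocount, log_base = log_base,
                 n = n, L = L),
            class = "res_pwm")
}

#' @export
print.res_pwm <- function(x, ...) {
  cat(sprintf(
    "res_pwm: %d symbols x %d columns (n = %d, pseudocount = %g, base %s)\n",
    nrow(x$probs), x$L, x$n, x$pseudocount,
    if (x$log_base == 2) "2" else "e"))
  invisible(x)
}

#' Score every residue of an alignment against a PWM
#'
#' The relative evolutionary score of residue `a_ij` (sequence `i`, column
#' `j`) is the log-odds ratio `log(p(a_ij, j) / q(a_ij))` of its
#' column-specific probability to its background probability, in the base
#' recorded in the PWM. Gaps are scored identically to residues.
#'
#' @param alignment the `res_alignment` the PWM was built from (or one with
#'   the same column count and alphabet).
#' @param pwm a [build_pwm()] model.
#' @return numeric n x L matrix of scores with sequence ids as rownames and
#'   `pos1..posL` as colnames.
#' @export
score_alignment <- function(alignment, pwm) {
  stopifnot(inherits(alignment, "res_alignment"), inherits(pwm, "res_pwm"))
  m <- alignment$rows
  if (ncol(m) != pwm$L)
    stop("alignment has ", ncol(m), " columns but PWM was built for ", pwm$L)
  n <- nrow(m)
  L <- ncol(m)
  aidx <- match(m, RES_ALPHABET)
  if (anyNA(aidx)) stop("alignment contains symbols outside the alphabet")
  aidx <- matrix(aidx, nrow = n)
  colidx <- matrix(rep(seq_len(L), each = n), nrow = n)
  scores <- log(pwm$probs[cbind(as.vector(aidx), as.vector(colidx))] /
                  pwm$background[as.vector(aidx)]) / log(pwm$log_base)
  scores <- matrix(scores, nrow = n,
                   dimnames = list(alignment$ids, paste0("pos", seq_len(L))))
  scores
}

#' Export a RES heatmap table ordered by lifespan
#'
#' Writes a TSV of scores at the requested columns with one row per species,
#' ordered from longest- to shortest-lived; lifespan ties are broken by
#' species id. Optionally renders a raster heatmap (requires the pheatmap
#' package).
#'
#' @param res score matrix from [score_alignment()].
#' @param traits trait data.frame covering all score rows.
#' @param site_subset integer vector of 1-based alignment columns (may be
#'   empty, giving a header-only table).
#' @param path output TSV path.
#' @param trait_col trait column used for ordering (default `"L_avg"`).
#' @param image optional PNG path for a raster heatmap.
#' @return `path`, invisibly.
#' @export
export_res_heatmap <- function(res, traits, site_subset, path,
                               trait_col = "L_avg", image = NULL) {
  ids <- rownames(res)
  if (!all(ids %in% traits$species))
    stop("traits are missing species: ",
         paste(setdiff(ids, traits$species), collapse = ", "))
  site_subset <- as.integer(site_subset)
  if (length(site_subset) > 0 &&
      (min(site_subset) < 1 || max(site_subset) > ncol(res)))
    stop("site index out of range 1..", ncol(res))
  life <- traits[[trait_col]][match(ids, traits$species)]
  ord <- order(-life, ids)
  df <- data.frame(species = ids[ord], lifespan = life[ord],
                   check.names = FALSE)
  if (length(site_subset) > 0) {
    sub <- res[ord, site_subset, drop = FALSE]
    colnames(sub) <- paste0("pos", site_subset)
    df <- cbind(df, as.data.frame(sub))
  } else {
    df <- df[0, , drop = FALSE]
  }
  write_tsv(df, path)
  if (!is.null(image) && length(site_subset) > 0 &&
      requireNamespace("pheatmap", quietly = TRUE)) {
    mat <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(mat) <- df$species
    grDevices::png(image, width = 1200, height = 900, res = 120)
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  invisible(path)
}
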