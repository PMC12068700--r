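# End-to-end pipeline: harmonize -> (optional lifespan normalization) ->
# RES scoring -> tree (build or load) -> phylogenetic signal -> per-site
# PGLS screen -> reference mapping -> table/JSON export with a run manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Executes harmonization, optional lifespan normalization, PWM/RES scoring,
#' tree construction (neighbor joining on p-distances) unless a tree is
#' supplied, Pagel's lambda estimation, the per-column PGLS screen, optional
#' mapping onto a reference sequence, and writes `sitefits.tsv`,
#' `rplars.tsv`, `res_heatmap.tsv`, `tree.nwk`, `summary.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param alignment a `res_alignment`.
#' @param traits trait data.frame (see [read_traits()]).
#' @param out_dir output directory (created if needed).
#' @param tree optional rooted [ape::phylo] tree; built from the alignment
#'   when `NULL`.
#' @param reference_id optional reference sequence id for residue mapping.
#' @param pseudocount PWM pseudocount (default 1).
#' @param log_base log base for scores (default 2).
#' @param alpha significance level of the screen (default 0.05).
#' @param lambda_policy `"fixed1"` (default; screen under the untransformed
#'   Brownian covariance) or `"estimated"` (use the ML lambda).
#' @param normalize if `TRUE`, fit the max-to-average lifespan model and
#'   screen against normalized lifespan (`L_norm`).
#' @param trait_col trait column used as response (default `"L_avg"`).
#' @param correction multiple-testing correction for the screen (`"none"`
#'   or `"bh"`).
#' @param input_checksums optional named list of file checksums recorded in
#'   the manifest.
#' @return invisibly, a list with elements `alignment`, `traits`, `tree`,
#'   `pwm`, `res`, `signal`, `screen`, `rplars`, `joint`, `summary`,
#'   `manifest`.
#' @export
run_full <- function(alignment, traits, out_dir, tree = NULL,
                     reference_id = NULL, pseudocount = 1, log_base = 2,
                     alpha = 0.05, lambda_policy = c("fixed1", "estimated"),
                     normalize = FALSE, trait_col = "L_avg",
                     correction = "none", input_checksums = NULL) {
  lambda_policy <- match.arg(lambda_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (normalize) {
    model <- .stage("normalize", fit_lifespan_regression(traits))
    traits <- .stage("normalize", normalize_lifespans(traits, model))
    trait_col <- "L_norm"
  } else model <- NULL

  if (is.null(tree)) {
    tree <- .stage("tree", neighbor_joining(pdistance(alignment)))
    tree_source <- "neighbor_joining(p-distance)"
  } else tree_source <- "supplied"

  h <- .stage("harmonize", harmonize(alignment, tree, traits))
  alignment <- h$alignment; tree <- h$tree; traits <- h$traits

  pwm <- .stage("score", build_pwm(alignment, pseudocount, log_base))
  res <- .stage("score", score_alignment(alignment, pwm))

  V <- .stage("covariance", bm_covariance(tree))
  y <- setNames(traits[[trait_col]], traits$species)
  signal <- .stage("signal", estimate_lambda(tree, y))
  lam <- if (lambda_policy == "estimated") signal$lambda_hat else 1

  screen <- .stage("screen",
                   site_screen(res, traits, V, alpha_screen = alpha,
                               lambda = lam, trait_col = trait_col,
                               correction = correction))
  rplars <- screen$rplars
  if (!is.null(reference_id) && nrow(rplars) > 0)
    rplars <- .stage("map", map_to_reference(rplars, alignment, reference_id))

  joint <- NULL
  if (nrow(screen$rplars) > 0) {
    # drop exactly collinear score patterns (identical columns) so the
    # joint design has full rank
    jcols <- screen$rplars$column[
      !duplicated(t(res[, screen$rplars$column, drop = FALSE]))]
    if (nrow(res) > length(jcols) + 2)
      joint <- .stage("joint_fit",
                      joint_model_fit(res, traits, V, jcols,
                                      lambda = lam, trait_col = trait_col))
  }

  .stage("export", {
    write_tsv(screen$sites, file.path(out_dir, "sitefits.tsv"))
    write_tsv(rplars, file.path(out_dir, "rplars.tsv"))
    export_res_heatmap(res, traits, screen$rplars$column,
                       file.path(out_dir, "res_heatmap.tsv"),
                       trait_col = trait_col)
    write_tree(tree, file.path(out_dir, "tree.nwk"))
    if (normalize) write_tsv(traits, file.path(out_dir, "traits_normalized.tsv"))
  })

  summary <- list(
    n_taxa = length(alignment$ids), n_columns = ncol(alignment$rows),
    n_dropped_taxa = length(h$dropped),
    n_constant_columns = sum(screen$sites$status == "constant_predictor"),
    n_rplars = nrow(screen$rplars),
    lambda_hat = signal$lambda_hat, lambda_boundary = signal$boundary,
    sigma2_hat = signal$sigma2_hat, signal_loglik = signal$loglik,
    lambda_used = lam,
    joint_aic = if (is.null(joint)) NA else joint$aic,
    joint_loglik = if (is.null(joint)) NA else joint$loglik,
    lifespan_alpha = if (is.null(model)) NA else model$alpha,
    lifespan_beta = if (is.null(model)) NA else model$beta)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- run_manifest("run", parameters = list(
    pseudocount = pseudocount, log_base = log_base, alpha = alpha,
    lambda_policy = lambda_policy, normalize = normalize,
    trait_col = trait_col, correction = correction,
    reference_id = reference_id, tree_source = tree_source),
    input_checksums = input_checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  message(sprintf(
    "run_full: %d taxa, %d columns, %d dropped taxa, %d constant columns, %d significant columns",
    summary$n_taxa, summary$n_columns, summary$n_dropped_taxa,
    summary$n_constant_columns, summary$n_rplars))

  invisible(list(alignment = alignment, traits = traits, tree = tree,
                 pwm = pwm, res = res, signal = signal, screen = screen,
                 rplars = rplars, joint = joint, summary = summary,
                 manifest = manifest))
}

#' Build a run manifest
#'
#' Records the command, every resolved parameter, input checksums, package
#' version and a timestamp so a run can be reproduced exactly.
#'
#' @param command command name.
#' @param parameters named list of resolved parameters.
#' @param input_checksums optional named list (e.g. from
#'   [tools::md5sum()]).
#' @return a named list.
#' @export
run_manifest <- function(command, parameters = list(),
                         input_checksums = NULL) {
  list(command = command,
       parameters = parameters,
       input_checksums = input_checksums,
       tool = "resphylo",
       version = as.character(packageVersion("resphylo")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
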