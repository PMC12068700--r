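test_that("PGLS with identity (or scaled-identity) covariance is OLS", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  fit <- pgls_fit(x, y, diag(3))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$status, "ok")

  set.seed(41)
  x <- rnorm(20)
  y <- 1 + 0.5 * x + rnorm(20)
  ols <- summary(lm(y ~ x))$coefficients
  for (c_scale in c(1, 7, 0.03)) {
    fit <- pgls_fit(x, y, c_scale * diag(20))
    expect_equal(fit$slope, ols["x", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$se_slope, ols["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(fit$t_stat, ols["x", "t value"], tolerance = 1e-10)
    expect_equal(fit$p_value, ols["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("PGLS matches the explicitly hand-solved 3-taxon system", {
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)
  x <- c(0, 1, 2)
  y <- c(1, 1, 3)
  fit <- pgls_fit(x, y, V)
  # oracle: beta = (X' V^-1 X)^-1 X' V^-1 y by direct matrix arithmetic
  X <- cbind(1, x)
  o <- gls_oracle(X, y, V)
  expect_equal(fit$intercept, o$beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, o$beta[2], tolerance = 1e-12)
  expect_equal(fit$se_slope, o$se[2], tolerance = 1e-12)
})

test_that("degenerate inputs are reported, not mis-fit", {
  V <- diag(4)
  # constant predictor: flagged, no inference
  fit <- pgls_fit(rep(2, 4), c(1, 2, 3, 4), V)
  expect_equal(fit$status, "constant_predictor")
  expect_true(is.na(fit$slope))
  # constant response: zero slope, t = 0, p = 1
  fit2 <- pgls_fit(c(1, 2, 3, 4), rep(5, 4), V)
  expect_equal(fit2$slope, 0, tolerance = 1e-12)
  expect_equal(fit2$t_stat, 0)
  expect_equal(fit2$p_value, 1)
  # singular covariance is an error mentioning the condition number
  Vs <- matrix(1, 4, 4)
  expect_error(pgls_fit(c(1, 2, 3, 4), c(1, 2, 3, 4), Vs),
               "singular.*condition")
})

test_that("whitened fits equal normal-equation fits on random instances", {
  set.seed(43)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    V <- random_pd(n)
    x <- rnorm(n)
    y <- rnorm(n)
    fit <- pgls_fit(x, y, V)
    o <- gls_oracle(cbind(1, x), y, V)
    expect_equal(fit$slope, o$beta[2], tolerance = 1e-8)
    expect_equal(fit$se_slope, o$se[2], tolerance = 1e-8)
    expect_equal(fit$p_value, o$p[2], tolerance = 1e-8)
  }
})

test_that("taxon permutation leaves the fit unchanged", {
  set.seed(47)
  n <- 15
  V <- random_pd(n)
  x <- rnorm(n)
  y <- rnorm(n)
  fit <- pgls_fit(x, y, V)
  perm <- sample(n)
  fit_p <- pgls_fit(x[perm], y[perm], V[perm, perm])
  for (f in c("slope", "intercept", "se_slope", "t_stat", "p_value"))
    expect_equal(fit_p[[f]], fit[[f]], tolerance = 1e-10)
})

test_that("PGLS agrees with an independent GLS fit under corBrownian", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(40, seed = 51)
  V <- bm_covariance(tr)
  y <- simulate_bm_trait(tr, sigma2 = 2, seed = 52)
  set.seed(53)
  x <- setNames(rnorm(40), tr$tip.label)
  fit <- pgls_fit(x[rownames(V)], y[rownames(V)], V)
  df <- data.frame(x = x, y = y, sp = names(x))
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(1, tr, form = ~sp),
                 method = "REML")
  tt <- summary(g)$tTable
  expect_equal(fit$slope, tt["x", "Value"], tolerance = 1e-6)
  expect_equal(fit$se_slope, tt["x", "Std.Error"], tolerance = 1e-6)
  expect_equal(fit$p_value, tt["x", "p-value"], tolerance = 1e-6)
})

test_that("site screen separates ok, constant and significant columns", {
  d <- simulate_dataset(sim_config(n_taxa = 50, L_total = 60,
                                   linked_columns = c(5L, 20L), seed = 61))
  res <- score_alignment(d$alignment, build_pwm(d$alignment))
  V <- bm_covariance(d$tree)
  sc <- site_screen(res, d$traits, V, alpha_screen = 0.05)
  expect_equal(nrow(sc$sites), 60)
  expect_true(all(sc$rplars$p_value < 0.05))
  expect_true(all(sc$rplars$status == "ok"))
  # the significant set is exactly the ok fits below alpha
  expect_equal(sc$rplars$column,
               sc$sites$column[sc$sites$status == "ok" &
                                 sc$sites$p_value < 0.05])
  # per-site AIC identity
  ok <- sc$sites$status == "ok"
  expect_equal(sc$sites$aic[ok], 2 * 3 - 2 * sc$sites$loglik[ok],
               tolerance = 1e-9)

  # BH correction is monotone and never admits more columns
  sc_bh <- site_screen(res, d$traits, V, correction = "bh")
  expect_true(all(sc_bh$rplars$column %in% sc$rplars$column))
  expect_true(all(sc_bh$sites$p_adj >= sc_bh$sites$p_value, na.rm = TRUE))

  # a fully constant alignment yields zero ok fits and no significant sites
  aln_const <- aln_from_strings(rep("AAKDE", 6), ids = paste0("s", 1:6))
  res_c <- score_alignment(aln_const, build_pwm(aln_const))
  traits_c <- data.frame(species = paste0("s", 1:6), L_avg = rnorm(6) + 10,
                         L_max = NA_real_)
  V_c <- diag(6)
  dimnames(V_c) <- list(paste0("s", 1:6), paste0("s", 1:6))
  sc_c <- site_screen(res_c, traits_c, V_c, alpha_screen = 0.05)
  expect_true(all(sc_c$sites$status == "constant_predictor"))
  expect_equal(nrow(sc_c$rplars), 0)
})

test_that("screening at lambda = 0 reduces to ordinary least squares", {
  d <- simulate_dataset(sim_config(n_taxa = 30, L_total = 20,
                                   linked_columns = 3L, seed = 67))
  res <- score_alignment(d$alignment, build_pwm(d$alignment))
  V <- bm_covariance(d$tree)
  sc0 <- site_screen(res, d$traits, V, lambda = 0)
  y <- d$traits$L_avg[match(rownames(res), d$traits$species)]
  vdiag <- diag(V[rownames(res), rownames(res)])
  for (j in which(sc0$sites$status == "ok")) {
    # lambda = 0 keeps only the diagonal of V, i.e. least squares with
    # weights 1 / V_ii (plain OLS when the tree is ultrametric)
    ols <- summary(lm(y ~ res[, j], weights = 1 / vdiag))$coefficients
    expect_equal(sc0$sites$slope[j], ols[2, "Estimate"], tolerance = 1e-8)
    expect_equal(sc0$sites$p_value[j], ols[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("joint model fit is consistent with per-site likelihoods", {
  d <- simulate_dataset(sim_config(n_taxa = 40, L_total = 30,
                                   linked_columns = c(7L, 15L), seed = 71))
  res <- score_alignment(d$alignment, build_pwm(d$alignment))
  V <- bm_covariance(d$tree)
  sc <- site_screen(res, d$traits, V)
  jm1 <- joint_model_fit(res, d$traits, V, columns = 7)
  expect_equal(jm1$loglik, sc$sites$loglik[7], tolerance = 1e-9)
  expect_equal(jm1$aic, sc$sites$aic[7], tolerance = 1e-9)
  expect_equal(jm1$aic, 2 * jm1$k - 2 * jm1$loglik, tolerance = 1e-9)

  jm2 <- joint_model_fit(res, d$traits, V, columns = c(7, 15))
  expect_equal(jm2$k, 4)
  expect_equal(jm2$aic, 2 * jm2$k - 2 * jm2$loglik, tolerance = 1e-9)

  # collinear predictors are rejected with the offending columns named
  res_dup <- cbind(res, res[, 7, drop = FALSE])
  colnames(res_dup)[ncol(res_dup)] <- "pos31"
  expect_error(joint_model_fit(res_dup, d$traits, V, columns = c(7, 31)),
               "collinear")
  expect_error(joint_model_fit(res, d$traits, V, columns = integer(0)),
               "at least one")
})

test_that("the true column set fits better than a random disjoint set", {
  set.seed(73)
  wins <- 0L
  n_rep <- 30
  for (i in 1:n_rep) {
    cfg <- sim_config(n_taxa = 60, L_total = 60,
                      linked_columns = c(10L, 25L, 40L),
                      effect = 0.95, seed = 7000 + i)
    d <- simulate_dataset(cfg)
    res <- score_alignment(d$alignment, build_pwm(d$alignment))
    V <- bm_covariance(d$tree)
    pool <- setdiff(seq_len(60), cfg$linked_columns)
    ok_var <- pool[apply(res[, pool, drop = FALSE], 2, var) > 0]
    # linked columns can be degenerate in score space: exactly collinear
    # (identical trait splits) or constant (balanced split with equal
    # backgrounds); compare on the informative patterns only, against a
    # decoy set of equal size
    cols_true <- cfg$linked_columns[
      apply(res[, cfg$linked_columns, drop = FALSE], 2, var) > 0]
    cols_true <- cols_true[!duplicated(t(res[, cols_true, drop = FALSE]))]
    decoy <- sample(ok_var, length(cols_true))
    a_true <- joint_model_fit(res, d$traits, V, cols_true)$aic
    a_dec <- joint_model_fit(res, d$traits, V, decoy)$aic
    if (a_true < a_dec) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("reference mapping skips gaps and preserves order", {
  aln <- aln_from_strings(c("ACDE", "A-CD"), ids = c("ref_full", "ref_gap"))
  sites <- data.frame(column = 1:4)
  m1 <- map_to_reference(sites, aln, "ref_full")
  expect_equal(m1$ref_residue, 1:4)
  expect_equal(m1$ref_symbol, c("A", "C", "D", "E"))

  m2 <- map_to_reference(sites, aln, "ref_gap")
  expect_equal(m2$ref_residue, c(1L, NA, 2L, 3L))
  expect_equal(m2$ref_symbol, c("A", "-", "C", "D"))

  expect_error(map_to_reference(sites, aln, "nope"), "not in alignment")

  # strict monotonicity over non-gap rows of random gapped references
  set.seed(79)
  for (i in 1:25) {
    L <- sample(10:40, 1)
    ref <- sample(c(RES_ALPHABET[1:20], "-"), L, replace = TRUE,
                  prob = c(rep(1, 20), 6))
    other <- sample(RES_ALPHABET[1:20], L, replace = TRUE)
    a <- new_alignment(rbind(ref, other), ids = c("r", "o"))
    mm <- map_to_reference(data.frame(column = 1:L), a, "r")
    nz <- !is.na(mm$ref_residue)
    expect_true(all(diff(mm$ref_residue[nz]) > 0))
    expect_equal(sum(nz), sum(ref != "-"))
  }
})
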