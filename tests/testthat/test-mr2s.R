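fixture_inputs <- function() {
  list(exposure = read_summary_stats_tsv(mr_fixture_path("mr_exposure_k3.tsv")),
       outcome = read_summary_stats_tsv(mr_fixture_path("mr_outcome_k3.tsv")),
       ld = read_ld_tsv(mr_fixture_path("mr_ld_k3.tsv")))
}

test_that("greedy clumping keeps the best of each LD clique", {
  st <- trait_summary_stats(c("a", "b", "c"), "6", c(1e6, 2e6, 3e6),
                            "A", "G", c(0.3, 0.25, 0.2),
                            c(0.05, 0.05, 0.05),
                            c(1e-10, 1e-8, 1e-6), 279)
  r <- matrix(c(1, sqrt(0.9), sqrt(0.1),
                sqrt(0.9), 1, sqrt(0.1),
                sqrt(0.1), sqrt(0.1), 1), 3)
  kept <- ld_clump(st, ld_matrix(c("a", "b", "c"), r), r2_max = 0.8)
  expect_identical(kept, c("a", "c"))

  # identity LD retains everything
  expect_identical(ld_clump(st, ld_matrix(c("a", "b", "c"), diag(3))),
                   st$id)

  # p-value ties break by position, then id
  st2 <- st; st2$p <- rep(1e-8, 3)
  kept2 <- ld_clump(st2, ld_matrix(c("a", "b", "c"), r), r2_max = 0.8)
  expect_identical(kept2, c("a", "c"))  # 'a' wins the tie by position

  expect_error(ld_clump(st, ld_matrix(c("a", "b"), diag(2))), "missing")
})

test_that("harmonization aligns alleles, strands and drops palindromes", {
  mk <- function(ids, ea, oa, beta) {
    trait_summary_stats(ids, "6", seq_along(ids) * 1000, ea, oa, beta,
                        rep(0.05, length(ids)), rep(1e-4, length(ids)),
                        200, rep(0.3, length(ids)))
  }
  ex <- mk(c("s1", "s2", "s3", "s4", "s5"), rep("A", 5),
           c("G", "G", "T", "G", "G"), c(0.3, 0.2, 0.4, 0.25, 0.15))
  ou <- mk(c("s1", "s2", "s3", "s4", "s5"),
           c("G", "T", "A", "A", "A"),
           c("A", "C", "T", "G", "C"),
           c(-0.2, 0.2, 0.5, 0.1, 0.2))
  ld <- ld_matrix(ex$id, diag(5))
  h <- harmonize(ex, ou, ld)
  v <- h$variants
  # s1: swapped alleles -> outcome beta negated
  expect_equal(v$beta_out[v$id == "s1"], 0.2)
  # s2: outcome on the other strand (T/C == A/G complemented) -> kept as-is
  expect_equal(v$beta_out[v$id == "s2"], 0.2)
  # s3: palindromic A/T -> dropped
  expect_false("s3" %in% v$id)
  expect_true("s3" %in% h$dropped$id)
  # s4: already aligned
  expect_equal(v$beta_out[v$id == "s4"], 0.1)
  # s5: A/C vs exposure A/G is irreconcilable
  expect_false("s5" %in% v$id)
  expect_match(h$dropped$reason[h$dropped$id == "s5"], "irreconcilable")

  # idempotence: re-harmonizing the aligned set changes nothing
  ex2 <- mk(v$id, v$effect_allele, v$other_allele, v$beta_exp)
  ou2 <- mk(v$id, v$effect_allele, v$other_allele, v$beta_out)
  h2 <- harmonize(ex2, ou2, ld_matrix(v$id, h$ld))
  expect_equal(h2$variants$beta_out, v$beta_out)
  expect_equal(h2$variants$beta_exp, v$beta_exp)

  expect_error(harmonize(ex[1:2, ], ou[1:2, ], ld), "fewer than 3")
})

test_that("orientation flips signs coherently and leaves Egger invariant", {
  # large cohorts so every sampled exposure beta stays positive
  ts <- sim_two_sample(0.4, k_variants = 12, n_exp = 5e4, n_out = 5e4,
                       seed = 61)
  h <- harmonize(ts$exposure, ts$outcome, ts$ld)
  expect_true(all(h$variants$beta_exp > 0))
  expect_identical(orient_positive(h)$variants, h$variants)

  # negate a subset of exposure rows: orientation must restore the fit
  hneg <- h
  flip <- c(2, 5, 9)
  hneg$variants$beta_exp[flip] <- -hneg$variants$beta_exp[flip]
  hneg$variants$beta_out[flip] <- -hneg$variants$beta_out[flip]
  s <- rep(1, 12); s[flip] <- -1
  hneg$ld <- hneg$ld * outer(s, s)
  hpos <- orient_positive(hneg)
  expect_true(all(hpos$variants$beta_exp > 0))
  expect_equal(abs(hpos$variants$beta_out), abs(h$variants$beta_out))
  e0 <- mr_egger_correlated(h)
  e1 <- mr_egger_correlated(hpos)
  expect_equal(e1$slope, e0$slope, tolerance = 1e-10)
  expect_equal(e1$slope_se, e0$slope_se, tolerance = 1e-10)
})

test_that("correlated Egger reduces to OLS under identity LD and equal SEs", {
  ts <- sim_two_sample(0.5, k_variants = 15, seed = 62)
  h <- orient_positive(harmonize(ts$exposure, ts$outcome, ts$ld))
  h$variants$se_out <- rep(0.04, 15)
  e <- mr_egger_correlated(h, "egger")
  ols <- stats::lm(h$variants$beta_out ~ h$variants$beta_exp)
  expect_equal(e$slope, unname(stats::coef(ols)[2]), tolerance = 1e-10)
  expect_equal(e$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-10)

  # IVW under identity LD equals the classical inverse-variance ratio
  ivw <- mr_egger_correlated(h, "ivw")
  w <- 1 / h$variants$se_out^2
  classical <- sum(w * h$variants$beta_exp * h$variants$beta_out) /
    sum(w * h$variants$beta_exp^2)
  expect_equal(ivw$slope, classical, tolerance = 1e-10)
  expect_error(pleiotropy_and_heterogeneity(ivw), "Egger")
})

test_that("the three-variant fixture matches a numeric minimization oracle", {
  fx <- fixture_inputs()
  h <- orient_positive(harmonize(fx$exposure, fx$outcome, fx$ld))
  e <- mr_egger_correlated(h, "egger")
  Omega <- outer(h$variants$se_out, h$variants$se_out) * h$ld
  qf <- function(th) {
    r <- h$variants$beta_out - th[1] - th[2] * h$variants$beta_exp
    drop(crossprod(r, solve(Omega, r)))
  }
  opt <- stats::optim(c(0, -1), qf, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 2000))
  expect_equal(e$intercept, opt$par[1], tolerance = 1e-8)
  expect_equal(e$slope, opt$par[2], tolerance = 1e-8)
  expect_equal(e$Q, opt$value, tolerance = 1e-8)
})

test_that("exact linear data give zero heterogeneity", {
  fx <- fixture_inputs()
  h <- orient_positive(harmonize(fx$exposure, fx$outcome, fx$ld))
  h$variants$beta_out <- 0.1 - 2 * h$variants$beta_exp
  e <- mr_egger_correlated(h, "egger")
  expect_equal(e$Q, 0, tolerance = 1e-20)
  expect_equal(e$Q_p, 1)
  expect_equal(e$slope, -2, tolerance = 1e-10)
  ph <- pleiotropy_and_heterogeneity(e)
  expect_match(ph$Q_label, "no evidence")
})

test_that("Egger slope transforms correctly under exposure unit changes", {
  ts <- sim_two_sample(0.5, k_variants = 20, seed = 63)
  h <- orient_positive(harmonize(ts$exposure, ts$outcome, ts$ld))
  e0 <- mr_egger_correlated(h)
  h2 <- h
  h2$variants$beta_exp <- 3 * h2$variants$beta_exp
  e2 <- mr_egger_correlated(h2)
  expect_equal(e2$slope, e0$slope / 3, tolerance = 1e-10)
  expect_equal(e2$slope_p, e0$slope_p, tolerance = 1e-10)
  expect_equal(e2$intercept, e0$intercept, tolerance = 1e-10)
})

test_that("the intercept test detects directional pleiotropy", {
  rej <- vapply(1:60, function(s) {
    ts <- sim_two_sample(0.3, k_variants = 50, n_exp = 2e5, n_out = 1e5,
                         pleiotropy = list(type = "directional",
                                           mean = 0.1, sd = 0.05),
                         seed = 700 + s)
    h <- orient_positive(harmonize(ts$exposure, ts$outcome, ts$ld))
    mr_egger_correlated(h)$intercept_p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.8)

  # balanced pleiotropy: rejection stays near the nominal level
  rej0 <- vapply(1:200, function(s) {
    ts <- sim_two_sample(0.3, k_variants = 50, n_exp = 2e5, n_out = 1e5,
                         pleiotropy = list(type = "balanced", sd = 0.02),
                         seed = 900 + s)
    h <- orient_positive(harmonize(ts$exposure, ts$outcome, ts$ld))
    mr_egger_correlated(h)$intercept_p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej0) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("Steiger matches the Fisher-z arithmetic oracle", {
  st <- steiger_from_r(0.5, 0.1, 1000, 1000)
  oracle <- (atanh(0.5) - atanh(0.1)) / sqrt(2 / 997)
  expect_equal(st$z_stat, oracle, tolerance = 1e-10)
  expect_identical(st$inferred_direction, "exposure->outcome")

  # symmetry and antisymmetry
  same <- steiger_from_r(0.3, 0.3, 500, 500)
  expect_equal(same$z_stat, 0)
  expect_equal(same$p, 1)
  fwd <- steiger_from_r(0.4, 0.2, 800, 400)
  rev <- steiger_from_r(0.2, 0.4, 400, 800)
  expect_equal(rev$z_stat, -fwd$z_stat)
  expect_identical(rev$inferred_direction, "outcome->exposure")

  # beta/se interface agrees with the correlation interface: with se = 1
  # the beta is the t statistic, so r2 = t^2 / (t^2 + n - 2)
  n <- 1000
  t_of <- function(r) r * sqrt((n - 2) / (1 - r^2))
  via_stats <- steiger_direction(t_of(0.5), 1, n, t_of(0.1), 1, n)
  expect_equal(via_stats$r2_exposure, 0.25, tolerance = 1e-10)
  expect_equal(via_stats$z_stat, st$z_stat, tolerance = 1e-10)

  expect_warning(steiger_from_r(1.2, 0.1, 100, 100), "capped")
  expect_error(steiger_from_r(0.5, 0.1, 3, 100), "exceed 3")
})

test_that("the reliability ratio integrates the grid as specified", {
  # dominant direction: no cell reverses, sentinel + flag
  dom <- steiger_reliability(0.5, 0.1)
  expect_true(dom$all_concordant)
  expect_equal(dom$R, 1e6)
  expect_equal(dom$n_neg, 0L)

  # equal correlations: perfect symmetry, R = 1
  sym <- steiger_reliability(0.3, 0.3)
  expect_equal(sym$R, 1, tolerance = 1e-12)

  # grid refinement changes R by < 5%
  coarse <- steiger_reliability(0.30, 0.25, ngrid = 50)
  fine <- steiger_reliability(0.30, 0.25, ngrid = 500)
  expect_lt(abs(coarse$R - fine$R) / fine$R, 0.05)
  expect_gt(coarse$R, 1)  # exposure direction favoured

  expect_error(steiger_reliability(0.3, 0.2, lower = 0), "lower")
})
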