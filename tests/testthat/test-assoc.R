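test_that("genotype coding matches the carrier definitions", {
  expect_equal(code_genotype(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(code_genotype(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(code_genotype(c(0, 1, 2), "recessive"), c(0, 0, 1))
  # imputed dosages round to the nearest genotype
  expect_equal(code_genotype(c(0.4, 0.6, 1.4, 1.6), "dominant"),
               c(0, 1, 1, 1))
  expect_equal(code_genotype(c(0.4, 0.6, 1.4, 1.6), "recessive"),
               c(0, 0, 0, 1))
  expect_error(code_genotype(1, "epistatic"), "arg")
  expect_error(code_genotype(3, "additive"), "0, 2")
})

test_that("qtl_scan recovers exact fits and flags monomorphic variants", {
  set.seed(2)
  d <- matrix(sample(0:2, 30, replace = TRUE), 30, 1)
  g <- tiny_geno(d)
  out <- qtl_scan(matrix(d, ncol = 1, dimnames = list(NULL, "m")), g)
  expect_equal(out$beta, 1, tolerance = 1e-12)
  expect_lt(out$p, 1e-200)

  g2 <- tiny_geno(cbind(d, 1))  # second variant monomorphic
  out2 <- qtl_scan(matrix(rnorm(30), ncol = 1), g2)
  expect_true(is.na(out2$beta[2]))
  expect_equal(out2$p[2], 1)
})

test_that("qtl_scan p-values are uniform under the null", {
  set.seed(3)
  n <- 300
  g <- tiny_geno(matrix(rbinom(n * 50, 2, 0.3), n, 50))
  Y <- matrix(rnorm(n * 40), n, 40)
  res <- qtl_scan(Y, g)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted meQTL effects clear the study-wide threshold", {
  # a 0.5 SD/allele effect at n = 279 has its median p at the 1.20e-8
  # threshold (ncp ~ 5.9 vs critical t ~ 5.8), so the hit rate is tested
  # against 0.5 minus its own 99% Monte-Carlo margin
  thr <- bonferroni_threshold(0.05, 7, 594262)
  n_rep <- 200
  hits <- vapply(seq_len(n_rep), function(s) {
    co <- sim_cohort("mediation", 279, seed = 4000 + s, n_probes = 20,
                     planted_dmr = 5:8)
    m <- rowMeans(co$meth$betas[, 5:8])
    res <- qtl_scan(matrix(m, ncol = 1),
                    methmediate:::subset_genotypes(co$geno, "rs_drv"))
    res$p < thr
  }, TRUE)
  expect_gte(mean(hits), 0.5 - 2.58 * sqrt(0.25 / n_rep))
})

test_that("bonferroni threshold reproduces the printed study value", {
  expect_equal(signif(bonferroni_threshold(0.05, 7, 594262), 3), 1.2e-08)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 2, 5), 1e-3)
  expect_error(bonferroni_threshold(0, 1, 1), "positive")
})

test_that("logistic scans are calibrated and consistent", {
  set.seed(5)
  n <- 2000
  # type-I rate within binomial 99% bounds of 0.05 over 1500 null variants
  g <- tiny_geno(matrix(rbinom(n * 1500, 2, 0.3), n, 1500))
  pheno <- phenotype_table(g$sample_ids, rbinom(n, 1, 0.5))
  res <- logistic_assoc_scan(pheno, g)
  expect_true(all(res$stat >= 0))
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 1500))

  # a planted log-OR of 1 at maf 0.3 is estimated consistently
  betas <- vapply(1:25, function(s) {
    set.seed(100 + s)
    gg <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, stats::plogis(-0.6 + gg))
    gt <- tiny_geno(matrix(gg, ncol = 1))
    logistic_assoc_scan(phenotype_table(gt$sample_ids, y), gt)$beta
  }, 0)
  expect_lt(abs(stats::median(betas) - 1), 0.15)
})

test_that("maxT adjustment dominates per-variant permutation p-values", {
  co <- cached_cohort("independent", 300, 101)
  sub <- methmediate:::subset_genotypes(co$geno,
                                        co$geno$variants$id[c(1, 5, 21)])
  mt <- maxt_adjust(co$pheno, sub, n_perm = 200, seed = 11)
  expect_true(all(mt$p_adj >= mt$p_raw))

  # single variant: the max over one statistic is itself
  one <- methmediate:::subset_genotypes(co$geno, "rs_drv")
  mt1 <- maxt_adjust(co$pheno, one, n_perm = 200, seed = 12)
  expect_identical(mt1$p_adj, mt1$p_raw)

  # duplicated variant columns receive identical adjusted p-values
  dup <- co$geno
  dup$variants <- dup$variants[c(1, 1), ]
  dup$variants$id <- c("a", "b")
  dup$dosages <- dup$dosages[, c(1, 1)]
  colnames(dup$dosages) <- c("a", "b")
  mt2 <- maxt_adjust(co$pheno, dup, n_perm = 150, seed = 13)
  expect_equal(mt2$p_adj[1], mt2$p_adj[2])

  # p_adj is rarely smaller than the asymptotic p under the null
  null_g <- tiny_geno(matrix(rbinom(200 * 20, 2, 0.4), 200, 20))
  null_ph <- phenotype_table(null_g$sample_ids,
                             rep(c(0L, 1L), each = 100))
  mtn <- maxt_adjust(null_ph, null_g, n_perm = 200, seed = 14)
  asym <- logistic_assoc_scan(null_ph, null_g)
  expect_lte(mean(mtn$p_adj < asym$p), 0.02)
})

test_that("conditioning on the causal driver removes a proxy's signal", {
  specs <- tiny_variants(2, maf = 0.4)
  blocks <- data.frame(start = 1, end = 2, r = 0.9)  # r^2 ~ 0.8 proxy
  ps <- vapply(1:11, function(s) {
    g <- sim_genotypes(4000, specs, blocks, seed = 300 + s)
    drv <- g$dosages[, 1]
    withr::with_seed(400 + s, {
      y <- rbinom(4000, 1, stats::plogis(-0.4 + drv))
    })
    ph <- phenotype_table(g$sample_ids, y)
    proxy <- methmediate:::subset_genotypes(g, "v02")
    uncond <- logistic_assoc_scan(ph, proxy)$p
    cond <- conditional_scan(ph, proxy,
                             condition_design = cbind(driver = drv))$p
    c(uncond, cond)
  }, c(0, 0))
  expect_lt(stats::median(ps[1, ]), 1e-6)
  expect_gt(stats::median(ps[2, ]), 0.05)
})

test_that("conditional_scan reduces to the unconditional scan and flags", {
  co <- cached_cohort("independent", 300, 101)
  sub <- methmediate:::subset_genotypes(co$geno,
                                        co$geno$variants$id[1:4])
  plain <- logistic_assoc_scan(co$pheno, sub)
  cond <- conditional_scan(co$pheno, sub, condition_design = NULL)
  expect_equal(cond$beta, plain$beta, tolerance = 1e-12)
  expect_equal(cond$p, plain$p, tolerance = 1e-12)

  # collinear condition column is flagged, not fitted
  cd <- cbind(self = sub$dosages[, 1])
  first <- methmediate:::subset_genotypes(sub, sub$variants$id[1])
  flagged <- conditional_scan(co$pheno, first, condition_design = cd)
  expect_true(is.na(flagged$beta))
  expect_match(flagged$reason, "collinear")

  # conditioning on an independent covariate barely moves the estimate
  set.seed(21)
  indep <- cbind(z = rnorm(300))
  cond2 <- conditional_scan(co$pheno, sub, condition_design = indep)
  expect_lt(max(abs(cond2$beta - plain$beta)), 0.1)
})

test_that("hla_condition_design builds presence/homozygote/interactions", {
  ad <- cbind(DRB1_1501 = c(0, 1, 2), DQB1_0302 = c(2, 0, 1))
  d <- hla_condition_design(ad, homozygote = "DRB1_1501",
                            interactions = list(c("DRB1_1501", "DQB1_0302")))
  expect_equal(unname(d[, "DRB1_1501_presence"]), c(0, 1, 1))
  expect_equal(unname(d[, "DRB1_1501_homozygote"]), c(0, 0, 1))
  expect_equal(unname(d[, "DRB1_1501_x_DQB1_0302"]), c(0, 0, 1))
})

test_that("genomic control clamps deflation and matches the null", {
  x <- rep(stats::qchisq(0.5, 1), 5)
  gc <- genomic_control(x)
  expect_equal(gc$lambda, 1)
  expect_equal(gc$chi2_corrected, x)

  withr::with_seed(31, {
    chi <- stats::rchisq(1e5, 1)
  })
  gcn <- genomic_control(chi)
  expect_equal(gcn$lambda, 1, tolerance = 0.01)

  # lambda < 1: p-values untouched
  gcd <- genomic_control(c(0.01, 0.02, 0.03))
  expect_lt(gcd$lambda, 1)
  expect_equal(gcd$chi2_corrected, c(0.01, 0.02, 0.03))
  expect_error(genomic_control(numeric()), "empty")
})

test_that("meta-analysis matches closed forms and the DL reference", {
  m <- meta_analyze(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(m$fixed_beta, 0.5)
  expect_equal(m$fixed_se, 0.1 / sqrt(2))
  expect_equal(m$Q, 0)
  expect_equal(m$tau2, 0)
  expect_equal(m$random_beta, m$fixed_beta)
  expect_equal(m$random_se, m$fixed_se)

  # independent implementation check
  b <- c(0.4, 0.9, 0.2, 0.6); s <- c(0.1, 0.2, 0.15, 0.12)
  m2 <- meta_analyze(b, s)
  rf <- metafor::rma(yi = b, sei = s, method = "DL")
  ff <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m2$fixed_beta, as.numeric(ff$beta), tolerance = 1e-10)
  expect_equal(m2$fixed_se, ff$se, tolerance = 1e-10)
  expect_equal(m2$random_beta, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(m2$tau2, rf$tau2, tolerance = 1e-10)
  expect_equal(m2$Q, rf$QE, tolerance = 1e-10)
  expect_equal(m2$I2, rf$I2 / 100, tolerance = 1e-6)

  # fixed effect lies within the study range; Q <= df forces random = fixed
  withr::with_seed(41, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      bb <- rnorm(k); ss <- runif(k, 0.05, 0.3)
      mm <- meta_analyze(bb, ss)
      expect_gte(mm$fixed_beta, min(bb))
      expect_lte(mm$fixed_beta, max(bb))
      if (mm$Q <= mm$df) expect_identical(mm$random_beta, mm$fixed_beta)
    }
  })
  expect_error(meta_analyze(0.5, 0.1), ">= 2")
})

test_that("fixed-effects confidence intervals attain nominal coverage", {
  withr::with_seed(51, {
    cover <- vapply(1:1000, function(i) {
      ss <- runif(4, 0.05, 0.2)
      bb <- rnorm(4, 0.3, ss)
      m <- meta_analyze(bb, ss)
      abs(m$fixed_beta - 0.3) <= 1.96 * m$fixed_se
    }, TRUE)
  })
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("additive coding is most powerful for additive effects", {
  ps <- vapply(1:40, function(s) {
    withr::with_seed(600 + s, {
      g <- rbinom(800, 2, 0.3)
      m <- 0.3 * g + rnorm(800)
    })
    gt <- tiny_geno(matrix(g, ncol = 1))
    vapply(c("additive", "dominant", "recessive"), function(md) {
      qtl_scan(matrix(m, ncol = 1), gt, model = md)$p
    }, 0)
  }, c(additive = 0, dominant = 0, recessive = 0))
  expect_lt(stats::median(ps["additive", ]),
            stats::median(ps["dominant", ]))
  expect_lt(stats::median(ps["additive", ]),
            stats::median(ps["recessive", ]))
})
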