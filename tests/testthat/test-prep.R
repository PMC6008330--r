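test_that("probe clustering follows the gap and annotation rules", {
  p <- probe_records(c("a", "b", "c"), "1", c(100, 200, 900))
  cl <- cluster_probes(p, max_gap_bp = 500)
  expect_length(cl, 2)
  expect_identical(cl[[1]]$member_probe_ids, c("a", "b"))
  expect_identical(cl[[2]]$member_probe_ids, "c")
  expect_equal(cl[[1]]$start, 100)
  expect_equal(cl[[1]]$end, 200)

  # isolated probes become singletons
  iso <- probe_records(letters[1:4], "1", c(0, 1000, 2000, 3000) + 1)
  expect_length(cluster_probes(iso, max_gap_bp = 500), 4)

  # island-annotation change splits even at tiny gaps
  ann <- probe_records(c("a", "b"), "1", c(100, 110),
                       c("island", "shore"))
  expect_length(cluster_probes(ann, 500, use_island_annotation = TRUE), 2)
  expect_length(cluster_probes(ann, 500, use_island_annotation = FALSE), 1)

  # unsorted input is sorted; chromosomes never share clusters
  mix <- probe_records(c("a", "b", "c"), c("2", "1", "1"), c(100, 300, 100))
  cl2 <- cluster_probes(mix, 500)
  expect_length(cl2, 2)
  expect_identical(cl2[[1]]$member_probe_ids, c("c", "b"))
})

test_that("region collapsing averages members and conserves probes", {
  b <- rbind(c(0.2, 0.4, 0.9), c(0.1, 0.3, 0.8))
  meth <- tiny_meth(b, pos = c(100, 200, 900))
  cl <- cluster_probes(meth$probes, 500)
  col <- collapse_regions(meth, cl)
  expect_equal(unname(col$betas[1, 1]), 0.3)
  expect_equal(unname(col$betas[, 2]), c(0.9, 0.8))
  expect_equal(ncol(col$betas), length(cl))

  # member order is irrelevant
  cl_rev <- cl
  cl_rev[[1]]$member_probe_ids <- rev(cl_rev[[1]]$member_probe_ids)
  expect_equal(collapse_regions(meth, cl_rev)$betas, col$betas)

  cl_bad <- cl
  cl_bad[[1]]$member_probe_ids <- c("cg001", "nope")
  expect_error(collapse_regions(meth, cl_bad), "nope")
})

test_that("cell deconvolution recovers pure and convex mixtures", {
  panel <- sim_cell_reference(sprintf("p%03d", 1:60),
                              cell_types = c("A", "B"), seed = 5)
  ref <- panel$reference_betas
  # a sample equal to a pure column -> indicator fractions
  meth <- methylation_table("s1", probe_records(panel$probe_ids, "1", 1:60),
                            matrix(ref[, "A"], 1))
  fr <- estimate_cell_fractions(meth, panel)
  expect_equal(unname(fr$fractions[1, ]), c(1, 0), tolerance = 1e-8)

  # exact convex recovery of a 0.3/0.7 mixture
  mix <- matrix(0.3 * ref[, 1] + 0.7 * ref[, 2], 1)
  fr2 <- estimate_cell_fractions(
    methylation_table("s1", probe_records(panel$probe_ids, "1", 1:60), mix),
    panel, normalize = TRUE)
  expect_equal(unname(fr2$fractions[1, ]), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("deconvolution under noise keeps RMSE small and rows sum to one", {
  set.seed(9)
  panel <- sim_cell_reference(sprintf("p%03d", 1:200), seed = 10)
  W <- methmediate:::rdirichlet(40, c(6, 3, 2, 1.5, 1, 1.5))
  mix <- W %*% t(panel$reference_betas)
  noisy <- clamp <- pmin(pmax(mix + matrix(stats::rnorm(40 * 200, 0, 0.05),
                                           40), 0), 1)
  meth <- methylation_table(sprintf("s%02d", 1:40),
                            probe_records(panel$probe_ids, "1", 1:200),
                            noisy)
  fr <- estimate_cell_fractions(meth, panel, normalize = TRUE)
  expect_lt(sqrt(mean((fr$fractions - W)^2)), 0.05)
  expect_lt(max(abs(rowSums(fr$fractions) - 1)), 1e-8)
})

test_that("deconvolution objective beats random feasible points", {
  set.seed(12)
  panel <- sim_cell_reference(sprintf("p%03d", 1:80), seed = 13)
  W <- methmediate:::rdirichlet(1, rep(2, 6))
  b <- drop(W %*% t(panel$reference_betas)) + stats::rnorm(80, 0, 0.05)
  b <- pmin(pmax(b, 0), 1)
  meth <- methylation_table("s1", probe_records(panel$probe_ids, "1", 1:80),
                            matrix(b, 1))
  fr <- estimate_cell_fractions(meth, panel)
  obj <- function(w) sum((b - panel$reference_betas %*% w)^2)
  best <- obj(fr$fractions[1, ])
  rand <- replicate(1000, obj(drop(methmediate:::rdirichlet(1, rep(1, 6)))))
  expect_true(all(best <= rand + 1e-12))
})

test_that("rank-deficient panels are rejected with the collinear types", {
  ref <- matrix(runif(40), 20, 2)
  panel <- cell_reference_panel(sprintf("p%02d", 1:20), c("X", "Y", "Ycopy"),
                                cbind(ref, ref[, 2]))
  meth <- methylation_table("s1", probe_records(panel$probe_ids, "1", 1:20),
                            matrix(runif(20), 1))
  expect_error(estimate_cell_fractions(meth, panel), "collinear")
})

test_that("cell-fraction PCs are orthogonal, ordered and reconstructive", {
  set.seed(20)
  fr <- structure(list(sample_ids = sprintf("s%02d", 1:30),
                       cell_types = c("A", "B", "C", "D"),
                       fractions = methmediate:::rdirichlet(30, c(4, 3, 2, 1))),
                  class = "cell_fractions")
  pcs <- cell_fraction_pcs(fr, 2)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-8)
  ve <- attr(pcs, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))

  # SVD identity: full reconstruction equals the centered input
  sv <- attr(pcs, "svd")
  X <- scale(fr$fractions, center = TRUE, scale = FALSE)
  expect_lt(max(abs(sv$u %*% diag(sv$d) %*% t(sv$v) - X)), 1e-8)

  # two perfectly anticorrelated types: PC1 captures ~all variance
  fr2 <- structure(list(sample_ids = sprintf("s%02d", 1:20),
                        cell_types = c("A", "B"),
                        fractions = cbind(A = runif(20))),
                   class = "cell_fractions")
  fr2$fractions <- cbind(fr2$fractions, B = 1 - fr2$fractions[, 1])
  pc1 <- cell_fraction_pcs(fr2, 1)
  expect_gt(attr(pc1, "var_explained")[1], 1 - 1e-10)

  # duplicated rows give duplicated scores
  fr3 <- fr
  fr3$fractions <- fr$fractions[c(1, 1, 2:29), ]
  pcs3 <- cell_fraction_pcs(fr3, 2)
  expect_equal(pcs3[1, ], pcs3[2, ], tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(cell_fraction_pcs(fr, 0), "n_pc")
  expect_error(cell_fraction_pcs(fr, 4), "n_pc")
})
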