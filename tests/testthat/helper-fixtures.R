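# shared builders for small in-code fixtures

tiny_variants <- function(k, maf = 0.3, chrom = "6", alleles = c("A", "G")) {
  variant_records(sprintf("v%02d", seq_len(k)), chrom,
                  1000L * seq_len(k), alleles[1], alleles[2],
                  rep(maf, length.out = k))
}

tiny_geno <- function(dosages, maf = 0.3) {
  dosages <- as.matrix(dosages)
  genotype_table(sprintf("s%03d", seq_len(nrow(dosages))),
                 tiny_variants(ncol(dosages), maf), dosages)
}

tiny_meth <- function(betas, pos = NULL, relation = "open_sea") {
  betas <- as.matrix(betas)
  k <- ncol(betas)
  methylation_table(sprintf("s%03d", seq_len(nrow(betas))),
                    probe_records(sprintf("cg%03d", seq_len(k)), "6",
                                  pos %||% (100L * seq_len(k)), relation),
                    betas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised cohorts: several test files reuse the same simulated datasets
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(scenario, n, seed, ...) {
  extra <- unlist(list(...))
  key <- paste(c(scenario, n, seed, names(extra), extra), collapse = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- sim_cohort(scenario, n, seed = seed, ...)
  .cohort_cache[[key]]
}

# DMR pipeline stage shared by the dmr tests and the acceptance suite:
# returns the significant regions and the best Jaccard overlap with the
# planted probe set
dmr_stage <- function(cohort, n_resamples = 200, seed = 1,
                      fwer_max = 0.05) {
  cl <- cluster_probes(cohort$meth$probes)
  idx <- probe_cluster_index(cl, cohort$meth$probes$id)
  pheno <- cohort$pheno
  pc <- probe_coefficients(cohort$meth, pheno, colnames(pheno$covariates))
  cand <- find_candidate_regions(pc$coef, idx, exclude = pc$constant)
  res <- dmr_fwer(cohort$meth, pheno, colnames(pheno$covariates), idx,
                  cand, n_resamples = n_resamples, seed = seed)
  planted <- cohort$meth$probes$id[cohort$truth$planted_dmr]
  jac <- 0
  sig <- res[res$fwer < fwer_max, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    ids <- strsplit(sig$probe_ids[i], ",")[[1]]
    j <- length(intersect(ids, planted)) / length(union(ids, planted))
    jac <- max(jac, j)
  }
  list(dmrs = res, sig = sig, jaccard = jac,
       n_sig = nrow(sig), candidates = cand)
}

# one CIT replicate on the cohort's planted pair
cit_replicate <- function(scenario, seed, n = 500, profile = "standard",
                          n_perm = 150) {
  co <- sim_cohort(scenario, n, seed = seed, effect_profile = profile)
  g <- co$geno$dosages[, co$truth$driver_variant]
  m <- rowMeans(co$meth$betas[, co$truth$planted_dmr, drop = FALSE])
  cit_classify(g, m, co$pheno$status, n_perm = n_perm, seed = seed + 1)
}

mr_fixture_path <- function(f) {
  system.file("extdata", f, package = "methmediate", mustWork = TRUE)
}
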