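#' Pipeline configuration
#'
#' Collects every stage threshold and seed of the end-to-end mediation
#' analysis. Thresholds default to the conventional values: DMR FWER 0.05
#' with the resampling count configurable, Bonferroni 0.05 over the
#' (regions x variants) meQTL family, maxT 0.05, CIT alpha 0.05, clumping
#' r2 0.8 in a 10,000 kb window.
#'
#' @param scenario simulated scenario (see [sim_truth()]).
#' @param n_samples cohort size.
#' @param seed master seed; stage seeds derive from it and are recorded in
#'   the output manifest.
#' @param effect_profile passed to [sim_cohort()].
#' @param path_effects optional overrides passed to [sim_cohort()].
#' @param dmr_fwer_max,meqtl_alpha,maxt_alpha,cit_alpha stage thresholds.
#' @param clump_r2,clump_window_kb clumping parameters.
#' @param n_resamples DMR label permutations.
#' @param n_perm_maxt,n_perm_cit permutation counts of the maxT and CIT
#'   stages.
#' @param cutoff_quantile,min_probes bump-hunting parameters.
#' @param n_cell_pc number of cell-fraction PCs used as covariates.
#' @param run_conditional,run_meta toggle the optional closing stages.
#' @param out_dir `NULL` (no files) or a directory for per-stage TSVs and
#'   the JSON manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = "mediation", n_samples = 500,
                            seed = 1L, effect_profile = "standard",
                            path_effects = NULL,
                            dmr_fwer_max = 0.05, meqtl_alpha = 0.05,
                            maxt_alpha = 0.05, cit_alpha = 0.05,
                            clump_r2 = 0.8, clump_window_kb = 10000,
                            n_resamples = 1000, n_perm_maxt = 1000,
                            n_perm_cit = 1000, cutoff_quantile = 0.975,
                            min_probes = 2, n_cell_pc = 2,
                            run_conditional = TRUE, run_meta = TRUE,
                            out_dir = NULL) {
  stopifnot(dmr_fwer_max > 0, dmr_fwer_max <= 1, meqtl_alpha > 0,
            maxt_alpha > 0, cit_alpha > 0, clump_r2 > 0, clump_r2 <= 1,
            n_resamples >= 100, n_perm_maxt >= 100, n_perm_cit >= 100)
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_covariates <- function(pheno, pcs) {
  cbind(as.matrix(pheno$covariates[, c("age", "sex", "smoking", "batch")]),
        pcs)
}

#' Run the end-to-end mediation pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, probe clustering and region
#' collapsing, cell-fraction estimation with PC covariates, bump-hunting
#' DMR detection with permutation FWER, meQTL scanning of the significant
#' regions with a Bonferroni filter, case-control association of the meQTL
#' variants with maxT adjustment, CIT classification of every surviving
#' (variant, region) pair, two-sample MR (Egger with the cohort LD matrix,
#' after clumping) of region methylation on expression, and optionally a
#' conditional scan on the driver haplotype plus a two-cohort split
#' meta-analysis. Emits per-stage tables, a manifest with the filter-funnel
#' counts (monotone non-increasing along the variant chain), and the seeds
#' needed to reproduce the run bitwise.
#'
#' @param config a [pipeline_config()].
#' @return list with the per-stage results and `manifest`.
#' @export
run_mediation_pipeline <- function(config) {
  cfg <- config
  seed <- as.integer(cfg$seed)
  stage_seed <- function(k) {
    as.integer((as.double(seed) * 101 + k * 7919) %% 2000003)
  }
  log_msg <- function(...) message("[methmediate] ", ...)

  log_msg("simulate: scenario=", cfg$scenario, " n=", cfg$n_samples,
          " seed=", seed)
  cohort <- sim_cohort(cfg$scenario, cfg$n_samples, seed = seed,
                       effect_profile = cfg$effect_profile,
                       path_effects = cfg$path_effects)
  geno <- cohort$geno; meth <- cohort$meth; pheno <- cohort$pheno

  # collapse + cell fractions
  clusters <- cluster_probes(meth$probes)
  cl_idx <- probe_cluster_index(clusters, meth$probes$id)
  collapsed <- collapse_regions(meth, clusters)
  fracs <- estimate_cell_fractions(meth, cohort$panel, normalize = TRUE)
  pcs <- cell_fraction_pcs(fracs, cfg$n_cell_pc)
  covs <- pipeline_covariates(pheno, pcs)

  # DMR stage
  pheno_cov <- phenotype_table(pheno$sample_ids, pheno$status,
                               as.data.frame(covs))
  cov_names <- colnames(covs)
  pc <- probe_coefficients(meth, pheno_cov, cov_names)
  cand <- find_candidate_regions(pc$coef, cl_idx, cfg$cutoff_quantile,
                                 cfg$min_probes, exclude = pc$constant)
  dmrs <- dmr_fwer(meth, pheno_cov, cov_names, cl_idx, cand,
                   n_resamples = cfg$n_resamples,
                   min_probes = cfg$min_probes, seed = stage_seed(1L))
  sig_dmrs <- dmrs[dmrs$fwer < cfg$dmr_fwer_max, , drop = FALSE]
  log_msg("dmr: ", nrow(cand), " candidates, ", nrow(sig_dmrs),
          " significant at FWER < ", cfg$dmr_fwer_max)

  result <- list(config = cfg, cohort = cohort, clusters = clusters,
                 collapsed = collapsed, cell_fractions = fracs,
                 dmrs = dmrs, sig_dmrs = sig_dmrs)
  manifest <- list(seed = seed,
                   stage_seeds = vapply(1:5, stage_seed, integer(1)),
                   scenario = cfg$scenario, n_samples = cfg$n_samples,
                   n_candidate_regions = nrow(cand),
                   n_dmrs = nrow(sig_dmrs),
                   n_meqtl_pairs = 0L, n_meqtl_snps = 0L,
                   n_assoc_snps = 0L, n_cit_significant = 0L,
                   cit_calls = character())

  if (nrow(sig_dmrs) == 0L) {
    result$manifest <- manifest
    return(finish_pipeline(result, cfg))
  }

  # DMR-level methylation: mean over each significant region's probes
  dmr_ids <- sprintf("DMR%d", seq_len(nrow(sig_dmrs)))
  dmr_meth <- vapply(seq_len(nrow(sig_dmrs)), function(i) {
    ids <- strsplit(sig_dmrs$probe_ids[i], ",")[[1]]
    rowMeans(meth$betas[, ids, drop = FALSE])
  }, numeric(length(meth$sample_ids)))
  colnames(dmr_meth) <- dmr_ids

  # meQTL stage with Bonferroni filter
  meqtl <- qtl_scan(dmr_meth, geno, covs, model = "additive")
  thr <- bonferroni_threshold(cfg$meqtl_alpha, ncol(dmr_meth),
                              nrow(geno$variants))
  sig_meqtl <- meqtl[!is.na(meqtl$p) & meqtl$p < thr, , drop = FALSE]
  meqtl_snps <- unique(sig_meqtl$variant_id)
  log_msg("meqtl: ", nrow(sig_meqtl), " significant pairs (",
          length(meqtl_snps), " SNPs) at p < ", signif(thr, 3))
  result$meqtl <- meqtl; result$sig_meqtl <- sig_meqtl
  manifest$n_meqtl_pairs <- nrow(sig_meqtl)
  manifest$n_meqtl_snps <- length(meqtl_snps)

  if (length(meqtl_snps) == 0L) {
    result$manifest <- manifest
    return(finish_pipeline(result, cfg))
  }

  # case-control association of meQTL SNPs with maxT adjustment
  sub <- subset_genotypes(geno, meqtl_snps)
  maxt <- maxt_adjust(pheno, sub, covs, n_perm = cfg$n_perm_maxt,
                      seed = stage_seed(2L))
  assoc_snps <- maxt$variant_id[maxt$p_adj < cfg$maxt_alpha]
  log_msg("assoc: ", length(assoc_snps), " SNPs at maxT p < ",
          cfg$maxt_alpha)
  result$maxt <- maxt
  manifest$n_assoc_snps <- length(assoc_snps)

  if (length(assoc_snps) == 0L) {
    result$manifest <- manifest
    return(finish_pipeline(result, cfg))
  }

  # CIT classification of surviving pairs
  pairs <- sig_meqtl[sig_meqtl$variant_id %in% assoc_snps,
                     c("variant_id", "outcome_id")]
  cits <- lapply(seq_len(nrow(pairs)), function(i) {
    v <- pairs$variant_id[i]; d <- pairs$outcome_id[i]
    cit_classify(geno$dosages[, v], dmr_meth[, d], pheno$status, covs,
                 alpha = cfg$cit_alpha, n_perm = cfg$n_perm_cit,
                 seed = stage_seed(3L) + i, variant_id = v, region_id = d)
  })
  cit_tab <- cit_results_table(cits)
  cit_sig <- cit_tab[!is.na(cit_tab$omnibus) &
                       cit_tab$omnibus < cfg$cit_alpha, , drop = FALSE]
  log_msg("cit: ", nrow(cit_sig), "/", nrow(cit_tab),
          " pairs significant; calls: ",
          paste(names(table(cit_tab$call)), table(cit_tab$call),
                sep = "=", collapse = ", "))
  result$cit <- cit_tab
  manifest$n_cit_significant <- length(unique(cit_sig$SNP))
  manifest$cit_calls <- cit_tab$call

  # MR stage: methylation (exposure) on expression (outcome), cohort LD
  top_dmr <- dmr_ids[which.max(tabulate(match(sig_meqtl$outcome_id, dmr_ids)))]
  mr_snps <- unique(sig_meqtl$variant_id[sig_meqtl$outcome_id == top_dmr])
  result$mr <- NULL
  if (length(mr_snps) >= 3) {
    sub2 <- subset_genotypes(geno, mr_snps)
    exp_stats <- scan_to_stats(
      qtl_scan(dmr_meth[, top_dmr, drop = FALSE], sub2, covs), sub2)
    out_stats <- scan_to_stats(
      qtl_scan(matrix(cohort$expr, ncol = 1,
                      dimnames = list(NULL, "expr")), sub2, covs), sub2)
    ld <- ld_matrix(mr_snps, stats::cor(sub2$dosages))
    kept <- ld_clump(exp_stats, ld, cfg$clump_r2, cfg$clump_window_kb * 1000)
    if (length(kept) >= 3) {
      h <- harmonize(exp_stats[exp_stats$id %in% kept, ],
                     out_stats[out_stats$id %in% kept, ],
                     ld_matrix(kept, ld$r[kept, kept, drop = FALSE]))
      h <- orient_positive(h)
      egger <- mr_egger_correlated(h, "egger")
      best <- which.min(exp_stats$p[match(kept, exp_stats$id)])
      bi <- match(kept[best], exp_stats$id)
      bo <- match(kept[best], out_stats$id)
      steiger <- steiger_direction(exp_stats$beta[bi], exp_stats$se[bi],
                                   exp_stats$n[bi], out_stats$beta[bo],
                                   out_stats$se[bo], out_stats$n[bo])
      result$mr <- list(egger = egger, steiger = steiger,
                        harmonized = h, dmr = top_dmr, snps = kept)
      log_msg("mr: egger slope ", signif(egger$slope, 4), " (p ",
              signif(egger$slope_p, 3), "), steiger ",
              steiger$inferred_direction)
    }
  }

  # optional conditional scan on the driver haplotype + split meta-analysis
  if (isTRUE(cfg$run_conditional)) {
    drv <- cohort$truth$driver_variant
    if (drv %in% colnames(geno$dosages)) {
      cond <- hla_condition_design(
        geno$dosages[, drv, drop = FALSE], homozygote = drv)
      others <- setdiff(meqtl_snps, drv)
      if (length(others)) {
        result$conditional <- conditional_scan(
          pheno, subset_genotypes(geno, others), cond, covs)
      }
    }
  }
  if (isTRUE(cfg$run_meta)) {
    half <- seq_len(floor(cfg$n_samples / 2))
    halves <- list(half, setdiff(seq_len(cfg$n_samples), half))
    top_snp <- maxt$variant_id[which.max(maxt$stat)]
    if (all(vapply(halves,
                   function(idx) length(unique(pheno$status[idx])) == 2,
                   TRUE))) {
      metas <- lapply(halves, function(idx) {
        logistic_assoc_scan(
          phenotype_table(pheno$sample_ids[idx], pheno$status[idx]),
          subset_genotypes(slice_samples(geno, idx), top_snp))
      })
      b <- vapply(metas, function(m) m$beta[1], 0)
      s <- vapply(metas, function(m) m$se[1], 0)
      if (all(is.finite(b)) && all(is.finite(s)) && all(s > 0)) {
        result$meta <- meta_analyze(b, s)
        result$meta_snp <- top_snp
      }
    }
  }

  result$manifest <- manifest
  finish_pipeline(result, cfg)
}

# subset a genotype table to named variants (order preserved as given)
subset_genotypes <- function(geno, ids) {
  j <- match(ids, geno$variants$id)
  if (anyNA(j)) stop_spec("unknown variant ids")
  genotype_table(geno$sample_ids, geno$variants[j, , drop = FALSE],
                 geno$dosages[, j, drop = FALSE])
}

slice_samples <- function(geno, idx) {
  genotype_table(geno$sample_ids[idx], geno$variants,
                 geno$dosages[idx, , drop = FALSE])
}

# convert a single-outcome qtl_scan result to trait summary statistics
scan_to_stats <- function(scan, geno) {
  j <- match(scan$variant_id, geno$variants$id)
  v <- geno$variants[j, ]
  trait_summary_stats(scan$variant_id, v$chrom, v$pos, v$effect_allele,
                      v$other_allele, scan$beta, scan$se, scan$p, scan$n,
                      clamp(colMeans(geno$dosages)[j] / 2, 1e-6, 1 - 1e-6))
}

# write per-stage TSVs and the JSON manifest when an output dir is set
finish_pipeline <- function(result, cfg) {
  m <- result$manifest
  chain <- c(m$n_meqtl_snps, m$n_assoc_snps, m$n_cit_significant)
  m$funnel_monotone <- all(diff(chain) <= 0)
  result$manifest <- m
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    tsv_write(result$dmrs, p("dmrs.tsv"))
    if (!is.null(result$meqtl)) tsv_write(result$meqtl, p("meqtl.tsv"))
    if (!is.null(result$maxt)) tsv_write(result$maxt, p("assoc_maxt.tsv"))
    if (!is.null(result$cit)) tsv_write(result$cit, p("cit.tsv"))
    if (!is.null(result$conditional))
      tsv_write(result$conditional, p("conditional.tsv"))
    if (!is.null(result$meta)) {
      mt <- result$meta
      tsv_write(data.frame(
        term = c(paste0("study", seq_along(mt$betas)), "fixed", "random"),
        beta = c(mt$betas, mt$fixed_beta, mt$random_beta),
        se = c(mt$ses, mt$fixed_se, mt$random_se)), p("meta.tsv"))
    }
    if (!is.null(result$mr)) {
      e <- result$mr$egger
      tsv_write(data.frame(term = c("slope", "intercept"),
                           estimate = c(e$slope, e$intercept),
                           se = c(e$slope_se, e$intercept_se),
                           p = c(e$slope_p, e$intercept_p)),
                p("mr_egger.tsv"))
    }
    write_sim_truth_json(result$cohort$truth, p("sim_truth.json"))
    jsonlite::write_json(m, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  result
}
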