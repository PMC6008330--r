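#' Synthetic cohorts with known causal structure
#'
#' The generators in this file emulate the data structure of a blood
#' methylation mediation study: diploid dosages with block LD around a risk
#' haplotype, a run of consecutive CpGs hypomethylated by the risk allele,
#' cell-composition mixtures confounding bulk methylation, a binary disease
#' phenotype generated under mediation / reverse-causation / independence,
#' and residualized expression negatively coupled to methylation. Every
#' generator is deterministic under a fixed `seed`.
#'
#' @name simcohort
NULL

#' Simulate genotype dosages with block LD
#'
#' Haplotypes are generated per LD block by a first-order copying process:
#' the first variant of a block is an independent Bernoulli draw at its
#' allele frequency and each subsequent variant is drawn conditionally on its
#' left neighbour so that the pairwise haplotype correlation of adjacent
#' variants matches the block's target `r`. Dosage is the sum of two
#' independent haplotypes, hence lies in \{0, 1, 2\}.
#'
#' @param n_samples number of individuals (>= 2).
#' @param variant_specs variant data frame from [variant_records()].
#' @param ld_blocks `NULL` (all variants independent) or a data frame with
#'   columns `start`, `end`, `r` giving variant-index ranges and the target
#'   adjacent-variant correlation within each block.
#' @param seed integer seed or `NULL`.
#' @return a [genotype_table()].
#' @export
sim_genotypes <- function(n_samples, variant_specs, ld_blocks = NULL,
                          seed = NULL) {
  if (n_samples < 2) stop_spec("n_samples must be >= 2")
  v <- variant_records(variant_specs$id, variant_specs$chrom,
                       variant_specs$pos, variant_specs$effect_allele,
                       variant_specs$other_allele, variant_specs$maf)
  m <- nrow(v)
  r_prev <- rep(0, m)
  if (!is.null(ld_blocks)) {
    for (b in seq_len(nrow(ld_blocks))) {
      s <- ld_blocks$start[b]; e <- ld_blocks$end[b]
      if (s < 1 || e > m || s > e) stop_spec("ld block indices out of range")
      if (abs(ld_blocks$r[b]) >= 1) stop_spec("|r| must be < 1")
      if (e > s) r_prev[(s + 1):e] <- ld_blocks$r[b]
    }
  }
  p <- v$maf
  dos <- maybe_seed(seed, {
    n_hap <- 2L * n_samples
    H <- matrix(0L, n_hap, m)
    for (j in seq_len(m)) {
      if (j == 1L || r_prev[j] == 0) {
        H[, j] <- stats::rbinom(n_hap, 1L, p[j])
      } else {
        x <- H[, j - 1L]
        p1 <- p[j - 1L]
        cv <- r_prev[j] * sqrt(p[j] * (1 - p[j]) * p1 * (1 - p1))
        pr <- clamp(p[j] + cv * (x - p1) / (p1 * (1 - p1)), 0, 1)
        H[, j] <- stats::rbinom(n_hap, 1L, pr)
      }
    }
    H[seq(1L, n_hap, 2L), , drop = FALSE] +
      H[seq(2L, n_hap, 2L), , drop = FALSE]
  })
  genotype_table(sprintf("S%04d", seq_len(n_samples)), v, dos)
}

#' Default variant panel around a risk haplotype
#'
#' Thirty variants on chromosome 6 in three ten-variant blocks. The first
#' block carries the causal driver (`rs_drv`, variant 5, allele frequency
#' 0.5) with adjacent-haplotype correlation 0.6; the second block has the
#' same LD but no effect; the third block is LD-free background. Alleles
#' are non-palindromic (A/G).
#'
#' @param n_variants total number of variants (multiple of 3 recommended).
#' @return list with elements `variant_specs`, `ld_blocks`, `driver_variant`.
#' @export
hla_variant_panel <- function(n_variants = 30) {
  k <- n_variants
  maf <- rep(seq(0.15, 0.5, length.out = 10), length.out = k)
  drv <- 5L
  maf[drv] <- 0.5
  specs <- variant_records(
    id = ifelse(seq_len(k) == drv, "rs_drv", sprintf("rs%04d", seq_len(k))),
    chrom = "6", pos = 32400000L + 5000L * seq_len(k),
    effect_allele = "A", other_allele = "G", maf = maf)
  b <- floor(k / 3)
  blocks <- data.frame(start = c(1L, b + 1L), end = c(b, 2L * b),
                       r = c(0.6, 0.6))
  list(variant_specs = specs, ld_blocks = blocks, driver_variant = "rs_drv")
}

#' Probe layout in island clusters
#'
#' `n_probes` CpG probes arranged in clusters of `probes_per_cluster`, with
#' 100 bp spacing inside a cluster and 10 kb gaps between clusters, all
#' annotated as island probes.
#'
#' @param n_probes total probe count.
#' @param probes_per_cluster probes per island cluster.
#' @param chrom,start genomic anchor of the layout.
#' @return probe data frame (see [probe_records()]).
#' @export
sim_probe_layout <- function(n_probes = 400, probes_per_cluster = 10,
                             chrom = "6", start = 32400000L) {
  idx <- seq_len(n_probes) - 1L
  cl <- idx %/% probes_per_cluster
  within <- idx %% probes_per_cluster
  probe_records(sprintf("cg%07d", seq_len(n_probes)), chrom,
                start + cl * 10000L + within * 100L, "island")
}

#' Reference methylation signatures for six blood cell types
#'
#' Cell-type specific beta values drawn once on the logit scale (sd 1.5
#' around a common probe baseline), mimicking the discriminating probes a
#' sorted-cell reference panel provides.
#'
#' @param probe_ids probe ids the panel covers.
#' @param cell_types names of the cell types.
#' @param seed integer seed.
#' @return a [cell_reference_panel()].
#' @export
sim_cell_reference <- function(probe_ids,
                               cell_types = c("Gran", "CD4T", "CD8T", "B",
                                              "NK", "Mono"),
                               seed = NULL) {
  np <- length(probe_ids); k <- length(cell_types)
  ref <- maybe_seed(seed, {
    base <- stats::rnorm(np, 0, 0.5)
    inv_logit(base + matrix(stats::rnorm(np * k, 0, 1.5), np, k))
  })
  cell_reference_panel(probe_ids, cell_types, ref)
}

# scenario presets: path effects in the units used by the generators
# (g_m: logit units per dosage; m_y, g_y: log-odds; y_m: logit shift for
# cases; m_expr: expression units per unit collapsed beta)
scenario_effects <- function(scenario, effect_profile) {
  strong <- identical(effect_profile, "strong")
  base <- c(g_m = 0, m_y = 0, g_y = 0, y_m = 0,
            conf_m = 0, conf_y = 0, m_expr = 5, g_expr = 0)
  eff <- switch(scenario,
    mediation = c(g_m = if (strong) -1 else -0.5,
                  m_y = if (strong) log(3) else log(2)),
    consequential = c(g_y = 1, y_m = -1),
    independent = c(g_m = -0.5, g_y = 0.5),
    confounded = c(conf_m = 0.5, conf_y = 0.5))
  base[names(eff)] <- eff
  base
}

#' Ground-truth specification for a simulated cohort
#'
#' Encodes which causal paths are active. The `mediation` scenario activates
#' G -> M -> Y (g_m = -0.5 logit per dosage, i.e. 0.5 SD of the planted-region
#' signal, and m_y = log 2 per SD); `effect_profile = "strong"` scales them to
#' the magnitude of a major HLA-class-II effect (1 SD, odds ratio 3).
#' `consequential` activates G -> Y -> M, `independent` G -> M and G -> Y
#' with no M-Y link (horizontal pleiotropy), and `confounded` leaks the batch
#' covariate into both M and Y.
#'
#' @param scenario one of mediation / consequential / independent / confounded.
#' @param n_probes number of probes in the layout.
#' @param planted_dmr integer probe indices of the planted region.
#' @param driver_variant id of the causal variant.
#' @param path_effects named numeric overrides of the scenario defaults.
#' @param cell_profiles list with `reference` (probes x types beta matrix) and
#'   `alpha` (Dirichlet concentration); built automatically when `NULL`.
#' @param effect_profile `"standard"` or `"strong"` (mediation only).
#' @param seed seed recorded with the truth and used for the reference panel.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(scenario = c("mediation", "consequential",
                                   "independent", "confounded"),
                      n_probes = 400, planted_dmr = 201:208,
                      driver_variant = "rs_drv", path_effects = NULL,
                      cell_profiles = NULL,
                      effect_profile = c("standard", "strong"),
                      seed = 1L) {
  scenario <- match.arg(scenario)
  effect_profile <- match.arg(effect_profile)
  if (any(planted_dmr < 1 | planted_dmr > n_probes))
    stop_spec("planted_dmr indices outside probe layout")
  eff <- scenario_effects(scenario, effect_profile)
  if (!is.null(path_effects)) {
    bad <- setdiff(names(path_effects), names(eff))
    if (length(bad)) stop_spec("unknown path effects: ", paste(bad, collapse = ", "))
    eff[names(path_effects)] <- path_effects
  }
  if (is.null(cell_profiles)) {
    ids <- sprintf("cg%07d", seq_len(n_probes))
    panel <- sim_cell_reference(ids, seed = seed)
    # whole-blood-like composition, granulocyte dominated
    alpha <- 60 * c(Gran = 0.55, CD4T = 0.15, CD8T = 0.1, B = 0.07,
                    NK = 0.05, Mono = 0.08)
    cell_profiles <- list(reference = panel$reference_betas, alpha = alpha)
  }
  w <- cell_profiles$alpha
  if (any(w <= 0)) stop_spec("Dirichlet concentrations must be positive")
  structure(list(scenario = scenario, path_effects = eff,
                 planted_dmr = as.integer(planted_dmr),
                 driver_variant = driver_variant,
                 cell_profiles = cell_profiles, seed = seed),
            class = "sim_truth")
}

driver_dosage <- function(geno, truth) {
  j <- match(truth$driver_variant, geno$variants$id)
  if (is.na(j)) stop_spec("driver variant '", truth$driver_variant,
                          "' not in genotype table")
  geno$dosages[, j]
}

#' Simulate methylation beta values
#'
#' Per-sample, per-probe signal on the logit scale: a cell-mixture baseline
#' (Dirichlet mixing weights over the reference profiles), plus, on the
#' planted-region probes only, a per-sample regional random effect
#' (`sample_sd`, inter-individual biological variability shared across the
#' region's probes), the genetic effect `g_m x dosage` at the driver variant,
#' and any extra shift supplied by the phenotype generator; plus independent
#' probe-level noise `noise_sd`. The result is mapped to \[0, 1\] by the
#' inverse logit.
#'
#' @param geno a [genotype_table()].
#' @param truth a [sim_truth()].
#' @param probe_layout probe data frame (see [sim_probe_layout()]).
#' @param noise_sd probe-level technical noise, logit scale (>= 0).
#' @param sample_sd regional biological variability, logit scale (>= 0).
#' @param extra_shift optional per-sample logit shift applied to the planted
#'   probes (used internally for reverse-causation and confounding).
#' @param seed integer seed or `NULL`.
#' @return a [methylation_table()] with the mixing weights in
#'   `attr(, "cell_weights")` and the generation parameters in `attr(, "gen")`.
#' @export
sim_methylation <- function(geno, truth, probe_layout, noise_sd = 0.1,
                            sample_sd = 1, extra_shift = NULL, seed = NULL) {
  if (noise_sd < 0) stop_spec("noise_sd must be >= 0")
  if (sample_sd < 0) stop_spec("sample_sd must be >= 0")
  np <- nrow(probe_layout)
  if (any(truth$planted_dmr > np))
    stop_spec("planted_dmr indices outside probe_layout")
  ref <- truth$cell_profiles$reference
  if (nrow(ref) != np) stop_spec("cell reference rows must match probes")
  n <- length(geno$sample_ids)
  dos <- driver_dosage(geno, truth)
  g_m <- truth$path_effects[["g_m"]]
  out <- maybe_seed(seed, {
    W <- rdirichlet(n, truth$cell_profiles$alpha)
    base <- W %*% t(ref)                       # n x probes, beta scale
    L <- logit(clamp(base, 1e-6, 1 - 1e-6))
    reg <- g_m * dos
    if (sample_sd > 0) reg <- reg + stats::rnorm(n, 0, sample_sd)
    if (!is.null(extra_shift)) reg <- reg + extra_shift
    L[, truth$planted_dmr] <- L[, truth$planted_dmr] + reg
    if (noise_sd > 0) L <- L + matrix(stats::rnorm(n * np, 0, noise_sd), n, np)
    list(betas = inv_logit(L), W = W)
  })
  meth <- methylation_table(geno$sample_ids, probe_layout, out$betas)
  attr(meth, "cell_weights") <- out$W
  attr(meth, "gen") <- list(noise_sd = noise_sd, sample_sd = sample_sd,
                            probe_layout = probe_layout)
  meth
}

collapsed_dmr_signal <- function(meth, truth) {
  rowMeans(meth$betas[, truth$planted_dmr, drop = FALSE])
}

#' Simulate the binary phenotype (and, where causal order demands,
#' regenerate methylation)
#'
#' Under `mediation`, disease status follows
#' `logit P(Y=1) = intercept + m_y * z(m_DMR)` where `m_DMR` is the
#' standardized collapsed beta of the planted region, which already carries
#' the genetic effect; Y is independent of G given M by construction. Under
#' `consequential`, status is drawn from the genotype first
#' (`intercept + g_y * dosage`) and methylation is regenerated with a
#' `y_m * Y` shift on the planted probes. Under `independent`, status depends
#' on genotype only (or on nothing when `g_y = 0`). Under `confounded`, the
#' batch covariate is leaked into both methylation and status.
#'
#' @param geno,meth,truth cohort pieces; `meth` must come from
#'   [sim_methylation()].
#' @param prevalence_intercept baseline log odds of disease.
#' @param seed integer seed or `NULL`.
#' @return a [phenotype_table()] with covariates age, sex, smoking, batch.
#'   When the scenario regenerates methylation the new table is attached as
#'   `attr(, "methylation")`.
#' @export
sim_phenotype <- function(geno, meth, truth, prevalence_intercept = 0,
                          seed = NULL) {
  n <- length(geno$sample_ids)
  eff <- truth$path_effects
  gen <- attr(meth, "gen")
  dos <- driver_dosage(geno, truth)
  res <- maybe_seed(seed, {
    cov <- data.frame(age = stats::rnorm(n, 45, 10),
                      sex = stats::rbinom(n, 1, 0.5),
                      smoking = stats::rbinom(n, 1, 0.3),
                      batch = stats::rbinom(n, 1, 0.5))
    meth2 <- NULL
    if (truth$scenario %in% c("mediation", "independent")) {
      m <- collapsed_dmr_signal(meth, truth)
      z <- as.numeric(scale(m))
      eta <- prevalence_intercept + eff[["m_y"]] * z + eff[["g_y"]] * dos
      y <- stats::rbinom(n, 1, inv_logit(eta))
    } else if (truth$scenario == "consequential") {
      eta <- prevalence_intercept + eff[["g_y"]] * dos
      y <- stats::rbinom(n, 1, inv_logit(eta))
      meth2 <- sim_methylation(geno, truth, gen$probe_layout,
                               noise_sd = gen$noise_sd,
                               sample_sd = gen$sample_sd,
                               extra_shift = eff[["y_m"]] * y)
    } else { # confounded
      eta <- prevalence_intercept + eff[["conf_y"]] * cov$batch
      y <- stats::rbinom(n, 1, inv_logit(eta))
      meth2 <- sim_methylation(geno, truth, gen$probe_layout,
                               noise_sd = gen$noise_sd,
                               sample_sd = gen$sample_sd,
                               extra_shift = eff[["conf_m"]] * cov$batch)
    }
    list(y = y, cov = cov, meth2 = meth2)
  })
  ph <- phenotype_table(geno$sample_ids, res$y, res$cov)
  attr(ph, "methylation") <- res$meth2
  ph
}

#' Simulate residualized expression coupled to methylation
#'
#' `expr = intercept - m_expr * m_DMR + noise`: the planted region's
#' collapsed methylation suppresses expression (negative coupling), the
#' analogue of residualized transcript abundance after covariate removal.
#'
#' @param meth,geno,truth cohort pieces.
#' @param intercept expression baseline.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed or `NULL`.
#' @return numeric vector, one value per sample.
#' @export
sim_expression <- function(meth, geno, truth, intercept = 10, noise_sd = 0.5,
                           seed = NULL) {
  m <- collapsed_dmr_signal(meth, truth)
  dos <- driver_dosage(geno, truth)
  maybe_seed(seed, {
    intercept - truth$path_effects[["m_expr"]] * m +
      truth$path_effects[["g_expr"]] * dos +
      stats::rnorm(length(m), 0, noise_sd)
  })
}

#' Simulate a full cohort under one scenario
#'
#' Convenience wrapper chaining [sim_genotypes()], [sim_methylation()],
#' [sim_phenotype()] and [sim_expression()] with the default variant panel
#' and probe layout. Sub-seeds are derived deterministically from `seed`.
#'
#' @param scenario passed to [sim_truth()].
#' @param n_samples cohort size.
#' @param seed master integer seed.
#' @param effect_profile passed to [sim_truth()].
#' @param path_effects optional overrides passed to [sim_truth()].
#' @param n_probes,planted_dmr probe layout geometry.
#' @param noise_sd,sample_sd passed to [sim_methylation()].
#' @return list with `geno`, `meth`, `pheno`, `expr`, `truth`,
#'   `probe_layout`, `panel` (the deconvolution reference).
#' @export
sim_cohort <- function(scenario = "mediation", n_samples = 500, seed = 1L,
                       effect_profile = "standard", path_effects = NULL,
                       n_probes = 400, planted_dmr = 201:208,
                       noise_sd = 0.1, sample_sd = 1) {
  seed <- as.integer(seed)
  sub_seed <- function(k) as.integer((as.double(seed) * k) %% 1000003)
  vp <- hla_variant_panel()
  layout <- sim_probe_layout(n_probes)
  truth <- sim_truth(scenario, n_probes = n_probes, planted_dmr = planted_dmr,
                     driver_variant = vp$driver_variant,
                     path_effects = path_effects,
                     effect_profile = effect_profile,
                     seed = sub_seed(7))
  geno <- sim_genotypes(n_samples, vp$variant_specs, vp$ld_blocks,
                        seed = sub_seed(11))
  meth <- sim_methylation(geno, truth, layout, noise_sd = noise_sd,
                          sample_sd = sample_sd, seed = sub_seed(13))
  pheno <- sim_phenotype(geno, meth, truth, seed = sub_seed(17))
  if (!is.null(attr(pheno, "methylation"))) meth <- attr(pheno, "methylation")
  expr <- sim_expression(meth, geno, truth, seed = sub_seed(19))
  panel <- cell_reference_panel(layout$id,
                                colnames(truth$cell_profiles$reference) %||%
                                  names(truth$cell_profiles$alpha),
                                truth$cell_profiles$reference)
  list(geno = geno, meth = meth, pheno = pheno, expr = expr, truth = truth,
       probe_layout = layout, panel = panel)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Two independent cohorts share true per-variant effects on the exposure
#' (`gamma ~ U(0.05, 0.2)`). Outcome effects are `theta * gamma` plus
#' optional pleiotropy, and both sets of estimates receive correlated
#' sampling noise with covariance `S R S` where `S = diag(se)` and `R` is
#' the LD correlation matrix. Standard errors scale as
#' `1 / sqrt(2 maf (1-maf) n)`.
#'
#' @param theta true causal effect of exposure on outcome.
#' @param k_variants number of instruments (>= 3).
#' @param ld `NULL` (identity) or `list(block_size =, r =)` for block LD with
#'   `r^|i-j|` decay within blocks.
#' @param pleiotropy `list(type = "none"|"balanced"|"directional",
#'   mean =, sd =)`.
#' @param n_exp,n_out cohort sizes (defaults mirror a 279-sample exposure
#'   cohort and a 156-sample outcome cohort).
#' @param seed integer seed or `NULL`.
#' @return list with `exposure` and `outcome` ([trait_summary_stats()]),
#'   `ld` ([ld_matrix()]) and `truth` (theta, gamma, alpha).
#' @export
sim_two_sample <- function(theta, k_variants = 50, ld = NULL,
                           pleiotropy = list(type = "none"),
                           n_exp = 279, n_out = 156, seed = NULL) {
  k <- k_variants
  if (k < 3) stop_spec("k_variants must be >= 3 (Egger needs >= 3)")
  type <- pleiotropy$type %||% "none"
  if (!type %in% c("none", "balanced", "directional"))
    stop_spec("unknown pleiotropy type '", type, "'")
  R <- diag(k)
  if (!is.null(ld)) {
    bs <- ld$block_size; r <- ld$r
    for (s in seq(1, k, by = bs)) {
      e <- min(s + bs - 1, k)
      idx <- s:e
      R[idx, idx] <- r^abs(outer(idx, idx, "-"))
    }
  }
  maybe_seed(seed, {
    maf <- stats::runif(k, 0.1, 0.5)
    gamma <- stats::runif(k, 0.05, 0.2)
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * n_exp)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_out)
    Lh <- chol(R)
    noise <- function(se) se * drop(crossprod(Lh, stats::rnorm(k)))
    alpha <- switch(type,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, pleiotropy$sd %||% 0.05),
      directional = stats::rnorm(k, pleiotropy$mean %||% 0.1,
                                 pleiotropy$sd %||% 0.05))
    b_exp <- gamma + noise(se_exp)
    b_out <- theta * gamma + alpha + noise(se_out)
    ids <- sprintf("rs%05d", seq_len(k))
    mk <- function(b, se, n) trait_summary_stats(
      ids, "6", 32000000L + 1000L * seq_len(k), "A", "G",
      b, se, 2 * stats::pnorm(-abs(b / se)), n, maf)
    list(exposure = mk(b_exp, se_exp, n_exp),
         outcome = mk(b_out, se_out, n_out),
         ld = ld_matrix(ids, R),
         truth = list(theta = theta, gamma = gamma, alpha = alpha))
  })
}
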