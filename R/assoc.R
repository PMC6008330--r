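#' Genotype coding under additive, dominant and recessive models
#'
#' Additive coding is the dosage itself; dominant codes carriers of at least
#' one copy (dosage >= 0.5), recessive codes homozygous carriers
#' (dosage >= 1.5). The 0.5/1.5 thresholds round imputed dosages to the
#' nearest genotype.
#'
#' @param dosage_vector dosages in \[0, 2\].
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return coded numeric vector.
#' @export
code_genotype <- function(dosage_vector,
                          model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  if (any(dosage_vector < 0 | dosage_vector > 2, na.rm = TRUE))
    stop_spec("dosages must lie in [0, 2]")
  switch(model,
         additive = dosage_vector,
         dominant = as.numeric(dosage_vector >= 0.5),
         recessive = as.numeric(dosage_vector >= 1.5))
}

#' Linear QTL scan of continuous outcomes on genotype
#'
#' For each (variant, outcome) pair, fits the least-squares model
#' `outcome ~ coded dosage + covariates` and reports the coefficient of the
#' coded dosage with a two-sided p-value from its t statistic. The scan is
#' vectorized over outcomes via the Frisch-Waugh identity. Monomorphic
#' variants are flagged with `beta = NA` and `p = 1`.
#'
#' @param outcome_matrix numeric matrix samples x outcomes (collapsed DMR
#'   methylation, expression, ...); column names are the outcome ids.
#' @param geno a [genotype_table()].
#' @param covariates `NULL`, matrix or data frame of covariate columns.
#' @param model genotype coding passed to [code_genotype()].
#' @return data.frame of association results: `variant_id`, `outcome_id`,
#'   `beta`, `se`, `stat`, `p`, `n`, `model`, `coding`.
#' @export
qtl_scan <- function(outcome_matrix, geno, covariates = NULL,
                     model = "additive") {
  Y <- as.matrix(outcome_matrix)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(Y)
  if (n != length(geno$sample_ids))
    stop_spec("outcome rows must match genotype samples")
  if (n < 10) stop_spec("need >= 10 complete cases")
  D <- base_design(n, covariates)
  qd <- qr(D)
  rY <- qr.resid(qd, Y)
  rss_y <- colSums(rY^2)
  df <- n - qd$rank - 1L
  out <- vector("list", ncol(geno$dosages))
  for (j in seq_len(ncol(geno$dosages))) {
    g <- code_genotype(geno$dosages[, j], model)
    rg <- qr.resid(qd, g)
    ssg <- sum(rg^2)
    if (ssg < 1e-12) {
      out[[j]] <- data.frame(variant_id = geno$variants$id[j],
                             outcome_id = colnames(Y),
                             beta = NA_real_, se = NA_real_,
                             stat = NA_real_, p = 1, n = n,
                             model = "linear", coding = model,
                             stringsAsFactors = FALSE)
      next
    }
    beta <- drop(crossprod(rY, rg)) / ssg
    rss <- pmax(rss_y - beta^2 * ssg, 0)
    se <- sqrt(rss / df / ssg)
    tt <- beta / se
    out[[j]] <- data.frame(variant_id = geno$variants$id[j],
                           outcome_id = colnames(Y),
                           beta = unname(beta), se = unname(se),
                           stat = unname(tt),
                           p = 2 * stats::pt(-abs(tt), df), n = n,
                           model = "linear", coding = model,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Bonferroni threshold for a two-dimensional test family
#'
#' `alpha / (n_outcomes x n_variants)`; e.g. 0.05 over 7 regions and
#' 594,262 variants gives 1.20e-8.
#'
#' @param alpha family-wise level.
#' @param n_outcomes,n_variants family dimensions.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_outcomes, n_variants) {
  if (alpha <= 0 || n_outcomes <= 0 || n_variants <= 0)
    stop_spec("all inputs must be positive")
  alpha / (n_outcomes * n_variants)
}

#' Case-control logistic association scan
#'
#' Per variant, a likelihood-ratio test of the coded dosage in
#' `status ~ dosage + covariates`; `beta` is the log-odds per dosage unit
#' with its Wald SE. Complete separation is flagged: the LRT p (still
#' defined through the deviances) is retained but the Wald SE is set to NA.
#'
#' @param pheno a [phenotype_table()].
#' @param geno a [genotype_table()].
#' @param covariates `NULL`, matrix or data frame.
#' @param model genotype coding.
#' @return data.frame: `variant_id`, `beta`, `se`, `stat` (LRT), `p`, `n`,
#'   `model`, `coding`, `separation`.
#' @export
logistic_assoc_scan <- function(pheno, geno, covariates = NULL,
                                model = "additive") {
  y <- pheno$status
  if (length(unique(y)) < 2) stop_spec("both classes must be present")
  n <- length(y)
  X0 <- base_design(n, covariates)
  out <- lapply(seq_len(ncol(geno$dosages)), function(j) {
    g <- code_genotype(geno$dosages[, j], model)
    if (stats::var(g) < 1e-12) {
      return(data.frame(variant_id = geno$variants$id[j], beta = NA_real_,
                        se = NA_real_, stat = NA_real_, p = 1, n = n,
                        model = "logistic", coding = model,
                        separation = FALSE, stringsAsFactors = FALSE))
    }
    lr <- logistic_lrt(X0, cbind(X0, g = g), y)
    data.frame(variant_id = geno$variants$id[j], beta = lr$beta,
               se = if (lr$separation) NA_real_ else lr$se,
               stat = lr$stat, p = max(lr$p, .Machine$double.xmin), n = n,
               model = "logistic", coding = model,
               separation = lr$separation, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' maxT permutation adjustment for a variant family
#'
#' Westfall-Young style single-step adjustment: the case/control labels are
#' permuted, the maximum LRT statistic over all variants is recorded per
#' permutation, and each variant's adjusted p-value is the add-one estimate
#' `(1 + #\{max null stat >= stat_j\}) / (n_perm + 1)`. With a single
#' variant this reduces to its own permutation p-value.
#'
#' @param pheno,geno,covariates,model as in [logistic_assoc_scan()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed or `NULL`.
#' @return data.frame: `variant_id`, `stat`, `p_raw` (single-variant
#'   permutation p), `p_adj`.
#' @export
maxt_adjust <- function(pheno, geno, covariates = NULL, model = "additive",
                        n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop_spec("n_perm must be >= 100")
  y <- pheno$status
  n <- length(y)
  X0 <- base_design(n, covariates)
  G <- vapply(seq_len(ncol(geno$dosages)),
              function(j) code_genotype(geno$dosages[, j], model),
              numeric(n))
  stat_of <- function(yy) {
    f0 <- logit_fit(X0, yy)
    vapply(seq_len(ncol(G)), function(j) {
      if (stats::var(G[, j]) < 1e-12) return(0)
      max(f0$deviance - logit_fit(cbind(X0, G[, j]), yy)$deviance, 0)
    }, 0)
  }
  obs <- stat_of(y)
  perm_stats <- maybe_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat_of(sample(y)), numeric(ncol(G)))
  })
  perm_stats <- matrix(perm_stats, nrow = ncol(G))
  max_null <- apply(perm_stats, 2, max)
  data.frame(
    variant_id = geno$variants$id,
    stat = obs,
    p_raw = vapply(seq_len(ncol(G)), function(j) {
      (1 + sum(perm_stats[j, ] >= obs[j])) / (n_perm + 1)
    }, 0),
    p_adj = vapply(obs, function(s) (1 + sum(max_null >= s)) / (n_perm + 1), 0),
    stringsAsFactors = FALSE)
}

#' Conditional logistic association scan
#'
#' Identical contract to [logistic_assoc_scan()] with the user-supplied
#' condition design (risk-allele presence/homozygosity indicators,
#' interactions, ancestry PCs) entering as fixed covariates. A condition
#' column collinear with the variant yields a flagged NA result.
#'
#' @param pheno,geno as in [logistic_assoc_scan()].
#' @param condition_design data frame or matrix of numeric condition columns
#'   (may be `NULL` / zero columns, in which case the scan equals the
#'   unconditional one).
#' @param covariates additional adjustment columns.
#' @return data.frame as [logistic_assoc_scan()] plus a `reason` column for
#'   flagged variants.
#' @export
conditional_scan <- function(pheno, geno, condition_design = NULL,
                             covariates = NULL) {
  cv <- NULL
  parts <- list()
  if (!is.null(covariates)) parts <- c(parts, list(as.matrix(covariates)))
  if (!is.null(condition_design) && NCOL(condition_design) > 0)
    parts <- c(parts, list(as.matrix(condition_design)))
  if (length(parts)) cv <- do.call(cbind, parts)
  y <- pheno$status
  n <- length(y)
  X0 <- base_design(n, cv)
  q0 <- qr(X0)
  out <- lapply(seq_len(ncol(geno$dosages)), function(j) {
    g <- geno$dosages[, j]
    base <- data.frame(variant_id = geno$variants$id[j], beta = NA_real_,
                       se = NA_real_, stat = NA_real_, p = 1, n = n,
                       model = "logistic", coding = "additive",
                       separation = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (stats::var(g) < 1e-12) {
      base$reason <- "monomorphic"
      return(base)
    }
    if (sum(qr.resid(q0, g)^2) < 1e-10 * sum(g^2)) {
      base$reason <- "collinear with condition design"
      return(base)
    }
    lr <- logistic_lrt(X0, cbind(X0, g = g), y)
    base$beta <- lr$beta
    base$se <- if (lr$separation) NA_real_ else lr$se
    base$stat <- lr$stat
    base$p <- max(lr$p, .Machine$double.xmin)
    base$separation <- lr$separation
    base
  })
  do.call(rbind, out)
}

#' Build an HLA-style condition design from allele dosages
#'
#' Helper producing presence (dosage >= 0.5) and homozygote (dosage >= 1.5)
#' indicator columns per allele, plus pairwise presence-interaction columns.
#'
#' @param allele_dosages data frame / matrix of allele dosages in \[0, 2\],
#'   one column per allele.
#' @param homozygote alleles (column names) that also get a homozygote term.
#' @param interactions list of character pairs; each adds a
#'   presence-x-presence product column.
#' @return numeric design matrix.
#' @export
hla_condition_design <- function(allele_dosages, homozygote = character(),
                                 interactions = list()) {
  A <- as.matrix(allele_dosages)
  pres <- (A >= 0.5) + 0
  colnames(pres) <- paste0(colnames(A), "_presence")
  out <- pres
  for (al in homozygote) {
    hom <- (A[, al] >= 1.5) + 0
    out <- cbind(out, hom)
    colnames(out)[ncol(out)] <- paste0(al, "_homozygote")
  }
  for (pr in interactions) {
    col <- (A[, pr[1]] >= 0.5) * (A[, pr[2]] >= 0.5)
    out <- cbind(out, col)
    colnames(out)[ncol(out)] <- paste0(pr[1], "_x_", pr[2])
  }
  out
}

#' Genomic-control correction of chi-square statistics
#'
#' `lambda = median(chi2) / 0.4549364` (the df-1 median); statistics are
#' divided by `max(lambda, 1)` — deflation is never applied — and p-values
#' recomputed from the df-1 chi-square distribution.
#'
#' @param chi2_values non-negative df-1 chi-square statistics.
#' @return list with `lambda`, `chi2_corrected`, `p_corrected`.
#' @export
genomic_control <- function(chi2_values) {
  if (!length(chi2_values)) stop_spec("empty chi2 input")
  if (any(chi2_values < 0)) stop_spec("chi2 values must be >= 0")
  lambda <- stats::median(chi2_values) / stats::qchisq(0.5, 1)
  corr <- chi2_values / max(lambda, 1)
  list(lambda = lambda, chi2_corrected = corr,
       p_corrected = stats::pchisq(corr, 1, lower.tail = FALSE))
}

#' Fixed- and random-effects meta-analysis of per-study effects
#'
#' Inverse-variance fixed effect, Cochran's Q, DerSimonian-Laird tau-square
#' and the corresponding random-effects estimate. When `Q <= df` the
#' heterogeneity estimate is zero and the random-effects result equals the
#' fixed-effects result exactly.
#'
#' @param betas,ses per-study effect sizes and standard errors (>= 2
#'   studies, all `ses > 0`).
#' @return object of class `meta_result`: per-study inputs plus
#'   `fixed_beta`, `fixed_se`, `fixed_p`, `random_beta`, `random_se`,
#'   `random_p`, `Q`, `df`, `Q_p`, `I2`, `tau2`.
#' @export
meta_analyze <- function(betas, ses) {
  k <- length(betas)
  if (k < 2) stop_spec("meta-analysis needs >= 2 studies")
  if (length(ses) != k || any(ses <= 0)) stop_spec("ses must be > 0")
  w <- 1 / ses^2
  fixed_beta <- sum(w * betas) / sum(w)
  fixed_se <- 1 / sqrt(sum(w))
  Q <- sum(w * (betas - fixed_beta)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  random_beta <- sum(wr * betas) / sum(wr)
  random_se <- 1 / sqrt(sum(wr))
  two_sided <- function(b, s) 2 * stats::pnorm(-abs(b / s))
  structure(list(betas = betas, ses = ses,
                 fixed_beta = fixed_beta, fixed_se = fixed_se,
                 fixed_p = two_sided(fixed_beta, fixed_se),
                 random_beta = random_beta, random_se = random_se,
                 random_p = two_sided(random_beta, random_se),
                 Q = Q, df = df,
                 Q_p = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = max(0, (Q - df) / Q), tau2 = tau2),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("<meta_result> k =", length(x$betas),
      sprintf("fixed %.4f (SE %.4f, p %.3g); random %.4f (SE %.4f, p %.3g); Q %.3f (p %.3g), I2 %.2f, tau2 %.4g\n",
              x$fixed_beta, x$fixed_se, x$fixed_p, x$random_beta,
              x$random_se, x$random_p, x$Q, x$Q_p, x$I2, x$tau2))
  invisible(x)
}
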