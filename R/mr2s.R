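#' Two-sample Mendelian randomization with correlated instruments
#'
#' Methylation at a differentially methylated region is the exposure,
#' residualized expression the outcome; the instruments are meQTL variants
#' that typically sit in strong LD, so the Egger and IVW estimators use a
#' generalized least-squares error covariance built from the outcome
#' standard errors and the signed LD correlation matrix.
#'
#' @name mr2s
NULL

#' Greedy LD clumping by p-value
#'
#' Sorts variants by ascending p (ties broken by position, then id), keeps
#' the best, drops every unkept variant with `r^2 > r2_max` within
#' `window_bp` of a kept variant, and repeats. Output preserves the input
#' order among kept variants.
#'
#' @param stats a [trait_summary_stats()].
#' @param ld an [ld_matrix()] covering every variant in `stats`.
#' @param r2_max squared-correlation threshold in (0, 1\] (default 0.8).
#' @param window_bp clumping window (default 1e7, i.e. 10,000 kb).
#' @return character vector of retained variant ids.
#' @export
ld_clump <- function(stats, ld, r2_max = 0.8, window_bp = 1e7) {
  if (r2_max <= 0 || r2_max > 1) stop_spec("r2_max must lie in (0, 1]")
  missing <- setdiff(stats$id, ld$ids)
  if (length(missing))
    stop_spec("variants missing from LD matrix: ",
              paste(missing, collapse = ", "))
  ord <- order(stats$p, stats$pos, stats$id)
  kept <- character()
  dropped <- character()
  for (i in ord) {
    id <- stats$id[i]
    if (id %in% dropped) next
    kept <- c(kept, id)
    r2 <- ld$r[id, stats$id]^2
    near <- abs(stats$pos - stats$pos[i]) <= window_bp
    drop_now <- stats$id[r2 > r2_max & near & stats$id != id]
    dropped <- union(dropped, setdiff(drop_now, kept))
  }
  stats$id[stats$id %in% kept]
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by id; palindromic variants (A/T or C/G) are dropped
#' outright. When the outcome's alleles are swapped relative to the
#' exposure the outcome beta is negated (and its EAF flipped); when they
#' match only after strand complementing, the outcome is complemented and
#' then aligned. Irreconcilable allele pairs are dropped with a logged
#' reason. The LD matrix is assumed signed with respect to the exposure
#' effect alleles, so outcome-side flips leave it unchanged; exposure-side
#' re-orientation happens in [orient_positive()].
#'
#' @param exposure,outcome [trait_summary_stats()] objects.
#' @param ld an [ld_matrix()] covering the shared variants.
#' @return object of class `harmonized_set`: a data.frame `variants` with
#'   aligned `beta_exp`, `se_exp`, `beta_out`, `se_out`, `n_exp`, `n_out`,
#'   `eaf_exp`, `flipped` (outcome orientation flips), the LD submatrix
#'   `ld`, and a `dropped` table of exclusions with reasons. Errors when
#'   fewer than 3 variants remain.
#' @export
harmonize <- function(exposure, outcome, ld) {
  shared <- intersect(exposure$id, outcome$id)
  ex <- exposure[match(shared, exposure$id), ]
  ou <- outcome[match(shared, outcome$id), ]
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- logical(length(shared))
  flipped <- logical(length(shared))
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    if (is_palindromic(ea, oa)) {
      dropped <- rbind(dropped, data.frame(id = shared[i],
                                           reason = "palindromic"))
      next
    }
    bea <- ou$effect_allele[i]; boa <- ou$other_allele[i]
    if (bea == ea && boa == oa) {
      keep[i] <- TRUE
    } else if (bea == oa && boa == ea) {
      ou$beta[i] <- -ou$beta[i]
      if (!is.na(ou$eaf[i])) ou$eaf[i] <- 1 - ou$eaf[i]
      keep[i] <- TRUE; flipped[i] <- TRUE
    } else if (complement_allele(bea) == ea && complement_allele(boa) == oa) {
      keep[i] <- TRUE  # strand fix, orientation already aligned
    } else if (complement_allele(bea) == oa && complement_allele(boa) == ea) {
      ou$beta[i] <- -ou$beta[i]
      if (!is.na(ou$eaf[i])) ou$eaf[i] <- 1 - ou$eaf[i]
      keep[i] <- TRUE; flipped[i] <- TRUE
    } else {
      dropped <- rbind(dropped, data.frame(id = shared[i],
                                           reason = "irreconcilable alleles"))
    }
  }
  ids <- shared[keep]
  if (length(ids) < 3)
    stop_spec("fewer than 3 variants remain after harmonization")
  missing <- setdiff(ids, ld$ids)
  if (length(missing))
    stop_spec("variants missing from LD matrix: ",
              paste(missing, collapse = ", "))
  v <- data.frame(id = ids,
                  chrom = ex$chrom[keep], pos = ex$pos[keep],
                  effect_allele = ex$effect_allele[keep],
                  other_allele = ex$other_allele[keep],
                  beta_exp = ex$beta[keep], se_exp = ex$se[keep],
                  beta_out = ou$beta[keep], se_out = ou$se[keep],
                  n_exp = ex$n[keep], n_out = ou$n[keep],
                  eaf_exp = ex$eaf[keep],
                  flipped = flipped[keep], stringsAsFactors = FALSE)
  structure(list(variants = v, ld = ld$r[ids, ids, drop = FALSE],
                 dropped = dropped), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set> ", nrow(x$variants), " variants (",
      nrow(x$dropped), " dropped)\n", sep = "")
  invisible(x)
}

#' Orient all exposure associations positive
#'
#' For each variant with a negative exposure beta, both betas are negated
#' and the variant's LD row/column re-signed (the effect allele definition
#' flips). Variants with an exposure beta of exactly zero are dropped with
#' a warning.
#'
#' @param h a `harmonized_set`.
#' @return the re-oriented `harmonized_set`; all exposure betas > 0.
#' @export
orient_positive <- function(h) {
  v <- h$variants
  zero <- v$beta_exp == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " variant(s) with zero exposure beta")
    v <- v[!zero, , drop = FALSE]
    h$ld <- h$ld[!zero, !zero, drop = FALSE]
  }
  neg <- v$beta_exp < 0
  if (any(neg)) {
    v$beta_exp[neg] <- -v$beta_exp[neg]
    v$beta_out[neg] <- -v$beta_out[neg]
    ea <- v$effect_allele[neg]
    v$effect_allele[neg] <- v$other_allele[neg]
    v$other_allele[neg] <- ea
    v$eaf_exp[neg] <- 1 - v$eaf_exp[neg]
    s <- ifelse(neg, -1, 1)
    h$ld <- h$ld * outer(s, s)
  }
  h$variants <- v
  h
}

#' MR-Egger / IVW regression with correlated instruments
#'
#' Generalized least squares of the outcome betas on the exposure betas
#' with error covariance `Omega_ij = se_out_i * se_out_j * r_ij`. The Egger
#' design includes a free intercept (the directional-pleiotropy term); IVW
#' is the intercept-free version. Residual heterogeneity is Cochran's
#' `Q = (b_out - X theta)' Omega^-1 (b_out - X theta)` on `k - 2` (Egger)
#' or `k - 1` (IVW) df, and the coefficient covariance is inflated by the
#' overdispersion scale `max(1, Q/df)`. P-values use the normal reference.
#' A near-singular `Omega` receives a ridge of `1e-8` on its diagonal
#' scale.
#'
#' @param h a `harmonized_set` (usually after [orient_positive()]).
#' @param method `"egger"` (k >= 3) or `"ivw"` (k >= 2).
#' @param ridge diagonal regularization applied when the covariance fails
#'   to factorize.
#' @return object of class `mr_result`: `slope`, `slope_se`, `slope_p`,
#'   `intercept`, `intercept_se`, `intercept_p` (Egger only), `Q`, `Q_df`,
#'   `Q_p`, `k_variants`, `overdispersion_scale`.
#' @export
mr_egger_correlated <- function(h, method = c("egger", "ivw"),
                                ridge = 1e-8) {
  method <- match.arg(method)
  v <- h$variants
  k <- nrow(v)
  if (method == "egger" && k < 3) stop_spec("Egger needs >= 3 variants")
  if (method == "ivw" && k < 2) stop_spec("IVW needs >= 2 variants")
  Omega <- outer(v$se_out, v$se_out) * h$ld
  ch <- try(chol(Omega), silent = TRUE)
  if (inherits(ch, "try-error")) {
    Omega <- Omega + diag(ridge * mean(diag(Omega)), k)
    ch <- try(chol(Omega), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop_spec("outcome covariance is singular even after ridge")
  }
  X <- if (method == "egger") cbind(intercept = 1, slope = v$beta_exp)
       else cbind(slope = v$beta_exp)
  # whiten with the cholesky factor: solve two triangular systems
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, v$beta_out, transpose = TRUE)
  XtX <- crossprod(Xw)
  theta <- solve(XtX, crossprod(Xw, yw))
  rownames(theta) <- colnames(X)
  resid <- yw - Xw %*% theta
  Q <- sum(resid^2)
  Q_df <- k - ncol(X)
  scale <- max(1, if (Q_df > 0) Q / Q_df else 1)
  covm <- solve(XtX) * scale
  se <- stats::setNames(sqrt(diag(covm)), colnames(X))
  pz <- function(b, s) 2 * stats::pnorm(-abs(b / s))
  slope <- theta["slope", 1]; slope_se <- se["slope"]
  res <- list(method = method, slope = unname(slope),
              slope_se = unname(slope_se),
              slope_p = pz(slope, slope_se),
              Q = Q, Q_df = Q_df,
              Q_p = if (Q_df > 0) stats::pchisq(Q, Q_df, lower.tail = FALSE)
                    else NA_real_,
              k_variants = k, overdispersion_scale = scale)
  if (method == "egger") {
    res$intercept <- unname(theta["intercept", 1])
    res$intercept_se <- unname(se["intercept"])
    res$intercept_p <- pz(res$intercept, res$intercept_se)
  }
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result> ", x$method, ", k = ", x$k_variants, "\n",
      sprintf("  slope %.4f (SE %.4f, p %.3g)\n", x$slope, x$slope_se,
              x$slope_p), sep = "")
  if (x$method == "egger")
    cat(sprintf("  intercept %.4f (SE %.4f, p %.3g)\n", x$intercept,
                x$intercept_se, x$intercept_p))
  cat(sprintf("  Q %.3f on %d df (p %.3g), overdispersion %.3f\n",
              x$Q, x$Q_df, x$Q_p, x$overdispersion_scale))
  invisible(x)
}

#' Pleiotropy and heterogeneity accessors
#'
#' Surfaces the Egger intercept test (directional pleiotropy) and the
#' Cochran Q test (heterogeneity) with interpretation labels; pure
#' accessors, nothing is recomputed.
#'
#' @param res an `mr_result` from [mr_egger_correlated()] with
#'   `method = "egger"`.
#' @param alpha labelling threshold.
#' @return list with `intercept_p`, `intercept_label`, `Q_p`, `Q_label`.
#' @export
pleiotropy_and_heterogeneity <- function(res, alpha = 0.05) {
  if (res$method != "egger")
    stop_spec("intercept test requires an Egger result")
  list(intercept_p = res$intercept_p,
       intercept_label = if (res$intercept_p < alpha)
         "evidence of directional pleiotropy" else
         "no evidence of directional pleiotropy",
       Q_p = res$Q_p,
       Q_label = if (!is.na(res$Q_p) && res$Q_p < alpha)
         "evidence of heterogeneity" else "no evidence of heterogeneity")
}

# variance explained by one variant from its t statistic
r2_from_stats <- function(beta, se, n) {
  t <- beta / se
  t^2 / (t^2 + n - 2)
}

#' Steiger directionality test
#'
#' Per-variant variance explained is recovered from the t statistic,
#' `r2 = t^2 / (t^2 + n - 2)`; the Fisher-z transformed correlations are
#' compared with `Z = (z_exp - z_out) / sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#' The inferred causal direction is exposure -> outcome exactly when the
#' exposure r2 is larger.
#'
#' @param beta_exp,se_exp,n_exp exposure association for one variant.
#' @param beta_out,se_out,n_out outcome association for the same variant.
#' @return object of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `z_stat`, `p`, `inferred_direction`.
#' @export
steiger_direction <- function(beta_exp, se_exp, n_exp,
                              beta_out, se_out, n_out) {
  if (n_exp <= 3 || n_out <= 3) stop_spec("sample sizes must exceed 3")
  r2e <- r2_from_stats(beta_exp, se_exp, n_exp)
  r2o <- r2_from_stats(beta_out, se_out, n_out)
  steiger_from_r(sqrt(r2e), sqrt(r2o), n_exp, n_out)
}

#' Steiger test from correlation magnitudes
#'
#' @param r_exp,r_out absolute variant-trait correlations.
#' @param n_exp,n_out sample sizes (> 3).
#' @return a `steiger_result` (see [steiger_direction()]).
#' @export
steiger_from_r <- function(r_exp, r_out, n_exp, n_out) {
  if (n_exp <= 3 || n_out <= 3) stop_spec("sample sizes must exceed 3")
  cap <- function(r) {
    if (abs(r) >= 1) {
      warning("correlation capped below 1")
      r <- sign(r) * (1 - 1e-12)
    }
    r
  }
  r_exp <- cap(r_exp); r_out <- cap(r_out)
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r_exp^2, r2_outcome = r_out^2,
                 z_stat = z, p = 2 * stats::pnorm(-abs(z)),
                 inferred_direction = if (r_exp^2 > r_out^2)
                   "exposure->outcome" else "outcome->exposure"),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "<steiger_result> r2_exp %.4f, r2_out %.4f, Z %.3f (p %.3g), %s\n",
    x$r2_exposure, x$r2_outcome, x$z_stat, x$p, x$inferred_direction))
  invisible(x)
}

#' Reliability ratio of the Steiger direction under measurement error
#'
#' Explores a grid of reliabilities `(rel_x, rel_y)` in `(lower, 1]^2`. In
#' each cell the observed correlations are disattenuated,
#' `r' = min(1 - 1e-12, r / sqrt(rel))`, and the difference of squared
#' correlations `d = r'_exp^2 - r'_out^2` is accumulated. The reliability
#' ratio is `R = sum(|d| over d > 0) / sum(|d| over d < 0)`: R > 1 means
#' the inferred exposure -> outcome direction survives most measurement
#' error configurations. When no cell reverses the direction, the
#' denominator is zero and a finite sentinel (1e6) is returned with the
#' `all_concordant` flag.
#'
#' @param r_exp,r_out absolute variant-trait correlations.
#' @param n_exp,n_out sample sizes (kept for interface symmetry; the grid
#'   integrand does not use them).
#' @param lower lower bound of the reliability grid, in (0, 1).
#' @param ngrid cells per axis (default 50).
#' @return list with `R`, `all_concordant`, `n_pos`, `n_neg`.
#' @export
steiger_reliability <- function(r_exp, r_out, n_exp = NULL, n_out = NULL,
                                lower = 0.5, ngrid = 50) {
  if (lower <= 0 || lower >= 1) stop_spec("grid lower bound must lie in (0, 1)")
  mids <- lower + (seq_len(ngrid) - 0.5) * (1 - lower) / ngrid
  disatten <- function(r, rel) pmin(1 - 1e-12, r / sqrt(rel))
  rx <- disatten(r_exp, mids)
  ry <- disatten(r_out, mids)
  d <- outer(rx^2, ry^2, "-")  # cell (i, j): rel_x = mids[i], rel_y = mids[j]
  pos <- sum(d[d > 0]); neg <- -sum(d[d < 0])
  if (neg == 0) {
    return(list(R = 1e6, all_concordant = TRUE,
                n_pos = sum(d > 0), n_neg = 0L))
  }
  list(R = pos / neg, all_concordant = FALSE,
       n_pos = sum(d > 0), n_neg = sum(d < 0))
}
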