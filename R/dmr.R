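#' Bump-hunting DMR detection with permutation FWER control
#'
#' A phenotype-associated differentially methylated region is a maximal
#' within-cluster run of consecutive probes whose covariate-adjusted
#' case-control coefficients all exceed a common cutoff with a consistent
#' sign. Family-wise error control comes from permuting the case/control
#' labels and comparing each observed region's area to the permutation
#' distribution of the maximum null area.
#'
#' @name dmr
NULL

#' Covariate-adjusted per-probe coefficients of case status
#'
#' For each probe, the least-squares coefficient of case status in
#' `beta ~ status + covariates`, computed by the Frisch-Waugh identity
#' (both the probe values and the status vector are residualized against
#' the covariate design). Constant probes get coefficient 0 with an
#' infinite SE flag and are excluded from downstream cutoff quantiles.
#'
#' @param meth a [methylation_table()].
#' @param pheno a [phenotype_table()].
#' @param covariate_names columns of `pheno$covariates` to adjust for
#'   (`NULL` for none).
#' @return list with `coef`, `se` (per probe), `df`, and the internals
#'   (`resid_betas`, `design`) reused by [dmr_fwer()].
#' @export
probe_coefficients <- function(meth, pheno, covariate_names = NULL) {
  n <- length(pheno$sample_ids)
  cv <- NULL
  if (!is.null(covariate_names)) {
    missing <- setdiff(covariate_names, colnames(pheno$covariates))
    if (length(missing))
      stop_spec("covariates not found: ", paste(missing, collapse = ", "))
    cv <- pheno$covariates[, covariate_names, drop = FALSE]
    if (anyNA(cv)) {
      keep <- stats::complete.cases(cv)
      stop_spec(sum(!keep), " samples have missing covariates; ",
                "complete-case filter the tables first")
    }
  }
  D <- base_design(n, cv)
  qd <- qr(D)
  r_s <- qr.resid(qd, pheno$status)
  r_B <- qr.resid(qd, meth$betas)
  ss <- sum(r_s^2)
  if (ss <= 0) stop_spec("status is collinear with the covariates")
  coef <- drop(crossprod(r_B, r_s)) / ss
  df <- n - qd$rank - 1L
  rss <- pmax(colSums(r_B^2) - coef^2 * ss, 0)
  constant <- apply(meth$betas, 2, function(x) max(x) - min(x) == 0)
  se <- sqrt(rss / df / ss)
  se[constant] <- Inf
  coef[constant] <- 0
  list(coef = unname(coef), se = unname(se), df = df,
       probe_ids = meth$probes$id, constant = constant,
       resid_betas = r_B, resid_status = r_s, design_qr = qd)
}

#' Running-mean smoothing of probe coefficients within clusters
#'
#' Off by default in the pipeline. `window` must be odd; probes in clusters
#' shorter than the window are left untouched, and cluster edges use
#' truncated windows.
#'
#' @param coefs numeric vector of per-probe coefficients.
#' @param clusters integer cluster index per probe (see
#'   [probe_cluster_index()]).
#' @param window odd window width; `window = 1` is the identity.
#' @return smoothed coefficient vector.
#' @export
smooth_coefficients <- function(coefs, clusters, window = 3) {
  if (window %% 2 != 1) stop_spec("window must be odd")
  if (window == 1) return(coefs)
  half <- (window - 1) / 2
  out <- coefs
  for (idx in split(seq_along(coefs), clusters)) {
    k <- length(idx)
    if (k < window) next
    sm <- vapply(seq_len(k), function(i) {
      lo <- max(1, i - half); hi <- min(k, i + half)
      mean(coefs[idx[lo:hi]])
    }, 0)
    out[idx] <- sm
  }
  out
}

#' Candidate region discovery
#'
#' The cutoff is the `cutoff_quantile` quantile of `|coef|` over all
#' non-constant probes. Candidates are maximal within-cluster runs of
#' consecutive probes whose coefficients all strictly exceed `+cutoff`, or
#' all fall strictly below `-cutoff`, of length at least `min_probes`.
#'
#' @param coefs per-probe coefficient vector (see [probe_coefficients()]).
#' @param clusters integer cluster index per probe.
#' @param cutoff_quantile quantile in (0.5, 1); default 0.975.
#' @param min_probes minimum run length (default 2).
#' @param exclude logical per probe: drop from the quantile and from runs
#'   (constant probes).
#' @return data.frame with one row per candidate: `start_idx`, `end_idx`
#'   (probe indices), `cluster`, `n_probes`, `value` (mean coefficient),
#'   `area` (sum of `|coef|`), plus the `cutoff` as an attribute.
#' @export
find_candidate_regions <- function(coefs, clusters, cutoff_quantile = 0.975,
                                   min_probes = 2, exclude = NULL) {
  if (cutoff_quantile <= 0.5 || cutoff_quantile >= 1)
    stop_spec("cutoff_quantile must lie in (0.5, 1)")
  use <- if (is.null(exclude)) rep(TRUE, length(coefs)) else !exclude
  cutoff <- stats::quantile(abs(coefs[use]), cutoff_quantile, names = FALSE)
  res <- candidate_runs(coefs, clusters, cutoff, min_probes, use)
  attr(res, "cutoff") <- cutoff
  res
}

# shared by observed and permuted passes: runs at a fixed cutoff
candidate_runs <- function(coefs, clusters, cutoff, min_probes, use) {
  state <- integer(length(coefs))
  state[use & coefs > cutoff] <- 1L
  state[use & coefs < -cutoff] <- -1L
  out <- list()
  for (idx in split(seq_along(coefs), clusters)) {
    st <- state[idx]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L & r$lengths >= min_probes
    for (j in which(keep)) {
      span <- idx[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        start_idx = span[1], end_idx = span[length(span)],
        cluster = clusters[span[1]], n_probes = length(span),
        value = mean(coefs[span]), area = sum(abs(coefs[span])))
    }
  }
  if (!length(out))
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      cluster = integer(), n_probes = integer(),
                      value = numeric(), area = numeric()))
  do.call(rbind, out)
}

#' Permutation FWER for candidate DMRs
#'
#' For each resample the case/control labels are permuted (covariates stay
#' attached to their samples), the per-probe coefficients are recomputed,
#' and the maximum candidate area under the *same* cutoff is recorded. Each
#' observed region's FWER is the add-one permutation estimate
#' `(1 + #\{max null area >= observed area\}) / (n_resamples + 1)`, so it is
#' bounded below by `1/(n_resamples+1)` and is non-increasing in area.
#'
#' @param meth,pheno,covariate_names as in [probe_coefficients()].
#' @param clusters integer cluster index per probe.
#' @param candidates result of [find_candidate_regions()] (carries the
#'   cutoff).
#' @param n_resamples number of label permutations (>= 100).
#' @param min_probes run-length threshold, matching the candidate pass.
#' @param seed integer seed or `NULL`.
#' @return data.frame of DMR results: `chrom`, `start`, `end` (1-based
#'   inclusive), `probe_ids` (comma-joined), `n_probes`, `value`, `area`,
#'   `fwer`; empty when there are no candidates.
#' @export
dmr_fwer <- function(meth, pheno, covariate_names = NULL, clusters,
                     candidates, n_resamples = 1000, min_probes = 2,
                     seed = NULL) {
  if (n_resamples < 100) stop_spec("n_resamples must be >= 100")
  pc <- probe_coefficients(meth, pheno, covariate_names)
  cutoff <- attr(candidates, "cutoff")
  if (is.null(cutoff)) stop_spec("candidates must carry their cutoff")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), probe_ids = character(),
                      n_probes = integer(), value = numeric(),
                      area = numeric(), fwer = numeric())
  if (!nrow(candidates)) return(empty)
  use <- !pc$constant
  max_null <- maybe_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      perm <- sample(pheno$status)
      r_s <- qr.resid(pc$design_qr, perm)
      ss <- sum(r_s^2)
      cf <- drop(crossprod(pc$resid_betas, r_s)) / ss
      cf[pc$constant] <- 0
      runs <- candidate_runs(cf, clusters, cutoff, min_probes, use)
      if (nrow(runs)) max(runs$area) else 0
    }, 0)
  })
  fwer <- vapply(candidates$area,
                 function(a) (1 + sum(max_null >= a)) / (n_resamples + 1), 0)
  data.frame(
    chrom = meth$probes$chrom[candidates$start_idx],
    start = meth$probes$pos[candidates$start_idx],
    end = meth$probes$pos[candidates$end_idx],
    probe_ids = vapply(seq_len(nrow(candidates)), function(i) {
      paste(meth$probes$id[candidates$start_idx[i]:candidates$end_idx[i]],
            collapse = ",")
    }, ""),
    n_probes = candidates$n_probes,
    value = candidates$value,
    area = candidates$area,
    fwer = fwer,
    stringsAsFactors = FALSE)
}
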