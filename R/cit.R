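#' Causal Inference Test for a binary outcome
#'
#' Classifies each genotype-methylation-phenotype triplet (G, M, Y) as
#' methylation *mediated* (G -> M -> Y), methylation *consequential*
#' (G -> Y -> M) or *independent*, via an omnibus test that takes the
#' maximum of four component p-values in each causal direction. Because the
#' phenotype is binary, the models with Y as outcome are logistic and tested
#' by likelihood ratio; models with M as outcome are linear and tested by
#' partial F.
#'
#' The fourth component is an equivalence-style permutation test of
#' conditional independence. Its construction (residual permutation of the
#' mediator that preserves the G-M association while destroying any M-Y
#' link beyond G) is a reconstruction of the cited logistic CIT's published
#' behaviour, not a line-by-line port; see the methods vignette.
#'
#' @name cit
NULL

# shared input screening; returns NULL when testable, else a reason string
cit_screen <- function(g, m, y) {
  if (!all(y %in% c(0, 1))) return("y must be binary 0/1")
  if (length(unique(y)) < 2) return("only one outcome class present")
  if (stats::var(g) < 1e-12) return("genotype has zero variance")
  if (stats::var(m) < 1e-12) return("mediator has zero variance")
  NULL
}

#' Component p-values of one CIT direction
#'
#' With mediator `m` and binary outcome `y`:
#' `p1` tests G in `y ~ covariates + g` (LRT),
#' `p2` tests G in `m ~ covariates + y + g` (partial F),
#' `p3` tests M in `y ~ covariates + g + m` (LRT).
#'
#' @param g dosage vector.
#' @param m continuous mediator.
#' @param y binary outcome.
#' @param covariates `NULL`, matrix or data frame.
#' @return list with `p1`, `p2`, `p3`, the underlying statistics, and an
#'   `untestable` flag (separation or zero variance; components NA).
#' @export
cit_component_pvalues <- function(g, m, y, covariates = NULL) {
  bad <- cit_screen(g, m, y)
  if (!is.null(bad))
    return(list(p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                untestable = TRUE, reason = bad))
  n <- length(y)
  X0 <- base_design(n, covariates)
  t1 <- logistic_lrt(X0, cbind(X0, g = g), y)
  t2 <- linear_partial_f(cbind(X0, y = y), cbind(X0, y = y, g = g), m)
  t3 <- logistic_lrt(cbind(X0, g = g), cbind(X0, g = g, m = m), y)
  untestable <- t1$separation || t3$separation || isTRUE(t2$degenerate)
  list(p1 = t1$p, p2 = t2$p, p3 = t3$p,
       stat1 = t1$stat, stat2 = t2$stat, stat3 = t3$stat,
       beta_gy = t1$beta, beta_gy_adj_m = attr_beta_g(X0, g, m, y),
       untestable = untestable,
       reason = if (untestable) "separation or degenerate fit" else NA_character_)
}

# coefficient of g in logistic y ~ cov + m + g (the adjusted G:Y strength)
attr_beta_g <- function(X0, g, m, y) {
  f <- logit_fit(cbind(X0, m = m, g = g), y)
  unname(f$coef["g"])
}

#' Conditional-independence permutation component (p4)
#'
#' The observed statistic is the LRT of G in `y ~ covariates + m + g`.
#' Null mediators are built by fitting `m ~ covariates + g` and adding
#' permuted residuals back to the fitted values, which preserves the G-M
#' association but destroys any M-Y association beyond G. p4 is the add-one
#' left-tail estimate `(1 + #\{T* <= T_obs\}) / (n_perm + 1)`: a small p4
#' means the observed conditional G effect is *smaller* than expected under
#' the no-mediation null, supporting G independent of Y given M. Ties count
#' toward the null (conservative).
#'
#' @inheritParams cit_component_pvalues
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed or `NULL`.
#' @return the p4 p-value (NA if untestable).
#' @export
cit_independence_p4 <- function(g, m, y, covariates = NULL, n_perm = 1000,
                                seed = NULL) {
  if (n_perm < 100) stop_spec("n_perm must be >= 100")
  if (!is.null(cit_screen(g, m, y))) return(NA_real_)
  n <- length(y)
  X0 <- base_design(n, covariates)
  lin <- stats::lm.fit(cbind(X0, g = g), m)
  fitted <- m - lin$residuals
  stat_g <- function(mm) {
    max(logit_fit(cbind(X0, m = mm), y)$deviance -
          logit_fit(cbind(X0, m = mm, g = g), y)$deviance, 0)
  }
  t_obs <- stat_g(m)
  t_null <- maybe_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) stat_g(fitted + sample(lin$residuals)), 0)
  })
  (1 + sum(t_null <= t_obs)) / (n_perm + 1)
}

# reactive-direction p4: outcome is m (linear), mediator is y; the null
# permutes y within rounded-dosage strata, preserving the g-y association
# exactly by conditional exchangeability
cit_reactive_p4 <- function(g, m, y, covariates = NULL, n_perm = 1000,
                            seed = NULL) {
  if (!is.null(cit_screen(g, m, y))) return(NA_real_)
  n <- length(y)
  X0 <- base_design(n, covariates)
  strata <- split(seq_len(n), round(g))
  stat_g <- function(yy) {
    f <- linear_partial_f(cbind(X0, y = yy), cbind(X0, y = yy, g = g), m)
    if (isTRUE(f$degenerate)) 0 else f$stat
  }
  t_obs <- stat_g(y)
  t_null <- maybe_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yy <- y
      for (idx in strata) if (length(idx) > 1) yy[idx] <- y[sample(idx)]
      stat_g(yy)
    }, 0)
  })
  (1 + sum(t_null <= t_obs)) / (n_perm + 1)
}

# reactive-direction analytic components (roles of m and y swapped; the
# outcome m is continuous so its models are linear)
cit_reactive_components <- function(g, m, y, covariates = NULL) {
  bad <- cit_screen(g, m, y)
  if (!is.null(bad))
    return(list(p1 = NA_real_, p2 = NA_real_, p3 = NA_real_,
                untestable = TRUE, reason = bad))
  n <- length(y)
  X0 <- base_design(n, covariates)
  t1 <- linear_partial_f(X0, cbind(X0, g = g), m)
  t2 <- logistic_lrt(cbind(X0, m = m), cbind(X0, m = m, g = g), y)
  t3 <- linear_partial_f(cbind(X0, g = g), cbind(X0, g = g, y = y), m)
  untestable <- t2$separation || isTRUE(t1$degenerate) || isTRUE(t3$degenerate)
  list(p1 = t1$p, p2 = t2$p, p3 = t3$p, untestable = untestable,
       reason = if (untestable) "separation or degenerate fit" else NA_character_)
}

#' Omnibus CIT p-value for one direction
#'
#' The maximum of the four component p-values; the causal claim of the
#' direction is supported only when every component is individually small,
#' which makes the omnibus conservative by construction.
#'
#' @inheritParams cit_independence_p4
#' @param direction `"causal"` (mediator m, outcome y) or `"reactive"`
#'   (roles swapped).
#' @return list with `omnibus_p` and the component list.
#' @export
cit_omnibus <- function(g, m, y, covariates = NULL, n_perm = 1000,
                        seed = NULL, direction = c("causal", "reactive")) {
  direction <- match.arg(direction)
  if (direction == "causal") {
    comp <- cit_component_pvalues(g, m, y, covariates)
    p4 <- if (comp$untestable) NA_real_ else
      cit_independence_p4(g, m, y, covariates, n_perm, seed)
  } else {
    comp <- cit_reactive_components(g, m, y, covariates)
    p4 <- if (comp$untestable) NA_real_ else
      cit_reactive_p4(g, m, y, covariates, n_perm, seed)
  }
  comp$p4 <- p4
  omnibus <- if (comp$untestable) NA_real_ else
    max(comp$p1, comp$p2, comp$p3, p4)
  list(omnibus_p = omnibus, components = comp)
}

#' Classify a (G, M, Y) triplet
#'
#' Runs the omnibus test in both directions and calls the triplet
#' `mediation` when only the causal direction is significant at `alpha`,
#' `consequential` when only the reactive direction is, `ambiguous` when
#' both are, `independent` when neither is, and `untestable` when a
#' direction could not be fit.
#'
#' @inheritParams cit_independence_p4
#' @param alpha significance level for the calls (default 0.05).
#' @param variant_id,region_id labels carried into the result.
#' @return object of class `cit_result` with per-direction p1-p4 and
#'   omnibus p-values, the call, and the G:Y coefficient with and without
#'   adjustment for M.
#' @export
cit_classify <- function(g, m, y, covariates = NULL, alpha = 0.05,
                         n_perm = 1000, seed = NULL,
                         variant_id = "g", region_id = "m") {
  seed2 <- if (is.null(seed)) NULL else as.integer(seed) + 1L
  causal <- cit_omnibus(g, m, y, covariates, n_perm, seed, "causal")
  reactive <- cit_omnibus(g, m, y, covariates, n_perm, seed2, "reactive")
  call <- if (is.na(causal$omnibus_p) || is.na(reactive$omnibus_p)) {
    "untestable"
  } else if (causal$omnibus_p < alpha && reactive$omnibus_p >= alpha) {
    "mediation"
  } else if (reactive$omnibus_p < alpha && causal$omnibus_p >= alpha) {
    "consequential"
  } else if (causal$omnibus_p < alpha && reactive$omnibus_p < alpha) {
    "ambiguous"
  } else {
    "independent"
  }
  structure(list(variant_id = variant_id, region_id = region_id,
                 causal = causal, reactive = reactive, call = call,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 beta_gy = causal$components$beta_gy,
                 beta_gy_adj_m = causal$components$beta_gy_adj_m),
            class = "cit_result")
}

#' @export
print.cit_result <- function(x, ...) {
  fmt <- function(d) {
    cm <- d$components
    sprintf("p1 %.3g, p2 %.3g, p3 %.3g, p4 %.3g -> omnibus %.3g",
            cm$p1, cm$p2, cm$p3, cm$p4, d$omnibus_p)
  }
  cat("<cit_result> ", x$variant_id, " x ", x$region_id, "\n",
      "  causal   (G->M->Y): ", fmt(x$causal), "\n",
      "  reactive (G->Y->M): ", fmt(x$reactive), "\n",
      "  call: ", x$call, " (alpha ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Flatten CIT results to a table
#'
#' @param results list of `cit_result` objects.
#' @return data.frame with one row per triplet mirroring the supplementary
#'   table layout: SNP, DMR, both directions' p1-p4 and omnibus, and the
#'   call.
#' @export
cit_results_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    cc <- x$causal$components; rc <- x$reactive$components
    data.frame(SNP = x$variant_id, DMR = x$region_id,
               p1 = cc$p1, p2 = cc$p2, p3 = cc$p3, p4 = cc$p4,
               omnibus = x$causal$omnibus_p,
               p1_rev = rc$p1, p2_rev = rc$p2, p3_rev = rc$p3, p4_rev = rc$p4,
               omnibus_rev = x$reactive$omnibus_p,
               call = x$call, stringsAsFactors = FALSE)
  }))
}
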