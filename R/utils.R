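# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_spec <- function(...) stop(..., call. = FALSE)

# run `code` under a fixed RNG state without disturbing the caller's stream;
# seed = NULL uses (and advances) the current stream
maybe_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Dirichlet draws via independent gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# logistic fit on a raw design matrix; returns deviance plus a separation
# flag (non-convergence or runaway coefficients)
logit_fit <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  coefs <- fit$coefficients
  sep <- !fit$converged || any(abs(coefs[!is.na(coefs)]) > 15)
  se <- rep(NA_real_, ncol(X))
  ok <- seq_len(fit$rank)
  R <- fit$qr$qr[ok, ok, drop = FALSE]
  R[lower.tri(R)] <- 0
  covm <- try(chol2inv(R), silent = TRUE)
  if (!inherits(covm, "try-error")) {
    piv <- fit$qr$pivot[ok]
    se[piv] <- sqrt(pmax(diag(covm), 0))
  }
  list(deviance = fit$deviance, coef = coefs, se = se,
       separation = sep, rank = fit$rank, converged = fit$converged)
}

# likelihood-ratio test of the trailing column(s) of X1 against nested X0
logistic_lrt <- function(X0, X1, y) {
  f0 <- logit_fit(X0, y)
  f1 <- logit_fit(X1, y)
  df <- ncol(X1) - ncol(X0)
  stat <- max(f0$deviance - f1$deviance, 0)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       beta = unname(f1$coef[ncol(X1)]), se = f1$se[ncol(X1)],
       separation = f0$separation || f1$separation)
}

# partial F test of the trailing column(s) of X1 against nested X0 (gaussian)
linear_partial_f <- function(X0, X1, y) {
  r0 <- stats::lm.fit(X0, y)
  r1 <- stats::lm.fit(X1, y)
  rss0 <- sum(r0$residuals^2)
  rss1 <- sum(r1$residuals^2)
  df1 <- r1$rank - r0$rank
  df2 <- length(y) - r1$rank
  if (df1 <= 0 || df2 <= 0 || rss1 <= 0) {
    return(list(stat = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                beta = NA_real_, degenerate = TRUE))
  }
  stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(stat = stat, df1 = df1, df2 = df2,
       p = stats::pf(stat, df1, df2, lower.tail = FALSE),
       beta = unname(r1$coefficients[ncol(X1)]), degenerate = FALSE)
}

# design matrix [1 | covariates]; covariates may be NULL, a matrix or df
base_design <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cv <- as.matrix(covariates)
  if (nrow(cv) != n) stop_spec("covariates have ", nrow(cv), " rows, expected ", n)
  if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  cbind(`(Intercept)` = 1, cv)
}

complement_allele <- function(a) chartr("ACGT", "TGCA", toupper(a))

is_palindromic <- function(a1, a2) {
  s <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  s %in% c("A T", "C G")
}
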