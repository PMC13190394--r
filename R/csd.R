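#' Pairwise cross-sectional correlations of residual rows
#'
#' Sample Pearson correlations between every pair of units' residual
#' series, the building block of all cross-sectional dependence (CSD)
#' statistics.
#'
#' @param residual_matrix N x T numeric matrix, one row per unit.
#' @return N x N correlation matrix (only the upper triangle is used by
#'   the tests; diagonal is 1).
#' @export
pairwise_correlations <- function(residual_matrix) {
  m <- as.matrix(residual_matrix)
  if (nrow(m) < 2L) stop("need at least two units", call. = FALSE)
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1L]
    lbl <- if (!is.null(rownames(m))) rownames(m)[bad] else as.character(bad)
    stop("degenerate (zero-variance) residual series for unit '", lbl, "'",
         call. = FALSE)
  }
  stats::cor(t(m))
}

new_csd_result <- function(test_name, statistic, p_value, N, T) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, N = N, T = T),
            class = "csd_result")
}

#' @export
print.csd_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (N = %d, T = %d)\n",
              x$test_name, x$statistic, x$p_value, x$N, x$T))
  invisible(x)
}

upper_pairs <- function(corr) corr[upper.tri(corr)]

#' Breusch-Pagan LM test of cross-sectional independence
#'
#' Statistic \eqn{T \sum_{i<j} \hat\rho_{ij}^2}, asymptotically
#' chi-square with N(N-1)/2 degrees of freedom under independence; suited
#' to panels where T is large relative to N.
#'
#' @param corr N x N pairwise correlation matrix
#'   (see [pairwise_correlations()]).
#' @param T number of time observations behind each correlation.
#' @return a `csd_result`.
#' @export
breusch_pagan_lm <- function(corr, T) {
  N <- nrow(corr)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  rho <- upper_pairs(corr)
  stat <- T * sum(rho^2)
  df <- N * (N - 1) / 2
  new_csd_result("BP_LM", stat, stats::pchisq(stat, df, lower.tail = FALSE),
                 N, T)
}

#' Pesaran scaled LM test of cross-sectional independence
#'
#' Standardizes the Breusch-Pagan statistic,
#' \eqn{\sqrt{1/(N(N-1))} \sum_{i<j} (T \hat\rho_{ij}^2 - 1)}, compared
#' to the standard normal (upper tail).
#'
#' @inheritParams breusch_pagan_lm
#' @return a `csd_result`.
#' @export
pesaran_scaled_lm <- function(corr, T) {
  N <- nrow(corr)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  rho <- upper_pairs(corr)
  stat <- sqrt(1 / (N * (N - 1))) * sum(T * rho^2 - 1)
  new_csd_result("scaled_LM", stat,
                 stats::pnorm(stat, lower.tail = FALSE), N, T)
}

#' Pesaran CD test of cross-sectional independence
#'
#' \eqn{CD = \sqrt{2T/(N(N-1))} \sum_{i<j} \hat\rho_{ij}}, standard
#' normal under the null for a wide range of N and T; two-sided p-value.
#' Because positive and negative correlations cancel, CD keeps its size
#' even when N exceeds T.
#'
#' @inheritParams breusch_pagan_lm
#' @return a `csd_result`.
#' @export
pesaran_cd <- function(corr, T) {
  N <- nrow(corr)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  rho <- upper_pairs(corr)
  stat <- sqrt(2 * T / (N * (N - 1))) * sum(rho)
  new_csd_result("CD", stat, 2 * stats::pnorm(-abs(stat)), N, T)
}

#' Bias-adjusted LM test of cross-sectional independence
#'
#' The Pesaran-Ullah-Yamagata correction of the Breusch-Pagan LM test for
#' panels where N is large relative to T: each squared correlation of OLS
#' residuals is centred and scaled by its exact finite-sample mean and
#' variance before standardizing. The mean and variance terms use the
#' annihilator matrices \eqn{M_i = I - X_i (X_i'X_i)^{-1} X_i'} of the
#' unit-wise regressions that produced the residuals.
#'
#' @param residual_matrix N x T matrix of unit-wise OLS residuals.
#' @param X_list list of N design matrices (T x k, including any
#'   intercept column) behind those residuals. A single matrix is
#'   recycled for all units.
#' @return a `csd_result`.
#' @export
bias_adjusted_lm <- function(residual_matrix, X_list) {
  m <- as.matrix(residual_matrix)
  N <- nrow(m); T <- ncol(m)
  if (N < 2L) stop("need N >= 2", call. = FALSE)
  if (is.matrix(X_list)) X_list <- rep(list(X_list), N)
  stopifnot(length(X_list) == N)
  k <- ncol(X_list[[1L]])
  if (T <= k + 1L) stop("need T > k + 1", call. = FALSE)
  corr <- pairwise_correlations(m)

  Tk <- T - k
  a2 <- 3 * ((Tk - 8) * (Tk + 2) + 24)^2 /
    ((Tk + 2) * (Tk - 2) * (Tk - 4))^2
  a1 <- a2 - 1 / Tk^2

  M <- lapply(X_list, function(X) {
    X <- as.matrix(X)
    diag(T) - X %*% solve(crossprod(X), t(X))
  })

  total <- 0
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      P <- M[[i]] %*% M[[j]]
      trP <- sum(diag(P))
      trP2 <- sum(P * t(P))
      mu <- trP / Tk
      v2 <- trP^2 * a1 + 2 * trP2 * a2
      total <- total + (Tk * corr[i, j]^2 - mu) / sqrt(v2)
    }
  }
  stat <- sqrt(2 / (N * (N - 1))) * total
  new_csd_result("bias_adjusted_LM", stat,
                 stats::pnorm(stat, lower.tail = FALSE), N, T)
}

# Unit-wise residuals used by the per-variable CSD report.
# "adf1": residuals of y_t on intercept + y_{t-1} (one row per unit,
#   T - 1 columns); levels of trending series would make the raw
#   correlations degenerate, so a dynamic filter is the default.
# "level_demeaned": time-demeaned levels.
csd_residuals <- function(panel, variable, residual_model = c("adf1", "level_demeaned")) {
  residual_model <- match.arg(residual_model)
  y <- panel_matrix(panel, variable)
  if (residual_model == "level_demeaned") {
    res <- y - rowMeans(y)
    return(list(residuals = res, X_list = NULL, k = 1L))
  }
  T <- ncol(y)
  res <- matrix(NA_real_, nrow(y), T - 1L, dimnames = list(rownames(y), NULL))
  X_list <- vector("list", nrow(y))
  for (i in seq_len(nrow(y))) {
    yi <- y[i, ]
    X <- cbind(1, yi[-T])
    fit <- stats::lm.fit(X, yi[-1L])
    res[i, ] <- fit$residuals
    X_list[[i]] <- X
  }
  list(residuals = res, X_list = X_list, k = 2L)
}

#' Per-variable cross-sectional dependence report
#'
#' Runs the Breusch-Pagan LM, Pesaran scaled LM, Pesaran CD and
#' bias-adjusted LM tests on unit-wise residuals of each variable.
#'
#' @param panel a [balanced_panel()].
#' @param variables variables to test; default all.
#' @param residual_model `"adf1"` (default; residuals of a unit-wise
#'   regression of the level on an intercept and its own first lag) or
#'   `"level_demeaned"` (time-demeaned levels). The choice is recorded in
#'   the output.
#' @return data frame with one row per (variable, test): statistic,
#'   p-value, N, T, residual model.
#' @export
csd_report <- function(panel, variables = names(panel$values),
                       residual_model = "adf1") {
  rows <- list()
  for (v in variables) {
    rs <- csd_residuals(panel, v, residual_model)
    corr <- pairwise_correlations(rs$residuals)
    Tr <- ncol(rs$residuals)
    tests <- list(breusch_pagan_lm(corr, Tr),
                  pesaran_scaled_lm(corr, Tr),
                  pesaran_cd(corr, Tr))
    if (!is.null(rs$X_list))
      tests <- c(tests, list(bias_adjusted_lm(rs$residuals, rs$X_list)))
    for (tt in tests)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = tt$test_name, statistic = tt$statistic,
        p_value = tt$p_value, N = tt$N, T = tt$T,
        residual_model = residual_model, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pesaran-Yamagata slope homogeneity test
#'
#' Tests whether regression slopes are identical across panel units
#' (H0: beta_i = beta for all i) via the weighted dispersion of unit-wise
#' OLS slopes around the pooled weighted fixed-effects slope:
#' \deqn{\tilde\Delta = \sqrt{N} (N^{-1}\tilde S - k) / \sqrt{2k}}
#' and its small-sample adjusted version with mean k and variance
#' 2k(T-k-1)/(T+1). Upper-tail standard-normal p-values.
#'
#' @param panel a [balanced_panel()].
#' @param dependent dependent variable name.
#' @param regressors character vector of regressor variable names.
#' @return list of class `slope_homogeneity_result` with `S_tilde`,
#'   `delta_tilde`, `delta_tilde_adj`, `k`, `p_values` (named pair) and
#'   the panel dimensions.
#' @export
slope_homogeneity <- function(panel, dependent, regressors) {
  k <- length(regressors)
  N <- panel$N; T <- panel$T
  if (T <= k + 2L) stop("need T > k + 2", call. = FALSE)

  # time-demean per unit (fixed-effects transform with unit intercepts)
  ymat <- panel_matrix(panel, dependent)
  Xarr <- lapply(regressors, function(v) panel_matrix(panel, v))

  beta_i <- matrix(NA_real_, N, k)
  XtX <- vector("list", N)
  Xty <- vector("list", N)
  Xd <- vector("list", N)
  yd <- vector("list", N)
  for (i in seq_len(N)) {
    yi <- ymat[i, ] - mean(ymat[i, ])
    Xi <- sapply(Xarr, function(m) m[i, ] - mean(m[i, ]))
    Xi <- matrix(Xi, ncol = k)
    qrX <- qr(Xi)
    if (qrX$rank < k)
      stop("rank-deficient regressor matrix for unit '", panel$units[i], "'",
           call. = FALSE)
    beta_i[i, ] <- qr.coef(qrX, yi)
    XtX[[i]] <- crossprod(Xi)
    Xty[[i]] <- crossprod(Xi, yi)
    Xd[[i]] <- Xi
    yd[[i]] <- yi
  }

  # null-consistent variance estimates: residuals at the pooled
  # (unweighted fixed-effects) slope, divided by T - 1. This scaling is
  # what gives the dispersion terms exact mean k and variance
  # 2k(T-k-1)/(T+1) under homogeneity with normal errors.
  beta_fe <- solve(Reduce(`+`, XtX), Reduce(`+`, Xty))
  sig2 <- vapply(seq_len(N), function(i) {
    e <- yd[[i]] - Xd[[i]] %*% beta_fe
    sum(e^2) / (T - 1L)
  }, numeric(1))

  A <- Reduce(`+`, Map(function(a, s) a / s, XtX, sig2))
  b <- Reduce(`+`, Map(function(a, s) a / s, Xty, sig2))
  beta_wfe <- solve(A, b)

  S <- 0
  for (i in seq_len(N)) {
    d <- beta_i[i, ] - beta_wfe
    S <- S + drop(t(d) %*% XtX[[i]] %*% d) / sig2[i]
  }

  delta <- sqrt(N) * (S / N - k) / sqrt(2 * k)
  v_adj <- 2 * k * (T - k - 1) / (T + 1)
  delta_adj <- sqrt(N) * (S / N - k) / sqrt(v_adj)
  structure(list(
    S_tilde = S, delta_tilde = delta, delta_tilde_adj = delta_adj, k = k,
    p_values = c(delta_tilde = stats::pnorm(delta, lower.tail = FALSE),
                 delta_tilde_adj = stats::pnorm(delta_adj, lower.tail = FALSE)),
    N = N, T = T, dependent = dependent, regressors = regressors),
    class = "slope_homogeneity_result")
}

#' @export
print.slope_homogeneity_result <- function(x, ...) {
  cat(sprintf("Slope homogeneity (%s ~ %s), N = %d, T = %d\n",
              x$dependent, paste(x$regressors, collapse = " + "), x$N, x$T))
  cat(sprintf("  Delta tilde      %8.3f  (p = %.4g)\n",
              x$delta_tilde, x$p_values[["delta_tilde"]]))
  cat(sprintf("  Delta tilde adj. %8.3f  (p = %.4g)\n",
              x$delta_tilde_adj, x$p_values[["delta_tilde_adj"]]))
  invisible(x)
}
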