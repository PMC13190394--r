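# Heterogeneous panel Granger causality via per-unit lag-augmented VARs
# (Toda-Yamamoto), Fisher combination of country p-values, and a residual
# bootstrap that preserves contemporaneous cross-sectional correlation.

# lagged values y[rows - j] for j = 1..m, as a matrix
lag_block <- function(y, rows, m) {
  vapply(seq_len(m), function(j) y[rows - j], numeric(length(rows)))
}

# OLS of the target equation of a bivariate level VAR(k + d):
# y_t on intercept, y lags 1..k+d, x lags 1..k+d (sample rows start..T).
# Returns the Wald statistic for joint nullity of x lags 1..k.
lavar_wald_core <- function(y, x, k, d, start) {
  T <- length(y)
  m <- k + d
  rows <- start:T
  n <- length(rows)
  X <- cbind(1, lag_block(y, rows, m), lag_block(x, rows, m))
  npar <- ncol(X)
  if (n - npar < 2L) stop("insufficient observations for VAR(", m, ")",
                          call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < npar) stop("singular design matrix", call. = FALSE)
  b <- qr.coef(qrX, y[rows])
  e <- y[rows] - X %*% b
  s2 <- sum(e^2) / (n - npar)
  XtXinv <- chol2inv(qr.R(qrX))
  idx <- (1L + m + 1L):(1L + m + k)     # first k cross-lag coefficients
  bk <- b[idx]
  V <- s2 * XtXinv[idx, idx, drop = FALSE]
  w <- drop(t(bk) %*% solve(V, bk))
  list(wald = w, coef = b, residuals = as.vector(e), nobs = n)
}

# Restricted (null) fit: x lags 1..k excluded, lags k+1..k+d kept.
# Returns coefficients split for the recursive rebuild, and residuals.
lavar_restricted <- function(y, x, k, d, start) {
  T <- length(y)
  m <- k + d
  rows <- start:T
  X <- cbind(1, lag_block(y, rows, m))
  if (d > 0L)
    X <- cbind(X, vapply((k + 1L):m, function(j) x[rows - j],
                         numeric(length(rows))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  b <- qr.coef(qrX, y[rows])
  e <- y[rows] - X %*% b
  list(intercept = b[1L], own = b[2L:(1L + m)],
       cross = if (d > 0L) b[(m + 2L):(m + 1L + d)] else numeric(0),
       cross_lags = if (d > 0L) (k + 1L):m else integer(0),
       residuals = as.vector(e))
}

# Rebuild a pseudo target series recursively from restricted estimates,
# observed initial conditions and a resampled innovation vector.
rebuild_series <- function(y, x, fit, m, start, innov) {
  T <- length(y)
  ystar <- y
  for (t in start:T) {
    v <- fit$intercept + sum(fit$own * ystar[(t - 1L):(t - m)])
    if (length(fit$cross) > 0L)
      v <- v + sum(fit$cross * x[t - fit$cross_lags])
    ystar[t] <- v + innov[t - start + 1L]
  }
  ystar
}

# Lean OLS Wald p-value used inside the bootstrap loop: same estimator as
# lavar_wald_core but via Cholesky on the normal equations. Returns NA on
# a (near-)singular design.
wald_p_fast <- function(yr, X, k, m) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-10 * max(diag(ch)))) return(NA_real_)
  XtXinv <- chol2inv(ch)
  b <- XtXinv %*% crossprod(X, yr)
  e <- yr - X %*% b
  s2 <- sum(e^2) / (length(yr) - ncol(X))
  idx <- (1L + m + 1L):(1L + m + k)
  bk <- b[idx]
  w <- drop(t(bk) %*% solve(s2 * XtXinv[idx, idx, drop = FALSE], bk))
  if (!is.finite(w) || w < 0) return(NA_real_)
  stats::pchisq(w, k, lower.tail = FALSE)
}

# Bootstrap distribution of the Fisher statistic for one direction.
# Whole cross-sectional residual vectors (all units, same time index) are
# resampled i.i.d. with replacement from the centred null-restricted
# residuals; pseudo target series are rebuilt recursively (vectorized
# across units) from the restricted estimates and observed initial
# conditions, with the source series held at its observed values.
ek_boot_direction <- function(tgt, src, k_i, dmax, start, B, p_floor) {
  N <- nrow(tgt); T <- ncol(tgt)
  L <- T - start + 1L
  m <- k_i + dmax
  m_max <- max(m)
  rowsT <- start:T

  C0 <- numeric(N)
  A <- matrix(0, N, m_max)
  E <- matrix(0, N, L)
  xpart <- matrix(0, N, L)
  Xx <- vector("list", N)
  for (i in seq_len(N)) {
    f <- lavar_restricted(tgt[i, ], src[i, ], k_i[i], dmax, start)
    C0[i] <- f$intercept
    A[i, seq_len(m[i])] <- f$own
    E[i, ] <- f$residuals - mean(f$residuals)
    if (length(f$cross) > 0L) {
      xp <- numeric(L)
      for (jj in seq_along(f$cross_lags))
        xp <- xp + f$cross[jj] * src[i, rowsT - f$cross_lags[jj]]
      xpart[i, ] <- xp
    }
    Xx[[i]] <- cbind(1, lag_block(src[i, ], rowsT, m[i]))
  }

  lam_star <- numeric(B)
  redraws <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(L, L, replace = TRUE)
    Y <- tgt
    for (t in rowsT) {
      lagcols <- Y[, t - seq_len(m_max), drop = FALSE]
      Y[, t] <- C0 + rowSums(A * lagcols) + xpart[, t - start + 1L] +
        E[, idx[t - start + 1L]]
    }
    ps <- numeric(N)
    ok <- TRUE
    for (i in seq_len(N)) {
      X <- cbind(lag_block(Y[i, ], rowsT, m[i]), Xx[[i]])
      # column order [ylags | 1 | xlags]: reorder to [1 | ylags | xlags]
      X <- X[, c(m[i] + 1L, seq_len(m[i]), (m[i] + 2L):ncol(X)), drop = FALSE]
      ps[i] <- wald_p_fast(Y[i, rowsT], X, k_i[i], m[i])
      if (is.na(ps[i])) { ok <- FALSE; break }
    }
    if (!ok) {
      redraws <- redraws + 1L
      if (redraws > 0.1 * B)
        stop("bootstrap replicate failures exceeded 10% of B", call. = FALSE)
      next
    }
    lam_star[b] <- fisher_combine(ps, p_floor)
    b <- b + 1L
  }
  list(lambda_star = lam_star, redraws = redraws)
}

#' Select the VAR lag order by AIC
#'
#' Fits the bivariate level VAR at orders 1..k_max on the common
#' effective sample t = k_max + dmax + 1, ..., T (so every candidate is
#' judged on the same observations) and returns the AIC-minimizing order;
#' ties break toward the smaller order.
#'
#' @param y_block 2 x T numeric matrix (two level series in rows).
#' @param k_max maximum candidate order (default 3).
#' @param dmax augmentation order used downstream (enters only through
#'   the common sample offset).
#' @return selected integer order k.
#' @export
select_lag_aic <- function(y_block, k_max = 3L, dmax = 1L) {
  stopifnot(nrow(y_block) == 2L)
  T <- ncol(y_block)
  start <- k_max + dmax + 1L
  n <- T - start + 1L
  if (n < 2L * (k_max + dmax) + 3L)
    stop("insufficient observations for lag selection with k_max = ",
         k_max, call. = FALSE)
  y1 <- y_block[1L, ]; y2 <- y_block[2L, ]
  rows <- start:T
  aic <- numeric(k_max)
  for (j in seq_len(k_max)) {
    X <- cbind(1, lag_block(y1, rows, j), lag_block(y2, rows, j))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) { aic[j] <- Inf; next }
    E <- cbind(qr.resid(qrX, y1[rows]), qr.resid(qrX, y2[rows]))
    S <- crossprod(E) / n
    det_ <- det(S)
    if (!is.finite(det_) || det_ <= 0) { aic[j] <- Inf; next }
    npar <- 2L * ncol(X)
    aic[j] <- log(det_) + 2 * npar / n
  }
  if (all(!is.finite(aic))) stop("lag selection failed: all candidate VARs singular",
                                 call. = FALSE)
  which.min(aic)  # which.min takes the first (smallest order) on ties
}

#' Country-level lag-augmented Wald causality test
#'
#' Estimates the target equation of the bivariate level VAR(k_i + dmax)
#' with intercept for one unit and tests joint nullity of the first k_i
#' lags of the source variable by a Wald statistic; the dmax augmentation
#' lags are left unrestricted so the statistic keeps its chi-square(k_i)
#' null distribution whatever the integration/cointegration properties of
#' the system.
#'
#' @param y_block 2 x T matrix: row 1 the source (x), row 2 the target
#'   (y) level series.
#' @param k_i lag order for the unit.
#' @param dmax augmentation order (maximum integration order).
#' @param start first sample period of the regression; default
#'   `k_i + dmax + 1` (the unit's maximal sample). Panel routines pass a
#'   common start so all units share the effective sample.
#' @param unit_id optional label.
#' @return list of class `country_causality`: `unit_id`, `wald`, `df`,
#'   `p_value`, `k_i`, `dmax`, `nobs`.
#' @export
lavar_wald <- function(y_block, k_i, dmax = 1L, start = NULL,
                       unit_id = NA_character_) {
  stopifnot(nrow(y_block) == 2L)
  x <- y_block[1L, ]; y <- y_block[2L, ]
  if (is.null(start)) start <- k_i + dmax + 1L
  fit <- lavar_wald_core(y, x, k_i, dmax, start)
  structure(list(unit_id = unit_id, wald = fit$wald, df = k_i,
                 p_value = stats::pchisq(fit$wald, k_i, lower.tail = FALSE),
                 k_i = k_i, dmax = dmax, nobs = fit$nobs),
            class = "country_causality")
}

#' Fisher combination of country p-values
#'
#' \eqn{\lambda = -2 \sum_i \ln \pi_i}; chi-square with 2N degrees of
#' freedom under cross-sectional independence and the joint null.
#'
#' @param p_values numeric vector of per-country p-values.
#' @param p_floor values below this are floored before taking logs (a
#'   zero p-value would make lambda infinite).
#' @return the Fisher statistic lambda.
#' @export
fisher_combine <- function(p_values, p_floor = 1e-16) {
  if (length(p_values) == 0L) stop("empty p-value list", call. = FALSE)
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  -2 * sum(log(pmax(p_values, p_floor)))
}

#' Panel causality test for one variable pair with bootstrap inference
#'
#' Runs the heterogeneous panel causality procedure for an ordered
#' variable pair: per-unit AIC lag selection (shared by both directions),
#' per-unit lag-augmented Wald tests, Fisher combination across units,
#' and a residual bootstrap of the panel statistic. The bootstrap
#' resamples whole cross-sectional residual vectors (all units, same time
#' index) from the null-restricted fits, preserving the contemporaneous
#' correlation structure that invalidates the asymptotic chi-square(2N)
#' reference distribution.
#'
#' @param panel a [balanced_panel()].
#' @param pair length-2 character vector (variable A, variable B).
#' @param directions which directional tests to run: `"both"` (default),
#'   `"A->B"` or `"B->A"`.
#' @param k_max maximum lag order for AIC selection.
#' @param dmax augmentation order (maximum integration order).
#' @param B bootstrap replicates (values below 100 trigger a warning).
#' @param seed integer seed for the bootstrap resampling.
#' @param p_floor floor applied inside [fisher_combine()].
#' @return list of class `causality_pair_result`: `pair`, `k_i` (named
#'   per unit), and `per_direction`, a named list with one entry per
#'   direction holding the per-country results (data frame), `lambda`,
#'   `asymptotic_p`, `bootstrap_p`, `B`, `seed` and the redraw count.
#' @export
bootstrap_panel_causality <- function(panel, pair, directions = "both",
                                      k_max = 3L, dmax = 1L, B = 1000L,
                                      seed = 1L, p_floor = 1e-16) {
  stopifnot(inherits(panel, "balanced_panel"), length(pair) == 2L)
  A <- pair[1L]; Bv <- pair[2L]
  if (!all(pair %in% names(panel$values)))
    stop("unknown variable in pair", call. = FALSE)
  B <- as.integer(B)
  if (B < 100L) warning("B < 100 bootstrap replicates: p-values will be coarse")
  N <- panel$N; T <- panel$T
  start <- k_max + dmax + 1L
  L <- T - start + 1L
  ma <- panel_matrix(panel, A)
  mb <- panel_matrix(panel, Bv)

  # one lag order per unit per pair, shared by both directions
  k_i <- integer(N)
  for (i in seq_len(N))
    k_i[i] <- select_lag_aic(rbind(ma[i, ], mb[i, ]), k_max = k_max,
                             dmax = dmax)
  names(k_i) <- panel$units

  dir_names <- switch(directions,
    both = c(paste0(A, "->", Bv), paste0(Bv, "->", A)),
    `A->B` = paste0(A, "->", Bv),
    `B->A` = paste0(Bv, "->", A),
    stop("directions must be 'both', 'A->B' or 'B->A'", call. = FALSE))

  set.seed(as.integer(seed))
  per_direction <- list()
  for (dn in dir_names) {
    if (dn == paste0(A, "->", Bv)) { src <- ma; tgt <- mb }
    else { src <- mb; tgt <- ma }

    wald <- pval <- numeric(N)
    for (i in seq_len(N)) {
      r <- lavar_wald_core(tgt[i, ], src[i, ], k_i[i], dmax, start)
      wald[i] <- r$wald
      pval[i] <- stats::pchisq(r$wald, k_i[i], lower.tail = FALSE)
    }
    lambda <- fisher_combine(pval, p_floor)

    boot <- ek_boot_direction(tgt, src, k_i, dmax, start, B, p_floor)

    per_direction[[dn]] <- list(
      countries = data.frame(country = panel$units, statistic = wald,
                             df = k_i, p_value = pval,
                             stringsAsFactors = FALSE, row.names = NULL),
      lambda = lambda,
      asymptotic_p = stats::pchisq(lambda, 2L * N, lower.tail = FALSE),
      bootstrap_p = (1 + sum(boot$lambda_star >= lambda)) / (B + 1),
      lambda_star = boot$lambda_star, B = B, seed = seed,
      redraws = boot$redraws)
  }

  notes <- character(0)
  if (N >= T)
    notes <- "N >= T: asymptotic chi-square(2N) inference is unreliable; use the bootstrap p-value."
  structure(list(pair = c(A, Bv), k_i = k_i, per_direction = per_direction,
                 start = start, dmax = dmax, notes = notes),
            class = "causality_pair_result")
}

#' @export
print.causality_pair_result <- function(x, ...) {
  cat(sprintf("Panel causality, pair (%s, %s); dmax = %d\n",
              x$pair[1L], x$pair[2L], x$dmax))
  for (dn in names(x$per_direction)) {
    d <- x$per_direction[[dn]]
    cat(sprintf("  %-14s lambda = %8.3f  asy p = %.4f  boot p = %.4f (B = %d)\n",
                dn, d$lambda, d$asymptotic_p, d$bootstrap_p, d$B))
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Run the causality test for every variable pair
#'
#' @param panel a [balanced_panel()].
#' @param variables three (or more) variable names; every unordered pair
#'   is tested in both directions.
#' @inheritParams bootstrap_panel_causality
#' @return named list of `causality_pair_result` objects, keyed
#'   `"A:B"`.
#' @export
run_all_pairs <- function(panel, variables = names(panel$values),
                          k_max = 3L, dmax = 1L, B = 1000L, seed = 1L,
                          p_floor = 1e-16) {
  if (length(variables) < 2L) stop("need at least two variables", call. = FALSE)
  pairs <- utils::combn(variables, 2L, simplify = FALSE)
  out <- list()
  for (j in seq_along(pairs)) {
    pr <- pairs[[j]]
    out[[paste(pr, collapse = ":")]] <- bootstrap_panel_causality(
      panel, pr, directions = "both", k_max = k_max, dmax = dmax, B = B,
      seed = stream_seed(seed, paste0("pair:", paste(pr, collapse = ":"))),
      p_floor = p_floor)
  }
  out
}

significance_stars <- function(p) {
  ifelse(p <= 0.01, "***", ifelse(p <= 0.05, "**", ifelse(p <= 0.10, "*", "")))
}

#' Tabulate a directional causality result like the published tables
#'
#' One row per country (statistic with significance stars, p-value) plus
#' a final Fisher row carrying the panel statistic and its bootstrap
#' p-value.
#'
#' @param result a `causality_pair_result`.
#' @param direction direction name (e.g. `"co2->migr"`); default the
#'   first direction in the result.
#' @return data frame with columns country, statistic, p_value, signif.
#' @export
ek_table <- function(result, direction = names(result$per_direction)[1L]) {
  d <- result$per_direction[[direction]]
  if (is.null(d)) stop("unknown direction '", direction, "'", call. = FALSE)
  tab <- d$countries
  rows <- data.frame(
    country = c(tab$country, "Fisher test statistic"),
    statistic = c(tab$statistic, d$lambda),
    p_value = c(tab$p_value, d$bootstrap_p),
    stringsAsFactors = FALSE)
  rows$signif <- significance_stars(rows$p_value)
  rows
}
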