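#' Cross-sectionally augmented Dickey-Fuller (CADF) regression
#'
#' Regresses the first difference of one unit's series on an intercept
#' (and optionally a trend), the lagged level, the cross-sectional average
#' of the lagged level, the cross-sectional average of the first
#' difference, and p lags of both the unit's own difference and the
#' average difference. The t-ratio of the lagged-level coefficient is the
#' unit's CADF statistic; augmenting with the cross-sectional averages
#' absorbs a common factor that would otherwise distort the ADF null
#' distribution.
#'
#' @param series numeric vector of length T (the unit's level series).
#' @param cross_avg_level numeric vector of length T: cross-sectional
#'   average of the levels (including this unit).
#' @param cross_avg_diff numeric vector of length T - 1: first difference
#'   of `cross_avg_level`.
#' @param p augmentation lag order (>= 0).
#' @param deterministic `"constant"` or `"constant_trend"`.
#' @param unit_id optional label carried into the result.
#' @return list of class `cadf_result`: `unit_id`, `t_statistic`,
#'   `lag_order`, `deterministic`, `nobs`.
#' @export
cadf <- function(series, cross_avg_level, cross_avg_diff, p = 1L,
                 deterministic = c("constant", "constant_trend"),
                 unit_id = NA_character_) {
  deterministic <- match.arg(deterministic)
  y <- as.numeric(series)
  T <- length(y)
  yb <- as.numeric(cross_avg_level)
  if (length(yb) != T) stop("cross_avg_level must have length T", call. = FALSE)
  dyb <- as.numeric(cross_avg_diff)
  if (length(dyb) != T - 1L)
    stop("cross_avg_diff must have length T - 1", call. = FALSE)
  p <- as.integer(p)
  if (p < 0L) stop("lag order p must be >= 0", call. = FALSE)

  dy <- diff(y)
  rows <- (p + 2L):T          # time indices of the response dy_t
  ri <- rows - 1L             # positions in the difference vectors
  X <- cbind(intercept = 1, y_lag = y[rows - 1L], avg_lag = yb[rows - 1L],
             avg_diff = dyb[ri])
  if (deterministic == "constant_trend") X <- cbind(X, trend = rows)
  if (p > 0L) {
    for (l in seq_len(p)) {
      X <- cbind(X, dy[ri - l], dyb[ri - l])
    }
  }
  n <- length(rows); kx <- ncol(X)
  if (n - kx < 2L)
    stop("insufficient observations for CADF with p = ", p, call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < kx)
    stop("collinear regressors in CADF regression",
         if (!is.na(unit_id)) paste0(" for unit '", unit_id, "'") else "",
         call. = FALSE)
  b <- qr.coef(qrX, dy[ri])
  e <- dy[ri] - X %*% b
  s2 <- sum(e^2) / (n - kx)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  structure(list(unit_id = unit_id, t_statistic = unname(b[2L] / se),
                 lag_order = p, deterministic = deterministic, nobs = n),
            class = "cadf_result")
}

# Truncation bounds applied to unit CADF statistics before averaging, as
# in the source method's truncated panel statistic.
cadf_truncation_bounds <- function(deterministic) {
  if (deterministic == "constant") c(-6.19, 2.61) else c(-6.42, 1.70)
}

#' CIPS panel unit-root statistic
#'
#' Computes the CADF statistic for every unit of a panel variable and
#' averages them (after truncation at the published bounds) into the CIPS
#' statistic. The null of a unit root in all units is rejected when CIPS
#' falls below the critical value.
#'
#' @param panel a [balanced_panel()].
#' @param variable variable name.
#' @param p CADF augmentation order (default 1; short panels cannot
#'   support deep augmentation).
#' @param deterministic `"constant"` or `"constant_trend"`.
#' @param critical_values length-3 numeric (1/5/10 percent) or `NULL` to
#'   interpolate from the embedded simulated table.
#' @return list of class `cips_result`: `cips`, `per_unit` (list of
#'   `cadf_result`, statistics truncated), `critical_values`, `decision`
#'   (named logical, reject at 1/5/10 percent), `N`, `T`, `p`,
#'   `deterministic`.
#' @export
cips <- function(panel, variable, p = 1L,
                 deterministic = c("constant", "constant_trend"),
                 critical_values = NULL) {
  deterministic <- match.arg(deterministic)
  y <- panel_matrix(panel, variable)
  N <- nrow(y); T <- ncol(y)
  if (N < 2L) stop("cross-sectional averages need N >= 2", call. = FALSE)
  yb <- colMeans(y)
  dyb <- diff(yb)
  bounds <- cadf_truncation_bounds(deterministic)
  per_unit <- vector("list", N)
  for (i in seq_len(N)) {
    r <- cadf(y[i, ], yb, dyb, p = p, deterministic = deterministic,
              unit_id = panel$units[i])
    r$t_statistic <- min(max(r$t_statistic, bounds[1L]), bounds[2L])
    per_unit[[i]] <- r
  }
  stat <- mean(vapply(per_unit, `[[`, numeric(1), "t_statistic"))
  if (is.null(critical_values))
    critical_values <- cips_critical_values(N, T, deterministic)
  decision <- stat < critical_values
  names(decision) <- c("1%", "5%", "10%")
  structure(list(cips = stat, per_unit = per_unit,
                 critical_values = critical_values, decision = decision,
                 N = N, T = T, p = p, deterministic = deterministic),
            class = "cips_result")
}

#' @export
print.cips_result <- function(x, ...) {
  stars <- if (x$decision[["1%"]]) "***" else if (x$decision[["5%"]]) "**"
           else if (x$decision[["10%"]]) "*" else ""
  cat(sprintf("CIPS = %.4f%s (N = %d, T = %d, p = %d, %s)\n", x$cips, stars,
              x$N, x$T, x$p, x$deterministic))
  cat(sprintf("critical values: 1%% %.2f, 5%% %.2f, 10%% %.2f\n",
              x$critical_values[1L], x$critical_values[2L],
              x$critical_values[3L]))
  invisible(x)
}

#' Interpolated CIPS critical values
#'
#' Returns 1/5/10 percent critical values for the truncated CIPS
#' statistic by bilinear interpolation over an embedded (N, T) grid of
#' simulated quantiles (100,000 draws per grid node under independent
#' random walks with the cross-sectional averages included in each CADF
#' regression). Queries outside the grid are clamped to its edge.
#'
#' @param N,T panel dimensions.
#' @param deterministic `"constant"` or `"constant_trend"`.
#' @return numeric vector of length 3 (1, 5, 10 percent).
#' @export
cips_critical_values <- function(N, T,
                                 deterministic = c("constant", "constant_trend")) {
  deterministic <- match.arg(deterministic)
  tab <- cips_cv_table[cips_cv_table$case == deterministic, ]
  Ns <- sort(unique(tab$N)); Ts <- sort(unique(tab$T))
  nq <- min(max(N, min(Ns)), max(Ns))
  tq <- min(max(T, min(Ts)), max(Ts))
  n0 <- max(Ns[Ns <= nq]); n1 <- min(Ns[Ns >= nq])
  t0 <- max(Ts[Ts <= tq]); t1 <- min(Ts[Ts >= tq])
  wn <- if (n1 == n0) 0 else (nq - n0) / (n1 - n0)
  wt <- if (t1 == t0) 0 else (tq - t0) / (t1 - t0)
  val <- function(nn, tt, col)
    tab[tab$N == nn & tab$T == tt, col]
  sapply(c("cv01", "cv05", "cv10"), function(col) {
    v00 <- val(n0, t0, col); v01 <- val(n0, t1, col)
    v10 <- val(n1, t0, col); v11 <- val(n1, t1, col)
    (1 - wn) * ((1 - wt) * v00 + wt * v01) +
      wn * ((1 - wt) * v10 + wt * v11)
  }, USE.NAMES = FALSE)
}

#' Simulate CIPS critical values
#'
#' Seeded fallback for (N, T) configurations far from the embedded grid:
#' simulates independent pure random walks, computes the truncated CIPS
#' statistic for each replicate and returns lower-tail quantiles. The
#' CADF regressions use p = 0 augmentation, matching how the embedded
#' table was generated.
#'
#' @param N,T panel dimensions.
#' @param deterministic `"constant"` or `"constant_trend"`.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param probs quantile levels.
#' @return numeric vector of quantiles (named by probability).
#' @export
simulate_cips_cv <- function(N, T, deterministic = c("constant", "constant_trend"),
                             reps = 10000L, seed = 1L,
                             probs = c(0.01, 0.05, 0.10)) {
  deterministic <- match.arg(deterministic)
  set.seed(as.integer(seed))
  stats_ <- numeric(reps)
  for (r in seq_len(reps))
    stats_[r] <- cips_stat_rw(N, T, deterministic)
  stats::quantile(stats_, probs = probs, names = TRUE, type = 7)
}

# One truncated CIPS draw under independent random walks, p = 0.
# Uses Frisch-Waugh: the regressors shared by all units (intercept,
# trend, avg lagged level, avg difference) are partialled out once.
cips_stat_rw <- function(N, T, deterministic) {
  y <- matrix(stats::rnorm(N * T), N, T)
  y <- t(apply(y, 1L, cumsum))
  yb <- colMeans(y)
  rows <- 2L:T
  W <- cbind(1, yb[rows - 1L], diff(yb))
  if (deterministic == "constant_trend") W <- cbind(W, rows)
  qw <- qr(W)
  dY <- t(y[, rows, drop = FALSE] - y[, rows - 1L, drop = FALSE]) # (T-1) x N
  Xl <- t(y[, rows - 1L, drop = FALSE])
  rd <- qr.resid(qw, dY)
  rx <- qr.resid(qw, Xl)
  bxx <- colSums(rx * rx)
  b <- colSums(rx * rd) / bxx
  df <- (T - 1L) - ncol(W) - 1L
  rss <- colSums((rd - rx * rep(b, each = nrow(rx)))^2)
  tstat <- b / sqrt(rss / df / bxx)
  bounds <- cadf_truncation_bounds(deterministic)
  mean(pmin(pmax(tstat, bounds[1L]), bounds[2L]))
}

#' Classify integration orders and determine dmax
#'
#' Applies the CIPS test to each variable in levels and, if the unit-root
#' null is not rejected at 5 percent, to its first difference. A variable
#' is I(0) when the level test rejects and I(1) when only the differenced
#' test rejects. `dmax`, the augmentation depth of the lag-augmented VAR,
#' is the maximum order across variables.
#'
#' @param panel a [balanced_panel()].
#' @param variables variables to classify; default all.
#' @param max_diff maximum differencing allowed (only 1 supported).
#' @param p,deterministic passed to [cips()].
#' @param level decision significance level: one of 0.01, 0.05, 0.10.
#' @return list of class `integration_summary`: `orders` (named integer),
#'   `dmax`, `detail` (per-variable `cips_result`s for level and
#'   difference).
#' @export
integration_order <- function(panel, variables = names(panel$values),
                              max_diff = 1L, p = 1L,
                              deterministic = "constant", level = 0.05) {
  lvl_name <- c("0.01" = "1%", "0.05" = "5%", "0.1" = "10%")[as.character(level)]
  if (is.na(lvl_name)) stop("level must be 0.01, 0.05 or 0.10", call. = FALSE)
  orders <- integer(0)
  detail <- list()
  for (v in variables) {
    r_lvl <- cips(panel, v, p = p, deterministic = deterministic)
    detail[[v]] <- list(level = r_lvl)
    if (r_lvl$decision[[lvl_name]]) {
      orders[v] <- 0L
      next
    }
    if (max_diff < 1L)
      stop("variable '", v, "': integration order exceeds max_diff",
           call. = FALSE)
    dpanel <- first_difference(panel, v)
    r_dif <- cips(dpanel, v, p = p, deterministic = deterministic)
    detail[[v]]$difference <- r_dif
    if (!r_dif$decision[[lvl_name]])
      stop("variable '", v, "': integration order exceeds max_diff",
           call. = FALSE)
    orders[v] <- 1L
  }
  structure(list(orders = orders, dmax = max(orders), detail = detail,
                 level = level), class = "integration_summary")
}

#' @export
print.integration_summary <- function(x, ...) {
  for (v in names(x$orders))
    cat(sprintf("%s: I(%d)\n", v, x$orders[[v]]))
  cat("dmax =", x$dmax, "\n")
  invisible(x)
}

#' CIPS report table for levels and first differences
#'
#' @param panel a [balanced_panel()].
#' @param variables variables to report; default all.
#' @param p,deterministic passed to [cips()].
#' @return data frame: variable, form (level/first_difference), cips,
#'   significance stars, and the three critical values.
#' @export
cips_report <- function(panel, variables = names(panel$values), p = 1L,
                        deterministic = "constant") {
  rows <- list()
  for (v in variables) {
    for (form in c("level", "first_difference")) {
      pan <- if (form == "level") panel else first_difference(panel, v)
      r <- cips(pan, v, p = p, deterministic = deterministic)
      stars <- if (r$decision[["1%"]]) "***" else if (r$decision[["5%"]]) "**"
               else if (r$decision[["10%"]]) "*" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, form = form, cips = r$cips, signif = stars,
        cv01 = r$critical_values[1L], cv05 = r$critical_values[2L],
        cv10 = r$critical_values[3L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
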