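# Cross-sectionally augmented ARDL (CS-ARDL) mean-group estimation.
# Each unit's ARDL(1,1,...) regression is augmented with lags 0..pT of the
# cross-sectional averages of the dependent variable and the regressors,
# absorbing common factors; unit coefficients are averaged (mean group)
# and long-run / error-correction quantities are derived algebraically.

#' Fit a CS-ARDL(1,1,...) model by unit-wise OLS with mean-group averaging
#'
#' Per unit, estimates
#' \deqn{y_{it} = a_i + \phi_i y_{i,t-1} + \sum_r (\beta_{0ir} x_{rit} +
#'   \beta_{1ir} x_{ri,t-1}) + \sum_{l=0}^{p_T} \delta_{il}' \bar z_{t-l}
#'   + e_{it}}
#' where \eqn{\bar z_t} stacks the cross-sectional averages of the
#' dependent variable and the regressors. Long-run coefficients
#' \eqn{\theta_{ir} = (\beta_{0ir} + \beta_{1ir}) / (1 - \phi_i)}, the
#' error-correction coefficient \eqn{\lambda_i = -(1 - \phi_i)} and the
#' short-run (differenced-form) coefficients \eqn{\beta_{0ir}} are derived
#' from the level-form fit; the same quantities are also read off an
#' exact error-correction re-parameterization of the regression as an
#' internal cross-check. Mean-group (MG) panel coefficients are the
#' arithmetic means across retained units with the nonparametric variance
#' \eqn{\sum_i (b_i - \bar b)^2 / (N(N-1))}.
#'
#' @param panel a [balanced_panel()].
#' @param dependent dependent variable name.
#' @param regressors character vector of regressor names.
#' @param pT truncation lag of the cross-sectional averages; default
#'   `floor(T^(1/3))`.
#' @param cross_averages set `FALSE` to drop the cross-average terms
#'   entirely (plain ARDL mean group).
#' @return list of class `csardl_result`: `per_unit` (data frame of unit
#'   coefficients from the level form), `per_unit_ecm` (same quantities
#'   from the ECM re-parameterization), `mg` (data frame: term, type,
#'   coefficient, std.error, t, p), `dropped` (unit labels), `pT`,
#'   `notes`.
#' @export
fit_cs_ardl <- function(panel, dependent, regressors,
                        pT = NULL, cross_averages = TRUE) {
  stopifnot(inherits(panel, "balanced_panel"))
  vars <- c(dependent, regressors)
  for (v in vars)
    if (!v %in% names(panel$values))
      stop("unknown variable '", v, "'", call. = FALSE)
  N <- panel$N; T <- panel$T
  if (is.null(pT)) pT <- floor(T^(1/3))
  pT <- as.integer(pT)
  nr <- length(regressors)

  ymat <- panel_matrix(panel, dependent)
  xmats <- lapply(regressors, function(v) panel_matrix(panel, v))
  avg <- lapply(vars, function(v) colMeans(panel_matrix(panel, v)))

  start <- max(1L, if (cross_averages) pT else 1L) + 1L
  rows <- start:T
  n <- length(rows)
  npar <- 2L + 2L * nr + if (cross_averages) (pT + 1L) * (nr + 1L) else 0L
  if (n - npar < 3L)
    stop("insufficient observations: T too small for pT = ", pT, call. = FALSE)

  Wavg <- NULL
  if (cross_averages) {
    Wavg <- do.call(cbind, lapply(avg, function(z)
      vapply(0:pT, function(l) z[rows - l], numeric(n))))
  }

  per <- list()
  per_ecm <- list()
  dropped <- character(0)
  for (i in seq_len(N)) {
    yi <- ymat[i, ]
    Xi <- cbind(1, yi[rows - 1L])
    for (x in xmats) Xi <- cbind(Xi, x[i, rows], x[i, rows - 1L])
    if (cross_averages) Xi <- cbind(Xi, Wavg)
    qrX <- qr(Xi)
    if (qrX$rank < ncol(Xi)) {
      dropped <- c(dropped, panel$units[i])
      next
    }
    b <- qr.coef(qrX, yi[rows])
    phi <- b[2L]
    beta0 <- b[2L + 2L * seq_len(nr) - 1L]
    beta1 <- b[2L + 2L * seq_len(nr)]
    theta <- (beta0 + beta1) / (1 - phi)
    ect <- -(1 - phi)
    per[[panel$units[i]]] <- c(phi = unname(phi),
      stats::setNames(beta0, paste0("beta0_", regressors)),
      stats::setNames(beta1, paste0("beta1_", regressors)),
      stats::setNames(theta, paste0("theta_", regressors)),
      ect = unname(ect))

    # ECM form: dy_t on [1, y_{t-1}, x_{t-1}, dx_t, averages]; identical
    # column space, so the mapped quantities must agree exactly.
    Zi <- cbind(1, yi[rows - 1L])
    for (x in xmats) Zi <- cbind(Zi, x[i, rows - 1L], x[i, rows] - x[i, rows - 1L])
    if (cross_averages) Zi <- cbind(Zi, Wavg)
    be <- qr.coef(qr(Zi), yi[rows] - yi[rows - 1L])
    lam <- be[2L]
    g_lag <- be[2L + 2L * seq_len(nr) - 1L]
    g_dif <- be[2L + 2L * seq_len(nr)]
    per_ecm[[panel$units[i]]] <- c(ect = unname(lam),
      stats::setNames(-g_lag / lam, paste0("theta_", regressors)),
      stats::setNames(g_dif, paste0("beta0_", regressors)))
  }

  kept <- length(per)
  if (kept < ceiling(0.8 * N))
    stop("fewer than 80% of units estimable (", kept, " of ", N, ")",
         call. = FALSE)
  if (length(dropped) > 0L)
    warning("units dropped for singularity: ", paste(dropped, collapse = ", "))

  per_unit <- as.data.frame(do.call(rbind, per))
  per_unit <- cbind(unit = names(per), per_unit, stringsAsFactors = FALSE)
  rownames(per_unit) <- NULL
  per_unit_ecm <- as.data.frame(do.call(rbind, per_ecm))
  per_unit_ecm <- cbind(unit = names(per_ecm), per_unit_ecm,
                        stringsAsFactors = FALSE)
  rownames(per_unit_ecm) <- NULL

  mg_row <- function(vals, term, type) {
    m <- mean(vals)
    se <- sqrt(sum((vals - m)^2) / (kept * (kept - 1L)))
    t <- m / se
    data.frame(term = term, type = type, coefficient = m, std.error = se,
               t_statistic = t, p_value = 2 * stats::pnorm(-abs(t)),
               stringsAsFactors = FALSE)
  }
  mg <- do.call(rbind, c(
    lapply(regressors, function(r)
      mg_row(per_unit[[paste0("theta_", r)]], r, "long_run")),
    lapply(regressors, function(r)
      mg_row(per_unit[[paste0("beta0_", r)]], paste0("d_", r), "short_run")),
    list(mg_row(per_unit$ect, "ECT(-1)", "error_correction"))))

  notes <- character(0)
  ect_mg <- mg$coefficient[mg$type == "error_correction"]
  if (ect_mg <= -2 || ect_mg >= 0)
    notes <- c(notes, sprintf(
      "mean-group ECT = %.3f lies outside (-2, 0): no stable adjustment implied",
      ect_mg))
  if (T < 30L)
    notes <- c(notes,
      "T < 30: CS-ARDL operates below the sample sizes where it performs best; treat results as supplementary")

  structure(list(dependent = dependent, regressors = regressors,
                 per_unit = per_unit, per_unit_ecm = per_unit_ecm, mg = mg,
                 dropped = dropped, pT = if (cross_averages) pT else NA_integer_,
                 N_used = kept, notes = notes),
            class = "csardl_result")
}

#' @export
print.csardl_result <- function(x, ...) {
  cat(sprintf("CS-ARDL(1,1,1) mean group, dependent: %s (pT = %s, N used = %d)\n",
              x$dependent, ifelse(is.na(x$pT), "none", x$pT), x$N_used))
  tab <- x$mg
  tab$signif <- significance_stars(tab$p_value)
  print(tab, row.names = FALSE, digits = 4)
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Interpret the error-correction coefficient
#'
#' A negative ECT of magnitude |λ| means a share |λ| of any deviation
#' from the long-run equilibrium is corrected each period; the implied
#' time back to equilibrium is roughly 1/|λ| periods.
#'
#' @param ect scalar error-correction coefficient, or a `csardl_result`
#'   (its mean-group ECT is used).
#' @return list of class `ect_interpretation`: `ect`, `stable` (logical),
#'   `pct_per_period` (percent corrected per period, `NA` if unstable),
#'   `periods_to_equilibrium` (ceiling of 1/|ect|, `NA` if unstable).
#' @export
ect_interpretation <- function(ect) {
  if (inherits(ect, "csardl_result"))
    ect <- ect$mg$coefficient[ect$mg$type == "error_correction"]
  stopifnot(is.numeric(ect), length(ect) == 1L, is.finite(ect))
  if (ect >= 0) {
    return(structure(list(ect = ect, stable = FALSE,
                          pct_per_period = NA_real_,
                          periods_to_equilibrium = NA_real_,
                          flag = "no stable adjustment"),
                     class = "ect_interpretation"))
  }
  structure(list(ect = ect, stable = TRUE,
                 pct_per_period = 100 * abs(ect),
                 periods_to_equilibrium = ceiling(1 / abs(ect)),
                 flag = NULL),
            class = "ect_interpretation")
}

#' @export
print.ect_interpretation <- function(x, ...) {
  if (!x$stable) {
    cat(sprintf("ECT = %.3f: no stable adjustment toward long-run equilibrium\n",
                x$ect))
  } else {
    cat(sprintf(
      "ECT = %.3f: %.0f%% of any deviation corrected per period (~%d periods to equilibrium)\n",
      x$ect, x$pct_per_period, x$periods_to_equilibrium))
  }
  invisible(x)
}
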