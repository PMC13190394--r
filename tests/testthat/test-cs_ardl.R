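# homogeneous ARDL(1,1) panel: y_it = phi y_{i,t-1} + b0 x_it + e_it
ardl_panel <- function(N, T, phi = 0.5, b0 = 0.3, seed = 1) {
  set.seed(seed)
  burn <- 20
  y <- x <- matrix(0, N, T + burn)
  for (i in seq_len(N)) {
    x[i, ] <- cumsum(rnorm(T + burn))
    for (t in 2:(T + burn))
      y[i, t] <- phi * y[i, t - 1] + b0 * x[i, t] + rnorm(1)
  }
  balanced_panel(list(y = y[, burn + 1:T], x = x[, burn + 1:T]))
}

test_that("without cross-averages the fit coincides with a plain ARDL mean group oracle", {
  pan <- ardl_panel(6, 40, seed = 3)
  fit <- fit_cs_ardl(pan, "y", "x", cross_averages = FALSE)

  # independent oracle: lm() per unit, averaged
  thetas <- phis <- numeric(6)
  ym <- panel_matrix(pan, "y"); xm <- panel_matrix(pan, "x")
  for (i in 1:6) {
    d <- data.frame(y = ym[i, -1], ylag = ym[i, -40],
                    x = xm[i, -1], xlag = xm[i, -40])
    cf <- coef(lm(y ~ ylag + x + xlag, data = d))
    phis[i] <- cf["ylag"]
    thetas[i] <- (cf["x"] + cf["xlag"]) / (1 - cf["ylag"])
  }
  expect_equal(fit$mg$coefficient[fit$mg$term == "x"], mean(thetas),
               tolerance = 1e-8)
  expect_equal(fit$mg$coefficient[fit$mg$type == "error_correction"],
               mean(-(1 - phis)), tolerance = 1e-8)
})

test_that("level-form and ECM-form long-run quantities agree exactly", {
  pan <- ardl_panel(8, 30, seed = 9)
  fit <- fit_cs_ardl(pan, "y", "x")
  lv <- fit$per_unit[order(fit$per_unit$unit), ]
  em <- fit$per_unit_ecm[order(fit$per_unit_ecm$unit), ]
  expect_equal(lv$theta_x, em$theta_x, tolerance = 1e-8)
  expect_equal(lv$ect, em$ect, tolerance = 1e-8)
  expect_equal(lv$beta0_x, em$beta0_x, tolerance = 1e-8)
})

test_that("mean-group quantities are arithmetic means with the nonparametric variance", {
  pan <- ardl_panel(7, 35, seed = 5)
  fit <- fit_cs_ardl(pan, "y", "x")
  th <- fit$per_unit$theta_x
  row <- fit$mg[fit$mg$term == "x" & fit$mg$type == "long_run", ]
  expect_equal(row$coefficient, mean(th))
  expect_equal(row$std.error, sqrt(sum((th - mean(th))^2) / (7 * 6)))
})

test_that("a degenerate regressor drops that unit with a warning", {
  pan <- ardl_panel(10, 30, seed = 11)
  vals <- pan$values
  vals$x[4, ] <- 0
  pan2 <- balanced_panel(vals)
  expect_warning(fit <- fit_cs_ardl(pan2, "y", "x", cross_averages = FALSE),
                 "dropped")
  expect_equal(fit$dropped, pan2$units[4])
  expect_equal(fit$N_used, 9)
})

test_that("too many singular units aborts the mean group", {
  pan <- ardl_panel(4, 30, seed = 13)
  vals <- pan$values
  vals$x[1, ] <- 0; vals$x[2, ] <- 0
  expect_error(
    suppressWarnings(fit_cs_ardl(balanced_panel(vals), "y", "x",
                                 cross_averages = FALSE)),
    "80%")
})

test_that("ECT interpretation reports correction speed or flags instability", {
  r <- ect_interpretation(-0.34)
  expect_true(r$stable)
  expect_equal(r$pct_per_period, 34)
  expect_equal(r$periods_to_equilibrium, 3)

  r1 <- ect_interpretation(-1)
  expect_equal(r1$periods_to_equilibrium, 1)
  expect_equal(r1$pct_per_period, 100)

  r2 <- ect_interpretation(0.1)
  expect_false(r2$stable)
  expect_true(is.na(r2$pct_per_period))
  expect_match(r2$flag, "no stable adjustment")
})

test_that("short panels carry the small-T caveat note", {
  pan <- ardl_panel(27, 21, seed = 17)
  fit <- fit_cs_ardl(pan, "y", "x")
  expect_true(any(grepl("T < 30", fit$notes)))
  expect_equal(fit$pT, 2L)   # floor(21^(1/3))
})
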