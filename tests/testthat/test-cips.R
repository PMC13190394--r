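test_that("CADF flags degenerate and shifted inputs correctly", {
  set.seed(3)
  y <- cumsum(rnorm(30))
  # unit identical to the cross-sectional average: lagged level and
  # averaged lagged level are the same column
  expect_error(cadf(y, y, diff(y)), "collinear")

  other <- cumsum(rnorm(30))
  avg <- (y + other) / 2
  t1 <- cadf(y, avg, diff(avg), p = 1)$t_statistic
  # adding a constant is absorbed by the intercept and average terms
  t2 <- cadf(y + 100, avg + 100, diff(avg), p = 1)$t_statistic
  expect_equal(t1, t2, tolerance = 1e-8)

  expect_error(cadf(y[1:6], avg[1:6], diff(avg[1:6]), p = 3),
               "insufficient")
})

test_that("stationary series give strongly negative CADF statistics", {
  set.seed(21)
  hits <- replicate(50, {
    y <- rnorm(100)
    avg <- (y + rnorm(100)) / 2
    cadf(y, avg, diff(avg), p = 0)$t_statistic < -2.5
  })
  expect_gt(mean(hits), 0.8)
})

test_that("CIPS equals the mean of per-unit CADF statistics exactly", {
  set.seed(14)
  pan <- balanced_panel(list(v = t(replicate(6, cumsum(rnorm(25))))))
  r <- cips(pan, "v", p = 1)
  expect_identical(r$cips,
                   mean(vapply(r$per_unit, `[[`, numeric(1), "t_statistic")))
  expect_length(r$per_unit, 6)
  expect_length(r$critical_values, 3)
  # critical values are ordered: 1% most negative
  expect_true(r$critical_values[1] < r$critical_values[2])
  expect_true(r$critical_values[2] < r$critical_values[3])
})

test_that("per-unit CADF statistics are truncated at the published bounds", {
  set.seed(15)
  # explosive-looking inputs can push raw t-ratios past the bounds
  y <- t(replicate(6, cumsum(rnorm(30)) + c(rep(0, 29), 50)))
  r <- cips(balanced_panel(list(v = y)), "v", p = 0)
  ts <- vapply(r$per_unit, `[[`, numeric(1), "t_statistic")
  expect_true(all(ts >= -6.19 & ts <= 2.61))
  r2 <- cips(balanced_panel(list(v = y)), "v", p = 0,
             deterministic = "constant_trend")
  ts2 <- vapply(r2$per_unit, `[[`, numeric(1), "t_statistic")
  expect_true(all(ts2 >= -6.42 & ts2 <= 1.70))
})

test_that("critical value interpolation is exact on grid nodes and monotone between them", {
  tab <- panelcausal:::cips_cv_table
  row <- tab[tab$case == "constant", ][1, ]
  cv <- cips_critical_values(row$N, row$T, "constant")
  expect_equal(cv, c(row$cv01, row$cv05, row$cv10))

  Ns <- sort(unique(tab$N[tab$case == "constant"]))
  mid <- cips_critical_values(mean(Ns[1:2]), row$T, "constant")
  lo <- cips_critical_values(Ns[1], row$T, "constant")
  hi <- cips_critical_values(Ns[2], row$T, "constant")
  expect_true(all(pmin(lo, hi) - 1e-12 <= mid & mid <= pmax(lo, hi) + 1e-12))

  # clamped outside the grid
  expect_equal(cips_critical_values(max(Ns) + 100, row$T, "constant"),
               cips_critical_values(max(Ns), row$T, "constant"))
})

test_that("stationary panels reject the unit-root null more than half the time", {
  set.seed(33)
  rej <- replicate(40, {
    y <- t(replicate(27, as.vector(stats::filter(rnorm(21), 0.3,
                                                 method = "recursive"))))
    r <- cips(balanced_panel(list(v = y)), "v", p = 0)
    r$decision[["5%"]]
  })
  expect_gt(mean(rej), 0.5)
})

test_that("integration orders classify I(0) and I(1) panels and apply the max rule", {
  set.seed(55)
  stat <- t(replicate(27, as.vector(stats::filter(rnorm(40), 0.2,
                                                  method = "recursive"))))
  rw <- t(replicate(27, cumsum(rnorm(40))))
  pan <- balanced_panel(list(a = stat, b = rw))
  io <- integration_order(pan, p = 0)
  expect_equal(unname(io$orders[["a"]]), 0L)
  expect_equal(unname(io$orders[["b"]]), 1L)
  expect_equal(io$dmax, 1L)

  # twice-integrated series exceed max_diff = 1
  set.seed(56)
  i2 <- t(replicate(27, cumsum(cumsum(rnorm(40)))))
  expect_error(integration_order(balanced_panel(list(c = i2)), p = 0),
               "exceeds max_diff")
})

test_that("cips_report mirrors the level/first-difference layout", {
  set.seed(71)
  pan <- balanced_panel(list(v = t(replicate(8, cumsum(rnorm(25)))),
                             w = t(replicate(8, cumsum(rnorm(25))))))
  rep_ <- cips_report(pan, p = 0)
  expect_equal(nrow(rep_), 4)
  expect_setequal(rep_$form, c("level", "first_difference"))
  expect_true(all(c("cips", "signif", "cv05") %in% names(rep_)))
})
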