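test_that("AIC lag selection recovers simple generating orders", {
  expect_equal(select_lag_aic(rw_block(40, seed = 1), k_max = 1), 1L)

  # white noise in levels: order 1 preferred at T = 200
  set.seed(2)
  picks <- replicate(20, {
    yb <- rbind(rnorm(200), rnorm(200))
    select_lag_aic(yb, k_max = 3)
  })
  expect_gt(mean(picks == 1), 0.7)

  # strong second-lag VAR dynamics: order 2 recovered
  set.seed(3)
  picks2 <- replicate(20, {
    T <- 200
    y <- x <- numeric(T)
    for (t in 3:T) {
      y[t] <- 0.3 * y[t - 1] + 0.5 * y[t - 2] + 0.3 * x[t - 2] + rnorm(1)
      x[t] <- 0.3 * x[t - 1] - 0.4 * x[t - 2] + rnorm(1)
    }
    select_lag_aic(rbind(y, x), k_max = 3)
  })
  expect_gt(mean(picks2 == 2), 0.7)

  expect_error(select_lag_aic(rw_block(8), k_max = 3), "insufficient")
})

test_that("the lag-augmented Wald test is invariant to regressor scale and flags singularity", {
  yb <- rw_block(60, seed = 10)
  r1 <- lavar_wald(yb, k_i = 2, dmax = 1)
  r2 <- lavar_wald(rbind(yb[1, ] * 1e6, yb[2, ]), k_i = 2, dmax = 1)
  expect_equal(r1$wald, r2$wald, tolerance = 1e-10)
  expect_equal(r1$df, 2)
  expect_equal(r1$p_value, pchisq(r1$wald, 2, lower.tail = FALSE))

  degenerate <- rbind(rep(0, 60), yb[2, ])
  expect_error(lavar_wald(degenerate, k_i = 1, dmax = 1), "singular")
})

test_that("an empty restriction set reproduces the unrestricted OLS exactly", {
  yb <- rw_block(50, seed = 20)
  un <- panelcausal:::lavar_wald_core(yb[2, ], yb[1, ], k = 2, d = 1,
                                      start = 4)
  re <- panelcausal:::lavar_restricted(yb[2, ], yb[1, ], k = 0, d = 3,
                                       start = 4)
  expect_equal(unname(c(re$intercept, re$own, re$cross)),
               unname(un$coef), tolerance = 1e-10)
  expect_equal(re$residuals, un$residuals, tolerance = 1e-10)
})

test_that("Fisher combination matches its closed form and refuses bad input", {
  expect_equal(fisher_combine(rep(1, 5)), 0)
  expect_equal(fisher_combine(exp(-1)), 2)
  expect_error(fisher_combine(numeric(0)), "empty")
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  # zeros are floored, not fatal
  expect_equal(fisher_combine(c(0, 1), p_floor = 1e-16),
               -2 * log(1e-16))
})

test_that("the panel Fisher statistic equals -2 sum log p of the country block", {
  cfg <- dgp_config(N = 5, T = 30, variables = c("x", "y"), seed = 77)
  res <- bootstrap_panel_causality(generate_panel(cfg), c("x", "y"),
                                   B = 100, seed = 1, k_max = 2)
  for (dn in names(res$per_direction)) {
    d <- res$per_direction[[dn]]
    expect_equal(d$lambda, -2 * sum(log(pmax(d$countries$p_value, 1e-16))))
    expect_true(all(d$countries$statistic >= 0))
    expect_true(all(d$countries$p_value > 0 & d$countries$p_value <= 1))
  }
})

test_that("lambda is invariant to affine rescaling of a variable", {
  cfg <- dgp_config(N = 4, T = 40, variables = c("x", "y"), seed = 13)
  pan <- generate_panel(cfg)
  vals <- pan$values
  vals$x <- vals$x * 1e6 + 500   # persons vs millions of persons
  pan2 <- balanced_panel(vals, units = pan$units, periods = pan$periods)
  r1 <- bootstrap_panel_causality(pan, c("x", "y"), B = 100, seed = 2,
                                  k_max = 1)
  r2 <- bootstrap_panel_causality(pan2, c("x", "y"), B = 100, seed = 2,
                                  k_max = 1)
  for (dn in c("x->y", "y->x"))
    expect_equal(r1$per_direction[[dn]]$lambda,
                 r2$per_direction[[dn]]$lambda, tolerance = 1e-8)
})

test_that("under independence lambda behaves like chi-square with 2N degrees of freedom", {
  set.seed(41)
  N <- 5
  lams <- replicate(200, {
    ps <- sapply(seq_len(N), function(i) {
      lavar_wald(rw_block(60), k_i = 1, dmax = 1)$p_value
    })
    fisher_combine(ps)
  })
  # chi-square(2N): mean 2N, variance 4N
  expect_lt(abs(mean(lams) - 2 * N), 3 * sqrt(4 * N / 200))
})

test_that("bootstrap inference is deterministic given the seed", {
  cfg <- dgp_config(N = 4, T = 30, variables = c("x", "y"), seed = 9)
  pan <- generate_panel(cfg)
  r1 <- bootstrap_panel_causality(pan, c("x", "y"), B = 120, seed = 5)
  r2 <- bootstrap_panel_causality(pan, c("x", "y"), B = 120, seed = 5)
  expect_identical(r1$per_direction[["x->y"]]$lambda_star,
                   r2$per_direction[["x->y"]]$lambda_star)
  expect_identical(r1$per_direction[["x->y"]]$bootstrap_p,
                   r2$per_direction[["x->y"]]$bootstrap_p)
  expect_warning(
    bootstrap_panel_causality(pan, c("x", "y"), B = 99, seed = 5,
                              directions = "A->B"), "B < 100")
})

test_that("run_all_pairs shares lag orders within a pair and mirrors the table layout", {
  cfg <- dgp_config(N = 6, T = 30, seed = 23)
  pan <- generate_panel(cfg)
  res <- run_all_pairs(pan, B = 100, seed = 4, k_max = 2)
  expect_setequal(names(res), c("co2:hexp", "co2:migr", "hexp:migr"))
  pr <- res[["co2:migr"]]
  expect_setequal(names(pr$per_direction), c("co2->migr", "migr->co2"))
  expect_identical(pr$per_direction[["co2->migr"]]$countries$df,
                   unname(pr$k_i))
  tab <- ek_table(pr, "co2->migr")
  expect_equal(nrow(tab), 7)  # N country rows + Fisher row
  expect_equal(tab$country[7], "Fisher test statistic")
  expect_true(all(c("statistic", "p_value", "signif") %in% names(tab)))
})
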