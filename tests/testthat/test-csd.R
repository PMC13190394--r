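test_that("pairwise correlations match a direct covariance computation", {
  m <- matrix(c(1, 4, 2, 8, 5, 7,
                2, 3, 9, 1, 6, 4,
                5, 5, 1, 2, 8, 3), 3, 6, byrow = TRUE)
  got <- pairwise_correlations(m)
  # brute-force formula oracle
  for (i in 1:2) for (j in (i + 1):3) {
    a <- m[i, ] - mean(m[i, ]); b <- m[j, ] - mean(m[j, ])
    expect_equal(got[i, j], sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  expect_equal(got, t(got))

  dup <- rbind(m[1, ], m[1, ])
  expect_equal(pairwise_correlations(dup)[1, 2], 1)
  neg <- rbind(m[1, ], -m[1, ])
  expect_equal(pairwise_correlations(neg)[1, 2], -1)

  degen <- rbind(m[1, ], rep(2, 6))
  expect_error(pairwise_correlations(degen), "degenerate")
})

test_that("CSD statistics follow their closed forms on simple inputs", {
  corr0 <- diag(2)
  expect_equal(breusch_pagan_lm(corr0, 10)$statistic, 0)
  expect_equal(breusch_pagan_lm(corr0, 10)$p_value, 1)
  expect_equal(pesaran_cd(corr0, 10)$statistic, 0)
  expect_equal(pesaran_cd(corr0, 10)$p_value, 1)

  corr <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  bp <- breusch_pagan_lm(corr, 10)
  expect_equal(bp$statistic, 10 * 0.25)          # T * rho^2, one pair
  expect_equal(bp$p_value, pchisq(2.5, 1, lower.tail = FALSE))

  cd <- pesaran_cd(corr, 10)
  expect_equal(cd$statistic, sqrt(2 * 10 / 2) * 0.5)
  sl <- pesaran_scaled_lm(corr, 10)
  expect_equal(sl$statistic, sqrt(1 / 2) * (10 * 0.25 - 1))
})

test_that("CSD report is invariant to positive rescaling of a unit's series", {
  pan <- toy_panel(N = 4, T = 20, seed = 2)
  r1 <- csd_report(pan)
  scaled <- pan$values
  scaled$y[2, ] <- scaled$y[2, ] * 1e6
  r2 <- csd_report(balanced_panel(scaled))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
})

test_that("BP LM is nonnegative while CD is signed", {
  set.seed(4)
  m <- matrix(rnorm(5 * 30), 5, 30)
  corr <- pairwise_correlations(m)
  expect_gte(breusch_pagan_lm(corr, 30)$statistic, 0)
  mneg <- rbind(m[1, ], -m[1, ] + rnorm(30, sd = 0.1))
  expect_lt(pesaran_cd(pairwise_correlations(mneg), 30)$statistic, 0)
})

test_that("one-factor dependence drives CD rejection toward one as T grows", {
  set.seed(31)
  rej <- sapply(c(30, 120), function(T) {
    mean(replicate(200, {
      f <- rnorm(T)
      load <- runif(8, 0.5, 1.5)
      m <- outer(load, f) + matrix(rnorm(8 * T), 8, T)
      pesaran_cd(pairwise_correlations(m), T)$p_value <= 0.05
    }))
  })
  expect_gte(rej[2], rej[1])
  expect_gt(rej[2], 0.95)
})

test_that("slope homogeneity dispersion is zero for identical units", {
  set.seed(7)
  x <- rnorm(12)
  y <- 1 + 2 * x + rnorm(12, sd = 0.2)
  pan <- balanced_panel(list(y = matrix(y, 2, 12, byrow = TRUE),
                             x = matrix(x, 2, 12, byrow = TRUE)))
  r <- slope_homogeneity(pan, "y", "x")
  expect_equal(r$S_tilde, 0, tolerance = 1e-10)
  expect_lt(r$delta_tilde, 0)
})

test_that("strongly heterogeneous slopes are rejected with high power", {
  set.seed(12)
  rej <- replicate(50, {
    N <- 20; T <- 40
    betas <- rnorm(N, 1, 0.5)
    x <- matrix(rnorm(N * T), N, T)
    y <- x * betas + matrix(rnorm(N * T), N, T)
    r <- slope_homogeneity(balanced_panel(list(y = y, x = x)), "y", "x")
    r$p_values[["delta_tilde_adj"]] <= 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("rank-deficient unit regressors are reported by unit", {
  pan <- toy_panel(N = 3, T = 10, seed = 5)
  vals <- pan$values
  vals$x[2, ] <- 4   # constant regressor demeans to zero for unit 2
  expect_error(slope_homogeneity(balanced_panel(vals), "y", "x"),
               "rank-deficient.*unit")
})
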