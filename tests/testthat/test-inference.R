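test_that("hpdi returns the earliest shortest window", {
  expect_equal(hpdi(seq(0, 1, by = 0.01), 0.5), c(0, 0.5))
  expect_equal(hpdi(rep(3.7, 10), 0.9), c(3.7, 3.7))
  # endpoint Monte Carlo noise is ~0.04 at 1e4 draws, so 1e5 draws are
  # needed for the +/-0.05 band around the closed-form quantiles
  set.seed(12)
  z <- rnorm(1e5)
  iv <- hpdi(z, 0.95)
  expect_lt(abs(iv[1] - (-1.96)), 0.05)
  expect_lt(abs(iv[2] - 1.96), 0.05)
  expect_error(hpdi(numeric(0)), "samples")
  expect_error(hpdi(z, 1.2), "prob")
})

test_that("hpdi widens with prob and stays inside the sample range", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(500, sd = runif(1, 0.5, 3))
    i80 <- hpdi(x, 0.8); i95 <- hpdi(x, 0.95)
    expect_lte(i95[1], i80[1])
    expect_gte(i95[2], i80[2])
    expect_gte(i80[1], min(x))
    expect_lte(i95[2], max(x))
  }
})

test_that("zero-variance mc_anova equals the closed-form OLS contrasts", {
  d <- make_posteriors(list(A = c(10, 10), B = c(12, 12)))
  r <- mc_anova(d, mc_config(n_reps = 50, seed = 1))
  expect_equal(r$contrasts$difference, 2)
  expect_equal(r$contrasts$lower, 2)
  expect_equal(r$contrasts$upper, 2)
  expect_true(r$contrasts$significant)

  # random small designs: coefficients equal lm() cell means exactly
  set.seed(99)
  for (i in 1:10) {
    g <- sample(2:4, 1)
    d <- make_posteriors(setNames(
      lapply(1:g, function(j) rnorm(sample(2:6, 1), mean = j)),
      LETTERS[1:g]))
    r <- mc_anova(d, mc_config(n_reps = 3, seed = i))
    fit <- lm(posterior_mean ~ population - 1, data = d)
    expect_equal(r$coefficients$estimate, unname(coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("mc_anova guards its design and config preconditions", {
  d <- make_posteriors(list(A = c(1, 2)))
  expect_error(mc_anova(d), "2 populations")
  d2 <- make_posteriors(list(A = c(1, 2), B = 3))
  expect_error(mc_anova(d2), "< 2 whales")
  expect_error(mc_config(n_reps = 0), "n_reps")
  expect_error(mc_config(hpdi_prob = 1), "hpdi_prob")
})

test_that("mc_anova recovers a known group difference", {
  set.seed(123)
  d <- make_posteriors(list(A = rnorm(15, 10, 0.2), B = rnorm(15, 11.5, 0.2)),
                       variance = 0.3^2)
  r <- mc_anova(d, mc_config(n_reps = 10000, seed = 7))
  truth <- mean(d$posterior_mean[d$population == "B"]) -
    mean(d$posterior_mean[d$population == "A"])
  expect_lt(abs(r$contrasts$difference - truth), 0.05)
  expect_lt(abs(r$contrasts$difference - 1.5), 0.15)
})

test_that("averaged coefficients are stable in the replicate count", {
  d <- make_posteriors(list(A = seq(9, 11, length.out = 10),
                            B = seq(11, 13, length.out = 10)),
                       variance = 0.4^2)
  r1 <- mc_anova(d, mc_config(n_reps = 1e4, seed = 3))
  r2 <- mc_anova(d, mc_config(n_reps = 1e5, seed = 4))
  # MC standard error of a group mean at 1e4 reps
  se <- sqrt(0.4^2 / 10 / 1e4)
  expect_true(all(abs(r1$coefficients$estimate - r2$coefficients$estimate) <
                    3 * se * sqrt(2)))
})

test_that("significance flags are exactly the HPDI-excludes-zero rule", {
  set.seed(5)
  d <- make_posteriors(list(A = rnorm(8, 10), B = rnorm(8, 10.2),
                            C = rnorm(8, 12)), variance = 0.5^2)
  r <- mc_anova(d, mc_config(n_reps = 5000, seed = 2))
  expect_equal(r$contrasts$significant,
               r$contrasts$lower > 0 | r$contrasts$upper < 0)
  expect_true(all(r$contrasts$lower <= r$contrasts$difference))
  expect_true(all(r$contrasts$difference <= r$contrasts$upper))
})

test_that("negative draws are counted, not truncated", {
  d <- make_posteriors(list(A = c(0.01, 0.01), B = c(0.02, 0.02)),
                       variance = 1)
  r <- mc_anova(d, mc_config(n_reps = 1000, seed = 1))
  expect_gt(r$n_negative_draws, 0)
})

test_that("mc_anova_table runs each measurement and binds contrasts", {
  d <- dplyr::bind_rows(
    dplyr::mutate(make_posteriors(list(A = c(1, 2), B = c(3, 4))),
                  measurement = "TL"),
    dplyr::mutate(make_posteriors(list(A = c(5, 6), B = c(7, 9))),
                  measurement = "BAI")
  )
  out <- mc_anova_table(d, mc_config(n_reps = 20, seed = 1))
  expect_setequal(unique(out$contrasts$measurement), c("TL", "BAI"))
  expect_equal(out$contrasts$difference[out$contrasts$measurement == "TL"], 2)
  expect_equal(out$contrasts$difference[out$contrasts$measurement == "BAI"],
               2.5)
})

test_that("allometry identifies proportional scaling as isometry", {
  TL <- c(18, 20, 22, 24, 26)
  f <- allometry_fit(0.2 * TL, TL)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_equal(f$classification, "isometry")
  # two distinct points: perfect interpolation (fit on 3 for the n guard)
  f2 <- allometry_fit(c(2, 4, 8), c(1, 2, 4))
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
  expect_error(allometry_fit(c(-1, 2, 3), c(1, 2, 3)), "log-domain")
  expect_error(allometry_fit(c(1, 2), c(1, 2)), ">= 3")
})

test_that("allometry slope is invariant to common rescaling", {
  set.seed(6)
  TL <- runif(20, 18, 26)
  m <- 0.1 * TL^1.2 * exp(rnorm(20, 0, 0.02))
  f1 <- allometry_fit(m, TL)
  f2 <- allometry_fit(m * 3, TL * 3)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
})

test_that("allometry CI covers a generative slope of 1.3", {
  set.seed(17)
  hits <- replicate(200, {
    TL <- runif(30, 18, 26)
    m <- 0.05 * TL^1.3 * exp(rnorm(30, 0, 0.05))
    f <- allometry_fit(m, TL)
    f$slope_lower <= 1.3 && 1.3 <= f$slope_upper
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Dixon's Q computes the r10 ratio and uses the critical table", {
  d <- dixon_q(c(1, 2, 3, 4, 10))
  expect_equal(d$statistic, 6 / 9)
  expect_equal(d$side, "high")
  # standard two-tailed critical value for n = 5 at alpha 0.05 is 0.710
  expect_equal(d$critical, 0.710)
  expect_false(d$outlier) # 0.667 < 0.710: retained
  # a clearer outlier is rejected
  expect_true(dixon_q(c(1, 1.1, 1.2, 1.3, 10))$outlier)
  # low-side suspect
  expect_equal(dixon_q(c(-10, 4, 5, 6, 7))$side, "low")
})

test_that("Dixon's Q handles degenerate and unsupported inputs", {
  d <- dixon_q(rep(2, 5))
  expect_false(d$performed)
  expect_true(is.na(d$outlier))
  expect_error(dixon_q(c(1, 2)), "unsupported n")
  expect_error(dixon_q(rnorm(31)), "unsupported n")
  expect_error(dixon_q(c(1, 2, 3), alpha = 0.2), "alpha")
})
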