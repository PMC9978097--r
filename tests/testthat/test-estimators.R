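test_that("Wald ratios follow the first-order delta method", {
  instr <- make_instruments(gamma = 0.1, Gamma = 0.05, se_Gamma = 0.02)
  wr <- wald_ratios(instr)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se_ratio, 0.2)
  expect_equal(wr$weight, 25)
  expect_equal(wr$weight, wr$se_ratio^-2)

  expect_equal(wald_ratios(make_instruments(0.1, 0))$ratio, 0)
  expect_equal(wald_ratios(make_instruments(-0.1, -0.05))$ratio,
               wald_ratios(make_instruments(0.1, 0.05))$ratio)
  expect_error(wald_ratios(make_instruments(c(0.1, 0), c(0.1, 0.1))), "v2",
               class = "mrflow_domain_error")
})

test_that("IVW matches the closed-form weighted mean and its regression form", {
  # ratios {1 (w=4), 2 (w=1)} -> beta 1.2, fixed se 1/sqrt(5)
  instr <- make_instruments(gamma = c(1, 1), Gamma = c(1, 2),
                            se_gamma = c(1e-9, 1e-9), se_Gamma = c(0.5, 1))
  est <- mr_ivw(instr, "fixed")
  expect_equal(est$beta, 1.2)
  expect_equal(est$se, 1 / sqrt(5))
  expect_equal(est$ci_low, 1.2 - 1.959964 / sqrt(5))
  expect_equal(est$ci_high, 1.2 + 1.959964 / sqrt(5))

  # identical ratios: beta exact, Q = 0, fixed = random
  instr_c <- make_instruments(gamma = c(0.1, 0.2, 0.4), Gamma = c(0.05, 0.1, 0.2))
  expect_equal(mr_ivw(instr_c, "fixed")$beta, 0.5)
  expect_equal(cochran_q(instr_c)$q, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(instr_c, "random")$se, mr_ivw(instr_c, "fixed")$se)

  # meta-analysis of ratios == weighted regression through the origin
  for (seed in 1:10) {
    instr_r <- random_instruments(j = 12, beta = 0.07, seed = seed)
    est_meta <- mr_ivw(instr_r, "fixed")
    w <- 1 / instr_r$se_Gamma^2
    slope_wls <- sum(w * instr_r$gamma * instr_r$Gamma) /
      sum(w * instr_r$gamma^2)
    expect_equal(est_meta$beta, slope_wls, tolerance = 1e-10)
  }
  expect_error(mr_ivw(instr[1, ]), class = "mrflow_usage_error")
})

test_that("random-effects IVW applies the multiplicative Q scaling", {
  instr <- random_instruments(j = 10, beta = 0.1, seed = 21)
  instr$Gamma[1] <- instr$Gamma[1] + 0.2   # inject heterogeneity
  fx <- mr_ivw(instr, "fixed")
  rn <- mr_ivw(instr, "random")
  q <- cochran_q(instr)$q
  expect_equal(rn$beta, fx$beta)
  expect_equal(rn$se, fx$se * max(1, sqrt(q / 9)))
})

test_that("maximum likelihood approaches IVW as exposure error vanishes", {
  instr <- random_instruments(j = 10, beta = 0.1, seed = 4)
  instr$se_gamma <- rep(1e-8, 10)
  ml <- mr_maximum_likelihood(instr)
  ivw <- mr_ivw(instr, "fixed")
  expect_lt(abs(ml$beta - ivw$beta), 1e-6)
  expect_equal(ml$se, ivw$se, tolerance = 1e-3)

  # sign equivariance: mirroring all instruments flips the estimate
  instr2 <- random_instruments(j = 8, beta = 0.2, seed = 5)
  m1 <- mr_maximum_likelihood(instr2)
  instr_m <- instr2
  instr_m$Gamma <- -instr_m$Gamma
  m2 <- mr_maximum_likelihood(instr_m)
  expect_equal(m2$beta, -m1$beta, tolerance = 1e-7)

  # single null dataset: estimate within 4 se of zero
  instr0 <- random_instruments(j = 10, beta = 0, seed = 6)
  m0 <- mr_maximum_likelihood(instr0)
  expect_lt(abs(m0$beta), 4 * m0$se)
})

test_that("MR-Egger recovers an exact linear relationship", {
  set.seed(8)
  g <- runif(6, 0.05, 0.3)
  instr <- make_instruments(gamma = g, Gamma = 0.3 + 0.5 * g)
  fit <- mr_egger(instr)
  expect_equal(fit$estimate$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$pleiotropy$intercept, 0.3, tolerance = 1e-10)

  # no pleiotropy: intercept exactly zero
  instr2 <- make_instruments(gamma = g, Gamma = 0.5 * g)
  expect_equal(mr_egger(instr2)$pleiotropy$intercept, 0, tolerance = 1e-12)

  expect_error(mr_egger(instr[1:2, ]), class = "mrflow_usage_error")
})

test_that("MR-Egger agrees with a weighted lm on oriented data", {
  instr <- random_instruments(j = 10, beta = 0.1, seed = 12)
  fit <- mr_egger(instr)
  flip <- instr$gamma < 0
  g <- abs(instr$gamma)
  G <- ifelse(flip, -instr$Gamma, instr$Gamma)
  ref <- lm(G ~ g, weights = 1 / instr$se_Gamma^2)
  sref <- summary(ref)
  expect_equal(fit$estimate$beta, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$estimate$se, sref$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(fit$pleiotropy$intercept, unname(coef(ref)[1]),
               tolerance = 1e-10)
  expect_equal(fit$pleiotropy$se, sref$coefficients[1, 2], tolerance = 1e-10)
  expect_equal(fit$estimate$p_value, sref$coefficients[2, 4],
               tolerance = 1e-10)
})

test_that("weighted median interpolates the cumulative-weight-half point", {
  # equal weights, odd count: the sample median
  instr <- make_instruments(gamma = c(1, 1, 1), Gamma = c(1, 2, 9))
  est <- mr_weighted_median(instr, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2)

  # dominant weight pins the estimate to that instrument's ratio
  instr2 <- make_instruments(gamma = c(1, 1, 1), Gamma = c(1, 2, 9),
                             se_Gamma = c(1, 0.01, 1))
  est2 <- mr_weighted_median(instr2, n_boot = 100, seed = 1)
  expect_equal(est2$beta, 2, tolerance = 0.01)

  expect_error(mr_weighted_median(instr, n_boot = 50),
               class = "mrflow_usage_error")
})

test_that("weighted mode finds the dominant cluster", {
  instr <- make_instruments(gamma = rep(1, 4), Gamma = c(1, 1.01, 0.99, 5))
  est <- mr_weighted_mode(instr, n_boot = 100, seed = 1, grid_n = 4000)
  expect_lt(abs(est$beta - 1), 0.2)

  # all ratios identical: exactly the common ratio
  instr_c <- make_instruments(gamma = c(1, 2, 4), Gamma = c(0.5, 1, 2))
  est_c <- mr_weighted_mode(instr_c, n_boot = 100, seed = 1)
  expect_equal(est_c$beta, 0.5)
})

test_that("bootstrap standard errors are bit-reproducible given the seed", {
  instr <- random_instruments(j = 8, beta = 0.1, seed = 30)
  a <- mr_weighted_median(instr, n_boot = 200, seed = 99)
  b <- mr_weighted_median(instr, n_boot = 200, seed = 99)
  expect_identical(a, b)
  c1 <- mr_weighted_mode(instr, n_boot = 200, seed = 99, grid_n = 2000)
  c2 <- mr_weighted_mode(instr, n_boot = 200, seed = 99, grid_n = 2000)
  expect_identical(c1, c2)
  d <- mr_weighted_median(instr, n_boot = 200, seed = 100)
  expect_false(identical(a$se, d$se))
})

test_that("mr_estimate returns one tidy row per requested method", {
  instr <- random_instruments(j = 8, beta = 0.1, seed = 31)
  est <- mr_estimate(instr, n_boot = 100, seed = 1, grid_n = 2000)
  expect_equal(nrow(est), 5)
  expect_setequal(est$method, c("ivw_fixed", "maximum_likelihood", "mr_egger",
                                "weighted_median", "weighted_mode"))
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
  expect_true(all(est$p_value > 0 & est$p_value <= 1))
  expect_error(mr_estimate(instr, methods = "banana"),
               class = "mrflow_usage_error")
})
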