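test_that("Cochran's Q matches hand computation and is invariant to order/flips", {
  # two instruments, ratios 0 and 1 with unit weights: beta = 0.5, Q = 0.5
  instr <- make_instruments(gamma = c(1, 1), Gamma = c(0, 1),
                            se_gamma = c(1e-9, 1e-9), se_Gamma = c(1, 1))
  het <- cochran_q(instr)
  expect_equal(het$q, 0.5)
  expect_equal(het$df, 1)
  expect_equal(het$p_value, pchisq(0.5, 1, lower.tail = FALSE))

  # identical ratios: Q = 0, p = 1
  instr_c <- make_instruments(gamma = c(1, 2), Gamma = c(0.5, 1))
  expect_equal(cochran_q(instr_c)$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(instr_c)$p_value, 1)

  instr_r <- random_instruments(j = 9, beta = 0.1, seed = 14)
  q1 <- cochran_q(instr_r)$q
  expect_equal(cochran_q(instr_r[sample(9), ])$q, q1)
  flipped <- instr_r
  flipped$gamma <- -flipped$gamma
  flipped$Gamma <- -flipped$Gamma
  expect_equal(cochran_q(flipped)$q, q1)
})

test_that("homogeneous simulations give Q with mean near its df", {
  set.seed(15)
  qs <- vapply(1:1000, function(i) {
    instr <- random_instruments(j = 6, beta = 0.1, seed = 20000 + i)
    cochran_q(instr)$q
  }, numeric(1))
  # chi-square(J-1): mean J-1 = 5, var 2(J-1); allow 3 MC SEs
  mc_se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - 5), 3 * mc_se + 0.05)
})

test_that("the Egger intercept rule gates on magnitude and p-value", {
  mk <- function(i, p) tibble::tibble(intercept = i, se = 0.01, p_value = p)
  expect_true(egger_intercept_rule(mk(0.02, 0.86)))
  expect_false(egger_intercept_rule(mk(0.15, 0.5)))
  expect_false(egger_intercept_rule(mk(0.01, 0.01)))
  # boundary: |intercept| must be strictly below, p strictly above
  expect_false(egger_intercept_rule(mk(0.1, 0.5)))
  expect_false(egger_intercept_rule(mk(0.02, 0.05)))
})

test_that("MR-PRESSO is deterministic and flags a planted outlier", {
  instr <- random_instruments(j = 10, beta = 0.1, seed = 16)
  r1 <- mr_presso(instr, n_sim = 400, seed = 5)
  r2 <- mr_presso(instr, n_sim = 400, seed = 5)
  expect_identical(r1, r2)
  expect_true(r1$global_p > 0 && r1$global_p <= 1)

  # plant a 10-se pleiotropic outlier
  out_instr <- instr
  out_instr$Gamma[3] <- out_instr$Gamma[3] + 10 * out_instr$se_Gamma[3]
  r3 <- mr_presso(out_instr, n_sim = 400, seed = 5)
  expect_true(out_instr$variant_id[3] %in% r3$outliers)
  expect_lt(r3$global_p, 0.05)
  expect_false(is.na(r3$distortion_p))

  expect_error(mr_presso(instr[1:3, ]), class = "mrflow_usage_error")
  expect_error(mr_presso(instr, n_sim = 100), class = "mrflow_usage_error")
})

test_that("leave-one-out rows equal direct IVW recomputation", {
  instr <- random_instruments(j = 5, beta = 0.1, seed = 17)
  tab <- leave_one_out(instr, model = "fixed")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$left_out, c(instr$variant_id, "(none)"))
  for (i in 1:5) {
    direct <- mr_ivw(instr[-i, ], "fixed")
    expect_equal(tab$beta[i], direct$beta, tolerance = 1e-12)
    expect_equal(tab$se[i], direct$se, tolerance = 1e-12)
    expect_equal(tab$p_value[i], direct$p_value, tolerance = 1e-12)
  }
  expect_equal(tab$beta[6], mr_ivw(instr, "fixed")$beta, tolerance = 1e-12)

  # homogeneous instruments: all rows inside the all-SNP CI, none influential
  all_row <- tab[tab$left_out == "(none)", ]
  loo_rows <- tab[tab$left_out != "(none)", ]
  expect_true(all(loo_rows$beta >= all_row$ci_low &
                  loo_rows$beta <= all_row$ci_high))
  expect_false(any(tab$influential))

  # J = 3 gives 4 rows
  expect_equal(nrow(leave_one_out(instr[1:3, ])), 4)
})

test_that("BH adjustment honours an explicit family size", {
  # worked examples with family m = 196
  expect_equal(bh_fdr(3.01e-6, m = 196), 5.8996e-4, tolerance = 1e-12)
  # matches the printed value at its reported precision
  expect_equal(round(bh_fdr(c(3.01e-6, 4.10e-4), m = 196)[2], 3), 0.040)
  expect_equal(bh_fdr(1), 1)
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), class = "mrflow_usage_error")
  expect_error(bh_fdr(c(0.1, 0)), class = "mrflow_usage_error")
})

test_that("BH matches an independent step-up oracle and stays monotone", {
  set.seed(18)
  for (trial in 1:20) {
    k <- sample(1:30, 1)
    m <- k + sample(0:170, 1)
    p <- runif(k)^2
    got <- bh_fdr(p, m = m)
    expect_equal(got, bh_oracle(p, m), tolerance = 1e-12)
    expect_true(all(got > 0 & got <= 1))
    # adjusted values share the order of the raw p-values
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
})
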