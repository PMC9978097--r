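test_that("p-value screen uses strict inequality and preserves order", {
  st <- make_study(3, p = c(1e-6, 2e-5, 1e-5))
  kept <- filter_by_pvalue(st, 1e-5)
  expect_equal(kept$variant_id, "s1")   # 1e-5 itself is excluded

  st2 <- make_study(4, p = c(0.2, 0.9, 1.0, 0.5))
  expect_equal(nrow(filter_by_pvalue(st2, 1.0)), 3)  # p = 1 fails p < 1

  expect_equal(nrow(filter_by_pvalue(make_study(0), 1e-5)), 0)
  expect_error(filter_by_pvalue(st, 0), class = "mrflow_usage_error")
})

test_that("clumping keeps the strongest of correlated nearby variants", {
  st <- make_study(2, p = c(1e-8, 1e-6), pos = c(100000L, 110000L))
  panel <- make_panel("s1", "s2", 0.5)
  expect_equal(ld_clump(st, panel)$variant_id, "s1")

  panel_low <- make_panel("s1", "s2", 0.005)
  expect_equal(nrow(ld_clump(st, panel_low)), 2)

  # beyond the window the r2 does not matter
  st_far <- make_study(2, p = c(1e-8, 1e-6), pos = c(100000L, 700001L))
  expect_equal(nrow(ld_clump(st_far, panel)), 2)

  # missing positions are a usage error naming the variant
  st_na <- tibble::as_tibble(st)
  st_na$position[2] <- NA_integer_
  expect_error(ld_clump(st_na, panel), "s2", class = "mrflow_usage_error")
})

test_that("greedy clumping equals the brute-force oracle on small instances", {
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    st <- make_study(
      n, p = 10^runif(n, -10, -2),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      pos = sample.int(800000L, n)
    )
    cmb <- t(combn(st$variant_id, 2))
    panel <- make_panel(cmb[, 1], cmb[, 2], runif(nrow(cmb))^2)
    got <- sort(ld_clump(st, panel, 0.01, 500)$variant_id)
    expect_equal(got, clump_oracle(st, panel, 0.01, 500), info = trial)
    # row order must not matter
    shuffled <- st[sample(nrow(st)), ]
    expect_equal(sort(ld_clump(shuffled, panel, 0.01, 500)$variant_id), got)
  }
})

test_that("every retained clumped pair is uncorrelated or distant", {
  set.seed(7)
  n <- 8
  st <- make_study(n, p = 10^runif(n, -9, -3), pos = sample.int(600000L, n))
  cmb <- t(combn(st$variant_id, 2))
  panel <- make_panel(cmb[, 1], cmb[, 2], runif(nrow(cmb))^4)
  kept <- ld_clump(st, panel, 0.05, 300)
  expect_gte(nrow(kept), 2)
  if (nrow(kept) >= 2) {
    pr <- t(combn(seq_len(nrow(kept)), 2))
    for (i in seq_len(nrow(pr))) {
      a <- pr[i, 1]; b <- pr[i, 2]
      dist_ok <- abs(kept$position[a] - kept$position[b]) > 300 * 1000
      r2_ok <- ld_r2(panel, kept$variant_id[a], kept$variant_id[b]) < 0.05
      expect_true(dist_ok || r2_ok)
    }
  }
})

test_that("PVE matches both printed forms and its hand-computed value", {
  expect_equal(pve_single(0, maf = 0.3, se = 0.01, n = 1000), 0)
  expect_equal(pve_single(1, maf = 0.5, se = 1, n = 1), 0.5)
  # the full formula with the common 2*maf*(1-maf) factor agrees with the
  # cancelled form to full precision
  b <- 0.27; m <- 0.12; se <- 0.031; n <- 18340
  full <- (2 * b^2 * m * (1 - m)) /
    (2 * b^2 * m * (1 - m) + 2 * se^2 * n * m * (1 - m))
  expect_equal(pve_single(b, maf = m, se = se, n = n), full, tolerance = 1e-14)
  # MAF symmetry
  expect_equal(pve_single(b, maf = m, se = se, n = n),
               pve_single(b, maf = 1 - m, se = se, n = n))
  expect_error(pve_single(0.1, maf = 1, se = 0.01, n = 100),
               class = "mrflow_domain_error")
})

test_that("PVE is monotone in |beta|, se and n", {
  base <- pve_single(0.2, se = 0.05, n = 5000)
  expect_gt(pve_single(0.3, se = 0.05, n = 5000), base)
  expect_lt(pve_single(0.2, se = 0.08, n = 5000), base)
  expect_lt(pve_single(0.2, se = 0.05, n = 9000), base)
})

test_that("F-statistic matches hand values in both forms", {
  expect_equal(f_statistic(0, n = 100, k = 1), 0)
  expect_equal(f_statistic(0.5, n = 1003, k = 1), 1001)
  expect_equal(f_statistic(0.5, n = 1003, k = 2), 500)
  expect_equal(f_statistic(0.5, n = 1003, k = 2, form = "literal"), 1000)
  expect_equal(f_statistic(0.5, n = 1003, k = 1, form = "literal"),
               f_statistic(0.5, n = 1003, k = 1))
  expect_error(f_statistic(1, n = 100), class = "mrflow_domain_error")
  expect_error(f_statistic(0.2, n = 2, k = 1), class = "mrflow_domain_error")
})

test_that("weak instruments are excluded at the F threshold", {
  instr <- random_instruments(j = 3, beta = 0, seed = 2)
  # craft strengths so per-variant F are {21.2, 9.9, 35.0}
  strengths <- tibble::tibble(
    variant_id = instr$variant_id, pve = c(0.002, 0.001, 0.003),
    f_stat = c(21.2, 9.9, 35.0), n_used = 10000
  )
  kept <- drop_weak(instr, strengths, f_min = 10)
  expect_equal(nrow(kept), 2)
  expect_equal(unname(attr(kept, "provenance")["dropped_weak"]), 1L)
  # all strong -> identity; all weak -> empty
  expect_equal(nrow(drop_weak(instr, strengths, f_min = 5)), 3)
  expect_equal(nrow(drop_weak(instr, strengths, f_min = 100)), 0)
})

test_that("instrument strength totals are consistent", {
  instr <- random_instruments(j = 6, beta = 0.1, seed = 9)
  instr$n <- 50000L
  s <- instrument_strength(instr)
  expect_equal(attr(s, "total_pve"), sum(s$pve))
  expect_equal(attr(s, "k"), 6)
  expect_true(all(s$pve >= 0 & s$pve < 1))
  expect_true(all(s$f_stat >= 0))
})
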