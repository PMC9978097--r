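exp_rec <- function(ea = "A", oa = "G", beta = 0.1, eaf = 0.3, id = "rs1") {
  list(variant_id = id, effect_allele = ea, other_allele = oa,
       beta = beta, se = 0.01, p_value = 1e-8, eaf = eaf)
}
out_rec <- function(ea = "A", oa = "G", beta = 0.05, eaf = 0.3, id = "rs1") {
  list(variant_id = id, effect_allele = ea, other_allele = oa,
       beta = beta, se = 0.02, p_value = 1e-3, eaf = eaf)
}

test_that("same-order, swapped and strand-flipped alleles align correctly", {
  h <- align_alleles(exp_rec(), out_rec())
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$Gamma, 0.05)

  h <- align_alleles(exp_rec(), out_rec(ea = "G", oa = "A", eaf = 0.3))
  expect_equal(h$action, "flipped")
  expect_equal(h$Gamma, -0.05)
  expect_equal(h$eaf_outcome, 0.7)

  # strand flip: T/C complements to A/G -> same order
  h <- align_alleles(exp_rec(), out_rec(ea = "T", oa = "C"))
  expect_equal(h$action, "kept_as_is")
  expect_equal(h$Gamma, 0.05)
  # strand flip + swap: C/T complements to G/A -> swapped
  h <- align_alleles(exp_rec(), out_rec(ea = "C", oa = "T"))
  expect_equal(h$action, "flipped")

  # irreconcilable alleles
  h <- align_alleles(exp_rec(), out_rec(ea = "A", oa = "C"))
  expect_equal(h$action, "dropped_mismatch")

  expect_error(align_alleles(exp_rec(id = "rs1"), out_rec(id = "rs2")),
               class = "mrflow_usage_error")
})

test_that("palindromic variants are resolved by allele frequency or dropped", {
  # maximal ambiguity: eaf exactly 0.5 drops for any positive window
  h <- align_alleles(exp_rec(ea = "A", oa = "T", eaf = 0.5),
                     out_rec(ea = "A", oa = "T", eaf = 0.5),
                     palindrome_window = 0.01)
  expect_equal(h$action, "dropped_palindromic")

  # concordant informative frequencies keep the record
  h <- align_alleles(exp_rec(ea = "A", oa = "T", eaf = 0.2),
                     out_rec(ea = "A", oa = "T", eaf = 0.25))
  expect_equal(h$action, "kept_as_is")

  # discordant frequencies flip it
  h <- align_alleles(exp_rec(ea = "C", oa = "G", eaf = 0.2),
                     out_rec(ea = "C", oa = "G", beta = 0.05, eaf = 0.8))
  expect_equal(h$action, "flipped")
  expect_equal(h$Gamma, -0.05)

  # missing eaf on either side drops unconditionally
  h <- align_alleles(exp_rec(ea = "A", oa = "T", eaf = NA),
                     out_rec(ea = "A", oa = "T", eaf = 0.2))
  expect_equal(h$action, "dropped_palindromic")
})

test_that("palindrome drop rate is monotone nondecreasing in the window", {
  set.seed(11)
  eafs_e <- runif(40, 0.05, 0.95)
  eafs_o <- eafs_e + rnorm(40, 0, 0.05)
  eafs_o <- pmin(pmax(eafs_o, 0.01), 0.99)
  drops <- vapply(c(0, 0.02, 0.05, 0.08, 0.15, 0.3), function(w) {
    sum(vapply(seq_along(eafs_e), function(i) {
      align_alleles(exp_rec(ea = "A", oa = "T", eaf = eafs_e[i]),
                    out_rec(ea = "A", oa = "T", eaf = eafs_o[i]),
                    palindrome_window = w)$action == "dropped_palindromic"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(drops) >= 0))
})

test_that("merging studies intersects, aligns, and records provenance", {
  e <- make_study(5, ids = paste0("rs", 1:5))
  o <- make_study(5, ids = paste0("rs", 3:7))
  instr <- harmonise_studies(e, o)
  expect_equal(nrow(instr), 3)
  expect_equal(sum(attr(instr, "provenance")), 3)

  # disjoint variant sets give an empty instrument set, not an error
  o2 <- make_study(3, ids = paste0("rx", 1:3))
  expect_equal(nrow(harmonise_studies(e, o2)), 0)

  # one swapped-order outcome among three shared variants
  o3 <- tibble::as_tibble(make_study(3, ids = paste0("rs", 1:3)))
  o3$effect_allele[2] <- "G"
  o3$other_allele[2] <- "A"
  instr3 <- harmonise_studies(e, o3)
  prov <- attr(instr3, "provenance")
  expect_equal(unname(prov["kept_as_is"]), 2L)
  expect_equal(unname(prov["flipped"]), 1L)
  expect_equal(instr3$Gamma[instr3$variant_id == "rs2"], -0.1)
})

test_that("double flip is the identity", {
  e <- exp_rec()
  o <- out_rec(ea = "G", oa = "A", beta = 0.07, eaf = 0.4)
  h1 <- align_alleles(e, o)
  expect_equal(h1$action, "flipped")
  # re-align the flipped record (now on the exposure's alleles) against exp
  o2 <- list(variant_id = "rs1", effect_allele = "A", other_allele = "G",
             beta = h1$Gamma, se = 0.02, p_value = 1e-3,
             eaf = h1$eaf_outcome)
  h2 <- align_alleles(e, o2)
  expect_equal(h2$action, "kept_as_is")
  # flipping back recovers the original outcome beta
  expect_equal(-h2$Gamma, o$beta)
})

test_that("causal estimates are invariant to which allele is called 'effect'", {
  instr <- random_instruments(j = 8, beta = 0.15, seed = 3)
  flipped <- instr
  flip_idx <- c(2, 5)
  flipped$gamma[flip_idx] <- -flipped$gamma[flip_idx]
  flipped$Gamma[flip_idx] <- -flipped$Gamma[flip_idx]
  for (fun in list(
    function(d) mr_ivw(d, "fixed"),
    mr_maximum_likelihood,
    function(d) mr_egger(d)$estimate,
    function(d) mr_weighted_median(d, n_boot = 100, seed = 5),
    function(d) mr_weighted_mode(d, n_boot = 100, seed = 5, grid_n = 2000)
  )) {
    a <- fun(instr)
    b <- fun(flipped)
    expect_equal(b$beta, a$beta, tolerance = 1e-12)
    expect_equal(b$se, a$se, tolerance = 1e-12)
  }
})
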