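# Seeded generator of two-sample GWAS summary statistics with known causal
# truth. The generative model is the standard two-sample MR one: true
# instrument effects gamma_j on a standardized exposure, a true causal
# effect beta on a standardized outcome, optional pleiotropic direct
# effects alpha_j (balanced or directional, with a controllable correlation
# to instrument strength that violates InSIDE), and sampling noise whose
# standard errors follow the standardized-trait closed form
# se = [2 n MAF (1 - MAF)]^(-1/2).

#' Describe a simulation scenario
#'
#' Bundles the ground truth of a simulated exposure-outcome pair. Defaults
#' describe a well-powered, clean two-sample design: 10 independent
#' instruments, both GWAS of 50,000 samples, instrument effects of standard
#' deviation 0.1 on the standardized exposure (per-variant F-statistics in
#' the hundreds, comfortably past the weak-instrument bound), no causal
#' effect and no pleiotropy.
#'
#' @param beta_causal True causal effect of exposure on outcome.
#' @param j Number of instruments.
#' @param maf_range Interval minor allele frequencies are drawn from.
#' @param gamma_sd Standard deviation of true instrument effects; draws are
#'   resampled away from zero so every `|gamma_j| > 0.1 * gamma_sd`.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects)
#'   or `"directional"` (mean `alpha_mean`).
#' @param alpha_mean,alpha_sd Mean and SD of pleiotropic direct effects.
#' @param inside_violation Correlation in \[-1, 1\] between pleiotropic
#'   effects and absolute instrument strength; nonzero values violate the
#'   InSIDE assumption.
#' @param invalid_fraction Proportion of instruments carrying pleiotropy.
#' @param seed Integer master seed.
#' @return A list of class `mr_scenario`.
#' @export
scenario_truth <- function(beta_causal = 0, j = 10, maf_range = c(0.05, 0.5),
                           gamma_sd = 0.1, n_exposure = 50000,
                           n_outcome = 50000,
                           pleiotropy_mode = c("none", "balanced", "directional"),
                           alpha_mean = 0, alpha_sd = 0.01,
                           inside_violation = 0, invalid_fraction = 0,
                           seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort_mr("`invalid_fraction` must lie in [0, 1].", "mrflow_usage_error")
  }
  if (abs(inside_violation) > 1) {
    abort_mr("`inside_violation` must lie in [-1, 1].", "mrflow_usage_error")
  }
  if (gamma_sd <= 0 || n_exposure <= 0 || n_outcome <= 0 || j < 1) {
    abort_mr("gamma_sd, sample sizes and j must be positive.",
             "mrflow_usage_error")
  }
  structure(
    list(beta_causal = beta_causal, j = as.integer(j), maf_range = maf_range,
         gamma_sd = gamma_sd, n_exposure = as.integer(n_exposure),
         n_outcome = as.integer(n_outcome),
         pleiotropy_mode = pleiotropy_mode, alpha_mean = alpha_mean,
         alpha_sd = alpha_sd, inside_violation = inside_violation,
         invalid_fraction = invalid_fraction, seed = as.integer(seed)),
    class = "mr_scenario"
  )
}

# Standardized-trait standard error of a per-allele GWAS effect.
se_standardized <- function(n, maf) {
  1 / sqrt(2 * n * maf * (1 - maf))
}

#' Simulate one two-sample GWAS summary-statistic pair
#'
#' Draws, for each instrument: a minor allele frequency uniform on
#' `maf_range`; a true exposure effect `gamma_j ~ N(0, gamma_sd^2)`
#' resampled away from zero; a pleiotropic direct effect `alpha_j` (zero for
#' valid instruments, otherwise drawn per `pleiotropy_mode`, with a rank
#' correlation of `inside_violation` to `|gamma_j|`); the true outcome
#' effect `beta_causal * gamma_j + alpha_j`; standard errors from the
#' standardized-trait closed form; and observed effects equal to truth plus
#' normal sampling noise, with two-sided normal p-values. Variants are
#' placed on chromosome 1 at 1-Mb spacing and the returned LD panel lists no
#' pairs (all pairwise r2 = 0) — use [simulate_ld_blocks()] for correlated
#' designs.
#'
#' @param truth An `mr_scenario` from [scenario_truth()].
#' @param variant_prefix Prefix for generated variant ids.
#' @return A list of class `mr_simulated_pair` with elements `exposure` and
#'   `outcome` (summary-statistic tibbles), `panel` (`mr_ld_panel`) and
#'   `truth` (the scenario plus the per-variant true effect table).
#' @export
simulate_pair <- function(truth, variant_prefix = "rs") {
  if (!inherits(truth, "mr_scenario")) {
    abort_mr("`truth` must come from scenario_truth().", "mrflow_usage_error")
  }
  j <- truth$j
  with_seed(truth$seed, {
    maf <- stats::runif(j, truth$maf_range[1], truth$maf_range[2])
    gamma <- stats::rnorm(j, 0, truth$gamma_sd)
    small <- abs(gamma) <= 0.1 * truth$gamma_sd
    while (any(small)) {
      gamma[small] <- stats::rnorm(sum(small), 0, truth$gamma_sd)
      small <- abs(gamma) <= 0.1 * truth$gamma_sd
    }
    alpha <- numeric(j)
    n_invalid <- round(truth$invalid_fraction * j)
    invalid <- rep(FALSE, j)
    if (truth$pleiotropy_mode != "none" && n_invalid > 0) {
      invalid[sample.int(j, n_invalid)] <- TRUE
      mu <- if (truth$pleiotropy_mode == "directional") truth$alpha_mean else 0
      raw <- stats::rnorm(n_invalid, 0, 1)
      if (truth$inside_violation != 0) {
        # mix an instrument-strength component into the pleiotropic draw so
        # that cor(alpha, |gamma|) approaches inside_violation
        gz <- scale(abs(gamma[invalid]))[, 1]
        if (n_invalid < 2 || stats::sd(abs(gamma[invalid])) == 0) gz <- rep(0, n_invalid)
        rho <- truth$inside_violation
        raw <- rho * gz + sqrt(1 - rho^2) * raw
      }
      alpha[invalid] <- mu + truth$alpha_sd * raw
    }
    # pleiotropic effects are defined relative to the exposure-increasing
    # allele (the oriented frame estimators work in); a variant reported on
    # its other allele carries the sign-flipped direct effect
    alpha <- sign(gamma) * alpha
    Gamma_true <- truth$beta_causal * gamma + alpha
    se_g <- se_standardized(truth$n_exposure, maf)
    se_G <- se_standardized(truth$n_outcome, maf)
    g_hat <- stats::rnorm(j, gamma, se_g)
    G_hat <- stats::rnorm(j, Gamma_true, se_G)
    ids <- paste0(variant_prefix, seq_len(j))
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, j, replace = TRUE)
    oa <- vapply(ea, function(a) {
      # avoid palindromic pairs so harmonization keeps every variant
      sample(setdiff(alleles, c(a, chartr("ACGT", "TGCA", a))), 1)
    }, character(1))
    exposure <- new_sumstats(
      tibble::tibble(
        variant_id = ids, chromosome = "1",
        position = as.integer(seq_len(j) * 1000000L),
        effect_allele = ea, other_allele = oa,
        beta = g_hat, se = se_g, p_value = p_from_z(g_hat / se_g),
        eaf = maf, n = truth$n_exposure
      ),
      trait_label = "simulated_exposure", total_n = truth$n_exposure,
      population_label = "simulated"
    )
    outcome <- new_sumstats(
      tibble::tibble(
        variant_id = ids, chromosome = "1",
        position = as.integer(seq_len(j) * 1000000L),
        effect_allele = ea, other_allele = oa,
        beta = G_hat, se = se_G, p_value = p_from_z(G_hat / se_G),
        eaf = maf, n = truth$n_outcome
      ),
      trait_label = "simulated_outcome", total_n = truth$n_outcome,
      population_label = "simulated"
    )
    panel <- new_ld_panel(
      tibble::tibble(variant_id_a = character(), variant_id_b = character(),
                     r2 = numeric()),
      positions = tibble::tibble(variant_id = ids, chromosome = "1",
                                 position = as.integer(seq_len(j) * 1000000L))
    )
    truth_table <- tibble::tibble(
      variant_id = ids, maf = maf, gamma_true = gamma, alpha_true = alpha,
      Gamma_true = Gamma_true, invalid = invalid
    )
    structure(
      list(exposure = exposure, outcome = outcome, panel = panel,
           truth = c(truth, list(per_variant = truth_table))),
      class = "mr_simulated_pair"
    )
  })
}

#' Simulate a block-structured LD panel
#'
#' Builds an LD panel in which within-block r2 decays geometrically with
#' marker distance, `r2(i, k) = rho^(2 |i - k|)` for adjacent-marker
#' correlation `rho`, and across-block r2 is zero. Variant positions are
#' evenly spaced.
#'
#' @param block_sizes Integer vector of variants per block.
#' @param rho Adjacent-marker correlation in \[0, 1).
#' @param positions_spacing_bp Base-pair spacing between consecutive
#'   variants, default 1000.
#' @param variant_prefix Prefix for generated variant ids.
#' @return A list with `panel` (`mr_ld_panel`) and `positions` (tibble
#'   `variant_id`, `chromosome`, `position`).
#' @export
simulate_ld_blocks <- function(block_sizes, rho,
                               positions_spacing_bp = 1000,
                               variant_prefix = "rs") {
  if (rho < 0 || rho >= 1) {
    abort_mr("`rho` must lie in [0, 1).", "mrflow_usage_error")
  }
  total <- sum(block_sizes)
  ids <- paste0(variant_prefix, seq_len(total))
  block_id <- rep(seq_along(block_sizes), block_sizes)
  pos_in_block <- unlist(lapply(block_sizes, seq_len))
  pairs <- list()
  if (rho > 0) {
    idx <- 1L
    for (b in seq_along(block_sizes)) {
      members <- which(block_id == b)
      if (length(members) < 2) next
      cmb <- utils::combn(members, 2)
      d <- abs(pos_in_block[cmb[1, ]] - pos_in_block[cmb[2, ]])
      pairs[[idx]] <- tibble::tibble(
        variant_id_a = ids[cmb[1, ]], variant_id_b = ids[cmb[2, ]],
        r2 = rho^(2 * d)
      )
      idx <- idx + 1L
    }
  }
  pairs <- if (length(pairs) > 0) dplyr::bind_rows(pairs) else
    tibble::tibble(variant_id_a = character(), variant_id_b = character(),
                   r2 = numeric())
  positions <- tibble::tibble(
    variant_id = ids, chromosome = "1",
    position = as.integer(seq_len(total) * positions_spacing_bp)
  )
  list(panel = new_ld_panel(pairs, positions), positions = positions)
}

#' Simulate a family of exposures against a shared outcome
#'
#' Generates `n_taxa` independent simulated exposures (all with zero causal
#' effect unless overridden per taxon) against one shared outcome study,
#' the setting used to exercise family-wise FDR calling. Each taxon draws
#' from its own seed substream derived from the master seed, so any single
#' taxon is independently reproducible.
#'
#' @param n_taxa Number of exposures.
#' @param base_truth Template `mr_scenario`; per-taxon scenarios copy it.
#' @param causal_beta Named or positional numeric vector (length `n_taxa`)
#'   of per-taxon causal effects; default all zero.
#' @param seed Master seed.
#' @return A list of class `mr_family` with `exposures` (list of
#'   summary-statistic tibbles), `outcome` (combined summary study),
#'   `panel`, and `truths` (list of per-taxon scenario truths).
#' @export
simulate_null_family <- function(n_taxa, base_truth = scenario_truth(),
                                 causal_beta = NULL, seed = 1L) {
  if (n_taxa < 1) {
    abort_mr("`n_taxa` must be at least 1.", "mrflow_usage_error")
  }
  causal_beta <- causal_beta %||% rep(0, n_taxa)
  if (length(causal_beta) != n_taxa) {
    abort_mr("`causal_beta` must have one entry per taxon.",
             "mrflow_usage_error")
  }
  exposures <- vector("list", n_taxa)
  outcome_rows <- vector("list", n_taxa)
  truths <- vector("list", n_taxa)
  positions <- vector("list", n_taxa)
  for (t in seq_len(n_taxa)) {
    tr <- base_truth
    tr$beta_causal <- causal_beta[t]
    tr$seed <- derive_seed(seed, t)
    pair <- simulate_pair(tr, variant_prefix = sprintf("t%d_rs", t))
    exposures[[t]] <- pair$exposure
    attr(exposures[[t]], "trait_label") <- sprintf("taxon_%03d", t)
    outcome_rows[[t]] <- tibble::as_tibble(pair$outcome)
    truths[[t]] <- pair$truth
    positions[[t]] <- pair$panel$positions
  }
  outcome <- new_sumstats(
    dplyr::bind_rows(outcome_rows),
    trait_label = "shared_outcome", total_n = base_truth$n_outcome,
    population_label = "simulated"
  )
  panel <- new_ld_panel(
    tibble::tibble(variant_id_a = character(), variant_id_b = character(),
                   r2 = numeric()),
    positions = dplyr::bind_rows(positions)
  )
  structure(
    list(exposures = exposures, outcome = outcome, panel = panel,
         truths = truths),
    class = "mr_family"
  )
}
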