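# Orchestration of the full two-sample MR study flow for one exposure-
# outcome pair: p-value screen -> LD clumping -> harmonization -> strength
# filter -> minimum-instrument gate -> five estimators -> sensitivity suite
# (with a single MR-PRESSO-driven outlier-removal pass) -> classification;
# plus the matrix, bidirectional and replication drivers and report writer.

#' Analysis configuration
#'
#' All tunable thresholds of the analysis in one validated list. Defaults
#' are the conventional values for microbiome-exposure MR screens: a loose
#' instrument p-value threshold of 1e-5, clumping at r2 < 0.01 within 500
#' kb, per-variant F >= 10, at least 3 instruments per testable pair, a
#' palindrome ambiguity window of 0.08, heterogeneity-driven choice of
#' fixed- vs random-effects IVW at alpha 0.05, the Egger intercept rule
#' (|intercept| < 0.1 and p > 0.05), MR-PRESSO with 1000 simulations,
#' nominal significance at 0.05, at least 3 nominally significant methods
#' for a causal candidate, and FDR calling at 0.05.
#'
#' @param p_threshold Instrument p-value screen (strict `<`).
#' @param clump_r2,clump_window_kb LD clumping parameters.
#' @param f_min Weak-instrument F bound.
#' @param min_ivs Minimum instruments for a testable pair.
#' @param palindrome_window Palindromic ambiguity half-width.
#' @param heterogeneity_alpha Cochran-Q alpha driving the IVW model choice.
#' @param egger_intercept_abs,egger_intercept_p Egger intercept rule.
#' @param presso_nsim MR-PRESSO simulation count.
#' @param nominal_alpha Nominal significance level.
#' @param methods_required Nominally significant methods needed for a
#'   causal candidate.
#' @param fdr_alpha FDR threshold for a significant call.
#' @param fdr_family_m Family size for BH adjustment; `NULL` means the
#'   number of exposures tested against the same outcome.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param mode_grid_n Density grid size for the weighted mode.
#' @param seed Master seed for every stochastic step.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 1e-5, clump_r2 = 0.01,
                      clump_window_kb = 500, f_min = 10, min_ivs = 3,
                      palindrome_window = 0.08, heterogeneity_alpha = 0.05,
                      egger_intercept_abs = 0.1, egger_intercept_p = 0.05,
                      presso_nsim = 1000, nominal_alpha = 0.05,
                      methods_required = 3, fdr_alpha = 0.05,
                      fdr_family_m = NULL, n_boot = 1000,
                      mode_grid_n = 10000, seed = 1L) {
  stopifnot(
    p_threshold > 0, p_threshold <= 1,
    clump_r2 > 0, clump_r2 <= 1, clump_window_kb > 0,
    f_min >= 0, min_ivs >= 1, palindrome_window >= 0,
    heterogeneity_alpha > 0, heterogeneity_alpha < 1,
    egger_intercept_abs > 0, egger_intercept_p > 0,
    presso_nsim >= 200, nominal_alpha > 0, nominal_alpha < 1,
    methods_required >= 1, fdr_alpha > 0, fdr_alpha < 1,
    n_boot >= 100, mode_grid_n >= 100
  )
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, f_min = f_min, min_ivs = min_ivs,
         palindrome_window = palindrome_window,
         heterogeneity_alpha = heterogeneity_alpha,
         egger_intercept_abs = egger_intercept_abs,
         egger_intercept_p = egger_intercept_p,
         presso_nsim = presso_nsim, nominal_alpha = nominal_alpha,
         methods_required = methods_required, fdr_alpha = fdr_alpha,
         fdr_family_m = fdr_family_m, n_boot = n_boot,
         mode_grid_n = mode_grid_n, seed = as.integer(seed)),
    class = "mr_config"
  )
}

#' Choose fixed- or random-effects IVW from the heterogeneity test
#'
#' Random effects when the Cochran-Q p-value is strictly below
#' `heterogeneity_alpha`, fixed effects otherwise (a p-value exactly at the
#' threshold keeps the fixed model).
#'
#' @param het Tibble from [cochran_q()].
#' @param config An `mr_config`.
#' @return `"fixed"` or `"random"`.
#' @export
choose_ivw_model <- function(het, config = mr_config()) {
  if (het$p_value < config$heterogeneity_alpha) "random" else "fixed"
}

#' Classify one exposure-outcome pair
#'
#' Classification ladder applied to a testable pair: `null` when the IVW
#' p-value is at or above the nominal level; `suggestive` when below it;
#' `causal_candidate` when suggestive and at least `methods_required` of the
#' estimators are nominally significant; `significant` when additionally
#' the FDR-adjusted IVW p-value is below `fdr_alpha`. Pairs failing the
#' minimum-instrument gate are classified `not_testable` upstream.
#'
#' @param p_ivw IVW p-value.
#' @param n_nominal_methods Count of nominally significant estimators.
#' @param fdr FDR-adjusted IVW p-value.
#' @param config An `mr_config`.
#' @return One of `"null"`, `"suggestive"`, `"causal_candidate"`,
#'   `"significant"`.
#' @export
classify_call <- function(p_ivw, n_nominal_methods, fdr,
                          config = mr_config()) {
  if (!is.finite(p_ivw)) {
    abort_mr("`p_ivw` must be finite.", "mrflow_usage_error")
  }
  if (p_ivw >= config$nominal_alpha) {
    return("null")
  }
  if (n_nominal_methods < config$methods_required) {
    return("suggestive")
  }
  if (is.na(fdr) || fdr >= config$fdr_alpha) {
    return("causal_candidate")
  }
  "significant"
}

not_testable_call <- function(exposure_label, outcome_label, counts) {
  structure(
    list(exposure_label = exposure_label, outcome_label = outcome_label,
         n_iv_initial = counts$initial, n_iv_final = counts$final,
         stage_counts = counts, estimates = NULL, sensitivity = NULL,
         strengths = NULL, instruments = NULL, fdr = NA_real_,
         p_ivw = NA_real_, n_nominal_methods = NA_integer_,
         classification = "not_testable", direction = NA_real_,
         outliers_removed = character()),
    class = "mr_call"
  )
}

run_estimation <- function(instruments, config) {
  het <- cochran_q(instruments)
  ivw_model <- choose_ivw_model(het, config)
  estimates <- mr_estimate(
    instruments, methods = mr_methods_all, ivw_model = ivw_model,
    n_boot = config$n_boot, seed = derive_seed(config$seed, 11),
    grid_n = config$mode_grid_n
  )
  pleio <- mr_egger(instruments)$pleiotropy
  presso <- if (nrow(instruments) >= 4) {
    mr_presso(instruments, n_sim = config$presso_nsim,
              outlier_alpha = config$nominal_alpha,
              seed = derive_seed(config$seed, 12))
  } else {
    NULL
  }
  list(het = het, ivw_model = ivw_model, estimates = estimates,
       pleiotropy = pleio, presso = presso)
}

#' Run the full MR analysis for one exposure-outcome pair
#'
#' Executes the complete per-pair study flow: p-value screen, greedy LD
#' clumping, allele harmonization, instrument-strength computation with the
#' weak-instrument filter, the minimum-instrument gate, the five causal
#' estimators (fixed- or random-effects IVW chosen from Cochran's Q), the
#' Egger intercept rule, and MR-PRESSO. If the PRESSO global test fails
#' (p below the nominal level) and outliers are flagged, the flagged
#' variants are removed and estimation plus sensitivity rerun exactly once.
#' Leave-one-out re-estimation and the classification ladder complete the
#' call. A pair failing the instrument gate returns a `not_testable` call,
#' never an error; every stage's instrument count is recorded.
#'
#' @param exposure,outcome Summary-statistic tibbles.
#' @param panel An `mr_ld_panel` for clumping.
#' @param config An `mr_config`.
#' @return An object of class `mr_call`; see [tidy.mr_call()] and
#'   [glance.mr_call()] for tabular views.
#' @export
run_pair <- function(exposure, outcome, panel, config = mr_config()) {
  stop_if_not_df(exposure, "exposure")
  stop_if_not_df(outcome, "outcome")
  exposure_label <- trait_label(exposure)
  outcome_label <- trait_label(outcome)
  counts <- list(initial = nrow(exposure))

  screened <- filter_by_pvalue(exposure, config$p_threshold)
  counts$screened <- nrow(screened)
  clumped <- if (nrow(screened) > 0) {
    ld_clump(screened, panel, config$clump_r2, config$clump_window_kb)
  } else {
    screened
  }
  counts$clumped <- nrow(clumped)
  instr <- harmonise_studies(clumped, outcome, config$palindrome_window)
  counts$harmonized <- nrow(instr)

  strengths <- NULL
  if (nrow(instr) > 0) {
    strengths <- instrument_strength(
      dplyr::mutate(instr, n = clumped$n[match(instr$variant_id,
                                               clumped$variant_id)]),
      n = total_n(exposure)
    )
    instr <- drop_weak(instr, strengths, config$f_min)
    strengths <- strengths[strengths$variant_id %in% instr$variant_id, ,
                           drop = FALSE]
  }
  counts$strong <- nrow(instr)
  counts$final <- nrow(instr)
  if (nrow(instr) < config$min_ivs) {
    return(not_testable_call(exposure_label, outcome_label, counts))
  }

  fit <- run_estimation(instr, config)
  outliers_removed <- character()
  if (!is.null(fit$presso) && fit$presso$global_p < config$nominal_alpha &&
      length(fit$presso$outliers) > 0) {
    # single corrective pass: remove flagged outliers, re-estimate once
    outliers_removed <- fit$presso$outliers
    instr2 <- instr[!(instr$variant_id %in% outliers_removed), , drop = FALSE]
    counts$final <- nrow(instr2)
    if (nrow(instr2) < config$min_ivs) {
      return(not_testable_call(exposure_label, outcome_label, counts))
    }
    instr <- new_instruments(instr2, attr(instr, "exposure_label"),
                             attr(instr, "outcome_label"),
                             attr(instr, "provenance"))
    strengths <- strengths[strengths$variant_id %in% instr$variant_id, ,
                           drop = FALSE]
    fit <- run_estimation(instr, config)
  }

  loo <- leave_one_out(instr, model = fit$ivw_model)
  ivw_row <- fit$estimates[fit$estimates$method %in% c("ivw_fixed", "ivw_random"), ]
  p_ivw <- ivw_row$p_value[1]
  n_nominal <- sum(fit$estimates$p_value < config$nominal_alpha)

  structure(
    list(
      exposure_label = exposure_label, outcome_label = outcome_label,
      n_iv_initial = counts$harmonized, n_iv_final = counts$final,
      stage_counts = counts,
      estimates = fit$estimates,
      sensitivity = list(
        heterogeneity = fit$het, ivw_model = fit$ivw_model,
        pleiotropy = fit$pleiotropy,
        egger_rule_pass = egger_intercept_rule(
          fit$pleiotropy, config$egger_intercept_abs, config$egger_intercept_p
        ),
        presso = fit$presso, leave_one_out = loo
      ),
      strengths = strengths, instruments = instr,
      fdr = NA_real_, p_ivw = p_ivw,
      n_nominal_methods = as.integer(n_nominal),
      classification = classify_call(p_ivw, n_nominal, NA_real_, config),
      direction = sign(ivw_row$beta[1]),
      outliers_removed = outliers_removed
    ),
    class = "mr_call"
  )
}

#' @export
print.mr_call <- function(x, ...) {
  cat(sprintf("<mr_call> %s -> %s: %s (IVs %s, IVW p = %s)\n",
              x$exposure_label, x$outcome_label, x$classification,
              format(x$n_iv_final), format(x$p_ivw, digits = 3)))
  invisible(x)
}

# Attach per-outcome BH-adjusted IVW p-values and final classifications to a
# list of calls. Family size defaults to the number of exposures tested
# against each outcome.
apply_fdr <- function(calls, config) {
  by_outcome <- split(seq_along(calls),
                      vapply(calls, `[[`, character(1), "outcome_label"))
  for (idx in by_outcome) {
    m <- config$fdr_family_m %||% length(idx)
    testable <- idx[vapply(calls[idx], function(cl) {
      cl$classification != "not_testable"
    }, logical(1))]
    if (length(testable) == 0) next
    p <- vapply(calls[testable], `[[`, numeric(1), "p_ivw")
    fdr <- bh_fdr(p, m = max(m, length(p)))
    for (i in seq_along(testable)) {
      cl <- calls[[testable[i]]]
      cl$fdr <- fdr[i]
      cl$classification <- classify_call(cl$p_ivw, cl$n_nominal_methods,
                                         cl$fdr, config)
      calls[[testable[i]]] <- cl
    }
  }
  calls
}

#' Run the MR analysis over an exposure-by-outcome matrix
#'
#' [run_pair()] over the Cartesian product of exposures and outcomes, each
#' pair on its own deterministic seed substream, followed by per-outcome
#' Benjamini-Hochberg adjustment of the IVW p-values (family size = number
#' of exposures, or `fdr_family_m` when set) and final classification.
#' Output ordering is deterministic: exposures then outcomes in the order
#' supplied.
#'
#' @param exposures List of exposure summary studies.
#' @param outcomes List of outcome summary studies (a single study may be
#'   passed directly).
#' @param panel An `mr_ld_panel`.
#' @param config An `mr_config`.
#' @return An object of class `mr_matrix`: a list of `mr_call`s with the
#'   config attached; [tidy.mr_matrix()] gives one row per pair and method.
#' @export
run_matrix <- function(exposures, outcomes, panel, config = mr_config()) {
  if (is.data.frame(exposures)) exposures <- list(exposures)
  if (is.data.frame(outcomes)) outcomes <- list(outcomes)
  calls <- list()
  k <- 0L
  for (oi in seq_along(outcomes)) {
    for (ei in seq_along(exposures)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- derive_seed(config$seed, k)
      calls[[k]] <- run_pair(exposures[[ei]], outcomes[[oi]], panel, cfg)
    }
  }
  calls <- apply_fdr(calls, config)
  structure(list(calls = calls, config = config), class = "mr_matrix")
}

#' @export
print.mr_matrix <- function(x, ...) {
  cls <- vapply(x$calls, `[[`, character(1), "classification")
  cat(sprintf("<mr_matrix> %d pair(s): %s\n", length(x$calls),
              paste(names(table(cls)), table(cls), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Bidirectional MR for one pair
#'
#' Runs the forward analysis and then the identical procedure with the
#' exposure and outcome roles swapped (instrument selection now performed on
#' the former outcome study), to probe reverse causation.
#'
#' @param exposure,outcome Summary-statistic tibbles.
#' @param panel An `mr_ld_panel`.
#' @param config An `mr_config`; the reverse pass uses the same thresholds
#'   (including the instrument p-value screen) on its own seed substream.
#' @return List with elements `forward` and `reverse`, both `mr_call`s.
#' @export
run_bidirectional <- function(exposure, outcome, panel,
                              config = mr_config()) {
  fwd <- run_pair(exposure, outcome, panel, config)
  cfg_rev <- config
  cfg_rev$seed <- derive_seed(config$seed, 999)
  rev <- run_pair(outcome, exposure, panel, cfg_rev)
  list(forward = fwd, reverse = rev)
}

#' Replication pass for a primary causal call
#'
#' Reruns the analysis on an independent replication exposure dataset and
#' judges concordance: the replication is concordant when its IVW p-value is
#' nominally significant and the estimated direction matches the primary
#' call.
#'
#' @param primary_call The discovery `mr_call`; must have reached at least
#'   the causal-candidate classification.
#' @param replication_exposure Replication exposure summary study.
#' @param outcome Outcome summary study.
#' @param panel An `mr_ld_panel`.
#' @param config An `mr_config`.
#' @return List with `call` (the replication `mr_call`) and `concordant`
#'   (logical).
#' @export
run_replication <- function(primary_call, replication_exposure, outcome,
                            panel, config = mr_config()) {
  if (!inherits(primary_call, "mr_call")) {
    abort_mr("`primary_call` must be an mr_call.", "mrflow_usage_error")
  }
  if (!(primary_call$classification %in% c("causal_candidate", "significant"))) {
    abort_mr("Replication requires a primary call of at least causal-candidate rank.",
             "mrflow_usage_error")
  }
  cfg <- config
  cfg$seed <- derive_seed(config$seed, 1001)
  rep_call <- run_pair(replication_exposure, outcome, panel, cfg)
  concordant <- !is.na(rep_call$p_ivw) &&
    rep_call$p_ivw < config$nominal_alpha &&
    !is.na(rep_call$direction) && !is.na(primary_call$direction) &&
    rep_call$direction == primary_call$direction
  list(call = rep_call, concordant = concordant)
}

format_ci <- function(beta, lo, hi) {
  sprintf("%.4g (%.4g, %.4g)", beta, lo, hi)
}

#' Write report tables for a set of calls
#'
#' Writes three tab-separated files into `dir`: `estimates.tsv` (one row per
#' pair and method: exposure, outcome, method, nSNP, beta with 95% CI,
#' p-value, joint F-statistic, heterogeneity / pleiotropy / PRESSO-global
#' p-values, FDR and classification), `scatter.tsv` (per-variant exposure
#' and outcome effects with standard errors and per-method fit lines), and
#' `leave_one_out.tsv`. Output is deterministic: rerunning with the same
#' inputs and seed reproduces the files byte for byte.
#'
#' @param x An `mr_matrix`, a list of `mr_call`s, or a single `mr_call`.
#' @param dir Output directory, created if missing.
#' @return Named character vector of the files written, invisibly.
#' @export
emit_report <- function(x, dir) {
  calls <- if (inherits(x, "mr_matrix")) x$calls
           else if (inherits(x, "mr_call")) list(x)
           else x
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_mr(sprintf("Cannot create %s", dir), "mrflow_io_error")
  }
  est_rows <- list()
  sc_rows <- list()
  loo_rows <- list()
  for (cl in calls) {
    if (is.null(cl$estimates)) next
    sens <- cl$sensitivity
    est_rows[[length(est_rows) + 1L]] <- dplyr::mutate(
      cl$estimates,
      exposure = cl$exposure_label, outcome = cl$outcome_label,
      beta_ci = format_ci(.data$beta, .data$ci_low, .data$ci_high),
      f_statistic = attr(cl$strengths, "total_f") %||% NA_real_,
      p_heterogeneity = sens$heterogeneity$p_value,
      p_pleiotropy = sens$pleiotropy$p_value,
      p_global_test = if (is.null(sens$presso)) NA_real_ else sens$presso$global_p,
      fdr = cl$fdr, classification = cl$classification,
      promising = !is.na(cl$fdr) & cl$fdr >= 0.05 & cl$fdr < 0.1,
      .before = 1
    )
    sc_rows[[length(sc_rows) + 1L]] <- dplyr::mutate(
      tibble::as_tibble(cl$instruments)[, c("variant_id", "gamma", "se_gamma",
                                            "Gamma", "se_Gamma")],
      exposure = cl$exposure_label, outcome = cl$outcome_label, .before = 1
    )
    loo_rows[[length(loo_rows) + 1L]] <- dplyr::mutate(
      sens$leave_one_out,
      exposure = cl$exposure_label, outcome = cl$outcome_label, .before = 1
    )
  }
  empty_est <- tibble::tibble(
    exposure = character(), outcome = character(), beta_ci = character(),
    f_statistic = numeric(), p_heterogeneity = numeric(),
    p_pleiotropy = numeric(), p_global_test = numeric(), fdr = numeric(),
    classification = character(), promising = logical(), method = character(),
    n_snp = integer(), beta = numeric(), se = numeric(), ci_low = numeric(),
    ci_high = numeric(), p_value = numeric(), model_notes = character()
  )
  est <- if (length(est_rows) > 0) dplyr::bind_rows(est_rows) else empty_est
  sc <- if (length(sc_rows) > 0) dplyr::bind_rows(sc_rows) else
    tibble::tibble(exposure = character(), outcome = character(),
                   variant_id = character(), gamma = numeric(),
                   se_gamma = numeric(), Gamma = numeric(),
                   se_Gamma = numeric())
  loo <- if (length(loo_rows) > 0) dplyr::bind_rows(loo_rows) else
    tibble::tibble(exposure = character(), outcome = character(),
                   left_out = character(), beta = numeric(), se = numeric(),
                   ci_low = numeric(), ci_high = numeric(),
                   p_value = numeric(), influential = logical())
  paths <- c(
    estimates = file.path(dir, "estimates.tsv"),
    scatter = file.path(dir, "scatter.tsv"),
    leave_one_out = file.path(dir, "leave_one_out.tsv")
  )
  readr::write_tsv(est, paths["estimates"], na = "NA", progress = FALSE)
  readr::write_tsv(sc, paths["scatter"], na = "NA", progress = FALSE)
  readr::write_tsv(loo, paths["leave_one_out"], na = "NA", progress = FALSE)
  invisible(paths)
}
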