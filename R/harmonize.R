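# Aligning exposure and outcome records on a shared effect allele. The
# exposure study defines the reference orientation; outcome records are
# flipped (beta negated, allele frequency complemented) when their alleles
# are reported in the opposite order, strand flips are resolved by base
# complementation, and palindromic variants (A/T, C/G) are kept only when
# both allele frequencies clearly identify the strand.

ACTION_LEVELS <- c("kept_as_is", "flipped", "dropped_palindromic",
                   "dropped_mismatch")

complement_alleles <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(ea, oa) {
  complement_alleles(ea) == oa
}

#' Align one outcome record to an exposure record's effect allele
#'
#' Core harmonization rule for a single shared variant. If the outcome's
#' effect/other alleles equal the exposure's in the same order the record is
#' kept as is; in swapped order the outcome beta is negated and its effect
#' allele frequency replaced by its complement; alleles matching only after
#' strand complementation are treated as same-order or swapped accordingly.
#' Palindromic variants (A/T or C/G pairs), for which strand cannot be
#' resolved from the alleles, are retained only when both allele frequencies
#' are available and both lie outside the ambiguity zone
#' `0.5 +/- palindrome_window`; the two frequencies then decide the flip.
#' Any other allele configuration is dropped as a mismatch.
#'
#' @param exp,out Single-row data frames (or lists) with fields
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `p_value`,
#'   `eaf` for the same variant in the exposure and outcome GWAS.
#' @param palindrome_window Half-width `w` of the allele-frequency ambiguity
#'   zone around 0.5 (default 0.08, i.e. 0.42-0.58).
#' @return One-row tibble with the harmonized instrument fields and an
#'   `action` column taking one of `kept_as_is`, `flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`.
#' @export
align_alleles <- function(exp, out, palindrome_window = 0.08) {
  if (!identical(as.character(exp$variant_id), as.character(out$variant_id))) {
    abort_mr("Exposure and outcome records refer to different variants.",
             "mrflow_usage_error")
  }
  r <- harmonize_vectors(
    exp_ea = exp$effect_allele, exp_oa = exp$other_allele,
    out_ea = out$effect_allele, out_oa = out$other_allele,
    out_beta = out$beta, out_eaf = out$eaf %||% NA_real_,
    exp_eaf = exp$eaf %||% NA_real_,
    palindrome_window = palindrome_window
  )
  tibble::tibble(
    variant_id = as.character(exp$variant_id),
    gamma = exp$beta, se_gamma = exp$se, p_exposure = exp$p_value,
    Gamma = r$Gamma, se_Gamma = out$se,
    eaf_exposure = exp$eaf %||% NA_real_, eaf_outcome = r$eaf_outcome,
    action = r$action
  )
}

# Vectorized harmonization kernel shared by align_alleles and
# harmonise_studies. Returns action plus the aligned outcome beta/eaf.
harmonize_vectors <- function(exp_ea, exp_oa, out_ea, out_oa, out_beta,
                              out_eaf, exp_eaf, palindrome_window) {
  n <- length(exp_ea)
  same <- out_ea == exp_ea & out_oa == exp_oa
  swapped <- out_ea == exp_oa & out_oa == exp_ea
  c_ea <- complement_alleles(out_ea)
  c_oa <- complement_alleles(out_oa)
  same_c <- c_ea == exp_ea & c_oa == exp_oa
  swapped_c <- c_ea == exp_oa & c_oa == exp_ea
  pal <- is_palindromic(exp_ea, exp_oa)

  action <- rep("dropped_mismatch", n)
  Gamma <- out_beta
  eaf_out <- out_eaf

  # non-palindromic: allele identity (possibly after strand complementation)
  keep_same <- !pal & (same | same_c)
  keep_flip <- !pal & !keep_same & (swapped | swapped_c)
  action[keep_same] <- "kept_as_is"
  action[keep_flip] <- "flipped"

  # palindromic: alleles alone cannot resolve strand; use the allele
  # frequencies, and only when both are far enough from 0.5
  pal_match <- pal & (same | swapped | same_c | swapped_c)
  w <- palindrome_window
  informative <- !is.na(exp_eaf) & !is.na(out_eaf) &
    abs(exp_eaf - 0.5) > w & abs(out_eaf - 0.5) > w
  pal_keep <- pal_match & informative
  concordant <- (exp_eaf < 0.5) == (out_eaf < 0.5)
  action[pal_keep & concordant] <- "kept_as_is"
  action[pal_keep & !concordant] <- "flipped"
  action[pal_match & !informative] <- "dropped_palindromic"

  flip <- action == "flipped"
  Gamma[flip] <- -out_beta[flip]
  eaf_out[flip] <- 1 - out_eaf[flip]
  list(action = action, Gamma = Gamma, eaf_outcome = eaf_out)
}

#' Harmonize an exposure and an outcome study into an instrument set
#'
#' Intersects the two studies on `variant_id`, applies [align_alleles()] to
#' every shared variant, and returns the retained instruments (actions
#' `kept_as_is` or `flipped`) ordered by chromosome, position and variant id
#' so all downstream output is deterministic. Counts of every action are
#' recorded in the `provenance` attribute; an empty intersection yields an
#' empty instrument set, not an error (the downstream minimum-instrument gate
#' handles it).
#'
#' @param exposure,outcome Summary-statistic tibbles (see [read_sumstats()]).
#' @param palindrome_window Ambiguity half-width for palindromic variants,
#'   see [align_alleles()].
#' @return A tibble of class `mr_instruments` with columns `variant_id`,
#'   `chromosome`, `position`, `gamma`, `se_gamma`, `p_exposure`, `Gamma`,
#'   `se_Gamma`, `eaf_exposure`, `eaf_outcome`, `action`, and attributes
#'   `exposure_label`, `outcome_label`, `provenance`.
#' @export
harmonise_studies <- function(exposure, outcome, palindrome_window = 0.08) {
  stop_if_not_df(exposure, "exposure")
  stop_if_not_df(outcome, "outcome")
  e <- tibble::as_tibble(exposure)
  o <- tibble::as_tibble(outcome)
  if (!("eaf" %in% names(e))) e$eaf <- NA_real_
  if (!("eaf" %in% names(o))) o$eaf <- NA_real_
  merged <- dplyr::inner_join(
    e, o,
    by = "variant_id", suffix = c("_exp", "_out")
  )
  prov <- stats::setNames(integer(length(ACTION_LEVELS)), ACTION_LEVELS)
  if (nrow(merged) == 0) {
    out <- tibble::tibble(
      variant_id = character(), chromosome = character(), position = integer(),
      gamma = numeric(), se_gamma = numeric(), p_exposure = numeric(),
      Gamma = numeric(), se_Gamma = numeric(),
      eaf_exposure = numeric(), eaf_outcome = numeric(), action = character()
    )
    return(new_instruments(out, trait_label(exposure), trait_label(outcome),
                           prov))
  }
  h <- harmonize_vectors(
    exp_ea = merged$effect_allele_exp, exp_oa = merged$other_allele_exp,
    out_ea = merged$effect_allele_out, out_oa = merged$other_allele_out,
    out_beta = merged$beta_out, out_eaf = merged$eaf_out,
    exp_eaf = merged$eaf_exp, palindrome_window = palindrome_window
  )
  tab <- table(factor(h$action, levels = ACTION_LEVELS))
  prov[names(tab)] <- as.integer(tab)
  res <- tibble::tibble(
    variant_id = merged$variant_id,
    chromosome = merged$chromosome_exp,
    position = merged$position_exp,
    gamma = merged$beta_exp, se_gamma = merged$se_exp,
    p_exposure = merged$p_value_exp,
    Gamma = h$Gamma, se_Gamma = merged$se_out,
    eaf_exposure = merged$eaf_exp, eaf_outcome = h$eaf_outcome,
    action = h$action
  )
  res <- res[res$action %in% c("kept_as_is", "flipped"), , drop = FALSE]
  res <- res[order(res$chromosome, res$position, res$variant_id), , drop = FALSE]
  new_instruments(res, trait_label(exposure), trait_label(outcome), prov)
}

new_instruments <- function(d, exposure_label, outcome_label, provenance) {
  out <- tibble::as_tibble(d)
  attr(out, "exposure_label") <- exposure_label
  attr(out, "outcome_label") <- outcome_label
  attr(out, "provenance") <- provenance
  class(out) <- c("mr_instruments", class(out))
  out
}

#' @export
print.mr_instruments <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("# Harmonized instruments: %s -> %s (%d retained; %s)\n",
              attr(x, "exposure_label") %||% "exposure",
              attr(x, "outcome_label") %||% "outcome",
              nrow(x),
              paste(names(prov), prov, sep = "=", collapse = ", ")))
  NextMethod()
}

#' Write a harmonized instrument table to TSV
#'
#' @param instruments An `mr_instruments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instruments, path) {
  cols <- c("variant_id", "gamma", "se_gamma", "p_exposure",
            "Gamma", "se_Gamma", "action")
  readr::write_tsv(tibble::as_tibble(instruments)[, cols], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}
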