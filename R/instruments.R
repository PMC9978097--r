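# Instrument selection: p-value screening, greedy LD clumping, proportion of
# variance explained (PVE), F-statistics, and the weak-instrument filter.

#' Screen a summary study at a p-value threshold
#'
#' Retains exactly the records with `p_value` strictly below `threshold`
#' (a variant sitting exactly at the threshold is excluded), preserving row
#' order. The conventional loose screen for microbiome exposures is 1e-5.
#'
#' @param study Summary-statistic tibble.
#' @param threshold Significance threshold in (0, 1].
#' @return The filtered study, same class and attributes.
#' @export
filter_by_pvalue <- function(study, threshold = 1e-5) {
  stop_if_not_df(study, "study")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort_mr("`threshold` must lie in (0, 1].", "mrflow_usage_error")
  }
  keep <- study$p_value < threshold
  out <- study[keep, , drop = FALSE]
  attr(out, "trait_label") <- trait_label(study)
  attr(out, "total_n") <- attr(study, "total_n")
  attr(out, "n_dropped") <- n_dropped(study)
  out
}

#' Greedy LD clumping of a summary study
#'
#' Repeatedly takes the unprocessed variant with the smallest p-value as an
#' index SNP and removes every other unprocessed variant on the same
#' chromosome within `window_kb` kilobases whose r2 with the index is at or
#' above `r2_threshold`. The result is the set of index SNPs: every retained
#' pair satisfies r2 below threshold or inter-variant distance beyond the
#' window. Ties in p-value are broken by (chromosome, position, variant_id)
#' ascending, so the output is independent of input row order.
#'
#' @param study Summary-statistic tibble; every record needs `chromosome` and
#'   `position`.
#' @param panel An `mr_ld_panel` (absent pairs count as r2 = 0).
#' @param r2_threshold Clumping r2 threshold in (0, 1], default 0.01.
#' @param window_kb Window half-width in kilobases around the index SNP
#'   (distance at or below the window counts as inside), default 500.
#' @return The clumped study, original row order preserved among survivors.
#' @export
ld_clump <- function(study, panel, r2_threshold = 0.01, window_kb = 500) {
  stop_if_not_df(study, "study")
  if (nrow(study) == 0) {
    return(study)
  }
  if (!inherits(panel, "mr_ld_panel")) {
    abort_mr("`panel` must be an mr_ld_panel.", "mrflow_usage_error")
  }
  if (r2_threshold <= 0 || r2_threshold > 1 || window_kb <= 0) {
    abort_mr("r2_threshold must be in (0,1] and window_kb > 0.",
             "mrflow_usage_error")
  }
  no_pos <- is.na(study$chromosome) | is.na(study$position)
  if (any(no_pos)) {
    abort_mr(sprintf("Missing position for variant(s): %s",
                     paste(study$variant_id[no_pos], collapse = ", ")),
             "mrflow_usage_error")
  }
  ord <- order(study$p_value, study$chromosome, study$position,
               study$variant_id)
  ids <- study$variant_id[ord]
  chr <- study$chromosome[ord]
  pos <- as.numeric(study$position[ord])
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, length(ids))
  index <- logical(length(ids))
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    index[i] <- TRUE
    cand <- which(alive & seq_along(ids) > i & chr == chr[i] &
                    abs(pos - pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_r2(panel, ids[i], ids[cand])
      alive[cand[r2 >= r2_threshold]] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep_ids <- ids[index]
  out <- study[study$variant_id %in% keep_ids, , drop = FALSE]
  attr(out, "trait_label") <- trait_label(study)
  attr(out, "total_n") <- attr(study, "total_n")
  out
}

#' Proportion of exposure variance explained by one variant
#'
#' Computes `2 b^2 m (1 - m) / (2 b^2 m (1 - m) + 2 se^2 n m (1 - m))` with
#' `m` the minor allele frequency, which after cancelling the common factor
#' `2 m (1 - m)` reduces to `b^2 / (b^2 + n se^2)`; the two forms agree to
#' full precision and the cancelled form is used, so PVE is computable even
#' when allele frequency is unavailable. When only the effect-allele
#' frequency is known, pass `maf = min(eaf, 1 - eaf)`.
#'
#' @param beta Per-allele effect estimate.
#' @param maf Minor allele frequency in (0, 1), or `NA` (unused by the
#'   cancelled form but validated when supplied).
#' @param se Standard error of `beta`, > 0.
#' @param n Sample size, > 0.
#' @return PVE in \[0, 1).
#' @export
pve_single <- function(beta, maf = NA_real_, se, n) {
  if (any(!is.na(maf) & (maf <= 0 | maf >= 1))) {
    abort_mr("`maf` must lie strictly between 0 and 1.", "mrflow_domain_error")
  }
  if (any(se <= 0) || any(n <= 0)) {
    abort_mr("`se` and `n` must be positive.", "mrflow_domain_error")
  }
  beta^2 / (beta^2 + n * se^2)
}

#' F-statistic of instrument strength from PVE
#'
#' Default (standard) form `F = [PVE / (1 - PVE)] * (n - k - 1) / k` for `k`
#' instruments explaining `pve` jointly in a sample of size `n`. The
#' `literal` form omits the division by `k`; the two coincide at `k = 1`,
#' the per-variant case the weak-instrument filter uses.
#'
#' @param pve Proportion of variance explained, in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments, default 1.
#' @param form `"standard"` (divide by k) or `"literal"`.
#' @return F value, >= 0.
#' @export
f_statistic <- function(pve, n, k = 1, form = c("standard", "literal")) {
  form <- match.arg(form)
  if (any(pve < 0 | pve >= 1)) {
    abort_mr("`pve` must lie in [0, 1).", "mrflow_domain_error")
  }
  if (any(n <= k + 1)) {
    abort_mr("`n` must exceed k + 1.", "mrflow_domain_error")
  }
  base <- pve / (1 - pve) * (n - k - 1)
  if (form == "standard") base / k else base
}

#' Per-variant and joint instrument strength
#'
#' Computes per-variant PVE and F (k = 1), and the joint strength of the set:
#' total PVE is the sum of per-variant PVEs and the joint F uses `k` equal to
#' the instrument count. Per-variant sample size is used when present,
#' falling back to the study-wide `n`.
#'
#' @param instruments An `mr_instruments` tibble (columns `gamma`,
#'   `se_gamma`) or any data frame with `beta`/`se` columns.
#' @param n Fallback sample size when per-variant `n` is absent.
#' @param form F-statistic form, see [f_statistic()].
#' @return A tibble with one row per variant (`variant_id`, `pve`,
#'   `f_stat`, `n_used`) and attributes `total_pve`, `total_f`, `k`.
#' @export
instrument_strength <- function(instruments, n = NULL,
                                form = c("standard", "literal")) {
  form <- match.arg(form)
  stop_if_not_df(instruments, "instruments")
  beta <- instruments$gamma %||% instruments$beta
  se <- instruments$se_gamma %||% instruments$se
  n_var <- instruments$n %||% rep(NA_real_, nrow(instruments))
  n_used <- ifelse(is.na(n_var), n %||% NA_real_, n_var)
  if (any(is.na(n_used))) {
    abort_mr("Sample size unavailable: supply per-variant `n` or the `n` argument.",
             "mrflow_usage_error")
  }
  pve <- pve_single(beta, se = se, n = n_used)
  f <- f_statistic(pve, n_used, k = 1)
  k <- nrow(instruments)
  out <- tibble::tibble(
    variant_id = instruments$variant_id, pve = pve, f_stat = f, n_used = n_used
  )
  attr(out, "total_pve") <- sum(pve)
  attr(out, "k") <- k
  n_joint <- max(n_used)
  attr(out, "total_f") <- if (k >= 1 && sum(pve) < 1 && n_joint > k + 1) {
    f_statistic(min(sum(pve), 1 - 1e-12), n_joint, k = k, form = form)
  } else {
    NA_real_
  }
  out
}

#' Exclude weak instruments by per-variant F-statistic
#'
#' Retains instruments whose per-variant F is at or above `f_min` (default
#' 10, the conventional weak-instrument bound) and updates the provenance
#' counts.
#'
#' @param instruments An `mr_instruments` tibble.
#' @param strengths Output of [instrument_strength()] on the same
#'   instruments.
#' @param f_min Minimum per-variant F.
#' @return The filtered `mr_instruments` tibble; a `dropped_weak` entry is
#'   added to the provenance attribute.
#' @export
drop_weak <- function(instruments, strengths, f_min = 10) {
  stop_if_not_df(instruments, "instruments")
  stop_if_not_df(strengths, "strengths")
  if (!identical(instruments$variant_id, strengths$variant_id)) {
    abort_mr("`strengths` must be computed on the same instruments.",
             "mrflow_usage_error")
  }
  keep <- strengths$f_stat >= f_min
  out <- instruments[keep, , drop = FALSE]
  prov <- attr(instruments, "provenance") %||%
    stats::setNames(integer(length(ACTION_LEVELS)), ACTION_LEVELS)
  prov["dropped_weak"] <- sum(!keep)
  new_instruments(out, attr(instruments, "exposure_label"),
                  attr(instruments, "outcome_label"), prov)
}
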