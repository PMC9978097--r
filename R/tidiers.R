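# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-method estimates of an MR call
#'
#' One row per estimator with the causal estimate, standard error, 95%
#' confidence bounds and p-value, plus the pair labels. A `not_testable`
#' call yields zero rows.
#'
#' @param x An `mr_call` from [run_pair()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_call <- function(x, ...) {
  if (is.null(x$estimates)) {
    return(tibble::tibble(
      exposure = character(), outcome = character(), method = character(),
      n_snp = integer(), beta = numeric(), se = numeric(),
      ci_low = numeric(), ci_high = numeric(), p_value = numeric()
    ))
  }
  dplyr::mutate(
    x$estimates[, c("method", "n_snp", "beta", "se", "ci_low", "ci_high",
                    "p_value")],
    exposure = x$exposure_label, outcome = x$outcome_label, .before = 1
  )
}

#' One-row summary of an MR call
#'
#' The pair labels, instrument counts, IVW p-value, number of nominally
#' significant methods, sensitivity p-values, FDR, classification and
#' direction.
#'
#' @param x An `mr_call`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mr_call <- function(x, ...) {
  sens <- x$sensitivity
  tibble::tibble(
    exposure = x$exposure_label, outcome = x$outcome_label,
    n_iv_initial = x$n_iv_initial, n_iv_final = x$n_iv_final,
    p_ivw = x$p_ivw,
    ivw_model = if (is.null(sens)) NA_character_ else sens$ivw_model,
    n_nominal_methods = x$n_nominal_methods,
    p_heterogeneity = if (is.null(sens)) NA_real_ else sens$heterogeneity$p_value,
    p_pleiotropy = if (is.null(sens)) NA_real_ else sens$pleiotropy$p_value,
    egger_rule_pass = if (is.null(sens)) NA else sens$egger_rule_pass,
    p_presso_global = if (is.null(sens) || is.null(sens$presso)) NA_real_
                      else sens$presso$global_p,
    n_outliers_removed = length(x$outliers_removed),
    fdr = x$fdr, direction = x$direction,
    classification = x$classification
  )
}

#' @rdname tidy.mr_call
#' @export
tidy.mr_matrix <- function(x, ...) {
  dplyr::bind_rows(lapply(x$calls, tidy.mr_call))
}

#' @rdname glance.mr_call
#' @export
glance.mr_matrix <- function(x, ...) {
  dplyr::bind_rows(lapply(x$calls, glance.mr_call))
}
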