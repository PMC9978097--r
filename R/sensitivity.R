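# Sensitivity machinery: Cochran's Q heterogeneity, the Egger-intercept
# pleiotropy rule, MR-PRESSO (global / outlier / distortion), leave-one-out
# re-estimation, and Benjamini-Hochberg FDR adjustment with an explicit
# family size.

#' Cochran's Q heterogeneity test across instruments
#'
#' `Q = sum w_j (ratio_j - beta_IVW_fixed)^2` with the inverse-variance
#' weights of the Wald ratios; the p-value is the upper tail of chi-square
#' with J - 1 degrees of freedom. Excess heterogeneity (p below the chosen
#' alpha) is the conventional trigger for the random-effects IVW model.
#'
#' @param instruments Harmonized instrument tibble; at least 2 instruments.
#' @return Tibble with `q`, `df`, `p_value`.
#' @export
cochran_q <- function(instruments) {
  check_instruments(instruments, 2, "cochran_q")
  wald_ratios(instruments)
  k <- ivw_kernel(instruments$gamma, instruments$se_gamma,
                  instruments$Gamma, instruments$se_Gamma)
  tibble::tibble(
    q = k$q, df = k$df,
    p_value = stats::pchisq(k$q, df = k$df, lower.tail = FALSE)
  )
}

#' Egger-intercept pleiotropy verdict
#'
#' Horizontal pleiotropy is judged ignorable when the absolute intercept is
#' below `abs_threshold` and its p-value exceeds `p_threshold` (defaults 0.1
#' and 0.05).
#'
#' @param pleiotropy Tibble from [mr_egger()]'s `pleiotropy` element
#'   (columns `intercept`, `se`, `p_value`).
#' @param abs_threshold Maximum tolerated absolute intercept.
#' @param p_threshold Minimum p-value for "no detectable pleiotropy".
#' @return `TRUE` (pass: no remarkable pleiotropy) or `FALSE`.
#' @export
egger_intercept_rule <- function(pleiotropy, abs_threshold = 0.1,
                                 p_threshold = 0.05) {
  abs(pleiotropy$intercept) < abs_threshold & pleiotropy$p_value > p_threshold
}

# Leave-one-out IVW slopes for all j at once, from running sums.
loo_slopes <- function(g, G, w) {
  s1 <- sum(w * g * G)
  s2 <- sum(w * g^2)
  (s1 - w * g * G) / (s2 - w * g^2)
}

#' MR-PRESSO residual-based pleiotropy test
#'
#' For each instrument j the IVW slope is refitted without j and the
#' observed weighted residual `RSS_j = w_j (Gamma_j - b_(-j) gamma_j)^2`
#' recorded (regression weights `w_j = 1/se_Gamma_j^2`); their sum is the
#' global observed residual sum of squares. A parametric null distribution
#' is built from `n_sim` simulated datasets in which each exposure effect is
#' drawn about its observed value and each outcome effect about its
#' leave-one-out fitted value, with the observed standard errors. The global
#' test compares the observed global RSS to its simulated distribution; the
#' outlier test compares each `RSS_j` to its own simulated values with
#' Bonferroni correction across instruments. When outliers are flagged, a
#' distortion p-value compares the change in the IVW estimate after outlier
#' removal against removals of equally many randomly chosen instruments.
#'
#' @param instruments Harmonized instrument tibble; at least 4 instruments.
#' @param n_sim Number of simulated null datasets (>= 200), default 1000.
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-variant outlier test, default 0.05.
#' @param seed Integer seed; identical data and seed give identical results.
#' @return A list of class `mr_presso` with elements `global_rss`,
#'   `global_p`, `outlier` (tibble `variant_id`, `rss`, `p_raw`, `p_adj`),
#'   `outliers` (flagged variant ids), and `distortion_p` (`NA` when no
#'   outlier is flagged).
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1L) {
  check_instruments(instruments, 4, "mr_presso")
  if (n_sim < 200) {
    abort_mr("`n_sim` must be at least 200.", "mrflow_usage_error")
  }
  g <- instruments$gamma
  sg <- instruments$se_gamma
  G <- instruments$Gamma
  sG <- instruments$se_Gamma
  j <- length(g)
  w <- 1 / sG^2
  b_loo <- loo_slopes(g, G, w)
  rss_obs <- w * (G - b_loo * g)^2
  global_obs <- sum(rss_obs)

  sims <- with_seed(seed, {
    gs <- matrix(stats::rnorm(n_sim * j, mean = rep(g, each = n_sim),
                              sd = rep(sg, each = n_sim)), nrow = n_sim)
    Gs <- matrix(stats::rnorm(n_sim * j, mean = rep(b_loo * g, each = n_sim),
                              sd = rep(sG, each = n_sim)), nrow = n_sim)
    wm <- matrix(w, nrow = n_sim, ncol = j, byrow = TRUE)
    s1 <- rowSums(wm * gs * Gs)
    s2 <- rowSums(wm * gs^2)
    b_loo_sim <- (s1 - wm * gs * Gs) / (s2 - wm * gs^2)
    rss_sim <- wm * (Gs - b_loo_sim * gs)^2
    list(rss = rss_sim, global = rowSums(rss_sim))
  })
  global_p <- (1 + sum(sims$global >= global_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(sims$rss >= matrix(rss_obs, nrow = n_sim, ncol = j,
                                           byrow = TRUE))) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  out_ids <- instruments$variant_id[p_adj < outlier_alpha]

  distortion_p <- NA_real_
  if (length(out_ids) > 0 && length(out_ids) < j - 1) {
    keep <- !(instruments$variant_id %in% out_ids)
    b_all <- ivw_kernel(g, sg, G, sG)$beta
    b_out <- ivw_kernel(g[keep], sg[keep], G[keep], sG[keep])$beta
    d_obs <- (b_out - b_all) / abs(b_all)
    n_rem <- length(out_ids)
    d_null <- with_seed(derive_seed(seed, 7), {
      vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(j, n_rem)
        kp <- setdiff(seq_len(j), drop_idx)
        b_s <- ivw_kernel(g[kp], sg[kp], G[kp], sG[kp])$beta
        (b_s - b_all) / abs(b_all)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(
    list(
      global_rss = global_obs, global_p = global_p,
      outlier = tibble::tibble(
        variant_id = instruments$variant_id, rss = rss_obs,
        p_raw = p_raw, p_adj = p_adj
      ),
      outliers = out_ids, distortion_p = distortion_p,
      n_sim = n_sim
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.4g, %d outlier(s)%s\n",
              x$global_rss, x$global_p, length(x$outliers),
              if (is.na(x$distortion_p)) "" else
                sprintf(", distortion p = %.4g", x$distortion_p)))
  invisible(x)
}

#' Leave-one-out re-estimation
#'
#' Refits the IVW estimator with each instrument removed in turn, plus the
#' all-instrument row, to expose single variants that dominate the causal
#' estimate. A row is flagged influential when its confidence interval no
#' longer covers the sign of the all-instrument estimate (flag only; nothing
#' is removed automatically).
#'
#' @param instruments Harmonized instrument tibble; at least 3 instruments.
#' @param model IVW model for every refit, `"fixed"` or `"random"`.
#' @return Tibble with J + 1 rows: `left_out` (variant id or `"(none)"`),
#'   `beta`, `se`, `ci_low`, `ci_high`, `p_value`, `influential`.
#' @export
leave_one_out <- function(instruments, model = c("fixed", "random")) {
  model <- match.arg(model)
  check_instruments(instruments, 3, "leave_one_out")
  j <- nrow(instruments)
  fit_row <- function(idx) {
    k <- ivw_kernel(instruments$gamma[idx], instruments$se_gamma[idx],
                    instruments$Gamma[idx], instruments$se_Gamma[idx], model)
    tibble::tibble(beta = k$beta, se = k$se,
                   ci_low = k$beta - Z_CRIT_95 * k$se,
                   ci_high = k$beta + Z_CRIT_95 * k$se,
                   p_value = p_from_z(k$beta / k$se))
  }
  rows <- purrr::map_dfr(seq_len(j), function(i) fit_row(setdiff(seq_len(j), i)))
  all_row <- fit_row(seq_len(j))
  out <- dplyr::bind_rows(
    dplyr::mutate(rows, left_out = instruments$variant_id, .before = 1),
    dplyr::mutate(all_row, left_out = "(none)", .before = 1)
  )
  # influential when the leave-one-out CI excludes the all-SNP estimate's sign
  sign_all <- sign(all_row$beta)
  out$influential <- out$left_out != "(none)" &
    ((sign_all >= 0 & out$ci_high < 0) | (sign_all <= 0 & out$ci_low > 0))
  out
}

#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Step-up FDR adjustment in which the family size `m` may exceed the number
#' of supplied p-values (tests not supplied are treated as rank fillers with
#' p = 1, which is exactly what adjusting with total count `m` does).
#' Adjusted values are capped at 1 and returned in input order.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param m Family size; at least `length(p_values)`. Defaults to the count
#'   supplied.
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort_mr("All p-values must lie in (0, 1].", "mrflow_usage_error")
  }
  if (m < length(p_values)) {
    abort_mr("`m` must be at least the number of p-values supplied.",
             "mrflow_usage_error")
  }
  stats::p.adjust(p_values, method = "BH", n = m)
}
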