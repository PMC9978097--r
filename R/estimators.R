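# The five causal estimators: inverse-variance weighted (fixed / random
# multiplicative), maximum likelihood, MR-Egger, weighted median, weighted
# mode. Each maps a harmonized instrument table to a one-row estimate tibble
# (method, n_snp, beta, se, ci_low, ci_high, p_value).
#
# Numeric kernels operate on bare vectors (gamma, se_gamma, Gamma, se_Gamma)
# so simulation loops avoid per-call data-frame overhead; the exported
# functions are thin tidy wrappers over them.

mr_methods_all <- c("ivw", "maximum_likelihood", "mr_egger",
                    "weighted_median", "weighted_mode")

check_instruments <- function(instruments, min_n, caller) {
  stop_if_not_df(instruments, "instruments")
  need <- c("gamma", "se_gamma", "Gamma", "se_Gamma")
  miss <- setdiff(need, names(instruments))
  if (length(miss) > 0) {
    abort_mr(sprintf("%s: missing column(s) %s", caller,
                     paste(miss, collapse = ", ")), "mrflow_usage_error")
  }
  if (nrow(instruments) < min_n) {
    abort_mr(sprintf("%s requires at least %d instruments (got %d).",
                     caller, min_n, nrow(instruments)), "mrflow_usage_error")
  }
  invisible(instruments)
}

estimate_row <- function(method, n_snp, beta, se, p_value = NULL, df = Inf,
                         model_notes = NA_character_) {
  if (is.null(p_value)) {
    p_value <- if (is.finite(df)) p_from_t(beta / se, df) else p_from_z(beta / se)
  }
  tibble::tibble(
    method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
    ci_low = beta - Z_CRIT_95 * se, ci_high = beta + Z_CRIT_95 * se,
    p_value = p_value, model_notes = model_notes
  )
}

#' Per-variant Wald ratio estimates
#'
#' The per-variant causal estimate is the ratio of the outcome effect to the
#' exposure effect; its standard error uses the first-order delta method
#' (outcome error only), `se_Gamma / |gamma|`, and the inverse-variance
#' weight is the reciprocal squared standard error.
#'
#' @param instruments Harmonized instrument tibble (columns `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma`).
#' @return Tibble with `variant_id`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratios <- function(instruments) {
  check_instruments(instruments, 1, "wald_ratios")
  zero <- instruments$gamma == 0
  if (any(zero)) {
    abort_mr(sprintf("Zero exposure effect for variant(s): %s",
                     paste(instruments$variant_id[zero], collapse = ", ")),
             "mrflow_domain_error")
  }
  se_ratio <- instruments$se_Gamma / abs(instruments$gamma)
  tibble::tibble(
    variant_id = instruments$variant_id %||% as.character(seq_len(nrow(instruments))),
    ratio = instruments$Gamma / instruments$gamma,
    se_ratio = se_ratio,
    weight = se_ratio^-2
  )
}

# ---- kernels ---------------------------------------------------------------

ivw_kernel <- function(g, sg, G, sG, model = "fixed") {
  r <- G / g
  w <- g^2 / sG^2
  sw <- sum(w)
  beta <- sum(w * r) / sw
  se_fixed <- sqrt(1 / sw)
  q <- sum(w * (r - beta)^2)
  j <- length(g)
  scale <- if (model == "random" && j > 1) max(1, sqrt(q / (j - 1))) else 1
  list(beta = beta, se = se_fixed * scale, q = q, df = j - 1, scale = scale)
}

# Profile -2 log likelihood of the bivariate normal measurement model:
# gamma_hat_j ~ N(gamma_j, sg^2), Gamma_hat_j ~ N(b * gamma_j, sG^2).
# Profiling the nuisance gamma_j analytically collapses it to a weighted
# residual sum with b-dependent variances.
ml_objective <- function(b, g, sg, G, sG) {
  sum((G - b * g)^2 / (sG^2 + b^2 * sg^2))
}

ml_kernel <- function(g, sg, G, sG) {
  ivw <- ivw_kernel(g, sg, G, sG)
  width <- max(50 * ivw$se, 1e-3, abs(ivw$beta))
  opt <- stats::optimize(ml_objective, interval = ivw$beta + c(-1, 1) * width,
                         g = g, sg = sg, G = G, sG = sG, tol = 1e-10)
  b <- opt$minimum
  # widen once if the optimum hit the bracket edge
  if (min(abs(b - (ivw$beta + c(-1, 1) * width))) < 1e-6 * width) {
    opt <- stats::optimize(ml_objective,
                           interval = ivw$beta + c(-1, 1) * 20 * width,
                           g = g, sg = sg, G = G, sG = sG, tol = 1e-10)
    b <- opt$minimum
  }
  # observed information from the profile curvature; -2logL = objective
  h <- max(1e-6, 1e-4 * abs(b))
  f0 <- ml_objective(b, g, sg, G, sG)
  fp <- ml_objective(b + h, g, sg, G, sG)
  fm <- ml_objective(b - h, g, sg, G, sG)
  d2 <- (fp - 2 * f0 + fm) / h^2
  if (!is.finite(d2) || d2 <= 0) {
    abort_mr("Maximum-likelihood estimation failed: non-positive curvature.",
             "mrflow_estimation_error",
             diagnostics = list(beta = b, curvature = d2))
  }
  list(beta = b, se = sqrt(2 / d2))
}

# Weighted least squares of G on g with intercept, weights 1/sG^2,
# instruments oriented so every g > 0. Residual dispersion is estimated
# (multiplicative error model) and inference is on t with J - 2 df.
egger_kernel <- function(g, sg, G, sG) {
  flip <- g < 0
  g[flip] <- -g[flip]
  G[flip] <- -G[flip]
  w <- 1 / sG^2
  j <- length(g)
  sw <- sum(w)
  xbar <- sum(w * g) / sw
  ybar <- sum(w * G) / sw
  sxx <- sum(w * (g - xbar)^2)
  sxy <- sum(w * (g - xbar) * (G - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  resid <- G - intercept - slope * g
  sigma2 <- sum(w * resid^2) / (j - 2)
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / sw + xbar^2 / sxx))
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_int,
       sigma2 = sigma2, df = j - 2)
}

weighted_median_kernel <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  if (s[1] >= 0.5) {
    return(r[1])
  }
  if (s[length(s)] <= 0.5) {
    return(r[length(r)])
  }
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# Silverman-type bandwidth on the ratio estimates; mad() is already scaled
# to be consistent for the normal (constant 1.4826 = 1/0.6745). A zero
# robust spread with positive sd falls back to the sd term.
mode_bandwidth <- function(r, bandwidth_factor) {
  j <- length(r)
  s1 <- stats::sd(r)
  s2 <- stats::mad(r)
  s <- if (s2 > 0) min(s1, s2) else s1
  bandwidth_factor * 0.9 * s * j^(-1 / 5)
}

weighted_mode_kernel <- function(r, w, bandwidth_factor = 1,
                                 grid_n = 10000) {
  p <- w / sum(w)
  h <- mode_bandwidth(r, bandwidth_factor)
  if (!is.finite(h) || h <= 0) {
    return(r[1]) # all ratios identical
  }
  lo <- min(r) - 3 * h
  hi <- max(r) + 3 * h
  grid <- seq(lo, hi, length.out = grid_n)
  # weighted Gaussian kernel density evaluated on the grid
  dens <- colSums(p * matrix(stats::dnorm(outer(r, grid, "-") / h),
                             nrow = length(r)))
  grid[which.max(dens)]
}

# Parametric bootstrap SE shared by the median and mode estimators: resample
# gamma_hat and Gamma_hat from their sampling normals, recompute ratios,
# weights and the point estimate.
bootstrap_se <- function(g, sg, G, sG, n_boot, seed, point_fun) {
  j <- length(g)
  # canonical orientation (gamma > 0) keeps the resampling invariant to
  # which allele each study called "effect"
  s <- sign(g)
  g <- abs(g)
  G <- s * G
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      gs <- stats::rnorm(j, g, sg)
      Gs <- stats::rnorm(j, G, sG)
      bad <- gs == 0
      if (any(bad)) gs[bad] <- .Machine$double.eps
      point_fun(Gs / gs, gs^2 / sG^2)
    }, numeric(1))
    stats::sd(est)
  })
}

# ---- exported estimators ---------------------------------------------------

#' Inverse-variance weighted causal estimate
#'
#' Combines the per-variant Wald ratios by inverse-variance meta-analysis:
#' the estimate is the weighted mean of the ratios, identically the weighted
#' least-squares slope of the outcome effects on the exposure effects through
#' the origin with weights `1/se_Gamma^2`. The fixed-effects standard error
#' is `(sum w)^(-1/2)`; the random-effects model scales it multiplicatively
#' by `max(1, sqrt(Q/(J-1)))` with Q Cochran's heterogeneity statistic.
#' Two-sided p-values use the standard normal reference.
#'
#' @param instruments Harmonized instrument tibble.
#' @param model `"fixed"` or `"random"`.
#' @return One-row estimate tibble (`method`, `n_snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `model_notes`).
#' @export
mr_ivw <- function(instruments, model = c("fixed", "random")) {
  model <- match.arg(model)
  check_instruments(instruments, 2, "mr_ivw")
  wald_ratios(instruments) # validates gamma != 0
  k <- ivw_kernel(instruments$gamma, instruments$se_gamma,
                  instruments$Gamma, instruments$se_Gamma, model)
  estimate_row(paste0("ivw_", model), nrow(instruments), k$beta, k$se,
               model_notes = sprintf("Q=%.6g; scale=%.6g", k$q, k$scale))
}

#' Maximum-likelihood causal estimate
#'
#' Maximizes the joint Gaussian likelihood in which each observed exposure
#' effect is normal about its true value and each observed outcome effect is
#' normal about `beta` times that true value; the per-variant true effects
#' are profiled out analytically, leaving a one-dimensional objective
#' minimized to 1e-10 from the IVW start point. The standard error comes
#' from the observed information (profile curvature); inference is normal.
#' Unlike IVW, the likelihood accounts for sampling error in the exposure
#' effects.
#'
#' @param instruments Harmonized instrument tibble.
#' @return One-row estimate tibble.
#' @export
mr_maximum_likelihood <- function(instruments) {
  check_instruments(instruments, 2, "mr_maximum_likelihood")
  wald_ratios(instruments)
  k <- ml_kernel(instruments$gamma, instruments$se_gamma,
                 instruments$Gamma, instruments$se_Gamma)
  estimate_row("maximum_likelihood", nrow(instruments), k$beta, k$se)
}

#' MR-Egger regression: causal slope and pleiotropy intercept
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept (weights `1/se_Gamma^2`), after orienting every
#' instrument so its exposure effect is positive. The slope is the causal
#' estimate, consistent under the InSIDE assumption even with directional
#' pleiotropy; the intercept estimates the average pleiotropic effect.
#' Residual dispersion is estimated (multiplicative error model) and both
#' coefficients are tested on Student-t with J - 2 degrees of freedom.
#'
#' @param instruments Harmonized instrument tibble; at least 3 instruments.
#' @return A list with `estimate` (one-row estimate tibble for the slope)
#'   and `pleiotropy` (tibble `intercept`, `se`, `p_value`).
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 3, "mr_egger")
  k <- egger_kernel(instruments$gamma, instruments$se_gamma,
                    instruments$Gamma, instruments$se_Gamma)
  est <- estimate_row("mr_egger", nrow(instruments), k$slope, k$se_slope,
                      df = k$df,
                      model_notes = sprintf("sigma2=%.6g", k$sigma2))
  pleio <- tibble::tibble(
    intercept = k$intercept, se = k$se_intercept,
    p_value = if (k$se_intercept > 0) {
      p_from_t(k$intercept / k$se_intercept, k$df)
    } else if (k$intercept == 0) 1 else .Machine$double.xmin
  )
  list(estimate = est, pleiotropy = pleio)
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted,
#' normalized inverse-variance weights accumulated, and the estimate read by
#' linear interpolation at cumulative weight one half. Consistent when at
#' least half the weight comes from valid instruments. The standard error is
#' the standard deviation of the estimator over `n_boot` parametric
#' bootstrap resamples of the summary statistics; inference is normal.
#'
#' @param instruments Harmonized instrument tibble; at least 3 instruments.
#' @param n_boot Bootstrap replicates (>= 100), default 1000.
#' @param seed Integer seed for the bootstrap; results are reproducible
#'   bit-for-bit given the seed.
#' @return One-row estimate tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1L) {
  check_instruments(instruments, 3, "mr_weighted_median")
  if (n_boot < 100) {
    abort_mr("`n_boot` must be at least 100.", "mrflow_usage_error")
  }
  wr <- wald_ratios(instruments)
  beta <- weighted_median_kernel(wr$ratio, wr$weight)
  se <- bootstrap_se(instruments$gamma, instruments$se_gamma,
                     instruments$Gamma, instruments$se_Gamma,
                     n_boot, seed, weighted_median_kernel)
  estimate_row("weighted_median", nrow(instruments), beta, se,
               model_notes = sprintf("n_boot=%d", n_boot))
}

#' Weighted mode causal estimate
#'
#' Clusters the per-variant Wald ratios implicitly through a weighted
#' Gaussian kernel density (Silverman-type bandwidth
#' `0.9 min(sd, mad) J^(-1/5)` scaled by `bandwidth_factor`) and takes the
#' density argmax, located on a fine fixed grid spanning the ratio range, as
#' the causal estimate. Consistent when the largest cluster of instruments
#' is valid, regardless of how much weight invalid instruments carry.
#' Standard error by the same parametric bootstrap as the weighted median.
#' If all ratios coincide the estimate is that common ratio.
#'
#' @param instruments Harmonized instrument tibble; at least 3 instruments.
#' @param bandwidth_factor Positive multiplier on the Silverman bandwidth.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed for the bootstrap.
#' @param grid_n Number of grid points for the density argmax, default 10000.
#' @return One-row estimate tibble.
#' @export
mr_weighted_mode <- function(instruments, bandwidth_factor = 1,
                             n_boot = 1000, seed = 1L, grid_n = 10000) {
  check_instruments(instruments, 3, "mr_weighted_mode")
  if (bandwidth_factor <= 0) {
    abort_mr("`bandwidth_factor` must be positive.", "mrflow_usage_error")
  }
  wr <- wald_ratios(instruments)
  beta <- weighted_mode_kernel(wr$ratio, wr$weight, bandwidth_factor, grid_n)
  se <- bootstrap_se(
    instruments$gamma, instruments$se_gamma,
    instruments$Gamma, instruments$se_Gamma, n_boot, seed,
    function(r, w) weighted_mode_kernel(r, w, bandwidth_factor, grid_n)
  )
  estimate_row("weighted_mode", nrow(instruments), beta, se,
               model_notes = sprintf("n_boot=%d; bw_factor=%g", n_boot,
                                     bandwidth_factor))
}

#' Run a panel of causal estimators on one instrument set
#'
#' Convenience wrapper running the requested estimators and binding their
#' one-row results into a single tidy table. The IVW model (fixed or random)
#' is chosen by the caller, typically from the heterogeneity test via
#' [choose_ivw_model()].
#'
#' @param instruments Harmonized instrument tibble.
#' @param methods Character vector among `ivw`, `maximum_likelihood`,
#'   `mr_egger`, `weighted_median`, `weighted_mode`.
#' @param ivw_model `"fixed"` or `"random"`.
#' @param n_boot Bootstrap replicates for the median/mode estimators.
#' @param seed Master seed; each bootstrap draws from its own derived
#'   substream.
#' @param grid_n Density grid size for the weighted mode.
#' @return Estimate tibble with one row per method.
#' @export
mr_estimate <- function(instruments, methods = mr_methods_all,
                        ivw_model = c("fixed", "random"),
                        n_boot = 1000, seed = 1L, grid_n = 10000) {
  ivw_model <- match.arg(ivw_model)
  bad <- setdiff(methods, mr_methods_all)
  if (length(bad) > 0) {
    abort_mr(sprintf("Unknown method(s): %s", paste(bad, collapse = ", ")),
             "mrflow_usage_error")
  }
  rows <- list()
  for (m in methods) {
    rows[[m]] <- switch(m,
      ivw = mr_ivw(instruments, ivw_model),
      maximum_likelihood = mr_maximum_likelihood(instruments),
      mr_egger = mr_egger(instruments)$estimate,
      weighted_median = mr_weighted_median(instruments, n_boot,
                                           derive_seed(seed, 1)),
      weighted_mode = mr_weighted_mode(instruments, 1, n_boot,
                                       derive_seed(seed, 2), grid_n = grid_n)
    )
  }
  dplyr::bind_rows(rows)
}
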