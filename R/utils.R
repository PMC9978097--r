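# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform .data
#' @importFrom stats pnorm pt pchisq qnorm optimize dnorm mad sd rnorm runif
#'   p.adjust setNames weighted.mean lm coef
#' @importFrom utils head
NULL

# 95% normal critical value fixed so tabular output is reproducible digit
# for digit across platforms.
Z_CRIT_95 <- 1.959964

abort_mr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "mrflow_error"), ...)
}

stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort_mr(sprintf("`%s` must be a data frame.", arg), "mrflow_usage_error")
  }
}

# Deterministic substream seeds: all randomness flows from one master seed so
# any single component (a bootstrap, a simulated taxon) is independently
# reproducible. Keeps derived seeds strictly below 2^31.
derive_seed <- function(master, index) {
  master <- as.double(master)
  s <- (master * 48271 + 104729 * as.double(index)) %% 2147483629
  as.integer(s) + 1L
}

# Run `expr` with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Two-sided p from a z statistic, clamped into (0, 1] so downstream logs and
# BH adjustment never see an exact zero.
p_from_z <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

p_from_t <- function(t, df) {
  p <- 2 * stats::pt(-abs(t), df = df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}
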