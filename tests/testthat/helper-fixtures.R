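# Fixtures and independent oracles used across the suite.

# Bare instrument table for estimator tests.
make_instruments <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                             se_Gamma = rep(0.01, length(gamma))) {
  tibble::tibble(
    variant_id = paste0("v", seq_along(gamma)),
    gamma = gamma, se_gamma = se_gamma, Gamma = Gamma, se_Gamma = se_Gamma
  )
}

# Random instrument table drawn from the clean generative model.
random_instruments <- function(j = 10, beta = 0.1, seed = 1,
                               n_exp = 50000, n_out = 50000) {
  pair <- mrflow::simulate_pair(mrflow::scenario_truth(
    beta_causal = beta, j = j, n_exposure = n_exp, n_outcome = n_out,
    seed = seed
  ))
  mrflow::harmonise_studies(pair$exposure, pair$outcome)
}

# Minimal summary study tibble with all canonical columns.
make_study <- function(n_var = 5, p = NULL, chrom = "1",
                       pos = NULL, ids = NULL, beta = NULL, se = NULL,
                       eaf = NULL, n = 10000L, label = "study") {
  ids <- ids %||% paste0("s", seq_len(n_var))
  d <- tibble::tibble(
    variant_id = ids,
    chromosome = rep_len(chrom, n_var),
    position = as.integer(pos %||% (seq_len(n_var) * 1000L)),
    effect_allele = rep_len("A", n_var),
    other_allele = rep_len("G", n_var),
    beta = beta %||% rep(0.1, n_var),
    se = se %||% rep(0.01, n_var),
    p_value = p %||% rep(1e-8, n_var),
    eaf = eaf %||% rep(0.3, n_var),
    n = rep_len(as.integer(n), n_var)
  )
  attr(d, "trait_label") <- label
  attr(d, "total_n") <- as.integer(max(n))
  class(d) <- c("mr_sumstats", class(d))
  d
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Panel built directly from a pair table (bypasses file I/O).
make_panel <- function(a, b, r2, positions = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(variant_id_a = a, variant_id_b = b, r2 = r2),
                   tmp, progress = FALSE)
  pos_path <- NULL
  if (!is.null(positions)) {
    pos_path <- tempfile(fileext = ".tsv")
    readr::write_tsv(positions, pos_path, progress = FALSE)
  }
  on.exit(unlink(c(tmp, pos_path)))
  mrflow::read_ld_panel(tmp, pos_path)
}

# Independent Benjamini-Hochberg step-up oracle, written directly from the
# step-up definition (sort ascending, q_r = min over r' >= r of p_(r') m / r',
# cap at 1, map back to input order).
bh_oracle <- function(p, m) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- numeric(k)
  for (r in seq_len(k)) {
    cand <- ps[r:k] * m / (r:k)
    q[r] <- min(1, cand)
  }
  # enforce monotonicity via the running minimum from the right
  for (r in rev(seq_len(k - 1))) q[r] <- min(q[r], q[r + 1])
  out <- numeric(k)
  out[ord] <- q
  out
}

# Brute-force clumping oracle: a direct, unoptimized transcription of the
# greedy recursion (smallest p as index, discard in-window correlated
# variants, recurse on the rest). Used on tiny instances only.
clump_oracle <- function(study, panel, r2_threshold, window_kb) {
  d <- tibble::as_tibble(study)
  kept <- character(0)
  while (nrow(d) > 0) {
    ord <- order(d$p_value, d$chromosome, d$position, d$variant_id)
    d <- d[ord, , drop = FALSE]
    idx <- d[1, ]
    kept <- c(kept, idx$variant_id)
    rest <- d[-1, , drop = FALSE]
    if (nrow(rest) == 0) break
    drop <- logical(nrow(rest))
    for (i in seq_len(nrow(rest))) {
      same_chr <- rest$chromosome[i] == idx$chromosome
      close <- abs(rest$position[i] - idx$position) <= window_kb * 1000
      r2 <- mrflow::ld_r2(panel, idx$variant_id, rest$variant_id[i])
      drop[i] <- same_chr && close && r2 >= r2_threshold
    }
    d <- rest[!drop, , drop = FALSE]
  }
  sort(kept)
}
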