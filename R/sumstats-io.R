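# Reading, validating and writing GWAS summary-statistic tables and pairwise
# LD panels. The canonical on-disk format is tab-separated text with a fixed
# header; a dialect map accommodates other column names.

SUMSTATS_COLS <- c(
  "variant_id", "chromosome", "position", "effect_allele", "other_allele",
  "beta", "se", "p_value", "eaf", "n"
)

REQUIRED_LOGICAL_COLS <- c(
  "variant_id", "effect_allele", "other_allele", "beta", "se", "p_value"
)

new_sumstats <- function(records, trait_label = "trait", total_n = NA_integer_,
                         population_label = NA_character_, n_dropped = 0L) {
  out <- tibble::as_tibble(records)
  attr(out, "trait_label") <- trait_label
  attr(out, "total_n") <- as.integer(total_n)
  attr(out, "population_label") <- population_label
  attr(out, "n_dropped") <- as.integer(n_dropped)
  class(out) <- c("mr_sumstats", class(out))
  out
}

#' Trait label, total sample size and drop count of a summary study
#'
#' Accessors for the study-level metadata carried alongside a summary-statistic
#' tibble: the trait label, the study-wide sample size (used for instrument
#' strength when per-variant `n` is absent), and the number of rows dropped
#' during validation.
#'
#' @param study A summary-statistic tibble from [read_sumstats()] or
#'   [simulate_pair()].
#' @return A string, an integer, or an integer count respectively.
#' @export
trait_label <- function(study) attr(study, "trait_label") %||% "trait"

#' @rdname trait_label
#' @export
total_n <- function(study) {
  tn <- attr(study, "total_n")
  if (!is.null(tn) && !is.na(tn)) {
    return(as.integer(tn))
  }
  if ("n" %in% names(study) && any(!is.na(study$n))) {
    return(as.integer(max(study$n, na.rm = TRUE)))
  }
  NA_integer_
}

#' @rdname trait_label
#' @export
n_dropped <- function(study) attr(study, "n_dropped") %||% 0L

# Per-row invariant check; returns a logical keep mask.
valid_association <- function(d) {
  allele_ok <- function(a) {
    !is.na(a) & nzchar(a) & grepl("^[ACGT]+$", a)
  }
  keep <- !is.na(d$variant_id) & nzchar(d$variant_id) &
    allele_ok(d$effect_allele) & allele_ok(d$other_allele) &
    d$effect_allele != d$other_allele &
    !is.na(d$beta) & is.finite(d$beta) &
    !is.na(d$se) & d$se > 0 &
    !is.na(d$p_value) & d$p_value > 0 & d$p_value <= 1
  eaf_bad <- !is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)
  n_bad <- !is.na(d$n) & d$n <= 0
  keep & !eaf_bad & !n_bad
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-variant association results into a
#' validated summary-statistic tibble. The canonical format is tab-separated
#' with header columns `variant_id, chromosome, position, effect_allele,
#' other_allele, beta, se, p_value, eaf, n` and `NA` as the missing-value
#' marker; `dialect` maps these logical names onto whatever headers the file
#' actually uses. Rows violating the per-variant invariants (non-positive
#' standard error, p-value outside (0, 1], malformed or identical alleles,
#' allele frequency outside \[0, 1\]) are dropped with a logged count. Allele
#' strings are uppercased; strand flipping is deferred to harmonization.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named character vector mapping logical column names to the
#'   file's header names, e.g. `c(beta = "Effect", se = "StdErr")`. Unmapped
#'   logical columns are looked up under their canonical names.
#' @param trait_label Label for the trait this study measured.
#' @param total_n Study-wide sample size; defaults to the maximum per-variant
#'   `n` when present.
#' @param population_label Optional ancestry/population annotation.
#' @param delim Field delimiter, default tab.
#' @return A tibble of class `mr_sumstats` with the canonical columns, plus
#'   attributes `trait_label`, `total_n`, `population_label` and `n_dropped`.
#' @seealso [write_sumstats()], [read_ld_panel()]
#' @export
read_sumstats <- function(path, dialect = NULL, trait_label = NULL,
                          total_n = NA_integer_, population_label = NA_character_,
                          delim = "\t") {
  if (!file.exists(path)) {
    abort_mr(sprintf("File not found: %s", path), "mrflow_io_error")
  }
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                      na = c("NA", ""), progress = FALSE,
                      show_col_types = FALSE),
    error = function(e) {
      abort_mr(sprintf("Cannot parse %s: %s", path, conditionMessage(e)),
               "mrflow_format_error")
    }
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort_mr(sprintf("Empty summary-statistics file: %s", path),
             "mrflow_format_error")
  }
  mapping <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), SUMSTATS_COLS)
    if (length(bad) > 0) {
      abort_mr(sprintf("Unknown logical column(s) in dialect: %s",
                       paste(bad, collapse = ", ")), "mrflow_usage_error")
    }
    mapping[names(dialect)] <- unname(dialect)
  }
  missing_req <- REQUIRED_LOGICAL_COLS[!(mapping[REQUIRED_LOGICAL_COLS] %in% names(raw))]
  if (length(missing_req) > 0) {
    abort_mr(sprintf("Missing required column(s): %s",
                     paste(missing_req, collapse = ", ")),
             "mrflow_format_error")
  }
  get_col <- function(logical_name) {
    src <- mapping[[logical_name]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }
  d <- tibble::tibble(
    variant_id = as.character(get_col("variant_id")),
    chromosome = as.character(get_col("chromosome")),
    position = suppressWarnings(as.integer(get_col("position"))),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    p_value = suppressWarnings(as.numeric(get_col("p_value"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    n = suppressWarnings(as.integer(get_col("n")))
  )
  keep <- valid_association(d)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    rlang::inform(sprintf("read_sumstats: dropped %d invalid row(s) from %s",
                          n_drop, basename(path)))
  }
  d <- d[keep, , drop = FALSE]
  dup <- duplicated(d$variant_id)
  if (any(dup)) {
    rlang::inform(sprintf("read_sumstats: dropped %d duplicate variant id(s)",
                          sum(dup)))
    n_drop <- n_drop + sum(dup)
    d <- d[!dup, , drop = FALSE]
  }
  if (is.na(total_n) && any(!is.na(d$n))) total_n <- max(d$n, na.rm = TRUE)
  new_sumstats(d,
    trait_label = trait_label %||% sub("\\.[^.]*$", "", basename(path)),
    total_n = total_n, population_label = population_label,
    n_dropped = n_drop
  )
}

#' Write a summary study to the canonical TSV format
#'
#' Writes the canonical tab-separated layout with `NA` as the missing marker.
#' Reading the file back with [read_sumstats()] reproduces every retained
#' record exactly for finite decimal inputs (numbers are serialized at full
#' double precision).
#'
#' @param study A summary-statistic tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(study, path) {
  stop_if_not_df(study, "study")
  d <- tibble::as_tibble(study)[, SUMSTATS_COLS]
  # full-precision serialization so the round trip is bit-identical
  fmt <- function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
  }
  out <- dplyr::mutate(d, dplyr::across(c("beta", "se", "p_value", "eaf"), fmt))
  tryCatch(
    readr::write_tsv(out, path, na = "NA", progress = FALSE),
    error = function(e) {
      abort_mr(sprintf("Cannot write %s: %s", path, conditionMessage(e)),
               "mrflow_io_error")
    }
  )
  invisible(path)
}

# ---- LD panels --------------------------------------------------------------

new_ld_panel <- function(pairs, positions = NULL, n_rejected = 0L) {
  pairs <- tibble::as_tibble(pairs)
  # canonical key order a <= b; self pairs implicit (r2 = 1)
  a <- pmin(pairs$variant_id_a, pairs$variant_id_b)
  b <- pmax(pairs$variant_id_a, pairs$variant_id_b)
  pairs <- tibble::tibble(variant_id_a = a, variant_id_b = b, r2 = pairs$r2)
  pairs <- dplyr::distinct(pairs, .data$variant_id_a, .data$variant_id_b,
                           .keep_all = TRUE)
  pairs <- pairs[pairs$variant_id_a != pairs$variant_id_b, , drop = FALSE]
  lookup <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(pairs)))
  if (nrow(pairs) > 0) {
    keys <- paste(pairs$variant_id_a, pairs$variant_id_b, sep = "\r")
    for (i in seq_len(nrow(pairs))) assign(keys[i], pairs$r2[i], envir = lookup)
  }
  structure(
    list(pairs = pairs,
         positions = if (is.null(positions)) NULL else tibble::as_tibble(positions),
         lookup = lookup,
         n_rejected = as.integer(n_rejected)),
    class = "mr_ld_panel"
  )
}

#' Read a pairwise LD panel from precomputed r-squared tables
#'
#' Reads a three-column tab-separated table (`variant_id_a`, `variant_id_b`,
#' `r2`) of pairwise linkage-disequilibrium values, with an optional positions
#' table (`variant_id`, `chromosome`, `position`). The symmetric closure is
#' applied: looking up (a, b) and (b, a) returns the same value, a variant's
#' LD with itself is 1, and any absent pair is treated as r2 = 0. Rows with
#' r2 outside \[0, 1\] are rejected with a logged count.
#'
#' @param path Path to the pairwise r2 TSV.
#' @param positions_path Optional path to a positions TSV.
#' @return An object of class `mr_ld_panel`.
#' @seealso [ld_r2()], [ld_clump()]
#' @export
read_ld_panel <- function(path, positions_path = NULL) {
  if (!file.exists(path)) {
    abort_mr(sprintf("File not found: %s", path), "mrflow_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("NA", ""), progress = FALSE,
                         show_col_types = FALSE)
  need <- c("variant_id_a", "variant_id_b", "r2")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort_mr(sprintf("LD table missing column(s): %s",
                     paste(miss, collapse = ", ")), "mrflow_format_error")
  }
  r2 <- suppressWarnings(as.numeric(raw$r2))
  bad <- is.na(raw$variant_id_a) | is.na(raw$variant_id_b) |
    is.na(r2) | r2 < 0 | r2 > 1
  if (any(bad)) {
    rlang::inform(sprintf(
      "read_ld_panel: rejected %d malformed row(s) (lines %s)",
      sum(bad), paste(utils::head(which(bad) + 1L, 5), collapse = ", ")
    ))
  }
  pairs <- tibble::tibble(
    variant_id_a = raw$variant_id_a[!bad],
    variant_id_b = raw$variant_id_b[!bad],
    r2 = r2[!bad]
  )
  positions <- NULL
  if (!is.null(positions_path)) {
    positions <- readr::read_tsv(
      positions_path,
      col_types = readr::cols(variant_id = "c", chromosome = "c", position = "i"),
      progress = FALSE, show_col_types = FALSE
    )
  }
  new_ld_panel(pairs, positions, n_rejected = sum(bad))
}

#' Look up pairwise r-squared in an LD panel
#'
#' Vectorized lookup honouring the panel contract: symmetric in its
#' arguments, 1 on the diagonal, and 0 for any pair the panel does not list.
#'
#' @param panel An `mr_ld_panel`.
#' @param a,b Character vectors of variant ids (recycled to common length).
#' @return Numeric vector of r2 values.
#' @export
ld_r2 <- function(panel, a, b) {
  if (!inherits(panel, "mr_ld_panel")) {
    abort_mr("`panel` must be an mr_ld_panel.", "mrflow_usage_error")
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keys <- paste(lo, hi, sep = "\r")
  out <- unlist(mget(keys, envir = panel$lookup, ifnotfound = 0),
                use.names = FALSE)
  out[a == b] <- 1
  out
}

#' @export
print.mr_ld_panel <- function(x, ...) {
  cat(sprintf("<mr_ld_panel> %d pairwise r2 value(s), %s positions\n",
              nrow(x$pairs),
              if (is.null(x$positions)) "no" else nrow(x$positions)))
  invisible(x)
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("# GWAS summary study: %s (n = %s, %d variants, %d dropped)\n",
              trait_label(x), format(total_n(x)), nrow(x), n_dropped(x)))
  NextMethod()
}
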