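#' Rescale raw per-lane factors to the grand-total convention
#'
#' Global scaling factors are only identified up to a common multiple, so
#' every method rescales its raw factors such that their sum equals the sum of
#' the lane total counts.  Ratios between lanes are preserved, and normalized
#' expression measures stay on the familiar scale of raw counts.
#'
#' @param raw Positive numeric vector of raw per-lane factors.
#' @param lane_totals Per-lane total read counts.
#' @return Numeric vector `d` with `sum(d) == sum(lane_totals)`.
#' @export
rescale_factors <- function(raw, lane_totals) {
  if (any(!is.finite(raw)) || any(raw <= 0)) {
    abort("raw normalization factors must be positive")
  }
  raw * (sum(lane_totals) / sum(raw))
}

factor_tibble <- function(lanes, d, method) {
  tibble(lane_id = lanes, d = as.numeric(d), method = method)
}

#' Per-lane normalization factors
#'
#' Three global scaling methods, all returning per-lane factors `d` rescaled
#' so that `sum(d)` equals the grand total count:
#'
#' * `total_count_factors()` — lane total counts (the RPKM convention).
#' * `housekeeping_factors()` — counts of one housekeeping gene (e.g. POLR2A)
#'   expected constant across conditions.
#' * `upper_quartile_factors()` — the per-lane 75th percentile of gene counts
#'   after dropping genes with zero reads in every lane.  Robust to a handful
#'   of very highly expressed genes that dominate lane totals.
#'
#' Factors enter downstream tests as offsets: a gene whose counts are
#' proportional to `d` across lanes is non-differentially expressed.
#'
#' @param counts A count table.
#' @param gene_id Housekeeping gene identifier.
#' @param probs Quantile used by `upper_quartile_factors()` (default 0.75).
#' @return A tibble with columns `lane_id`, `d`, `method`.
#' @export
total_count_factors <- function(counts) {
  counts <- validate_counts(counts)
  lanes <- lane_ids(counts)
  tot <- colSums(count_matrix(counts))
  if (any(tot == 0)) {
    abort(sprintf("lane '%s' has zero total count", lanes[which(tot == 0)[1]]))
  }
  factor_tibble(lanes, rescale_factors(tot, tot), "total")
}

#' @rdname total_count_factors
#' @export
housekeeping_factors <- function(counts, gene_id) {
  counts <- validate_counts(counts)
  lanes <- lane_ids(counts)
  i <- match(gene_id, counts$gene_id)
  if (is.na(i)) abort(sprintf("housekeeping gene '%s' not found", gene_id))
  raw <- as.numeric(count_matrix(counts)[i, ])
  if (any(raw == 0)) {
    abort(sprintf("housekeeping gene '%s' has zero count in lane '%s'",
                  gene_id, lanes[which(raw == 0)[1]]))
  }
  tot <- colSums(count_matrix(counts))
  factor_tibble(lanes, rescale_factors(raw, tot), "housekeeping")
}

#' @rdname total_count_factors
#' @export
upper_quartile_factors <- function(counts, probs = 0.75) {
  counts <- validate_counts(counts)
  lanes <- lane_ids(counts)
  m <- count_matrix(counts)
  keep <- rowSums(m) > 0
  if (sum(keep) < 4) abort("fewer than 4 genes with reads in any lane")
  # type-7 (linear interpolation) quantile; zeros kept when the gene has
  # reads in some other lane
  raw <- apply(m[keep, , drop = FALSE], 2, quantile, probs = probs,
               names = FALSE, type = 7)
  if (any(raw <= 0)) {
    abort(sprintf("upper quartile is zero in lane '%s'",
                  lanes[which(raw <= 0)[1]]))
  }
  factor_tibble(lanes, rescale_factors(raw, colSums(m)), "upper_quartile")
}

#' Full quantile normalization of a count table
#'
#' Forces every lane to share one count distribution: for each rank the
#' reference value is the median across lanes of the rank-th smallest count;
#' each lane's counts are replaced by the reference values at their ranks.
#' The result is rounded half-away-from-zero back to integers so count-based
#' tests still apply.  Genes with zero reads in every lane are left at zero
#' and excluded from the rank computation.
#'
#' Tied counts within a lane can be handled two ways.  The default
#' (`ties = "sequential"`) assigns the reference order statistics position by
#' position (ties broken by input order), so after normalization every lane
#' has *exactly* the reference as its sorted count vector — the defining
#' property of quantile normalization, exact up to integer rounding.
#' `ties = "mean"` instead gives all tied counts the mean reference over
#' their tied ranks (the microarray convention): symmetric in the tied genes,
#' but lanes then share the reference only approximately wherever a tie
#' spans a gap in the reference.
#'
#' @param counts A count table with at least two lanes.
#' @param ties `"sequential"` (default) or `"mean"`; see Details.
#' @return A count table of the same shape with quantile-normalized integer
#'   counts.
#' @export
quantile_normalize <- function(counts, ties = c("sequential", "mean")) {
  ties <- match.arg(ties)
  counts <- validate_counts(counts)
  lanes <- lane_ids(counts)
  if (length(lanes) < 2) abort("quantile normalization needs >= 2 lanes")
  m <- count_matrix(counts)
  keep <- rowSums(m) > 0
  sub <- m[keep, , drop = FALSE]
  sorted <- apply(sub, 2, sort)
  ref <- apply(sorted, 1, median)
  norm <- apply(sub, 2, function(x) {
    y <- numeric(length(x))
    y[order(x)] <- ref
    if (ties == "mean") y <- ave(y, x, FUN = mean)
    y
  })
  m[keep, ] <- floor(norm + 0.5)  # half-away-from-zero; counts are >= 0
  out <- counts
  for (j in seq_along(lanes)) out[[lanes[j]]] <- as.integer(m[, j])
  out
}

#' Per-length expression measure (RPKM-style)
#'
#' Reads per kilobase of gene model per million (normalized) reads:
#' `count / (d/1e6) / (length/1e3)`.  With total-count factors this is RPKM;
#' any factor set can stand in for the per-million denominator.
#'
#' @param counts Count table with a `length` column.
#' @param factors Factor tibble from one of the factor functions.
#' @return Tibble with `gene_id`, `length`, and one numeric column per lane.
#' @export
per_length_measure <- function(counts, factors) {
  counts <- validate_counts(counts)
  if (!"length" %in% names(counts)) {
    abort("per_length_measure requires gene lengths")
  }
  lanes <- lane_ids(counts)
  d <- factor_lookup(factors, lanes)
  out <- counts[c("gene_id", "length")]
  for (ln in lanes) {
    out[[ln]] <- counts[[ln]] / (d[[ln]] / 1e6) / (counts$length / 1e3)
  }
  out
}

#' Read or write a factor table
#'
#' Factors are stored as a two-column TSV (`lane_id`, `d`) with an optional
#' `method` column.
#'
#' @param path File path.
#' @param factors Factor tibble.
#' @return The factor tibble (read) or `path` invisibly (write).
#' @export
read_factors <- function(path) {
  f <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  if (!all(c("lane_id", "d") %in% names(f))) {
    abort("factor file must have columns lane_id and d")
  }
  if (any(f$d <= 0)) abort("factors must be positive")
  f
}

#' @rdname read_factors
#' @export
write_factors <- function(factors, path) {
  readr::write_tsv(factors, path, quote = "none", eol = "\n")
  invisible(path)
}

# named vector of factors for the requested lanes
factor_lookup <- function(factors, lanes) {
  i <- match(lanes, factors$lane_id)
  if (anyNA(i)) abort(sprintf("no factor for lane '%s'", lanes[is.na(i)][1]))
  d <- factors$d[i]
  if (any(d <= 0)) abort("factors must be positive")
  setNames(d, lanes)
}
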