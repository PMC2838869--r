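#' Lane columns of a count table
#'
#' A count table is a tibble with a `gene_id` column, an optional `length`
#' column, and one non-negative integer column per lane.  This helper returns
#' the lane column names in table order.
#'
#' @param counts A count table (see Details).
#' @return Character vector of lane ids.
#' @export
lane_ids <- function(counts) {
  setdiff(names(counts), c("gene_id", "length"))
}

#' Validate a count table
#'
#' Checks the invariants every downstream operation relies on: unique gene and
#' lane labels, non-negative integral counts, and positive gene lengths when a
#' `length` column is present.  Errors name the offending gene and lane.
#'
#' @param counts Tibble with `gene_id`, optional `length`, and lane columns.
#' @return The validated table, invisibly coerced to a tibble with integer
#'   lane columns.
#' @export
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (!"gene_id" %in% names(counts)) {
    abort("count table must have a 'gene_id' column")
  }
  lanes <- lane_ids(counts)
  if (anyDuplicated(counts$gene_id)) {
    abort(paste0("duplicated gene_id: ",
                 counts$gene_id[duplicated(counts$gene_id)][1]))
  }
  if (anyDuplicated(lanes)) abort("duplicated lane columns")
  for (ln in lanes) {
    x <- counts[[ln]]
    if (!is.numeric(x) || anyNA(x)) {
      bad <- counts$gene_id[which(!is.finite(x) | is.na(x))[1]]
      abort(sprintf("non-numeric or missing count for gene '%s' in lane '%s'",
                    bad, ln))
    }
    if (any(x < 0)) {
      abort(sprintf("negative count for gene '%s' in lane '%s'",
                    counts$gene_id[which(x < 0)[1]], ln))
    }
    if (any(x != round(x))) {
      abort(sprintf("non-integer count for gene '%s' in lane '%s'",
                    counts$gene_id[which(x != round(x))[1]], ln))
    }
    counts[[ln]] <- as.integer(round(x))
  }
  if ("length" %in% names(counts)) {
    len <- counts$length
    if (anyNA(len) || any(len < 1)) {
      abort(sprintf("gene_length must be >= 1 (gene '%s')",
                    counts$gene_id[which(is.na(len) | len < 1)[1]]))
    }
    counts$length <- as.integer(len)
  }
  counts
}

#' Read a gene-by-lane count table
#'
#' Reads a delimited text file with gene ids in the first column, lane ids in
#' the header, and an optional `length` column, validating every cell.  A
#' MatrixMarket triplet file is also accepted (`dialect = "mtx"`) with sidecar
#' `<path>.rows` / `<path>.cols` label files.
#'
#' @param path File to read.
#' @param dialect `"tsv"` (default), `"csv"`, or `"mtx"`.
#' @return A validated count tibble.
#' @export
read_count_table <- function(path, dialect = c("tsv", "csv", "mtx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("count file not found: %s", path))
  if (dialect == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".rows"))
    lanes <- readLines(paste0(path, ".cols"))
    if (length(genes) != nrow(m) || length(lanes) != ncol(m)) {
      abort("MTX sidecar label files do not match matrix dimensions")
    }
    out <- bind_cols(tibble(gene_id = genes),
                     as_tibble(`colnames<-`(m, lanes)))
    return(validate_counts(out))
  }
  delim <- if (dialect == "csv") "," else "\t"
  out <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(out) < 2 || names(out)[1] != "gene_id") {
    abort(sprintf("malformed header in %s: first column must be 'gene_id'",
                  path))
  }
  validate_counts(out)
}

#' Write a count table
#'
#' Deterministic, byte-stable delimited output: rows and columns in the order
#' given, tab separator by default, no quoting, counts printed as integers.
#'
#' @param counts A validated count table.
#' @param path Output file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  counts <- validate_counts(counts)
  delim <- if (dialect == "csv") "," else "\t"
  readr::write_delim(counts, path, delim = delim, quote = "none", eol = "\n")
  invisible(path)
}

#' Read and write lane metadata
#'
#' Lane metadata is a tibble with columns `lane_id`, `condition`, `flow_cell`,
#' `library_prep`, and `total_count`.  When a count table is supplied the
#' total counts are checked against its column sums.
#'
#' @param path File to read or write.
#' @param counts Optional count table for consistency checking.
#' @return A lane-metadata tibble.
#' @export
read_lane_info <- function(path, counts = NULL) {
  if (!file.exists(path)) abort(sprintf("lane file not found: %s", path))
  li <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  validate_lane_info(li, counts)
}

#' @rdname read_lane_info
#' @param lane_info Lane-metadata tibble to write.
#' @export
write_lane_info <- function(lane_info, path) {
  readr::write_tsv(lane_info, path, quote = "none", eol = "\n")
  invisible(path)
}

#' @rdname read_lane_info
#' @export
validate_lane_info <- function(lane_info, counts = NULL) {
  lane_info <- as_tibble(lane_info)
  need <- c("lane_id", "condition")
  miss <- setdiff(need, names(lane_info))
  if (length(miss)) abort(paste("lane_info missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(lane_info$lane_id)) abort("duplicated lane_id")
  if (!"flow_cell" %in% names(lane_info)) lane_info$flow_cell <- "FC1"
  if (!"library_prep" %in% names(lane_info)) lane_info$library_prep <- "LP1"
  if (!is.null(counts)) {
    counts <- validate_counts(counts)
    lanes <- lane_ids(counts)
    if (!setequal(lanes, lane_info$lane_id)) {
      abort("lane ids in counts and lane_info differ")
    }
    sums <- vapply(lane_info$lane_id, function(l) sum(counts[[l]]), double(1))
    if ("total_count" %in% names(lane_info)) {
      if (any(lane_info$total_count != sums)) {
        bad <- lane_info$lane_id[which(lane_info$total_count != sums)[1]]
        abort(sprintf("total_count for lane '%s' does not match column sum",
                      bad))
      }
    } else {
      lane_info$total_count <- as.integer(sums)
    }
  }
  lane_info
}

#' Pool lanes by a metadata field
#'
#' Sums read counts across lanes sharing the same value of a lane-metadata
#' field (typically `condition`).  Pooling by summation is justified when
#' counts are Poisson across replicate lanes, since sums of independent
#' Poisson counts are Poisson.
#'
#' @param counts A count table.
#' @param lane_info Lane metadata covering every lane column.
#' @param group_by Name of the lane-metadata field to pool on.
#' @return A count table with one column per group, group labels sorted.
#' @export
pool_lanes <- function(counts, lane_info, group_by = "condition") {
  counts <- validate_counts(counts)
  if (!group_by %in% names(lane_info)) {
    abort(sprintf("unknown lane_info field '%s'", group_by))
  }
  lanes <- lane_ids(counts)
  lane_info <- validate_lane_info(lane_info)
  grp <- setNames(as.character(lane_info[[group_by]]), lane_info$lane_id)
  if (!all(lanes %in% names(grp))) abort("lane_info does not cover all lanes")
  out <- counts[intersect(c("gene_id", "length"), names(counts))]
  for (g in sort(unique(grp[lanes]))) {
    member <- lanes[grp[lanes] == g]
    out[[g]] <- as.integer(rowSums(as.matrix(counts[member])))
  }
  out
}

# integer matrix of the lane columns, genes as rownames
count_matrix <- function(counts, lanes = lane_ids(counts)) {
  m <- as.matrix(counts[lanes])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}
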