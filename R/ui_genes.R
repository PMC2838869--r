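# Coordinates in every tibble of this file are 0-based half-open; the
# IRanges/GenomicRanges machinery used internally is 1-based closed, so
# conversion happens exactly here.
to_iranges <- function(start, end) IRanges::IRanges(start + 1L, end)
from_iranges <- function(r) {
  tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' Read transcript annotation from GTF/GFF
#'
#' Parses a GTF (GFF2.2) file into an exon-level tibble with 0-based
#' half-open coordinates.  Exons are flagged `coding` when they overlap a CDS
#' feature of the same gene; these flags drive the masking step of
#' [build_ui_genes()].
#'
#' @param path GTF file.
#' @param chromosomes Optional allow-list of chromosome names (default: keep
#'   all).
#' @return Tibble with columns `gene_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `coding`.
#' @export
read_gtf_annotation <- function(path, chromosomes = NULL) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(gr$type)
  ex <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  if (!length(ex)) abort("annotation contains no exon features")
  coding <- rep(FALSE, length(ex))
  if (length(cds)) {
    hits <- GenomicRanges::findOverlaps(ex, cds, ignore.strand = TRUE)
    same_gene <- ex$gene_id[S4Vectors::queryHits(hits)] ==
      cds$gene_id[S4Vectors::subjectHits(hits)]
    coding[unique(S4Vectors::queryHits(hits)[same_gene])] <- TRUE
  }
  out <- tibble(
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    coding = coding
  )
  if (!is.null(chromosomes)) out <- filter(out, .data$chrom %in% chromosomes)
  arrange(out, .data$gene_id, .data$transcript_id, .data$start)
}

#' Constitutive exons of one gene
#'
#' The base-level intersection of exonic coverage across all isoforms of a
#' gene, returned as maximal disjoint intervals: a base belongs to the result
#' exactly when every transcript of the gene has an exon covering it.
#'
#' @param transcripts Exon tibble for a single gene (columns `transcript_id`,
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @return Tibble with `chrom`, `start`, `end` of the constitutive intervals
#'   (possibly zero rows).
#' @export
constitutive_exons <- function(transcripts) {
  if (!nrow(transcripts)) abort("gene has no transcripts")
  if (length(unique(transcripts$chrom)) > 1) {
    abort("transcripts of one gene on multiple chromosomes")
  }
  per_tx <- lapply(split(transcripts, transcripts$transcript_id),
                   function(tx) IRanges::reduce(to_iranges(tx$start, tx$end)))
  acc <- per_tx[[1]]
  for (r in per_tx[-1]) acc <- IRanges::intersect(acc, r)
  bind_cols(tibble(chrom = rep(transcripts$chrom[1], length(acc))),
            from_iranges(acc))
}

#' Build union-intersection (UI) genes
#'
#' A UI gene is a gene-level region of interest: the union of the gene's
#' constitutive exons minus the coding exons of all *other* genes, so that
#' reads over it are attributable to the gene irrespective of isoform and
#' free of coding overlap with neighbours.  Genes whose UI region is empty
#' are omitted; genes annotated on several chromosomes are skipped with a
#' warning.
#'
#' @param annotation Exon tibble as from [read_gtf_annotation()].
#' @param chromosomes Optional chromosome allow-list.
#' @return Tibble with one row per UI region: `gene_id`, `chrom`, `start`,
#'   `end`, sorted by `gene_id` then `start`.
#' @export
build_ui_genes <- function(annotation, chromosomes = NULL) {
  if (!is.null(chromosomes)) {
    annotation <- filter(annotation, .data$chrom %in% chromosomes)
  }
  genes <- split(annotation, annotation$gene_id)
  coding <- filter(annotation, .data$coding)
  out <- lapply(sort(names(genes)), function(g) {
    tx <- genes[[g]]
    if (length(unique(tx$chrom)) > 1) {
      warn(sprintf("gene '%s' spans multiple chromosomes; skipped", g))
      return(NULL)
    }
    ce <- constitutive_exons(tx)
    if (!nrow(ce)) return(NULL)
    mask <- filter(coding, .data$gene_id != g, .data$chrom == tx$chrom[1])
    r <- to_iranges(ce$start, ce$end)
    if (nrow(mask)) {
      r <- IRanges::setdiff(r, IRanges::reduce(to_iranges(mask$start,
                                                          mask$end)))
    }
    if (!length(r)) return(NULL)
    bind_cols(tibble(gene_id = g, chrom = tx$chrom[1]), from_iranges(r))
  })
  bind_rows(out)
}

#' UI gene lengths
#'
#' @param ui_genes UI-region tibble from [build_ui_genes()].
#' @return Tibble with `gene_id` and `length` (total UI bases).
#' @export
ui_lengths <- function(ui_genes) {
  ui_genes |>
    group_by(.data$gene_id) |>
    summarise(length = as.integer(sum(.data$end - .data$start)),
              .groups = "drop")
}

#' Count uniquely mapped reads over UI genes
#'
#' Counts, per UI gene and lane, the alignments that overlap the gene's UI
#' regions by at least one base.  Strands are pooled.  Each read counts at
#' most once per gene, however many of the gene's regions it touches; a read
#' overlapping UI regions of two different genes increments both (rare after
#' UI masking).  Alignments flagged non-unique are ignored; alignments on
#' chromosomes absent from the UI set are tallied as unassigned and reported
#' with a message.
#'
#' @param alignments Tibble with columns `read_id`, `lane_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `unique` (logical).
#' @param ui_genes UI-region tibble from [build_ui_genes()].
#' @return A count table: `gene_id`, `length`, one integer column per lane
#'   (lanes sorted), covering every UI gene including zero-count ones.
#' @export
count_reads <- function(alignments, ui_genes) {
  lanes <- sort(unique(alignments$lane_id))
  if ("unique" %in% names(alignments)) {
    alignments <- filter(alignments, .data$unique)
  }
  lens <- ui_lengths(ui_genes)
  out <- tibble(gene_id = lens$gene_id, length = lens$length)
  known <- alignments$chrom %in% unique(ui_genes$chrom)
  if (any(!known)) {
    message(sprintf("%d alignment(s) on unknown chromosomes left unassigned",
                    sum(!known)))
    alignments <- alignments[known, , drop = FALSE]
  }
  gr_ui <- GenomicRanges::GRanges(ui_genes$chrom,
                                  to_iranges(ui_genes$start, ui_genes$end))
  gr_al <- GenomicRanges::GRanges(alignments$chrom,
                                  to_iranges(alignments$start,
                                             alignments$end))
  hits <- GenomicRanges::findOverlaps(gr_al, gr_ui, ignore.strand = TRUE)
  pairs <- tibble(
    lane_id = alignments$lane_id[S4Vectors::queryHits(hits)],
    read_id = alignments$read_id[S4Vectors::queryHits(hits)],
    gene_id = ui_genes$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  for (ln in lanes) {
    tab <- table(pairs$gene_id[pairs$lane_id == ln])
    v <- as.integer(tab[out$gene_id])
    v[is.na(v)] <- 0L
    out[[ln]] <- v
  }
  validate_counts(out)
}

#' Sample a fixed-length UI subregion
#'
#' Chooses a contiguous window of exactly `width` bases in UI coordinate
#' space (along the concatenated UI bases of the gene), start uniform over
#' the valid positions, and maps it back to genomic intervals.  Deterministic
#' for a fixed seed.  Genes shorter than `width` are ineligible.
#'
#' @param ui_gene UI-region tibble for a single gene.
#' @param width Window width in bases (default 250).
#' @param seed Integer seed.
#' @return UI-region tibble of the sampled window (total width `width`), or
#'   zero rows if the gene is shorter than `width` (with a warning).
#' @export
sample_fixed_length <- function(ui_gene, width = 250, seed) {
  if (missing(seed)) abort("seed required")
  stopifnot(length(unique(ui_gene$gene_id)) == 1)
  ui_gene <- arrange(ui_gene, .data$start)
  w <- ui_gene$end - ui_gene$start
  total <- sum(w)
  if (total < width) {
    warn(sprintf("gene '%s' is shorter than %d bases; ineligible",
                 ui_gene$gene_id[1], width))
    return(ui_gene[0, , drop = FALSE])
  }
  s <- withr_seed(seed, sample.int(total - width + 1L, 1L) - 1L)
  ui_window(ui_gene, s, width)
}

# map UI-space window [s, s+width) back to genomic intervals
ui_window <- function(ui_gene, s, width) {
  offs <- cumsum(c(0L, ui_gene$end - ui_gene$start))
  pieces <- lapply(seq_len(nrow(ui_gene)), function(i) {
    lo <- max(s, offs[i])
    hi <- min(s + width, offs[i + 1])
    if (hi <= lo) return(NULL)
    g <- ui_gene[i, , drop = FALSE]
    g$start <- g$start + (lo - offs[i])
    g$end <- g$start + (hi - lo)
    g
  })
  bind_rows(pieces)
}

#' Read alignments from BED or SAM
#'
#' `read_alignments_bed()` reads BED6 (or BED4+) intervals; BED is already
#' 0-based half-open.  `read_alignments_sam()` reads the mandatory columns of
#' a SAM text file, reconstructing the aligned reference span from the CIGAR
#' string (M/D/N/=/X consume reference bases) and skipping unmapped records.
#' Uniqueness of mapping is mapper-specific, so both readers accept a
#' predicate `unique_fn(df)` returning one logical per record; the default
#' treats every record as unique, and for SAM a minimum mapping quality can
#' be used instead.
#'
#' @param path Alignment file.
#' @param lane_id Lane label attached to every record.
#' @param unique_fn Optional predicate for unique mapping.
#' @param min_mapq SAM only: records with `mapq >= min_mapq` count as unique
#'   (ignored when `unique_fn` is given).
#' @return Alignment tibble for [count_reads()].
#' @export
read_alignments_bed <- function(path, lane_id, unique_fn = NULL) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bed <- as.data.frame(rtracklayer::import(path, format = "bed"))
  out <- tibble(read_id = if ("name" %in% names(bed)) as.character(bed$name)
                else sprintf("read%06d", seq_len(nrow(bed))),
                lane_id = lane_id,
                chrom = as.character(bed$seqnames),
                start = bed$start - 1L,
                end = bed$end,
                strand = as.character(bed$strand))
  out$unique <- if (is.null(unique_fn)) TRUE else unique_fn(out)
  out
}

#' @rdname read_alignments_bed
#' @export
read_alignments_sam <- function(path, lane_id, unique_fn = NULL,
                                min_mapq = 0) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) return(tibble(read_id = character(), lane_id = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 unique = logical()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  rname <- vapply(f, `[[`, "", 3)
  pos <- as.integer(vapply(f, `[[`, "", 4))
  mapq <- as.integer(vapply(f, `[[`, "", 5))
  cigar <- vapply(f, `[[`, "", 6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  span <- vapply(cigar, cigar_reference_span, integer(1), USE.NAMES = FALSE)
  out <- tibble(read_id = qname, lane_id = lane_id, chrom = rname,
                start = pos - 1L, end = pos - 1L + span,
                strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                mapq = mapq)[mapped, , drop = FALSE]
  out$unique <- if (is.null(unique_fn)) out$mapq >= min_mapq else
    unique_fn(out)
  select(out, -"mapq")
}

cigar_reference_span <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  as.integer(sum(n[op %in% c("M", "D", "N", "=", "X")]))
}

#' Write intervals as BED
#'
#' Writes UI regions (or alignments) as BED6; scores are 0 and the name field
#' carries the gene or read id.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and a `gene_id` or
#'   `read_id` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions[["gene_id"]] %||% regions[["read_id"]] %||%
    rep(".", nrow(regions))
  strand <- regions[["strand"]] %||% rep(".", nrow(regions))
  df <- data.frame(regions$chrom, regions$start, regions$end, name, 0L,
                   strand)
  readr::write_tsv(df, path, col_names = FALSE, quote = "none", eol = "\n")
  invisible(path)
}
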