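# Small fixtures built in code, shared across test files.

toy_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    length = c(500L, 1000L, 250L, 2000L),
    L1 = c(10L, 0L, 5L, 100L),
    L2 = c(20L, 0L, 9L, 210L),
    L3 = c(12L, 3L, 4L, 95L),
    L4 = c(25L, 6L, 11L, 200L)
  )
}

toy_lane_info <- function() {
  tibble::tibble(
    lane_id = c("L1", "L2", "L3", "L4"),
    condition = c("A", "A", "B", "B"),
    flow_cell = c("FC1", "FC2", "FC1", "FC2"),
    library_prep = c("LP1", "LP1", "LP2", "LP2")
  )
}

unit_factors <- function(lanes, d = 1) {
  tibble::tibble(lane_id = lanes, d = rep(d, length(lanes)),
                 method = "manual")
}

# two genes on chr1 (gA with two exons and a neighbour gB overlapping its
# tail), one gene on chr2 with two isoforms
toy_ann <- function() {
  dplyr::bind_rows(
    tibble::tibble(gene_id = "gA", transcript_id = "gA.t1", chrom = "chr1",
                   start = c(0L, 200L), end = c(100L, 300L), strand = "+",
                   coding = TRUE),
    tibble::tibble(gene_id = "gB", transcript_id = "gB.t1", chrom = "chr1",
                   start = 280L, end = 400L, strand = "-", coding = TRUE),
    tibble::tibble(gene_id = "gC", transcript_id = c("gC.t1", "gC.t1",
                                                     "gC.t2"),
                   chrom = "chr2",
                   start = c(0L, 150L, 50L), end = c(100L, 250L, 250L),
                   strand = "+", coding = c(TRUE, TRUE, TRUE))
  )
}

# per-base set-arithmetic oracle for UI construction on a toy chromosome
ui_oracle <- function(annotation, genome_size = 10000L) {
  genes <- split(annotation, annotation$gene_id)
  lapply(genes, function(tx) {
    chroms <- unique(tx$chrom)
    if (length(chroms) > 1) return(NULL)
    base_sets <- lapply(split(tx, tx$transcript_id), function(t1) {
      unique(unlist(mapply(seq.int, t1$start, t1$end - 1L,
                           SIMPLIFY = FALSE)))
    })
    const <- Reduce(intersect, base_sets)
    other <- annotation[annotation$gene_id != tx$gene_id[1] &
                          annotation$chrom == chroms & annotation$coding, ,
                        drop = FALSE]
    if (nrow(other)) {
      mask <- unique(unlist(mapply(seq.int, other$start, other$end - 1L,
                                   SIMPLIFY = FALSE)))
      const <- setdiff(const, mask)
    }
    sort(const)
  })
}

# bases covered by a UI tibble, per gene
ui_bases <- function(ui) {
  lapply(split(ui, ui$gene_id), function(g) {
    sort(unique(unlist(mapply(seq.int, g$start, g$end - 1L,
                              SIMPLIFY = FALSE))))
  })
}

# non-overlapping genes on their own 3 kb blocks: UI = constitutive exons
spaced_annotation <- function(n_genes, seed) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
    orig <- (i - 1L) * 3000L
    n_ex <- sample(1:3, 1)
    gaps <- sample(50:200, n_ex, TRUE)
    widths <- sample(150:600, n_ex, TRUE)
    starts <- orig + cumsum(gaps) + c(0L, cumsum(widths[-n_ex]))
    tibble::tibble(gene_id = sprintf("g%03d", i),
                   transcript_id = sprintf("g%03d.t1", i),
                   chrom = "chr1", start = starts,
                   end = starts + widths, strand = "+", coding = TRUE)
  }))
}

random_annotation <- function(n_genes, seed) {
  set.seed(seed)
  recs <- lapply(seq_len(n_genes), function(i) {
    chrom <- sample(c("chr1", "chr2"), 1)
    orig <- sample.int(5000L, 1)
    n_tx <- sample(1:3, 1)
    dplyr::bind_rows(lapply(seq_len(n_tx), function(t) {
      n_ex <- sample(1:4, 1)
      starts <- sort(orig + sample.int(600L, n_ex))
      widths <- sample(20:120, n_ex, replace = TRUE)
      ends <- starts + widths
      # enforce non-overlapping sorted exons within the transcript
      for (k in seq_len(n_ex)[-1]) {
        starts[k] <- max(starts[k], ends[k - 1] + 1L)
        ends[k] <- starts[k] + widths[k]
      }
      tibble::tibble(gene_id = sprintf("g%03d", i),
                     transcript_id = sprintf("g%03d.t%d", i, t),
                     chrom = chrom, start = starts, end = ends,
                     strand = "+",
                     coding = sample(c(TRUE, FALSE), n_ex, TRUE, c(.8, .2)))
    }))
  })
  dplyr::bind_rows(recs)
}
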