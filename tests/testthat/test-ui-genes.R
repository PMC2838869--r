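test_that("constitutive exons are the base-level isoform intersection", {
  # single isoform: exons unchanged
  one <- toy_ann()[toy_ann()$gene_id == "gA", ]
  ce <- constitutive_exons(one)
  expect_equal(ce$start, c(0L, 200L))
  expect_equal(ce$end, c(100L, 300L))
  # two isoforms [0,100) and [50,150): intersection [50,100)
  two <- tibble::tibble(gene_id = "g", transcript_id = c("t1", "t2"),
                        chrom = "chr1", start = c(0L, 50L),
                        end = c(100L, 150L), strand = "+", coding = TRUE)
  ce <- constitutive_exons(two)
  expect_equal(ce$start, 50L)
  expect_equal(ce$end, 100L)
  # disjoint isoforms: empty result
  disj <- two
  disj$start <- c(0L, 200L)
  disj$end <- c(100L, 300L)
  expect_equal(nrow(constitutive_exons(disj)), 0)
  expect_error(constitutive_exons(two[0, ]), "no transcripts")
  multi <- two
  multi$chrom <- c("chr1", "chr2")
  expect_error(constitutive_exons(multi), "multiple chromosomes")
})

test_that("UI genes subtract other genes' coding exons", {
  ui <- build_ui_genes(toy_ann())
  # gA constitutive [0,100)+[200,300); gB coding [280,400) -> gA UI ends 280
  a <- ui[ui$gene_id == "gA", ]
  expect_equal(a$start, c(0L, 200L))
  expect_equal(a$end, c(100L, 280L))
  # gC isoforms [0,100)+[150,250) and [50,250): constitutive [50,100)+[150,250)
  c_ <- ui[ui$gene_id == "gC", ]
  expect_equal(c_$start, c(50L, 150L))
  expect_equal(c_$end, c(100L, 250L))
  expect_equal(ui_lengths(ui)$length[ui_lengths(ui)$gene_id == "gA"], 180L)
  # a gene fully inside another gene's coding exon is omitted
  swallowed <- dplyr::bind_rows(
    toy_ann(),
    tibble::tibble(gene_id = "gD", transcript_id = "gD.t1", chrom = "chr1",
                   start = 300L, end = 350L, strand = "+", coding = FALSE))
  expect_false("gD" %in% build_ui_genes(swallowed)$gene_id)
  # non-coding exons of other genes do NOT mask
  noncoding_nb <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", transcript_id = "g1.t", chrom = "c",
                   start = 0L, end = 100L, strand = "+", coding = TRUE),
    tibble::tibble(gene_id = "g2", transcript_id = "g2.t", chrom = "c",
                   start = 50L, end = 150L, strand = "+", coding = FALSE))
  ui2 <- build_ui_genes(noncoding_nb)
  expect_equal(ui2[ui2$gene_id == "g1", ]$end, 100L)
})

test_that("UI construction matches a per-base set-arithmetic oracle on
           randomized annotations", {
  for (seed in c(101, 102)) {
    ann <- random_annotation(30, seed = seed)
    ui <- build_ui_genes(ann)
    oracle <- ui_oracle(ann)
    got <- ui_bases(ui)
    for (g in names(oracle)) {
      if (length(oracle[[g]])) {
        expect_equal(got[[g]], oracle[[g]], info = paste(seed, g))
      } else {
        expect_false(g %in% names(got))
      }
    }
    # UI regions never overlap other genes' coding exons
    coding <- ann[ann$coding, ]
    for (g in names(got)) {
      mask <- coding[coding$gene_id != g, ]
      mask_bases <- unlist(mapply(seq.int, mask$start, mask$end - 1L,
                                  SIMPLIFY = FALSE))
      chrom_of <- unique(ui$chrom[ui$gene_id == g])
      mask_bases <- mask_bases[rep(mask$chrom, mask$end - mask$start) ==
                                 chrom_of]
      expect_length(intersect(got[[g]], mask_bases), 0)
    }
    # constitutive exons lie inside every isoform's exonic union
    genes <- split(ann, ann$gene_id)
    for (g in names(got)) {
      for (tx in split(genes[[g]], genes[[g]]$transcript_id)) {
        txb <- unlist(mapply(seq.int, tx$start, tx$end - 1L,
                             SIMPLIFY = FALSE))
        ce <- constitutive_exons(genes[[g]])
        if (nrow(ce)) {
          ceb <- unlist(mapply(seq.int, ce$start, ce$end - 1L,
                               SIMPLIFY = FALSE))
          expect_length(setdiff(ceb, txb), 0)
        }
      }
    }
  }
})

test_that("read counting matches all-pairs overlap enumeration", {
  ui <- build_ui_genes(toy_ann())
  set.seed(111)
  n <- 100
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:n),
    lane_id = sample(c("L1", "L2"), n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample.int(500L, n, TRUE) - 1L,
    strand = sample(c("+", "-"), n, TRUE),
    unique = TRUE
  )
  reads$end <- reads$start + 35L
  counted <- count_reads(reads, ui)
  # brute-force O(n*m) oracle
  for (g in unique(ui$gene_id)) {
    regions <- ui[ui$gene_id == g, ]
    for (ln in c("L1", "L2")) {
      sub <- reads[reads$lane_id == ln, ]
      hit <- vapply(seq_len(nrow(sub)), function(i) {
        any(sub$chrom[i] == regions$chrom &
              sub$start[i] < regions$end & sub$end[i] > regions$start)
      }, logical(1))
      expect_equal(counted[[ln]][counted$gene_id == g], sum(hit))
    }
  }
  # total assignments cannot exceed reads per gene (each read once per gene)
  expect_lte(max(as.matrix(counted[c("L1", "L2")])), n)
})

test_that("a read spanning two regions of one UI gene counts once", {
  ui <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = c(0L, 200L), end = c(100L, 300L))
  read <- tibble::tibble(read_id = "r1", lane_id = "L1", chrom = "chr1",
                         start = 50L, end = 250L, strand = "+",
                         unique = TRUE)
  expect_equal(count_reads(read, ui)$L1, 1L)
  # non-unique reads are ignored; unknown chromosomes reported
  read$unique <- FALSE
  expect_equal(count_reads(read, ui)$L1, 0L)
  offchrom <- tibble::tibble(read_id = "r2", lane_id = "L1", chrom = "chrX",
                             start = 0L, end = 35L, strand = "+",
                             unique = TRUE)
  expect_message(count_reads(offchrom, ui), "unassigned")
})

test_that("fixed-length UI windows are seeded, contiguous in UI space, and
           exactly the requested width", {
  ui <- tibble::tibble(gene_id = "g", chrom = "chr1",
                       start = c(0L, 500L), end = c(100L, 700L)) # 300 bases
  w1 <- sample_fixed_length(ui, width = 250, seed = 10)
  w2 <- sample_fixed_length(ui, width = 250, seed = 10)
  expect_equal(w1, w2)
  expect_equal(sum(w1$end - w1$start), 250L)
  # all windows map inside the gene's UI bases
  expect_length(setdiff(ui_bases(w1)$g, ui_bases(ui)$g), 0)
  # a window spanning the region boundary splits into two intervals
  spanning <- FALSE
  for (s in 1:40) {
    w <- sample_fixed_length(ui, width = 250, seed = s)
    expect_equal(sum(w$end - w$start), 250L)
    if (nrow(w) == 2) spanning <- TRUE
  }
  expect_true(spanning)
  # gene of exactly the window width returns itself
  exact <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 0L,
                          end = 250L)
  expect_equal(sample_fixed_length(exact, 250, seed = 1), exact)
  short <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 0L,
                          end = 100L)
  expect_warning(res <- sample_fixed_length(short, 250, seed = 1),
                 "ineligible")
  expect_equal(nrow(res), 0)
})

test_that("GTF annotation and BED/SAM alignments read correctly", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttest\texon\t101\t200\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1";'),
    paste0("chr1\ttest\tCDS\t121\t180\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1";'),
    paste0("chr1\ttest\texon\t301\t400\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "gB.t1";')
  ), gtf)
  ann <- read_gtf_annotation(gtf)
  expect_equal(nrow(ann), 2)
  # GTF is 1-based inclusive; internal coordinates 0-based half-open
  expect_equal(ann$start[ann$gene_id == "gA"], 100L)
  expect_equal(ann$end[ann$gene_id == "gA"], 200L)
  expect_true(ann$coding[ann$gene_id == "gA"])
  expect_false(ann$coding[ann$gene_id == "gB"])

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t45\tr1\t0\t+", "chr2\t99\t134\tr2\t0\t-"), bed)
  al <- read_alignments_bed(bed, lane_id = "L1")
  expect_equal(al$start, c(10L, 99L))
  expect_equal(al$end, c(45L, 134L))

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t11\t42\t35M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t101\t3\t10M5N25M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), sam)
  al <- read_alignments_sam(sam, lane_id = "L1", min_mapq = 10)
  expect_equal(nrow(al), 2) # unmapped r3 skipped
  expect_equal(al$start, c(10L, 100L))
  expect_equal(al$end[1], 45L)
  expect_equal(al$end[2], 100L + 10L + 5L + 25L) # N consumes reference
  expect_equal(al$strand, c("+", "-"))
  expect_equal(al$unique, c(TRUE, FALSE)) # mapq threshold
})

test_that("UI regions write as BED6", {
  ui <- build_ui_genes(toy_ann())
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(ui, path)
  lines <- readLines(path)
  expect_length(lines, nrow(ui))
  expect_match(lines[1], "^chr1\t0\t100\tgA\t0")
})
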