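#' Simulation configuration
#'
#' Describes a synthetic multi-lane two-condition sequencing experiment.
#' Counts are generated as `X_ij ~ Poisson(d_i * lambda_{a(i),j} *
#' exp(theta_i))`: per-gene condition expression levels `lambda`, known lane
#' depths `d_i`, and optional multiplicative flow-cell / library-preparation
#' effects shared across genes.
#'
#' Defaults emulate a two-flow-cell reference-sample comparison: 14 lanes
#' (7 per condition, conditions split across two flow-cells, one library
#' preparation per condition), baseline expression log-normal with
#' `sdlog = 1.645` — heavy-tailed so that the top 5% of genes carry roughly
#' half of the total counts — and lane depths of 200,000 reads with 20%
#' lane-to-lane spread.  Differentially expressed genes receive symmetric
#' log-fold-changes: `lambda` of the first condition is multiplied by
#' `exp(lfc/2)` and of the second by `exp(-lfc/2)`, so `lfc` equals the
#' condition contrast reported by [run_de()].
#'
#' @param n_genes Number of genes.
#' @param lanes Tibble with `lane_id`, `condition`, `flow_cell`,
#'   `library_prep`, `depth`; `NULL` for the default 14-lane layout.
#' @param mean_depth Mean lane depth when `lanes` is `NULL`.
#' @param expression_sdlog Log-normal scale of baseline expression.
#' @param de_fraction Fraction of genes differentially expressed.
#' @param lfc_law Function `n -> n` signed log-fold-changes for DE genes.
#' @param highcount_de_bias If `TRUE`, DE genes are the highest-expression
#'   genes and all share one direction (up in the first condition).
#' @param flowcell_effect_sd,libprep_effect_sd Log-scale SDs of the
#'   multiplicative technical effects (0 disables them).
#' @param length_law Function `n -> n` gene lengths in bases.
#' @param counts_per_base If `TRUE`, expected counts are proportional to gene
#'   length (expression is per-base).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       lanes = NULL,
                       mean_depth = 2e5,
                       expression_sdlog = 1.645,
                       de_fraction = 0,
                       lfc_law = function(n) sample(c(-1, 1), n, TRUE) *
                         runif(n, 0.5, 4),
                       highcount_de_bias = FALSE,
                       flowcell_effect_sd = 0,
                       libprep_effect_sd = 0,
                       length_law = function(n) pmax(
                         250L, as.integer(round(rlnorm(n, log(1500), 0.6)))),
                       counts_per_base = FALSE) {
  if (is.null(lanes)) {
    lanes <- tibble(
      lane_id = sprintf("L%02d", 1:14),
      condition = rep(c("A", "B"), each = 7),
      flow_cell = rep(rep(c("FC1", "FC2"), c(4, 3)), 2),
      library_prep = rep(c("LPA", "LPB"), each = 7),
      depth = rep(mean_depth, 14) # jittered at simulate time
    )
  }
  stopifnot(n_genes >= 1, de_fraction >= 0, de_fraction <= 1,
            all(lanes$depth > 0))
  structure(list(n_genes = n_genes, lanes = lanes, mean_depth = mean_depth,
                 expression_sdlog = expression_sdlog,
                 de_fraction = de_fraction, lfc_law = lfc_law,
                 highcount_de_bias = highcount_de_bias,
                 flowcell_effect_sd = flowcell_effect_sd,
                 libprep_effect_sd = libprep_effect_sd,
                 length_law = length_law,
                 counts_per_base = counts_per_base),
            class = "sim_config")
}

#' Simulate a gene-by-lane count table with known truth
#'
#' Draws Poisson counts under the configuration's generative model.  All
#' randomness flows from `seed` in a fixed substream order (depth jitter,
#' lengths, expression, DE assignment, technical effects, counts), so the
#' same seed regenerates the identical bundle.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required).
#' @return List with `counts` (count table with `length` column),
#'   `lane_info`, and `truth` (per-gene `lambda_A`, `lambda_B`, `lfc`, `de`,
#'   `length`; per-lane effects as attribute `lane_effects`).
#' @export
simulate_counts <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("seed required")
  withr_seed(seed, {
    lanes <- config$lanes
    # depth jitter unless explicit depths were supplied
    if (!is.null(config$mean_depth) && all(lanes$depth == lanes$depth[1])) {
      lanes$depth <- config$mean_depth * exp(rnorm(nrow(lanes), 0, 0.2))
    }
    n <- config$n_genes
    len <- config$length_law(n)
    base <- rlnorm(n, meanlog = 0, sdlog = config$expression_sdlog)
    if (config$counts_per_base) base <- base * len
    rel <- base / sum(base)
    n_de <- round(config$de_fraction * n)
    de <- rep(FALSE, n)
    lfc <- numeric(n)
    if (n_de > 0) {
      idx <- if (config$highcount_de_bias) order(rel,
                                                 decreasing = TRUE)[1:n_de]
      else sample.int(n, n_de)
      de[idx] <- TRUE
      lfc[idx] <- if (config$highcount_de_bias) {
        abs(config$lfc_law(n_de))
      } else config$lfc_law(n_de)
    }
    conds <- sort(unique(lanes$condition))
    lamA <- rel * exp(lfc / 2)
    lamB <- rel * exp(-lfc / 2)
    theta <- lane_effects(lanes, config)
    mu <- outer(lamA, lanes$depth * exp(theta))
    isB <- lanes$condition == conds[2]
    mu[, isB] <- outer(lamB, (lanes$depth * exp(theta))[isB])
    x <- matrix(rpois(length(mu), mu), nrow = n)
    counts <- tibble(gene_id = sprintf("g%05d", seq_len(n)),
                     length = len)
    for (j in seq_len(nrow(lanes))) counts[[lanes$lane_id[j]]] <- x[, j]
    counts <- validate_counts(counts)
    lane_info <- tibble(lane_id = lanes$lane_id,
                        condition = lanes$condition,
                        flow_cell = lanes$flow_cell,
                        library_prep = lanes$library_prep,
                        total_count = colSums(x))
    truth <- tibble(gene_id = counts$gene_id,
                    lambda_A = lamA, lambda_B = lamB,
                    lfc = lfc, de = de, length = len)
    attr(truth, "lane_effects") <- tibble(lane_id = lanes$lane_id,
                                          depth = lanes$depth,
                                          theta = theta)
    list(counts = counts, lane_info = lane_info, truth = truth)
  })
}

lane_effects <- function(lanes, config) {
  theta <- numeric(nrow(lanes))
  if (config$flowcell_effect_sd > 0) {
    fc <- factor(lanes$flow_cell)
    theta <- theta + rnorm(nlevels(fc), 0,
                           config$flowcell_effect_sd)[as.integer(fc)]
  }
  if (config$libprep_effect_sd > 0) {
    lp <- factor(paste(lanes$flow_cell, lanes$library_prep))
    theta <- theta + rnorm(nlevels(lp), 0,
                           config$libprep_effect_sd)[as.integer(lp)]
  }
  theta
}

#' Simulate a noisy gold-standard table
#'
#' Emulates an independent assay (qRT-PCR style) of the true log-fold-changes:
#' measured log-ratio = truth + Gaussian noise.
#'
#' @param truth Truth tibble from [simulate_counts()].
#' @param noise_sd Measurement noise SD on the natural-log scale.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `log_ratio`.
#' @export
simulate_gold <- function(truth, noise_sd = 0.25, seed) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (missing(seed)) abort("seed required")
  withr_seed(seed, tibble(gene_id = truth$gene_id,
                          log_ratio = truth$lfc +
                            rnorm(nrow(truth), 0, noise_sd)))
}

#' Simulate aligned reads over UI genes
#'
#' Draws a Poisson number of reads per gene and places each read's start
#' uniformly along the gene's UI bases (mapped back to genomic coordinates),
#' with a fixed read length.  Emitted as a coordinate-sorted alignment
#' tibble writable with [write_bed()].  Genes whose UI length is below the
#' read length are skipped with a warning.
#'
#' @param ui_genes UI-region tibble.
#' @param expected_counts Named numeric vector of per-gene expected read
#'   counts (names = gene ids).
#' @param lane_id Lane label for the records.
#' @param read_length Read length in bases (default 35).
#' @param seed Integer seed.
#' @return Alignment tibble (`read_id`, `lane_id`, `chrom`, `start`, `end`,
#'   `strand`, `unique`), sorted by `chrom`, `start`.
#' @export
simulate_reads <- function(ui_genes, expected_counts, lane_id,
                           read_length = 35, seed) {
  if (missing(seed)) abort("seed required")
  lens <- ui_lengths(ui_genes)
  withr_seed(seed, {
    recs <- lapply(seq_len(nrow(lens)), function(i) {
      g <- lens$gene_id[i]
      mu <- if (g %in% names(expected_counts)) expected_counts[[g]] else 0
      if (mu <= 0) return(NULL)
      if (lens$length[i] < read_length) {
        warn(sprintf("gene '%s' UI length < read length; skipped", g))
        return(NULL)
      }
      nr <- rpois(1, mu)
      if (nr == 0) return(NULL)
      regions <- arrange(ui_genes[ui_genes$gene_id == g, , drop = FALSE],
                         .data$start)
      starts_ui <- sample.int(lens$length[i] - read_length + 1L, nr,
                              replace = TRUE) - 1L
      # genomic position of each UI base offset
      offs <- cumsum(c(0L, regions$end - regions$start))
      seg <- findInterval(starts_ui, offs, rightmost.closed = FALSE)
      gstart <- regions$start[seg] + (starts_ui - offs[seg])
      tibble(read_id = sprintf("%s_%s_r%05d", lane_id, g, seq_len(nr)),
             lane_id = lane_id,
             chrom = regions$chrom[seg],
             start = gstart,
             end = gstart + read_length,
             strand = sample(c("+", "-"), nr, replace = TRUE),
             unique = TRUE)
    })
    out <- bind_rows(recs)
    if (!nrow(out)) {
      out <- tibble(read_id = character(), lane_id = character(),
                    chrom = character(), start = integer(), end = integer(),
                    strand = character(), unique = logical())
    }
    arrange(out, .data$chrom, .data$start)
  })
}

#' Canned scenario: highly expressed genes bias total-count normalization
#'
#' Builds the situation in which global total-count scaling misleads: a small
#' fraction of genes (default 5%) carries roughly half of all reads and is
#' over-expressed in one condition, so lane totals differ between conditions
#' for purely biological reasons.  Total-count factors then absorb the shift
#' and bias the log-fold-change estimates of the null majority away from
#' zero, while the upper-quartile factors — driven by the bulk of the
#' distribution, which the high-count genes never cross — do not.  The
#' high-count genes' shifts span the conventional DE threshold, so a gold
#' standard built from the truth contains both DE and non-DE genes and ROC
#' curves are well defined.
#'
#' `de_fraction > 0` additionally makes a slice of ordinary genes strongly
#' DE in both directions.  Note that widespread strong DE — even
#' direction-balanced — slightly shifts the per-lane upper quartile itself
#' (more genes cross the quartile upward than downward), so the
#' upper-quartile factors are exactly unbiased only when the DE mass sits
#' above the quartile; see the methods vignette.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param bias If `FALSE`, the high-count genes are not DE (control).
#' @param de_fraction Fraction of ordinary genes strongly DE (default 0).
#' @param gold_noise_sd Gold-standard measurement noise.
#' @return List with `counts`, `lane_info`, `truth`, `gold`, and `config`.
#' @export
scenario_highcount_bias <- function(seed, n_genes = 2000, bias = TRUE,
                                    de_fraction = 0,
                                    gold_noise_sd = 0.05) {
  cfg <- sim_config(n_genes = n_genes, expression_sdlog = 1.645)
  bundle <- withr_seed(seed, {
    sim <- simulate_counts(cfg, seed = seed + 1L)
    truth <- sim$truth
    n <- nrow(truth)
    top <- order(truth$lambda_A + truth$lambda_B,
                 decreasing = TRUE)[seq_len(round(0.05 * n))]
    ordinary <- setdiff(seq_len(n), top)
    de_idx <- if (de_fraction > 0) {
      sample(ordinary, round(de_fraction * length(ordinary)))
    } else integer(0)
    lfc <- numeric(n)
    if (bias) lfc[top] <- runif(length(top), 1.5, 3.0)
    lfc[de_idx] <- sample(c(-1, 1), length(de_idx), TRUE) *
      runif(length(de_idx), 2.2, 4)
    truth$lfc <- lfc
    truth$de <- lfc != 0
    truth$lambda_A <- truth$lambda_A * exp(lfc / 2)
    truth$lambda_B <- truth$lambda_B * exp(-lfc / 2)
    # regenerate counts under the adjusted rates with the original depths
    eff <- attr(sim$truth, "lane_effects")
    muA <- outer(truth$lambda_A, eff$depth)
    muB <- outer(truth$lambda_B, eff$depth)
    isB <- sim$lane_info$condition == "B"
    mu <- muA
    mu[, isB] <- muB[, isB]
    x <- matrix(rpois(length(mu), mu), nrow = n)
    counts <- sim$counts
    for (j in seq_along(eff$lane_id)) counts[[eff$lane_id[j]]] <- x[, j]
    counts <- validate_counts(counts)
    lane_info <- sim$lane_info
    lane_info$total_count <- colSums(x)
    gold <- simulate_gold(truth, noise_sd = gold_noise_sd, seed = seed + 2L)
    list(counts = counts, lane_info = lane_info, truth = truth, gold = gold,
         config = cfg)
  })
  bundle
}

#' Canned scenario: gene-length bias of DE statistics
#'
#' Counts proportional to gene length with small-to-moderate per-gene effects
#' (log-fold-changes drawn from `N(0, 0.5)`, the "nearly every gene slightly
#' DE" regime typical of reference-sample comparisons).  Longer genes give
#' larger counts, hence smaller standard errors and larger |t| for the same
#' effect — the length bias that inverse-square-root-length weighting and
#' fixed-width resampling remove.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param lfc_sd SD of the per-gene log-fold-changes.
#' @return List with `counts`, `lane_info`, `truth`.
#' @export
scenario_length_bias <- function(seed, n_genes = 500, lfc_sd = 0.5) {
  cfg <- sim_config(
    n_genes = n_genes,
    expression_sdlog = 0,
    de_fraction = 1,
    lfc_law = function(n) rnorm(n, 0, lfc_sd),
    length_law = function(n) as.integer(round(runif(n, 250, 5000))),
    counts_per_base = TRUE,
    mean_depth = 2e5
  )
  simulate_counts(cfg, seed = seed)
}
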