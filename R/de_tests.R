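#' Fisher's exact test for differential expression of one gene
#'
#' Compares the split of a gene's pooled reads between two conditions to the
#' split of the normalization offsets: the 2x2 table is
#' `rbind(c(xA, xB), c(round(dA) - xA, round(dB) - xB))` and the p-value is
#' the exact two-sided hypergeometric probability.  The two-sided rule is the
#' minimum-likelihood convention: sum the probabilities of all tables (fixed
#' margins) no more probable than the observed one, with a `1 + 1e-7`
#' relative guard for floating-point ties (the convention of
#' [stats::fisher.test()]).
#'
#' @param xA,xB Pooled condition counts for the gene.
#' @param dA,dB Pooled condition offsets (rescaled normalization factors
#'   summed per condition); rounded to integers for the table margins.
#' @param gene_id Optional gene label.
#' @return A one-row tibble: `gene_id`, `statistic` (the observed table
#'   probability), `df`, `p_value`, `direction`, `method`, `flag`.
#' @export
fisher_exact_de <- function(xA, xB, dA, dB, gene_id = NA_character_) {
  rdA <- round(dA); rdB <- round(dB)
  if (rdA - xA < 0 || rdB - xB < 0) {
    abort("offsets are smaller than gene counts: inconsistent factors")
  }
  p <- fisher_two_sided_p(xA, xB, rdA, rdB)
  est <- log((xA / dA) / (xB / dB))
  tibble(gene_id = gene_id,
         statistic = dhyper(xA, rdA, rdB, xA + xB),
         df = NA_integer_,
         p_value = p,
         direction = direction_of(ifelse(xA + xB == 0, NA_real_, est)),
         method = "fisher",
         flag = NA_character_)
}

# minimum-likelihood two-sided hypergeometric p for one table
fisher_two_sided_p <- function(xA, xB, rdA, rdB) {
  k <- xA + xB
  lo <- max(0, k - rdB)
  hi <- min(k, rdA)
  support <- lo:hi
  dens <- dhyper(support, rdA, rdB, k)
  obs <- dens[support == xA]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Mantel-Haenszel test across strata
#'
#' Combines per-stratum 2x2 tables (one per flow-cell, built exactly as in
#' [fisher_exact_de()] with per-stratum offsets) into the Cochran
#' Mantel-Haenszel chi-square statistic with one degree of freedom and no
#' continuity correction.  A single stratum reduces to the ordinary 1-df
#' chi-square of that table.  Strata with a zero margin carry no information
#' and are dropped with a warning.
#'
#' @param strata Tibble with one row per stratum and columns `xA`, `xB`,
#'   `dA`, `dB`.
#' @param gene_id Optional gene label.
#' @return A one-row tibble as in [fisher_exact_de()], `method = "mh"`;
#'   `direction` comes from the Mantel-Haenszel common odds ratio.
#' @export
mantel_haenszel_de <- function(strata, gene_id = NA_character_) {
  need <- c("xA", "xB", "dA", "dB")
  if (!all(need %in% names(strata))) {
    abort("strata must have columns xA, xB, dA, dB")
  }
  a <- strata$xA
  b <- strata$xB
  c_ <- round(strata$dA) - a
  d_ <- round(strata$dB) - b
  if (any(c_ < 0 | d_ < 0)) {
    abort("offsets are smaller than gene counts: inconsistent factors")
  }
  n <- a + b + c_ + d_
  keep <- (a + b) > 0 & (c_ + d_) > 0 & (a + c_) > 0 & (b + d_) > 0 & n > 1
  if (!all(keep)) {
    warn(sprintf("dropping %d stratum/strata with a zero margin",
                 sum(!keep)))
  }
  if (!any(keep)) abort("all strata have a zero margin")
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]; d_ <- d_[keep]; n <- n[keep]
  e <- (a + b) * (a + c_) / n
  v <- (a + b) * (c_ + d_) * (a + c_) * (b + d_) / (n^2 * (n - 1))
  stat <- (sum(a - e))^2 / sum(v)
  or_num <- sum(a * d_ / n)
  or_den <- sum(b * c_ / n)
  est <- log(or_num) - log(or_den)
  tibble(gene_id = gene_id,
         statistic = stat,
         df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         direction = direction_of(ifelse(or_num + or_den == 0, NA_real_,
                                         est)),
         method = "mh",
         flag = if (all(keep)) NA_character_ else "dropped_strata")
}

#' Weight t statistics by inverse square-root gene length
#'
#' Longer genes accumulate more reads and therefore smaller standard errors,
#' so unweighted t statistics rank long genes ahead of short genes with equal
#' effects.  Dividing each t statistic by `sqrt(length)` removes the length
#' dependence of the ranking; p-values are recomputed from the normal
#' reference.
#'
#' @param result A result tibble from a t-family test (`t_glm` or `t_delta`).
#' @param length Per-gene length in bases, aligned with `result` rows.
#' @return The result tibble with weighted `statistic` and `p_value`, and
#'   `method` suffixed `"_lw"`.
#' @export
weight_by_length <- function(result, length) {
  if (!all(result$method %in% c("t_glm", "t_delta"))) {
    abort("length weighting applies to t-family statistics only")
  }
  if (length(length) != nrow(result) || anyNA(length) || any(length < 1)) {
    abort("length must be >= 1 for every result row")
  }
  result$statistic <- result$statistic / sqrt(length)
  result$p_value <- 2 * pnorm(-abs(result$statistic))
  result$p_value[result$flag %in% "zero_count"] <- 1
  result$method <- paste0(result$method, "_lw")
  result
}

#' Low-count gene filter
#'
#' Flags genes whose pooled read count in either condition falls below a
#' threshold (default 20 reads).  Removing such genes restores the
#' sensitivity of t statistics, which cannot handle zero or very low counts.
#'
#' @param counts A count table with two conditions in `lane_info`.
#' @param lane_info Lane metadata.
#' @param threshold Minimum pooled reads required in *both* conditions;
#'   genes with strictly fewer in either condition are dropped.
#' @return Tibble with `gene_id`, pooled counts per condition, and `keep`.
#' @export
filter_low_count <- function(counts, lane_info, threshold = 20) {
  pooled <- pool_lanes(counts, lane_info, "condition")
  conds <- lane_ids(pooled)
  if (length(conds) != 2) abort("low-count filter requires two conditions")
  tibble(gene_id = pooled$gene_id,
         pooled_1 = pooled[[conds[1]]],
         pooled_2 = pooled[[conds[2]]],
         keep = pooled[[conds[1]]] >= threshold &
           pooled[[conds[2]]] >= threshold)
}

#' Fixed-length count resampling
#'
#' Replaces each gene's counts by the counts falling in a fixed-length
#' subregion: given a gene total `x` and uniform read placement along the
#' gene, the count in a window of `width` bases is `Binomial(x, width /
#' length)`.  Genes shorter than `width` are dropped.  Used to show that the
#' length dependence of DE statistics is a property of gene length, not of
#' expression level.
#'
#' @param counts Count table with a `length` column.
#' @param width Window width in bases (default 250).
#' @param seed Integer seed; resampling is deterministic given the seed.
#' @return A count table with `length` set to `width` for the retained genes.
#' @export
resample_fixed_length_counts <- function(counts, width = 250, seed) {
  counts <- validate_counts(counts)
  if (!"length" %in% names(counts)) abort("gene lengths required")
  if (missing(seed)) abort("seed required")
  keep <- counts$length >= width
  out <- counts[keep, , drop = FALSE]
  lanes <- lane_ids(out)
  withr_seed(seed, {
    for (ln in lanes) {
      out[[ln]] <- as.integer(stats::rbinom(nrow(out), out[[ln]],
                                            width / out$length))
    }
  })
  out$length <- as.integer(rep(width, nrow(out)))
  out
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run a differential-expression test on every gene
#'
#' Batch driver applying one test per gene between the two biological
#' conditions.  GLM-based statistics (`"lr"`, `"t_glm"`) use per-lane counts
#' with per-lane offsets `log d_i`; `"t_delta"` and `"fisher"` pool counts and
#' offsets by condition; `"mh"` pools within condition and flow-cell and
#' combines flow-cell strata.  Per-gene failures are recorded in the `flag`
#' column, never aborting the batch.
#'
#' @param counts A count table.
#' @param lane_info Lane metadata with exactly two conditions.
#' @param factors Factor tibble (see [total_count_factors()]).
#' @param method One of `"lr"`, `"t_glm"`, `"t_delta"`, `"fisher"`, `"mh"`.
#' @param design Full design for the GLM methods (see [fit_poisson_glm()]).
#' @param filter_min If non-`NULL`, drop genes with pooled count below this in
#'   either condition before testing.
#' @param weight_length Divide t-family statistics by `sqrt(length)`.
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column `p_adj`.
#' @return A tibble with one row per (retained) gene, in input order:
#'   `gene_id`, `statistic`, `df`, `p_value`, `direction`, `method`, `flag`,
#'   `estimate` (condition log-fold-change where defined), and `p_adj`.
#' @export
run_de <- function(counts, lane_info, factors,
                   method = c("lr", "t_glm", "t_delta", "fisher", "mh"),
                   design = "condition", filter_min = NULL,
                   weight_length = FALSE, adjust = TRUE) {
  method <- match.arg(method)
  counts <- validate_counts(counts)
  lane_info <- validate_lane_info(lane_info)
  conds <- sort(unique(lane_info$condition))
  if (length(conds) != 2) abort("run_de requires exactly two conditions")
  if (!is.null(filter_min)) {
    mask <- filter_low_count(counts, lane_info, filter_min)
    counts <- counts[mask$keep, , drop = FALSE]
  }
  lanes <- lane_info$lane_id
  d <- factor_lookup(factors, lanes)
  m <- count_matrix(counts, lanes)
  est <- de_estimates(m, lane_info, d, conds)

  res <- switch(
    method,
    lr = glm_batch(m, lane_info, factors, design, lr = TRUE),
    t_glm = glm_batch(m, lane_info, factors, design, lr = FALSE),
    t_delta = bind_rows(lapply(seq_len(nrow(m)), function(j) {
      per_gene_safely(rownames(m)[j], "t_delta",
                      t_statistic_delta(est$xA[j], est$xB[j], est$dA,
                                        est$dB, gene_id = rownames(m)[j]))
    })),
    fisher = bind_rows(lapply(seq_len(nrow(m)), function(j) {
      per_gene_safely(rownames(m)[j], "fisher",
                      fisher_exact_de(est$xA[j], est$xB[j], est$dA,
                                      est$dB, gene_id = rownames(m)[j]))
    })),
    mh = mh_batch(m, lane_info, d, conds)
  )
  res$estimate <- est$lfc
  if (weight_length) {
    if (!"length" %in% names(counts)) abort("gene lengths required")
    res <- weight_by_length(res, counts$length)
  }
  if (adjust) res$p_adj <- p.adjust(res$p_value, method = "BH")
  res
}

# pooled counts/offsets and moment log-fold-change estimates per gene
de_estimates <- function(m, lane_info, d, conds) {
  inA <- lane_info$condition == conds[1]
  xA <- rowSums(m[, lane_info$lane_id[inA], drop = FALSE])
  xB <- rowSums(m[, lane_info$lane_id[!inA], drop = FALSE])
  dA <- sum(d[lane_info$lane_id[inA]])
  dB <- sum(d[lane_info$lane_id[!inA]])
  lfc <- log((xA / dA) / (xB / dB))
  lfc[xA + xB == 0] <- NA_real_
  list(xA = xA, xB = xB, dA = dA, dB = dB, lfc = unname(lfc))
}

glm_batch <- function(m, lane_info, factors, design, lr) {
  null_design <- nested_null_design(design)
  bind_rows(lapply(seq_len(nrow(m)), function(j) {
    g <- rownames(m)[j]
    full <- fit_poisson_glm(m[j, ], lane_info, factors, design, gene_id = g)
    if (lr) {
      null <- fit_poisson_glm(m[j, ], lane_info, factors, null_design,
                              gene_id = g)
      lr_test(full, null)
    } else {
      t_statistic_glm(full)
    }
  }))
}

# a per-gene failure becomes a flagged NA row, never an aborted batch
per_gene_safely <- function(gene_id, method, expr) {
  tryCatch(expr, error = function(e) {
    tibble(gene_id = gene_id, statistic = NA_real_, df = NA_integer_,
           p_value = NA_real_, direction = "0", method = method,
           flag = conditionMessage(e))
  })
}

nested_null_design <- function(design) {
  switch(design,
         condition = "null",
         condition_flowcell = "flowcell",
         libprep_within_flowcell = "flowcell_libprep",
         abort(sprintf("no nested null for design '%s'", design)))
}

mh_batch <- function(m, lane_info, d, conds) {
  strata_of <- split(lane_info, lane_info$flow_cell)
  per_stratum <- lapply(strata_of, function(li) {
    inA <- li$condition == conds[1]
    if (!any(inA) || all(inA)) return(NULL)
    list(lanesA = li$lane_id[inA], lanesB = li$lane_id[!inA])
  })
  per_stratum <- per_stratum[!vapply(per_stratum, is.null, logical(1))]
  if (!length(per_stratum)) {
    abort("no flow-cell stratum contains both conditions")
  }
  bind_rows(lapply(seq_len(nrow(m)), function(j) {
    st <- bind_rows(lapply(per_stratum, function(s) {
      tibble(xA = sum(m[j, s$lanesA]), xB = sum(m[j, s$lanesB]),
             dA = sum(d[s$lanesA]), dB = sum(d[s$lanesB]))
    }))
    tryCatch(
      suppressWarnings(mantel_haenszel_de(st, gene_id = rownames(m)[j])),
      error = function(e) {
        tibble(gene_id = rownames(m)[j], statistic = NA_real_, df = 1L,
               p_value = NA_real_, direction = "0", method = "mh",
               flag = "degenerate")
      })
  }))
}
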