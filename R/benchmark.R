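#' Classify gold-standard genes by qRT-PCR log-ratio
#'
#' Splits genes into non-DE, DE (with sign), and no-call classes from their
#' gold-standard log-fold-changes: `|lr| < a` is non-DE, `|lr| > b` is DE+
#' or DE- by sign, and `a <= |lr| <= b` is a no-call, excluded from ROC
#' accounting.  The defaults `a = 0.2`, `b = 2.0` are the thresholds
#' conventionally used when benchmarking sequencing calls against qRT-PCR
#' on reference RNA comparisons; log-ratios are on the natural
#' scale and oriented as condition A minus condition B (first condition
#' alphabetically), matching the `estimate` column of [run_de()].
#'
#' @param gold Tibble with columns `gene_id` and `log_ratio`.
#' @param a,b Non-DE and DE thresholds, `0 <= a < b`.
#' @return The tibble with an added `class` column in
#'   `{"nonDE", "DE+", "DE-", "no-call"}`.
#' @export
classify_gold <- function(gold, a = 0.2, b = 2.0) {
  if (!(a >= 0 && a < b)) abort("thresholds must satisfy 0 <= a < b")
  lr <- gold$log_ratio
  gold$class <- dplyr::case_when(
    abs(lr) < a ~ "nonDE",
    abs(lr) > b & lr > 0 ~ "DE+",
    abs(lr) > b & lr < 0 ~ "DE-",
    TRUE ~ "no-call"
  )
  gold
}

#' Confusion counts for direction-aware DE calls
#'
#' Tallies true/false positives and negatives against a classified gold
#' standard, requiring agreement in *direction* for a true positive: a DE
#' call on a gold-DE gene in the wrong direction is a false positive, a
#' non-DE call on a gold-DE gene a false negative.  No-call genes must be
#' removed beforehand (as [roc_curve()] does); genes absent from the gold
#' standard are excluded with a warning.
#'
#' @param calls Tibble with `gene_id` and `call` in
#'   `{"nonDE", "DE+", "DE-"}`.
#' @param gold Classified gold standard from [classify_gold()].
#' @return One-row tibble `TP`, `FP`, `TN`, `FN`, `P`, `N`.
#' @export
confusion_at_threshold <- function(calls, gold) {
  gold <- filter(gold, .data$class != "no-call")
  unknown <- !calls$gene_id %in% gold$gene_id
  if (any(unknown)) {
    warn(sprintf("%d gene(s) absent from gold standard excluded",
                 sum(unknown)))
    calls <- calls[!unknown, , drop = FALSE]
  }
  j <- left_join(calls, gold[c("gene_id", "class")], by = "gene_id")
  de_gold <- j$class %in% c("DE+", "DE-")
  de_call <- j$call %in% c("DE+", "DE-")
  tibble(
    TP = sum(de_gold & de_call & j$call == j$class),
    FP = sum(de_call & (!de_gold | j$call != j$class)),
    TN = sum(!de_gold & !de_call),
    FN = sum(de_gold & !de_call),
    P = sum(de_gold),
    N = sum(!de_gold)
  )
}

#' Direction-aware ROC curve against a gold standard
#'
#' Sweeps the p-value threshold over every observed value; at each threshold
#' genes with `p <= t` are called DE in their estimated direction (direction
#' `"0"` is never a positive call) and the rest non-DE.  TPR is TP divided by
#' the number of gold-DE genes; FPR is FP divided by the number of gold
#' non-DE genes.  No-call genes are ignored throughout.  The curve includes
#' the (0, 0) point and the all-called endpoint and is sorted by FPR.
#'
#' @param results DE result tibble with `gene_id`, `p_value`, `direction`.
#' @param gold Classified gold standard ([classify_gold()]), or a raw gold
#'   tibble plus `a`/`b`.
#' @param a,b Thresholds used if `gold` lacks a `class` column.
#' @return Tibble with `threshold`, `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`.
#' @export
roc_curve <- function(results, gold, a = 0.2, b = 2.0) {
  if (!"class" %in% names(gold)) gold <- classify_gold(gold, a, b)
  gold <- filter(gold, .data$class != "no-call")
  j <- dplyr::inner_join(results, gold[c("gene_id", "class")], by = "gene_id")
  j <- j[!is.na(j$p_value), , drop = FALSE]
  P <- sum(j$class %in% c("DE+", "DE-"))
  N <- sum(j$class == "nonDE")
  if (P == 0 || N == 0) abort("ROC undefined: need both DE and non-DE genes")
  dir_call <- ifelse(j$direction == "+", "DE+",
                     ifelse(j$direction == "-", "DE-", "nonDE"))
  callable <- dir_call != "nonDE"
  gold_de <- j$class %in% c("DE+", "DE-")
  correct <- callable & gold_de & dir_call == j$class
  # sweep: gene becomes a positive call once threshold >= its p-value
  thresholds <- sort(unique(j$p_value))
  ord <- order(j$p_value)
  p_sorted <- j$p_value[ord]
  tp_inc <- cumsum((correct & callable)[ord])
  fp_inc <- cumsum((callable & !correct)[ord])
  idx <- findInterval(thresholds, p_sorted)
  TP <- tp_inc[idx]
  FP <- fp_inc[idx]
  out <- tibble(threshold = c(-Inf, thresholds),
                TP = c(0L, TP), FP = c(0L, FP))
  out$FN <- P - out$TP
  # TN counts gold-nonDE genes not called DE; FP additionally includes
  # wrong-direction calls on gold-DE genes, so TN is tracked separately
  fp_on_null <- cumsum((callable & !gold_de)[ord])
  out$TN <- N - c(0L, fp_on_null[idx])
  out$TPR <- out$TP / P
  out$FPR <- out$FP / N
  arrange(out, .data$FPR, .data$TPR)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) step curve, computed over the
#' observed FPR range.
#'
#' @param roc ROC tibble from [roc_curve()].
#' @return Scalar area.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$FPR, roc$TPR)
  x <- roc$FPR[o]
  y <- roc$TPR[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Poisson goodness-of-fit over replicate lanes
#'
#' For each gene, fits the offset-only Poisson model to the replicate lanes
#' of one condition (fitted mean `d_i * lambda_hat` with
#' `lambda_hat = sum(x) / sum(d)`) and returns the Pearson chi-square
#' statistic with `lanes - 1` degrees of freedom, plus the matching
#' theoretical chi-square quantile for QQ display.  Genes with zero counts in
#' every lane are excluded.  Under lane-level Poisson variation the
#' statistics follow the chi-square reference; systematic departures indicate
#' extra-Poisson technical variation or a poor normalization.
#'
#' @param counts A count table.
#' @param lane_info Lane metadata.
#' @param factors Factor tibble.
#' @param condition Condition whose replicate lanes are assessed (default:
#'   all lanes in `lane_info`).
#' @return Tibble with `gene_id`, `statistic`, `df`, `theoretical_quantile`,
#'   sorted as input (all-zero genes dropped).
#' @export
poisson_gof <- function(counts, lane_info, factors, condition = NULL) {
  counts <- validate_counts(counts)
  lane_info <- validate_lane_info(lane_info)
  if (!is.null(condition)) {
    lane_info <- filter(lane_info, .data$condition == !!condition)
  }
  if (nrow(lane_info) < 2) abort("goodness-of-fit needs >= 2 replicate lanes")
  lanes <- lane_info$lane_id
  d <- factor_lookup(factors, lanes)
  m <- count_matrix(counts, lanes)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  lambda <- rowSums(m) / sum(d)
  mu <- outer(lambda, d)
  stat <- rowSums((m - mu)^2 / mu)
  df <- length(lanes) - 1L
  out <- tibble(gene_id = rownames(m), statistic = unname(stat),
                df = df)
  r <- rank(out$statistic, ties.method = "first")
  out$theoretical_quantile <- qchisq((r - 0.5) / nrow(out), df = df)
  out
}

#' Sequencing error-rate proxy from read categories
#'
#' Given counts of purity-filtered reads mapping with up to two mismatches
#' (FMM) and the perfectly matching subset (FPM), the fraction
#' `(FMM - FPM) / FMM` is a rough estimate of the sequencing error rate
#' (assuming no SNPs).  Vectorised; `fmm = 0` yields `NA` with a flag.
#'
#' @param fmm,fpm Non-negative counts with `fpm <= fmm` elementwise.
#' @return Tibble with `fmm`, `fpm`, `error_rate`, `flag`.
#' @export
error_rate_proxy <- function(fmm, fpm) {
  if (any(fpm > fmm)) abort("fpm must not exceed fmm")
  if (any(fmm < 0 | fpm < 0)) abort("counts must be non-negative")
  er <- ifelse(fmm == 0, NA_real_, (fmm - fpm) / fmm)
  tibble(fmm = fmm, fpm = fpm, error_rate = er,
         flag = ifelse(fmm == 0, "undefined", NA_character_))
}
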