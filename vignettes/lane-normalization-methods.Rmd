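---
title: "Normalization and differential expression for lane-based mRNA-Seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization and differential expression for lane-based mRNA-Seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laneseq)
library(tibble)
```

## The model

An mRNA-Seq experiment on a multi-lane sequencer produces, after read
mapping and gene-level counting, a table of counts $X_{ij}$ for gene $j$ in
lane $i$.  Lanes differ in sequencing depth and possibly in flow-cell and
library-preparation batch, so raw counts are not comparable between lanes.
laneseq works throughout with the Poisson log-linear model

$$\log \mathbb{E}[X_{ij}] \;=\; \lambda_{a(i),j} \;+\; \theta_{ij} \;+\; \log d_i,$$

where $a(i)$ is the biological condition assayed in lane $i$,
$\lambda_{a(i),j}$ the gene's log expression level in that condition,
$\theta_{ij}$ optional technical effects (flow-cell, library preparation),
and $d_i$ a known per-lane scale entering as an offset.  The Poisson
assumption is appropriate for *technical* replicate lanes of one RNA
sample; biological replicates are over-dispersed and outside this package's
scope (a negative-binomial extension would be the natural follow-on).

Two consequences of the model shape the whole package:

* counts may be **pooled across lanes by summation** (sums of independent
  Poissons are Poisson), which is how the exact and delta-method tests
  collapse the lanes of a condition;
* the offsets $d_i$ **define the null hypothesis**: a gene whose counts are
  proportional to $d$ across lanes is non-differentially expressed, so the
  choice of normalization is a modelling decision, not a preprocessing
  detail.

## Normalization

Three global (single-factor-per-lane) scalings are provided, all rescaled
so that $\sum_i d_i$ equals the grand total count, which fixes the
arbitrary common multiple without changing any between-lane ratio:

* **total-count** — $d_i \propto$ lane totals; the RPKM convention;
* **housekeeping** — $d_i \propto$ the counts of one gene of presumed
  constant expression (POLR2A is the classical choice);
* **upper-quartile** — $d_i \propto$ the 75th percentile of the lane's
  counts over genes with reads in at least one lane.  The median is
  uninformative for typical count tables (it sits in the zero/low-count
  mass), so the upper quartile is the lowest convenient quantile that
  tracks sequencing effort.  The quantile estimator is the type-7
  (linear-interpolation) convention, fixed for determinism.

Lane totals are dominated by a small number of extremely highly expressed
genes — in the package's default synthetic conditions the top 5% of genes
carry roughly half of all reads, matching what reference RNA samples show.
If those few genes are differentially expressed, total-count factors absorb
a biological signal into the presumed-technical scale and bias the
log-fold-change estimates of every other gene; the upper quartile, which
those genes sit far above, does not.  `scenario_highcount_bias()` generates
exactly this situation with known truth, and the acceptance suite verifies
both the bias under total-count factors and its absence under
upper-quartile factors, together with the resulting ROC ordering.

**Full quantile normalization** forces all lanes onto one count
distribution: the reference at each rank is the median across lanes of the
rank-th smallest count, and each lane's counts are replaced by the
reference values at their ranks, rounded half-away-from-zero back to
integers so the count-based tests below remain applicable.  Genes with zero
reads in every lane are excluded from the rank computation and stay at
zero.  Ties admit two conventions, and the difference matters:

* `ties = "sequential"` (default) assigns the reference order statistics
  position by position, ties broken by input order.  Every lane's sorted
  vector then *equals* the reference exactly, so the defining invariant of
  quantile normalization holds to rounding precision.
* `ties = "mean"` gives tied counts the mean reference over their tied
  ranks (the microarray convention).  This is symmetric in the tied genes
  but flattens reference gaps wherever a tie spans one, so lanes share the
  reference only approximately — on realistic heavy-tailed count matrices
  the sorted vectors can disagree by tens of counts at sparse high ranks.

The default favours the exact distribution-matching invariant; the mean
rule is retained for users who prefer symmetric treatment of ties.  Either
way the procedure is idempotent to within one count per entry.

`per_length_measure()` provides the RPKM-style readout
$x / (d/10^6) / (L/10^3)$ for any factor set.

## Differential-expression tests

Five per-gene statistics compare two conditions, all consuming the same
factors as offsets:

* **likelihood ratio** (`lr`): $2(\ell_\text{full} - \ell_\text{null})$
  between nested Poisson fits, $\chi^2$ reference.  Fitting uses base R's
  IRLS (`glm.fit`) with the closed-form group MLEs
  $\hat\lambda_g = \sum_{i \in g} x_i / \sum_{i \in g} d_i$ as an exactness
  check in the tests (agreement to $10^{-8}$ relative).  A condition with
  all-zero counts pushes its coefficient to the boundary; the fit is
  flagged rather than failed, and the LR statistic remains finite and
  informative.
* **GLM Wald t** (`t_glm`): condition contrast over its standard error from
  the observed-information covariance.
* **delta-method t** (`t_delta`): on condition-pooled counts,
  $[\log(x_A/d_A) - \log(x_B/d_B)] / \sqrt{1/x_A + 1/x_B}$.
* **Fisher's exact test** (`fisher`): the gene's pooled counts against the
  pooled offsets in a 2×2 table, two-sided by the minimum-likelihood rule
  (sum of all table probabilities not exceeding the observed one, with a
  $1 + 10^{-7}$ relative guard for floating-point ties — the same
  convention as `stats::fisher.test`, which serves as the independent
  oracle in the tests).  Offsets are rounded to integers for the margins.
* **Mantel-Haenszel** (`mh`): the Cochran-Mantel-Haenszel 1-df chi-square
  (no continuity correction) over per-flow-cell 2×2 tables, for a condition
  effect adjusted for flow-cell as a stratification variable.  Implemented
  directly because the single-stratum case must reduce to the ordinary
  table chi-square (times the CMH's $(N-1)/N$ variance factor), which
  `stats::mantelhaen.test` — the oracle for two or more strata — declines
  to compute.  An exact stratified test is deliberately not attempted: the
  asymptotic CMH statistic is standard and well calibrated at sequencing
  depths.

The tests differ materially only at low counts.  When one condition has
zero reads, both t statistics collapse — the estimated standard error
becomes huge (Wald) or infinite (delta method) and p-values cluster at 1
regardless of the other condition's count — while the likelihood-ratio and
exact tests degrade gracefully, their p-values falling monotonically as the
nonzero count grows.  This zero-count dichotomy is asserted directly in the
acceptance suite.  `filter_low_count()` (default: at least 20 pooled reads
in *both* conditions, strict inequality excludes) removes the regime where
the t statistics fail; above it, all five tests rank genes near-identically
(rank correlation > 0.99 in the agreement test).

Directions are signed as first condition (alphabetically) minus second; a
tied estimate gets direction `"0"` and is never counted as a positive call.

## Gene-length bias

Longer genes accumulate proportionally more reads, hence smaller relative
standard errors, hence larger test statistics *for the same
log-fold-change*.  Two remedies are implemented:

* `weight_by_length()` divides t statistics by $\sqrt{L}$, which removes
  the length dependence of the ranking;
* fixed-width resampling restricts every gene to the same number of bases,
  either geometrically (`sample_fixed_length()`, a contiguous window in
  UI-coordinate space, uniform start, seeded) or at the count level
  (`resample_fixed_length_counts()`): given a gene's total $x$ and uniform
  read placement, the count falling in a $w$-base window is
  $\mathrm{Binomial}(x, w/L)$, so seeded binomial thinning reproduces the
  window count distribution without re-placing reads.  The default width
  of 250 bases keeps most annotated genes eligible while equalizing
  information content.

A subtlety worth stating: under a strict point null the unweighted t
statistic is already pivotal (length-free), and weighting would *introduce*
a negative length association through the $1/\sqrt{L}$ factor.  The bias
the remedies target appears when genes carry real, mostly small effects —
the typical situation when comparing distinct reference RNAs, where hardly
any gene is exactly null.  `scenario_length_bias()` therefore draws
per-gene log-fold-changes from $\mathrm{N}(0, 0.5)$ with counts
proportional to length; on that scenario the acceptance suite shows a
clearly positive Spearman association between $|t|$ and length that both
remedies drive into the noise band ($\pm 3$ Monte-Carlo SE of zero).

## Union-intersection genes and read counting

To quantify whole-gene expression without isoform modelling, a
**union-intersection (UI) gene** is the union of the gene's constitutive
exons (bases present in *every* isoform, computed as a base-level
intersection and merged to maximal intervals) minus the coding exons of all
other genes.  Non-coding exons of neighbours do not mask.  Genes with an
empty UI region are omitted; genes annotated on several chromosomes are
skipped with a warning.  Internally all interval arithmetic runs on
IRanges/GenomicRanges with 0-based half-open coordinates, converted exactly
once at the GTF (1-based closed) and BED (0-based half-open) boundaries.

`count_reads()` counts alignments overlapping a gene's UI regions by at
least one base, strands pooled, each read at most once per gene.  The
overlap rule is deliberately the simplest auditable one; because UI
construction already removed coding overlaps between genes, a read hitting
two genes' UI regions is rare — it increments both and is visible in the
per-gene totals.  Uniqueness of mapping is mapper-specific, so the BED/SAM
readers expose a pluggable uniqueness predicate (default: minimum mapping
quality for SAM, all-unique for BED).

## Benchmarking against a gold standard

Given independent log-fold-change measurements (qRT-PCR style), genes are
classed as non-DE ($|r| < a$), DE with sign ($|r| > b$), or no-call
($a \le |r| \le b$, excluded from all accounting); the defaults $a = 0.2$,
$b = 2.0$ are the conventional benchmark thresholds.  The ROC sweep calls a
gene DE at threshold $t$ when $p \le t$, with the estimated direction, and
scores a true positive **only when the direction matches** the gold
standard; a wrong-direction call on a gold-DE gene is a false positive.
TPR divides by the gold-DE count $P$; FPR divides by the gold non-DE count
$N$ even though wrong-direction false positives arise from gold-DE genes —
the margins of the confusion table support $N$ as the denominator, and the
convention is isolated in one place should a user prefer otherwise.  The
sweep runs over the observed p-values, giving the exact step curve, with
$(0,0)$ and the all-called endpoint included.  Log-ratios are on the
natural scale and oriented like the package's condition contrast; a gold
table on another base must be converted first.

`poisson_gof()` checks the lane-level Poisson assumption itself: per gene,
the offset-only model is fit to the replicate lanes of one condition
($\hat\mu_i = d_i \hat\lambda$) and the Pearson statistic
$\sum_i (x_i - \hat\mu_i)^2 / \hat\mu_i$ is referred to
$\chi^2_{\text{lanes}-1}$, displayed as a QQ plot by `plot_gof_qq()`.  The
Pearson form (not deviance) is used because its $\chi^2$ calibration at
moderate counts is the better known of the two; all-zero genes are
excluded.  On simulated Poisson lanes the full distribution matches the
reference (Kolmogorov-Smirnov check in the acceptance suite).

`error_rate_proxy()` computes $(\mathrm{FMM} - \mathrm{FPM}) /
\mathrm{FMM}$ from counts of purity-filtered mismatch-tolerant and
perfectly matching reads, a rough sequencing error rate assuming no SNPs.

## The synthetic-data generator

`simulate_counts()` draws $X_{ij} \sim \mathrm{Poisson}(d_i\,
\lambda_{a(i),j}\, e^{\theta_i})$ under a `sim_config()`.  Defaults emulate
a two-flow-cell, 14-lane (7 per condition) reference-sample comparison:

* **depths**: 200,000 expected reads per lane with 20% log-normal
  lane-to-lane jitter — desk-scale, roughly a hundredth of a real lane, so
  the whole suite runs in minutes while per-gene counts stay in the
  realistic tens-to-thousands range;
* **expression law**: log-normal with $\sigma = 1.645$, chosen so the top
  5% of genes carry about half the total counts (the value solves
  $\Phi(\sigma - z_{0.95}) = 0.5$), reproducing the skew that makes
  total-count normalization fragile;
* **effects**: DE genes receive symmetric shifts $\pm\mathrm{lfc}/2$ so the
  truth's `lfc` equals the reported condition contrast; flow-cell and
  library-preparation multipliers are gene-shared log-normal effects,
  off by default;
* **gold standard**: truth plus Gaussian noise (`simulate_gold()`),
  emulating an independent assay;
* **reads**: `simulate_reads()` places Poisson numbers of fixed-length
  reads uniformly along UI bases, so `count_reads()` recovers the drawn
  counts exactly — the end-to-end consistency check.

All randomness flows from a single seed with a fixed substream order;
identical seeds regenerate byte-identical bundles, which the CLI smoke
tests assert on the written files.

What the generator does **not** emulate: biological (between-individual)
over-dispersion, sequence-composition effects on coverage, exon-junction
reads, positional bias along transcripts, and mapping ambiguity.  Passing
tests therefore certify the statistical machinery under the stated Poisson
model, not robustness to those real-data complications.

## Numerical and design choices

* Problem sizes in the tests and acceptance script (10,000 null genes for
  the size check; 5,000 genes × 7 lanes for goodness-of-fit calibration;
  2,000 genes for the normalization scenario; 500 genes for the
  length-bias scenario; exact-test grids stratified up to margins of 200)
  were chosen as the smallest that give the Monte-Carlo bands quoted with
  comfortable margins.
* Monte-Carlo bands are $\pm 3$ SE.  For the median log-ratio of null
  genes the SE combines the per-gene term $1.2533\,\mathrm{sd}/\sqrt{m}$
  with the factor-ratio term shared across genes (per-lane scale estimates
  are order statistics with their own sampling error, estimated from the
  spread across replicate lanes relative to the known simulated depths).
* Rounding of quantile-normalized counts is half-away-from-zero; counts
  are non-negative so this is `floor(x + 0.5)`.
* GLM fits cap at 50 IRLS iterations at tolerance $10^{-12}$; boundary
  fits are detected by coefficient magnitude > 30 on the log scale and
  flagged `converged = FALSE`.
* A known limitation of quantile-based scaling: widespread strong DE, even
  direction-balanced, shifts the upper quartile slightly (more genes cross
  it upward than downward since it sits in the upper tail), so
  upper-quartile factors are exactly unbiased only when the DE mass lies
  above the quartile — as it does for the high-count-minority scenario.
  `scenario_highcount_bias(de_fraction = ...)` exposes the effect.
* `run_de` never aborts a batch on a per-gene failure: the row is flagged
  (e.g. `zero_count`, `boundary`, or the error message) with `NA`
  statistics where nothing sensible exists.

## Session info

```{r}
sessionInfo()
```
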