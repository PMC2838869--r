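test_that("Fisher's exact test agrees with stats::fisher.test", {
  set.seed(51)
  cases <- rbind(
    expand.grid(xA = 0:6, xB = 0:6, dA = 20, dB = 35),
    data.frame(xA = c(0, 3, 10, 40), xB = c(10, 3, 1, 5),
               dA = c(1000, 50, 200, 180), dB = c(1000, 60, 150, 220))
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    r <- fisher_exact_de(cs$xA, cs$xB, cs$dA, cs$dB)
    tab <- matrix(c(cs$xA, cs$dA - cs$xA, cs$xB, cs$dB - cs$xB), 2)
    expect_equal(r$p_value, fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher test symmetry and direction", {
  expect_equal(fisher_exact_de(7, 7, 100, 100)$p_value, 1)
  a <- fisher_exact_de(3, 11, 120, 90)
  b <- fisher_exact_de(11, 3, 90, 120)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$direction, "-")
  expect_equal(b$direction, "+")
  expect_equal(fisher_exact_de(0, 0, 50, 50)$direction, "0")
  expect_error(fisher_exact_de(10, 0, 5, 50), "inconsistent")
})

test_that("zero-count genes get a p continuum from Fisher, like LR", {
  p <- vapply(1:30, function(xb) fisher_exact_de(0, xb, 1000, 1000)$p_value,
              double(1))
  expect_true(all(diff(p) < 0))
})

test_that("Mantel-Haenszel matches mantelhaen.test and reduces to the
           single-table chi-square", {
  strata <- tibble::tibble(xA = c(12, 30), xB = c(5, 18),
                           dA = c(100, 220), dB = c(90, 260))
  r <- mantel_haenszel_de(strata)
  arr <- array(0, dim = c(2, 2, 2))
  for (k in 1:2) {
    arr[, , k] <- matrix(c(strata$xA[k], strata$dA[k] - strata$xA[k],
                           strata$xB[k], strata$dB[k] - strata$xB[k]), 2)
  }
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(r$statistic, unname(mh$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, mh$p.value, tolerance = 1e-10)
  # K = 1 reduces to the 1-df chi-square of that table: the CMH variance
  # carries an (N-1)/N factor relative to the Pearson statistic
  one <- mantel_haenszel_de(strata[1, ])
  tab <- matrix(c(12, 88, 5, 85), 2)
  cs <- chisq.test(tab, correct = FALSE)
  N <- sum(tab)
  expect_equal(one$statistic, unname(cs$statistic) * (N - 1) / N,
               tolerance = 1e-10)
  # two identical balanced null tables give statistic 0
  nul <- tibble::tibble(xA = c(4, 4), xB = c(4, 4), dA = c(50, 50),
                        dB = c(50, 50))
  expect_equal(mantel_haenszel_de(nul)$statistic, 0, tolerance = 1e-12)
  # zero-margin strata are dropped with a warning; all dropped errors
  degen <- tibble::tibble(xA = c(0, 12), xB = c(0, 5), dA = c(0, 100),
                          dB = c(0, 90))
  expect_warning(r2 <- mantel_haenszel_de(degen), "zero margin")
  expect_equal(r2$statistic, one$statistic, tolerance = 1e-10)
  expect_error(suppressWarnings(mantel_haenszel_de(degen[1, ])),
               "all strata")
})

test_that("length weighting divides t statistics by sqrt(length)", {
  r <- t_statistic_delta(100, 50, 1, 1)
  w <- weight_by_length(r, 400)
  expect_equal(w$statistic, r$statistic / 20)
  expect_equal(w$method, "t_delta_lw")
  expect_equal(weight_by_length(r, 1)$statistic, r$statistic)
  expect_error(weight_by_length(fisher_exact_de(1, 2, 10, 10), 100),
               "t-family")
})

test_that("low-count filter drops genes below the pooled threshold in either
           condition", {
  counts <- tibble::tibble(gene_id = c("low", "edge", "zero", "high"),
                           L1 = c(9L, 10L, 0L, 500L),
                           L2 = c(10L, 10L, 0L, 500L),
                           L3 = c(100L, 10L, 500L, 500L),
                           L4 = c(0L, 10L, 500L, 500L))
  mask <- filter_low_count(counts, toy_lane_info(), threshold = 20)
  expect_equal(mask$keep, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(filter_low_count(counts,
                                dplyr::mutate(toy_lane_info(),
                                              condition = "A"), 20),
               "two conditions")
})

test_that("run_de produces one ordered row per gene for every method", {
  set.seed(61)
  sim <- simulate_counts(sim_config(n_genes = 40, de_fraction = 0.3),
                         seed = 62)
  f <- upper_quartile_factors(sim$counts)
  for (m in c("lr", "t_glm", "t_delta", "fisher", "mh")) {
    res <- run_de(sim$counts, sim$lane_info, f, method = m)
    expect_equal(res$gene_id, sim$counts$gene_id)
    expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
    expect_true(all(res$direction %in% c("+", "-", "0")))
    expect_equal(res$method[1], m)
  }
  # permuting gene order permutes results identically
  perm <- sample(nrow(sim$counts))
  res1 <- run_de(sim$counts, sim$lane_info, f, method = "fisher")
  res2 <- run_de(sim$counts[perm, ], sim$lane_info, f, method = "fisher")
  expect_equal(res2$p_value, res1$p_value[perm])
  # single gene gives a singleton result
  one <- run_de(sim$counts[1, ], sim$lane_info, f, method = "t_delta")
  expect_equal(nrow(one), 1)
})

test_that("BH adjustment follows the step-up procedure", {
  counts <- tibble::tibble(gene_id = sprintf("g%d", 1:4),
                           L1 = c(100L, 90L, 80L, 30L),
                           L2 = c(100L, 90L, 80L, 30L),
                           L3 = c(30L, 35L, 35L, 30L),
                           L4 = c(30L, 35L, 35L, 31L))
  res <- run_de(counts, toy_lane_info(), unit_factors(toy_lane_info()$lane_id),
                method = "lr")
  expect_equal(res$p_adj, p.adjust(res$p_value, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 1.0), "BH"),
               c(0.04, 0.04, 0.04, 1.0))
})

test_that("well-expressed genes rank near-identically under all tests", {
  set.seed(71)
  sim <- simulate_counts(sim_config(n_genes = 150, de_fraction = 0.4,
                                    expression_sdlog = 0.8,
                                    mean_depth = 3e4,
                                    lfc_law = function(n)
                                      rnorm(n, 0, 0.8)),
                         seed = 72)
  f <- total_count_factors(sim$counts)
  keep <- filter_low_count(sim$counts, sim$lane_info, 20)$keep
  counts <- sim$counts[keep, ]
  ps <- sapply(c("lr", "fisher", "t_glm", "t_delta"), function(m) {
    run_de(counts, sim$lane_info, f, method = m)$p_value
  })
  for (m in c("fisher", "t_glm", "t_delta")) {
    expect_gt(cor(rank(ps[, "lr"]), rank(ps[, m]), method = "spearman"),
              0.99)
  }
})

test_that("fixed-width count resampling is a seeded binomial thinning", {
  counts <- toy_counts()
  r1 <- resample_fixed_length_counts(counts, width = 250, seed = 5)
  r2 <- resample_fixed_length_counts(counts, width = 250, seed = 5)
  expect_equal(r1, r2)
  expect_true(all(r1$length == 250L))
  expect_false("g3" %in% r1$gene_id == FALSE) # g3 has length exactly 250
  expect_true(all(as.matrix(r1[lane_ids(r1)]) <=
                    as.matrix(counts[counts$gene_id %in% r1$gene_id,
                                     lane_ids(counts)])))
  # width equal to gene length keeps counts unchanged
  expect_equal(r1[r1$gene_id == "g3", lane_ids(r1)],
               counts[counts$gene_id == "g3", lane_ids(counts)])
})
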