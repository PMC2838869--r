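#' Fit a per-gene Poisson log-linear model with offsets
#'
#' The expected count of a gene in lane `i` is modelled on the natural-log
#' scale as the condition expression level plus the known offset `log(d_i)`
#' and, optionally, flow-cell or library-preparation effects:
#' `log E[X_i] = lambda_{a(i)} + theta_i + log(d_i)`.
#'
#' Supported designs:
#' * `"null"` — one common rate (intercept only),
#' * `"condition"` — one rate per biological condition,
#' * `"condition_flowcell"` — condition plus additive flow-cell effects,
#' * `"libprep_within_flowcell"` — condition plus library-preparation effects
#'   nested within flow-cell.
#'
#' Fitting uses iteratively reweighted least squares
#' ([stats::glm.fit()]); for the null and two-group designs the maximum
#' likelihood estimates have the closed form `sum(counts)/sum(d)` per group
#' and the iterative fit reproduces them to near machine precision.  A group
#' with all-zero counts drives its coefficient to minus infinity; the fit is
#' then flagged `converged = FALSE` (coefficient magnitude > 30 on the log
#' scale) rather than raising an error.
#'
#' @param gene_counts Named numeric vector of counts, names = lane ids (or an
#'   unnamed vector in `lane_info` order).
#' @param lane_info Lane metadata tibble.
#' @param factors Factor tibble giving the per-lane offsets `d`.
#' @param design One of the design strings above.
#' @param gene_id Optional gene label carried into the result.
#' @return An object of class `poisson_fit`: a list with elements
#'   `gene_id`, `coefficients`, `vcov`, `log_likelihood`, `converged`,
#'   `design`, `design_labels`, `n_lanes`, `conditions`.
#' @export
fit_poisson_glm <- function(gene_counts, lane_info, factors,
                            design = c("condition", "null",
                                       "condition_flowcell",
                                       "libprep_within_flowcell",
                                       "flowcell", "flowcell_libprep"),
                            gene_id = NA_character_) {
  design <- match.arg(design)
  lane_info <- validate_lane_info(lane_info)
  lanes <- lane_info$lane_id
  if (!is.null(names(gene_counts))) {
    gene_counts <- gene_counts[lanes]
  } else if (length(gene_counts) != length(lanes)) {
    abort("gene_counts length does not match lane_info")
  }
  d <- factor_lookup(factors, lanes)
  X <- design_matrix(lane_info, design)
  fit <- suppressWarnings(
    glm.fit(X, as.numeric(gene_counts), family = poisson(),
            offset = log(d),
            control = list(epsilon = 1e-12, maxit = 50))
  )
  beta <- fit$coefficients
  # observed-information covariance from the final IRLS weights
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(V) <- list(colnames(X), colnames(X))
  mu <- fit$fitted.values
  ll <- sum(dpois(round(gene_counts), lambda = pmax(mu, 1e-300), log = TRUE))
  structure(list(
    gene_id = gene_id,
    coefficients = beta,
    vcov = V,
    log_likelihood = ll,
    converged = isTRUE(fit$converged) && all(abs(beta) <= 30),
    design = design,
    design_labels = colnames(X),
    n_lanes = length(lanes),
    conditions = sort(unique(lane_info$condition))
  ), class = "poisson_fit")
}

design_matrix <- function(lane_info, design) {
  cond <- factor(lane_info$condition)
  X <- switch(
    design,
    null = matrix(1, nrow(lane_info), 1,
                  dimnames = list(NULL, "(Intercept)")),
    flowcell = stats::model.matrix(~ factor(lane_info$flow_cell)),
    flowcell_libprep = stats::model.matrix(
      ~ factor(lane_info$flow_cell) +
        factor(lane_info$flow_cell):factor(lane_info$library_prep)),
    condition = stats::model.matrix(~ 0 + cond),
    condition_flowcell = stats::model.matrix(
      ~ 0 + cond + factor(lane_info$flow_cell)),
    libprep_within_flowcell = stats::model.matrix(
      ~ 0 + cond + factor(lane_info$flow_cell) +
        factor(lane_info$flow_cell):factor(lane_info$library_prep))
  )
  colnames(X) <- sub("^cond", "condition:", colnames(X))
  colnames(X) <- gsub("factor\\(lane_info\\$flow_cell\\)", "flowcell:",
                      colnames(X))
  colnames(X) <- gsub("factor\\(lane_info\\$library_prep\\)", "libprep:",
                      colnames(X))
  # drop aliased columns so the fit is full rank
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("Poisson GLM fit (%s design)%s\n", x$design,
              if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id)))
  print(round(x$coefficients, 4))
  cat(sprintf("log-likelihood %.4f, converged: %s\n",
              x$log_likelihood, x$converged))
  invisible(x)
}

#' Tidy a per-gene Poisson fit
#'
#' @param x A `poisson_fit` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per coefficient (`term`,
#'   `estimate`, `std.error`); `glance()`: a one-row tibble with
#'   `log_likelihood`, `df`, `converged`, `design`.
#' @export
tidy.poisson_fit <- function(x, ...) {
  tibble(term = x$design_labels,
         estimate = unname(x$coefficients),
         std.error = sqrt(pmax(diag(x$vcov), 0)))
}

#' @rdname tidy.poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble(log_likelihood = x$log_likelihood,
         df = length(x$coefficients),
         converged = x$converged,
         design = x$design)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# names of condition coefficients within a fit
condition_terms <- function(fit) {
  grep("^condition:", fit$design_labels, value = TRUE)
}

# estimated condition log-fold-change (first condition minus second,
# alphabetical), NA when not a two-condition design
condition_contrast <- function(fit) {
  ct <- condition_terms(fit)
  if (length(ct) != 2) return(list(estimate = NA_real_, se = NA_real_))
  cvec <- setNames(numeric(length(fit$design_labels)), fit$design_labels)
  cvec[ct[1]] <- 1
  cvec[ct[2]] <- -1
  est <- sum(cvec * fit$coefficients)
  se <- sqrt(max(drop(t(cvec) %*% fit$vcov %*% cvec), 0))
  list(estimate = est, se = se)
}

direction_of <- function(est, tol = 0) {
  ifelse(is.na(est) | abs(est) <= tol, "0", ifelse(est > 0, "+", "-"))
}

#' Likelihood-ratio test between nested Poisson fits
#'
#' Twice the log-likelihood difference between a full and a nested null fit,
#' referred to the chi-square distribution with degrees of freedom equal to
#' the difference in parameter count.  Unlike Wald t statistics, the
#' likelihood ratio degrades gracefully for genes with zero counts in one
#' condition: the statistic stays finite and grows with the other condition's
#' count, giving a continuum of p-values.
#'
#' @param fit_full,fit_null `poisson_fit` objects for the same gene with the
#'   null design nested in the full design.
#' @return A one-row tibble: `gene_id`, `statistic`, `df`, `p_value`,
#'   `direction`, `method`, `flag`.
#' @export
lr_test <- function(fit_full, fit_null) {
  if (!all(fit_null$design_labels %in% c("(Intercept)",
                                         fit_full$design_labels)) ||
      length(fit_null$design_labels) >= length(fit_full$design_labels)) {
    abort("null design must be nested in the full design")
  }
  if (!identical(fit_full$gene_id, fit_null$gene_id)) {
    abort("fits are for different genes")
  }
  stat <- 2 * (fit_full$log_likelihood - fit_null$log_likelihood)
  if (stat < 0 && stat > -1e-8) stat <- 0
  df <- length(fit_full$design_labels) - length(fit_null$design_labels)
  con <- condition_contrast(fit_full)
  tibble(gene_id = fit_full$gene_id,
         statistic = stat,
         df = as.integer(df),
         p_value = pchisq(stat, df = df, lower.tail = FALSE),
         direction = direction_of(con$estimate),
         method = "lr",
         flag = if (!fit_full$converged) "boundary" else NA_character_)
}

#' Wald t statistic from a Poisson GLM fit
#'
#' The estimated condition log-fold-change divided by its standard error from
#' the observed-information covariance of the fit, with a two-sided normal
#' reference.  When one condition has zero counts the estimated standard
#' error is extremely large and the p-value is driven to one — the
#' characteristic failure mode of Wald statistics on low counts.
#'
#' @param fit A two-condition `poisson_fit`.
#' @return A one-row tibble as in [lr_test()], `method = "t_glm"`.
#' @export
t_statistic_glm <- function(fit) {
  con <- condition_contrast(fit)
  if (is.na(con$estimate)) abort("contrast requires a two-condition design")
  stat <- if (con$se > 0) con$estimate / con$se else 0
  tibble(gene_id = fit$gene_id,
         statistic = stat,
         df = NA_integer_,
         p_value = 2 * pnorm(-abs(stat)),
         direction = direction_of(con$estimate),
         method = "t_glm",
         flag = if (!fit$converged) "boundary" else NA_character_)
}

#' Delta-method t statistic on pooled condition counts
#'
#' For pooled counts `xA`, `xB` with pooled offsets `dA`, `dB`, the statistic
#' is `(log(xA/dA) - log(xB/dB)) / sqrt(1/xA + 1/xB)`, the first-order
#' delta-method variance of a log count.  A zero count in either condition
#' makes the variance infinite; the statistic is reported as 0 with p-value 1
#' and flagged `zero_count`.
#'
#' @param xA,xB Pooled condition counts.
#' @param dA,dB Pooled condition offsets.
#' @param gene_id Optional gene label.
#' @return A one-row tibble as in [lr_test()], `method = "t_delta"`.
#' @export
t_statistic_delta <- function(xA, xB, dA, dB, gene_id = NA_character_) {
  est <- log(xA / dA) - log(xB / dB)
  if (xA == 0 || xB == 0) {
    return(tibble(gene_id = gene_id, statistic = 0, df = NA_integer_,
                  p_value = 1,
                  direction = direction_of(ifelse(xA + xB == 0, NA_real_,
                                                  est)),
                  method = "t_delta", flag = "zero_count"))
  }
  stat <- est / sqrt(1 / xA + 1 / xB)
  tibble(gene_id = gene_id, statistic = stat, df = NA_integer_,
         p_value = 2 * pnorm(-abs(stat)),
         direction = direction_of(est),
         method = "t_delta", flag = NA_character_)
}
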