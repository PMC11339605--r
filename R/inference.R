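#' Liability threshold for a given prevalence
#'
#' Under the liability threshold model a standard-normal latent liability
#' produces disease when it exceeds \eqn{T = \Phi^{-1}(1-K)}, where `K` is
#' the population prevalence.
#'
#' @param K Prevalence in (0, 1).
#' @return The threshold `T` (strictly decreasing in `K`).
#' @examples
#' ltm_threshold(0.5)     # 0
#' ltm_threshold(0.0321)  # about 1.85
#' @export
ltm_threshold <- function(K) {
  if (!is.numeric(K) || any(K <= 0) || any(K >= 1)) {
    stop_bad_arg("`K` must be in (0, 1)")
  }
  qnorm(1 - K)
}

#' Liability-threshold-model parameters
#'
#' @param K Prevalence in (0, 1).
#' @param V Proportion of liability variance explained by the PRS, in
#'   \eqn{[0, 1)}.
#' @return A list with `K`, `V` and the recomputed threshold `T`.
#' @export
ltm_params <- function(K, V) {
  if (!is.numeric(V) || V < 0 || V >= 1) stop_bad_arg("`V` must be in [0, 1)")
  list(K = K, V = V, T = ltm_threshold(K))
}

#' Case probability given a PRS under the liability threshold model
#'
#' With liability \eqn{L \sim N(0,1)}, PRS explaining variance `V`
#' (so that \eqn{E[L\mid PRS=prs] = prs} and
#' \eqn{Var(L \mid PRS) = 1 - V} for a PRS on the liability scale), the
#' probability of being a case is
#' \deqn{\Pr(L > T \mid PRS = prs) = 1 - \Phi\!\big((T - prs)/\sqrt{1-V}\big).}
#' Averaging over \eqn{prs \sim N(0, V)} recovers the prevalence `K`.
#'
#' A variance-standardized PRS column is put on the liability scale by
#' multiplying by \eqn{\sqrt{V}}.
#'
#' @param prs Numeric vector of liability-scale PRS values.
#' @param params An [ltm_params()] list (fields `K`, `V`, `T`).
#' @return Vector of case probabilities, strictly increasing in `prs`.
#' @export
ltm_case_probability <- function(prs, params) {
  V <- params$V
  if (is.null(V) || V < 0 || V >= 1) stop_bad_arg("`V` must be in [0, 1)")
  Tt <- params$T %||% ltm_threshold(params$K)
  1 - pnorm((Tt - prs) / sqrt(1 - V))
}

# ---------------------------------------------------------------------------
# Permutation testing
# ---------------------------------------------------------------------------

perm_statistics <- function(statistic, stat_args) {
  tail_q <- stat_args$tail_q %||% 0.95
  switch(statistic,
    mean = function(x) mean(x),
    median = function(x) median(x),
    variance = function(x) var(x),
    `tail-proportion` = {
      # threshold fixed from the pooled sample, set by the caller
      thr <- stat_args$tail_threshold
      if (is.null(thr)) stop_bad_arg("tail-proportion needs `tail_threshold`")
      function(x) mean(x > thr)
    },
    `ltm-rate` = {
      params <- stat_args$ltm
      if (is.null(params)) stop_bad_arg("ltm-rate needs `ltm` params")
      function(x) mean(ltm_case_probability(sqrt(params$V) * x, params))
    },
    stop_bad_arg("unknown statistic `", statistic, "`")
  )
}

#' Monte Carlo permutation test comparing two groups
#'
#' Computes the difference in a summary statistic between two groups and
#' its permutation distribution under `n_perm` random relabelings of the
#' pooled values. The default p-value is two-sided with the add-one
#' correction, \eqn{p = (1 + \#\{|d^*| \ge |d|\})/(B+1)}, so the minimum
#' attainable p is \eqn{1/(B+1)}. `literal_one_sided = TRUE` instead returns
#' the one-sided proportion of permuted statistic differences exceeding
#' the observed difference, without the add-one correction (the form that
#' yields an asymmetric pairwise heat map from sampling error alone).
#'
#' @param values Numeric vector.
#' @param labels Group label per value.
#' @param group_a,group_b The two labels to compare.
#' @param statistic One of `"mean"`, `"median"`, `"variance"`,
#'   `"tail-proportion"` (proportion above the pooled `tail_q` quantile),
#'   `"ltm-rate"` (mean liability-threshold case probability; `values`
#'   are taken as a standardized PRS and scaled by \eqn{\sqrt{V}}).
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param literal_one_sided Use the one-sided uncorrected proportion?
#' @param tail_q Pooled quantile for `"tail-proportion"` (default 0.95).
#' @param ltm An [ltm_params()] list, required for `"ltm-rate"`.
#' @return A list of class `permutation_test_result` with fields
#'   `statistic_name`, `observed_stat` (difference a minus b),
#'   `n_permutations`, `p_value`, `seed`, `two_sided`.
#' @export
permutation_test <- function(values, labels, group_a, group_b,
                             statistic = "mean", n_perm = 2000, seed = 1L,
                             literal_one_sided = FALSE, tail_q = 0.95,
                             ltm = NULL) {
  if (n_perm < 1) stop_bad_arg("`n_perm` must be at least 1")
  xa <- values[labels == group_a]
  xb <- values[labels == group_b]
  if (length(xa) == 0 || length(xb) == 0) {
    stop_bad_arg("both groups must be non-empty")
  }
  # canonical group order, so that swapping group_a/group_b reuses the
  # identical permutation stream (sign-flipped differences)
  swap <- as.character(group_a) > as.character(group_b)
  pooled <- if (swap) c(xb, xa) else c(xa, xb)
  n_first <- if (swap) length(xb) else length(xa)
  stat_args <- list(tail_q = tail_q, ltm = ltm)
  if (statistic == "tail-proportion") {
    stat_args$tail_threshold <- quantile(pooled, tail_q, names = FALSE)
  }
  f <- perm_statistics(statistic, stat_args)
  d_obs <- f(xa) - f(xb)
  n <- length(pooled)
  d_perm <- withr::with_seed(derive_seed(seed, 4L), {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, n_first)
      f(pooled[idx]) - f(pooled[-idx])
    }, numeric(1))
  })
  if (swap) d_perm <- -d_perm
  p <- if (literal_one_sided) {
    mean(d_perm > d_obs)
  } else {
    (1 + sum(abs(d_perm) >= abs(d_obs))) / (n_perm + 1)
  }
  structure(list(
    statistic_name = statistic,
    observed_stat = d_obs,
    n_permutations = n_perm,
    p_value = p,
    seed = seed,
    two_sided = !literal_one_sided
  ), class = "permutation_test_result")
}

#' Pairwise permutation tests across all groups with BH correction
#'
#' Runs [permutation_test()] for every pair of groups and applies the
#' Benjamini-Hochberg correction jointly across all pairs. With
#' `ordered = FALSE` (default) each unordered pair is tested once and the
#' matrices are symmetric; with `ordered = TRUE` both directions are
#' tested separately with different Monte Carlo draws, giving the
#' asymmetric-by-sampling-error heat-map behaviour.
#'
#' @inheritParams permutation_test
#' @param ordered Test ordered pairs separately?
#' @param ... Passed on to [permutation_test()].
#' @return A list with matrices `p` and `p_adjusted` (groups by groups,
#'   `NA` on the diagonal) and the data frame `pairs`.
#' @export
pairwise_permutation_matrix <- function(values, labels, statistic = "mean",
                                        n_perm = 2000, seed = 1L,
                                        ordered = FALSE, ...) {
  groups <- sort(unique(labels))
  G <- length(groups)
  if (G < 2) stop_bad_arg("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop_bad_arg("singleton group(s): ",
                 paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pairs <- if (ordered) {
    expand.grid(a = groups, b = groups, stringsAsFactors = FALSE)
  } else {
    as.data.frame(t(combn(groups, 2)), stringsAsFactors = FALSE) |>
      setNames(c("a", "b"))
  }
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pvals <- vapply(seq_len(nrow(pairs)), function(i) {
    permutation_test(values, labels, pairs$a[i], pairs$b[i],
                     statistic = statistic, n_perm = n_perm,
                     seed = derive_seed(seed, 100L + i), ...)$p_value
  }, numeric(1))
  padj <- bh_adjust(pvals)
  pm <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  am <- pm
  ia <- match(pairs$a, groups); ib <- match(pairs$b, groups)
  pm[cbind(ia, ib)] <- pvals
  am[cbind(ia, ib)] <- padj
  if (!ordered) {
    pm[cbind(ib, ia)] <- pvals
    am[cbind(ib, ia)] <- padj
  }
  pairs$p <- pvals
  pairs$p_adjusted <- padj
  list(p = pm, p_adjusted = am, pairs = pairs)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, clipped at 1.
#'
#' @param pvalues Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_bad_arg("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Mid-rank tie handling; exact enumeration for small untied samples and
#' the normal approximation with continuity correction otherwise
#' (the standard `stats::wilcox.test` switch at 50 observations).
#'
#' @param values_a,values_b Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_bad_arg("both samples must be non-empty")
  }
  p <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                correct = TRUE)$p.value
  )
  # fully tied data carries no evidence against the null
  if (is.nan(p)) 1 else p
}

#' Directly age-standardized rate
#'
#' Weighted average of age-band-specific rates using standard-population
#' weights: \eqn{\sum_b w_b (c_b / n_b) / \sum_b w_b}. Scale-invariant in
#' the weights.
#'
#' @param cases_by_band,persons_by_band,standard_weights Aligned numeric
#'   vectors over age bands; weights non-negative, not all zero. A band
#'   with zero persons and zero cases is skipped with a warning; zero
#'   persons with positive cases is an error.
#' @return The standardized rate.
#' @export
age_standardized_rate <- function(cases_by_band, persons_by_band,
                                  standard_weights) {
  k <- length(cases_by_band)
  if (length(persons_by_band) != k || length(standard_weights) != k) {
    stop_bad_arg("inputs must have the same length")
  }
  if (any(standard_weights < 0) || sum(standard_weights) == 0) {
    stop_bad_arg("weights must be non-negative and not all zero")
  }
  bad <- persons_by_band == 0 & cases_by_band > 0
  if (any(bad)) {
    stop_bad_arg("band(s) with cases but no persons: ",
                 paste(which(bad), collapse = ", "))
  }
  skip <- persons_by_band == 0
  if (any(skip)) {
    warning("skipping empty band(s): ", paste(which(skip), collapse = ", "))
  }
  keep <- !skip
  sum(standard_weights[keep] * cases_by_band[keep] / persons_by_band[keep]) /
    sum(standard_weights[keep])
}

#' Individual- versus group-level correlation scan (Simpson's paradox)
#'
#' For every pair of the supplied variables, computes the Pearson
#' correlation across all individuals and the Pearson correlation across
#' group means, flags pairs whose correlation signs reverse between the
#' two levels while passing significance screens at both levels
#' (Benjamini-Hochberg-adjusted within each level).
#'
#' @param cohort Data frame with a `group` column.
#' @param variables Character vector of numeric column names to scan
#'   (include the outcome column to scan each variable against the
#'   observed rate).
#' @param individual_alpha BH-adjusted significance screen at the
#'   individual level (default 0.01).
#' @param group_alpha BH-adjusted significance screen at the group-mean
#'   level (default 0.05).
#' @return Data frame with one row per pair: `var1`, `var2`,
#'   `individual_r`, `individual_p_adj`, `group_r`, `group_p_adj`,
#'   `reversal_flag`. Pairs involving a constant variable are skipped
#'   with a warning.
#' @export
simpsons_scan <- function(cohort, variables, individual_alpha = 0.01,
                          group_alpha = 0.05) {
  if (!"group" %in% names(cohort)) stop_bad_arg("`cohort` needs a `group` column")
  groups <- unique(cohort$group)
  if (length(groups) < 3) {
    stop_bad_arg("group-level correlation needs at least 3 groups")
  }
  miss <- setdiff(variables, names(cohort))
  if (length(miss) > 0) {
    stop_bad_arg("unknown variable(s): ", paste(miss, collapse = ", "))
  }
  const <- variables[vapply(variables,
                            function(v) var(cohort[[v]]) == 0, logical(1))]
  if (length(const) > 0) {
    warning("skipping constant variable(s): ", paste(const, collapse = ", "))
    variables <- setdiff(variables, const)
  }
  if (length(variables) < 2) stop_bad_arg("need at least 2 usable variables")
  gm <- aggregate(cohort[variables], by = list(group = cohort$group), mean)
  pair_idx <- combn(length(variables), 2)
  res <- lapply(seq_len(ncol(pair_idx)), function(j) {
    v1 <- variables[pair_idx[1, j]]
    v2 <- variables[pair_idx[2, j]]
    ind <- suppressWarnings(cor.test(cohort[[v1]], cohort[[v2]]))
    grp <- suppressWarnings(cor.test(gm[[v1]], gm[[v2]]))
    data.frame(var1 = v1, var2 = v2,
               individual_r = unname(ind$estimate),
               individual_p = ind$p.value,
               group_r = unname(grp$estimate),
               group_p = grp$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$individual_p_adj <- bh_adjust(out$individual_p)
  out$group_p_adj <- bh_adjust(out$group_p)
  out$reversal_flag <- sign(out$individual_r) != sign(out$group_r) &
    out$individual_p_adj < individual_alpha &
    out$group_p_adj < group_alpha
  out
}
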