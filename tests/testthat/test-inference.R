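test_that("liability threshold matches the inverse-normal relationship", {
  expect_identical(ltm_threshold(0.5), 0)
  expect_equal(ltm_threshold(0.0321), 1.8508, tolerance = 1e-4)
  expect_equal(ltm_threshold(0.975), -qnorm(0.975), tolerance = 1e-12)
  ks <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(ltm_threshold(ks)) < 0))
  expect_error(ltm_threshold(0), "0, 1")
  expect_error(ltm_threshold(1), "0, 1")
})

test_that("LTM case probability matches closed-form anchor points", {
  # a PRS at the threshold gives probability 1/2 for any V
  for (V in c(0, 0.3, 0.8)) {
    p <- ltm_params(K = 0.0321, V = V)
    expect_equal(ltm_case_probability(p$T, p), 0.5)
  }
  expect_equal(ltm_case_probability(0, ltm_params(0.5, 0)), 0.5)
  # anchor at a 3.21% prevalence threshold (T = 1.8504 to printed digits)
  p <- list(K = 0.0321, V = 0.25, T = 1.8504)
  expect_equal(ltm_case_probability(1.0, p),
               1 - pnorm(0.8504 / sqrt(0.75)), tolerance = 1e-12)
  expect_equal(ltm_case_probability(1.0, p), 0.1632, tolerance = 1e-3)
  # strictly increasing in the PRS
  probs <- ltm_case_probability(seq(-2, 2, 0.1), p)
  expect_true(all(diff(probs) > 0))
  expect_error(ltm_params(0.1, 1), "\\[0, 1\\)")
})

test_that("averaging LTM case probabilities over the PRS distribution
           recovers the prevalence", {
  for (K in c(0.5, 0.0321)) {
    for (V in c(0, 0.05, 0.25)) {
      params <- ltm_params(K, V)
      prs <- withr::with_seed(100 + round(1000 * V),
                              rnorm(2e5, 0, sqrt(V)))
      est <- mean(ltm_case_probability(prs, params))
      expect_equal(est, K, tolerance = 5e-3, label = paste("K", K, "V", V))
    }
  }
})

test_that("BH adjustment equals the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  withr::with_seed(1, {
    for (i in 1:20) {
      p <- runif(sample(1:30, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_direct(p), tolerance = 1e-14)
      expect_true(all(q >= p - 1e-14))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-14))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("Mann-Whitney agrees with exhaustive enumeration on small
           samples", {
  expect_equal(mann_whitney(1, 1), 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # enumeration oracle: two-sided p from all C(n, na) splits of the
  # rank-sum statistic
  enum_p <- function(xa, xb) {
    pooled <- c(xa, xb)
    na <- length(xa)
    u_of <- function(idx) {
      sum(rank(pooled)[idx]) - na * (na + 1) / 2
    }
    u_obs <- u_of(seq_len(na))
    mu <- na * length(xb) / 2
    us <- apply(combn(length(pooled), na), 2, u_of)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  }
  withr::with_seed(8, {
    for (i in 1:10) {
      na <- sample(2:5, 1)
      nb <- sample(2:5, 1)
      xa <- rnorm(na)
      xb <- rnorm(nb, mean = i %% 3)
      expect_equal(mann_whitney(xa, xb), enum_p(xa, xb),
                   tolerance = 1e-10)
    }
  })
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("large-sample Mann-Whitney approximation tracks the exact test", {
  withr::with_seed(9, {
    xa <- rnorm(15)
    xb <- rnorm(15, 0.8)
  })
  p_exact <- wilcox.test(xa, xb, exact = TRUE)$p.value
  p_approx <- wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_approx), 0.01)
  expect_equal(mann_whitney(xa, xb), p_exact)
})

test_that("permutation test attains the minimum p under complete
           separation", {
  withr::with_seed(2, {
    xa <- rnorm(30)
    xb <- rnorm(30) + 10 * sd(xa)
  })
  vals <- c(xa, xb)
  labs <- rep(c("a", "b"), each = 30)
  res <- permutation_test(vals, labs, "a", "b", "mean", n_perm = 2000,
                          seed = 3)
  expect_equal(res$p_value, 1 / 2001)
  expect_equal(res$n_permutations, 2000)
})

test_that("Monte Carlo permutation p matches exhaustive enumeration", {
  withr::with_seed(4, {
    xa <- rnorm(3)
    xb <- rnorm(3, 1)
  })
  p_ex <- exhaustive_perm_p(xa, xb)
  B <- 1e5
  res <- permutation_test(c(xa, xb), rep(1:2, each = 3), 1, 2, "mean",
                          n_perm = B, seed = 11)
  se <- sqrt(p_ex * (1 - p_ex) / B)
  expect_lt(abs(res$p_value - p_ex), 3 * se + 2 / B)
})

test_that("permutation p-values are calibrated under the null", {
  B <- 199
  pvals <- vapply(1:500, function(i) {
    x <- withr::with_seed(3000 + i, rnorm(20))
    permutation_test(x, rep(1:2, each = 10), 1, 2, "mean", n_perm = B,
                     seed = 5000 + i)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 1 / (B + 1) & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation test is label-symmetric for symmetric statistics
           and supports all named statistics", {
  coh <- small_cohort(n_groups = 2, group_size = 60, seed = 14)
  vals <- coh$prs
  labs <- coh$group
  for (stat in c("mean", "median", "variance", "tail-proportion")) {
    r1 <- permutation_test(vals, labs, 1, 2, stat, n_perm = 300, seed = 6)
    r2 <- permutation_test(vals, labs, 2, 1, stat, n_perm = 300, seed = 6)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12,
                 label = stat)
  }
  ltm <- ltm_params(0.1, 0.05)
  r <- permutation_test(vals, labs, 1, 2, "ltm-rate", n_perm = 100,
                        seed = 6, ltm = ltm)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_error(permutation_test(vals, labs, 1, 2, "kurtosis"), "unknown")
  expect_error(permutation_test(vals, labs, 1, 2, "mean", n_perm = 0),
               "n_perm")
})

test_that("literal one-sided mode is uncorrected and direction-sensitive", {
  withr::with_seed(10, x <- rnorm(40))
  labs <- rep(1:2, each = 20)
  res <- permutation_test(x, labs, 1, 2, "mean", n_perm = 200, seed = 7,
                          literal_one_sided = TRUE)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_false(res$two_sided)
  # direction flips the one-sided p around its complement
  res2 <- permutation_test(x, labs, 2, 1, "mean", n_perm = 200, seed = 7,
                           literal_one_sided = TRUE)
  expect_equal(res$p_value + res2$p_value, 1, tolerance = 0.15)
})

test_that("the pairwise matrix tests every pair once and adjusts jointly", {
  coh <- small_cohort(n_groups = 9, group_size = 40, seed = 19)
  m <- pairwise_permutation_matrix(coh$prs, coh$group, "mean",
                                   n_perm = 99, seed = 8)
  expect_equal(nrow(m$pairs), 36)  # choose(9, 2)
  expect_equal(m$p, t(m$p))
  expect_equal(bh_adjust(m$pairs$p), m$pairs$p_adjusted)
  expect_error(
    pairwise_permutation_matrix(c(coh$prs, 0), c(coh$group, 99), "mean"),
    "singleton"
  )
})

test_that("hugely shifted groups all reach the minimum adjusted p", {
  withr::with_seed(20, base <- rnorm(40))
  vals <- c(base, base + 100, base + 200)
  labs <- rep(1:3, each = 40)
  m <- pairwise_permutation_matrix(vals, labs, "mean", n_perm = 99,
                                   seed = 9)
  expect_true(all(m$pairs$p == 1 / 100))
  expect_true(all(m$pairs$p_adjusted == 1 / 100))
})

test_that("identical groups are rarely declared different", {
  hits <- vapply(1:60, function(i) {
    x <- withr::with_seed(7000 + i, rnorm(60))
    m <- pairwise_permutation_matrix(x, rep(1:2, each = 30), "mean",
                                     n_perm = 99, seed = 8000 + i)
    any(m$pairs$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.10)  # nominal 5% plus binomial slack
})

test_that("age standardization matches the weighted-rate formula", {
  expect_equal(age_standardized_rate(c(10, 30), c(100, 100), c(3, 1)),
               0.15)
  # equal weights give the crude mean of band rates
  expect_equal(age_standardized_rate(c(5, 20), c(50, 100), c(1, 1)),
               mean(c(0.1, 0.2)))
  # single band returns that band's rate regardless of weight
  expect_equal(age_standardized_rate(7, 70, 5), 0.1)
  # scale invariance in the weights
  r1 <- age_standardized_rate(c(1, 2, 3), c(10, 20, 30), c(1, 2, 3))
  r2 <- age_standardized_rate(c(1, 2, 3), c(10, 20, 30), c(10, 20, 30))
  expect_equal(r1, r2, tolerance = 1e-14)
  expect_error(age_standardized_rate(c(1, 1), c(10, 0), c(1, 1)),
               "no persons")
  expect_warning(age_standardized_rate(c(1, 0), c(10, 0), c(1, 1)),
                 "skipping")
})

test_that("the correlation scan flags engineered reversals and counts
           pairs correctly", {
  G <- 21
  cfg <- cohort_config(n_groups = G, group_sizes = 3000,
                       group_effects = seq(-0.3, 0.3, length.out = G),
                       seed = 112)
  coh <- generate_base_cohort(cfg)
  ret <- apply_participation_bias(
    coh, bias_config(1, seq(0, 1, length.out = G), seed = 112)
  )
  scan <- simpsons_scan(ret, c("prs", "age", "pce", "outcome"))
  row <- scan[scan$var1 == "prs" & scan$var2 == "outcome", ]
  expect_true(row$reversal_flag)
  expect_gt(row$individual_r, 0)
  expect_lt(row$group_r, 0)
  # nine variables scan 36 pairs
  vars9 <- c("prs", "pce", "age", "total_chol", "hdl", "sbp", "bmi",
             "tdi", "outcome")
  expect_equal(nrow(simpsons_scan(coh, vars9)), 36)
  expect_error(simpsons_scan(coh[coh$group == 1, ], c("prs", "pce")),
               "3 groups")
})

test_that("random group labels almost never trigger reversal flags", {
  coh <- small_cohort(n_groups = 7, group_size = 100, seed = 23,
                      prevalence = 0.2)
  flags <- vapply(1:200, function(i) {
    shuffled <- coh
    shuffled$group <- withr::with_seed(9000 + i, sample(coh$group))
    any(simpsons_scan(shuffled, c("prs", "pce", "outcome"))$reversal_flag)
  }, logical(1))
  # joint screen (individual BH < 0.01 AND group BH < 0.05 AND sign flip)
  # must not fire above the group-level nominal rate
  expect_lte(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})
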