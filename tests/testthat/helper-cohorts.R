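# Shared fixtures built in code.

# Small cohort with known group structure for model tests.
small_cohort <- function(n_groups = 6, group_size = 300, seed = 42,
                         prevalence = 0.1) {
  cfg <- cohort_config(n_groups = n_groups, group_sizes = group_size,
                       prevalence = prevalence, seed = seed)
  generate_base_cohort(cfg)
}

# Grouped logistic data with known within (beta) and between (gamma)
# coefficients; group means enter via the empirical means so recovery is
# exact in expectation.
simulate_mundlak_data <- function(G = 40, n_per = 250, beta = 0.8,
                                  gamma = 0.8, intercept = -2.5,
                                  seed = 1) {
  withr::with_seed(seed, {
    group <- rep(seq_len(G), each = n_per)
    centre <- rep(seq(-1, 1, length.out = G), each = n_per)
    x <- centre + rnorm(G * n_per)
    xbar <- ave(x, group)
    eta <- intercept + beta * (x - xbar) + gamma * xbar
    y <- rbinom(G * n_per, 1, plogis(eta))
    data.frame(group = group, x = x, outcome = y)
  })
}

# Toy PCE-style coefficient table used across risk-score tests.
toy_pce_table <- function(coefs = list(log_age = 1.0), mean_lp = log(55),
                          s0 = 0.95) {
  pce_coefficients(list(strata = list(
    female = list(coefficients = coefs, mean_lp = mean_lp, s0 = s0),
    male = list(coefficients = coefs, mean_lp = mean_lp, s0 = s0)
  )))
}

# Direct step-up BH formula, independent of stats::p.adjust.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive two-sided permutation p-value over all label assignments.
exhaustive_perm_p <- function(xa, xb, stat = mean) {
  pooled <- c(xa, xb)
  na <- length(xa)
  d_obs <- stat(xa) - stat(xb)
  splits <- combn(length(pooled), na)
  d_all <- apply(splits, 2, function(idx) {
    stat(pooled[idx]) - stat(pooled[-idx])
  })
  mean(abs(d_all) >= abs(d_obs) - 1e-12)
}

# Brute-force AUC over all case-control pairs.
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
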