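#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_base_cohort()].
#' The generator draws a latent standard-normal disease liability
#' \eqn{L = \sqrt{V}\,PRS + w_E\,PCE + b_g + \epsilon} with the component
#' variances summing to one, and sets the binary outcome to
#' \eqn{D = 1\{L > T\}} with \eqn{T = \Phi^{-1}(1-K)} so that the expected
#' case rate equals the prevalence `K`.
#'
#' @param n_groups Number of groups (assessment centres). Default 21.
#' @param group_sizes Integer vector of per-group sizes (length `n_groups`,
#'   all at least 2), or a single number taken as a common size.
#' @param prevalence Target disease prevalence `K` in (0, 1). Default
#'   0.0321, a typical incidence rate for coronary artery disease in a
#'   large middle-aged cohort.
#' @param prs_variance Proportion `V` of liability variance explained by
#'   the polygenic risk score, in \eqn{[0, 1)}. Default 0.05.
#' @param env_weight Weight \eqn{w_E} of the standardized non-genetic risk
#'   score in the liability. Default 0.5 (non-genetic factors explain 25%
#'   of liability variance).
#' @param group_effect_sd Standard deviation of group-level liability
#'   shifts \eqn{b_g}. Default 0 (exchangeable groups).
#' @param group_effects Optional explicit numeric vector of per-group
#'   liability shifts (length `n_groups`); overrides `group_effect_sd`.
#'   The individual-weighted variance of the shifts enters the liability
#'   variance budget in place of `group_effect_sd^2`.
#' @param age_range Two-element numeric vector of enrolment ages.
#'   Default `c(40, 69)`.
#' @param covariate_loadings Named numeric vector of correlations between
#'   each measured non-genetic covariate and the latent non-genetic risk
#'   factor; see Details. `NULL` uses built-in defaults.
#' @param age_weight Correlation between age and the non-genetic risk
#'   score. Default 0.4.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @details The non-genetic score (`pce` column) is a standardized latent
#' factor combining age and an age-independent component. Measured
#' covariates (total cholesterol, HDL, systolic blood pressure, BMI,
#' Townsend deprivation index, smoking, hypertension medication, diabetes)
#' are noisy loadings on the age-independent component, scaled to
#' realistic units so that eligibility filtering and PCE-style scoring can
#' be exercised on synthetic data.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_base_cohort()]
#' @export
cohort_config <- function(n_groups = 21,
                          group_sizes = 1000,
                          prevalence = 0.0321,
                          prs_variance = 0.05,
                          env_weight = 0.5,
                          group_effect_sd = 0,
                          group_effects = NULL,
                          age_range = c(40, 69),
                          covariate_loadings = NULL,
                          age_weight = 0.4,
                          seed = 1L) {
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      prevalence <= 0 || prevalence >= 1) {
    stop_bad_arg("`prevalence` (K) must be a single number in (0, 1)")
  }
  if (!is.numeric(prs_variance) || length(prs_variance) != 1 ||
      prs_variance < 0 || prs_variance >= 1) {
    stop_bad_arg("`prs_variance` (V) must be a single number in [0, 1)")
  }
  if (n_groups < 1) stop_bad_arg("`n_groups` must be at least 1")
  if (length(group_sizes) == 1) {
    group_sizes <- rep(as.integer(group_sizes), n_groups)
  }
  if (length(group_sizes) != n_groups) {
    stop_bad_arg("`group_sizes` has length ", length(group_sizes),
                 " but `n_groups` is ", n_groups)
  }
  if (any(group_sizes < 2)) stop_bad_arg("all group sizes must be >= 2")
  if (!is.null(group_effects)) {
    if (length(group_effects) != n_groups) {
      stop_bad_arg("`group_effects` must have length `n_groups`")
    }
    # individual-weighted variance of the (centred) deterministic shifts
    w <- group_sizes / sum(group_sizes)
    mu_b <- sum(w * group_effects)
    group_effects <- group_effects - mu_b
    group_var <- sum(w * group_effects^2)
  } else {
    group_var <- group_effect_sd^2
  }
  resid_var <- 1 - prs_variance - env_weight^2 - group_var
  if (resid_var < 0) {
    stop_bad_arg("liability component variances exceed 1: V + env_weight^2 ",
                 "+ group_effect_sd^2 = ", format(1 - resid_var))
  }
  if (abs(age_weight) >= 1) stop_bad_arg("`age_weight` must be in (-1, 1)")
  loadings <- default_covariate_loadings()
  if (!is.null(covariate_loadings)) {
    if (is.null(names(covariate_loadings)) ||
        !all(names(covariate_loadings) %in% names(loadings))) {
      stop_bad_arg("`covariate_loadings` must be named; known covariates: ",
                   paste(names(loadings), collapse = ", "))
    }
    loadings[names(covariate_loadings)] <- covariate_loadings
  }
  structure(list(
    n_groups = as.integer(n_groups),
    group_sizes = as.integer(group_sizes),
    prevalence = prevalence,
    prs_variance = prs_variance,
    env_weight = env_weight,
    group_effect_sd = group_effect_sd,
    group_effects = group_effects,
    resid_var = resid_var,
    age_range = age_range,
    covariate_loadings = loadings,
    age_weight = age_weight,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

default_covariate_loadings <- function() {
  c(total_chol = 0.35, hdl = -0.45, sbp = 0.45, bmi = 0.40, tdi = 0.25,
    smoking = 0.35, htn_med = 0.45, diabetes = 0.40)
}

# Realistic marginal scales for the measured covariates (means/SDs typical
# of a middle-aged UK cohort; binary covariates given as population rates).
covariate_scales <- function() {
  list(
    total_chol = c(mean = 226.7, sd = 35),
    hdl        = c(mean = 56.8,  sd = 15),
    sbp        = c(mean = 137.2, sd = 18),
    bmi        = c(mean = 27.0,  sd = 4.5),
    tdi        = c(mean = 0,     sd = 3),
    smoking    = c(rate = 0.43),
    htn_med    = c(rate = 0.134),
    diabetes   = c(rate = 0.013)
  )
}

#' Generate a synthetic cohort under the liability threshold model
#'
#' One row per individual: group label, age, sex, standardized PRS,
#' non-genetic risk score (`pce`) and measured covariates, the latent
#' liability (hidden column `.liability`, retained for testing), and the
#' binary outcome `outcome = 1` when liability exceeds
#' \eqn{T = \Phi^{-1}(1-K)}.
#'
#' The PRS is centred and variance-standardized over the cohort, so its
#' liability-scale contribution is \eqn{\sqrt{V}\,PRS}. Identical seeds
#' give identical cohorts.
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with columns `id`, `group`, `age`, `sex`, `prs`,
#'   `pce`, `total_chol`, `hdl`, `sbp`, `bmi`, `tdi`, `smoking`,
#'   `htn_med`, `diabetes`, `.liability`, `outcome`.
#' @examples
#' cfg <- cohort_config(n_groups = 4, group_sizes = 500, seed = 7)
#' coh <- generate_base_cohort(cfg)
#' mean(coh$outcome)  # close to cfg$prevalence
#' @export
generate_base_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_bad_arg("`config` must be created with cohort_config()")
  }
  n <- sum(config$group_sizes)
  withr::with_seed(derive_seed(config$seed, 1L), {
    group <- rep(seq_len(config$n_groups), times = config$group_sizes)
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(runif(n) < 0.5, "female", "male")

    prs_raw <- rnorm(n)
    prs <- as.numeric(scale(prs_raw))  # mean 0, sample variance 1

    # Non-genetic score: age component plus an age-independent factor.
    z_age <- (age - mean(config$age_range)) /
      sqrt(diff(config$age_range)^2 / 12)
    w_age <- config$age_weight
    env0 <- rnorm(n)
    pce <- w_age * z_age + sqrt(1 - w_age^2) * env0

    b_g <- if (!is.null(config$group_effects)) {
      config$group_effects[group]
    } else if (config$group_effect_sd > 0) {
      rnorm(config$n_groups, 0, config$group_effect_sd)[group]
    } else {
      rep(0, n)
    }
    liability <- sqrt(config$prs_variance) * prs +
      config$env_weight * pce +
      b_g +
      sqrt(config$resid_var) * rnorm(n)

    threshold <- ltm_threshold(config$prevalence)
    outcome <- as.integer(liability > threshold)

    covars <- draw_measured_covariates(env0, config$covariate_loadings)

    out <- data.frame(
      id = seq_len(n), group = group, age = age, sex = sex,
      prs = prs, pce = pce,
      covars,
      stringsAsFactors = FALSE
    )
    out$.liability <- liability
    out$outcome <- outcome
    out
  })
}

# Measured covariates as noisy loadings on the age-independent non-genetic
# factor; continuous ones rescaled to realistic units, binary ones via a
# latent-threshold draw at the stated population rate.
draw_measured_covariates <- function(env0, loadings) {
  n <- length(env0)
  scales <- covariate_scales()
  out <- list()
  for (nm in names(loadings)) {
    lam <- loadings[[nm]]
    latent <- lam * env0 + sqrt(1 - lam^2) * rnorm(n)
    sc <- scales[[nm]]
    if ("rate" %in% names(sc)) {
      out[[nm]] <- as.integer(latent > qnorm(1 - sc[["rate"]]))
    } else {
      out[[nm]] <- sc[["mean"]] + sc[["sd"]] * latent
    }
  }
  as.data.frame(out)
}

#' Configuration for liability-dependent participation bias
#'
#' Parameters for [apply_participation_bias()]: each individual is retained
#' with probability
#' \eqn{\mathrm{logit}^{-1}\!\big(-(s\,g_{grp}\,L + a\,(age-\bar{age}) + c)\big)},
#' where `s` is `strength`, \eqn{g_{grp}} the group's gradient multiplier,
#' `L` the latent liability, `a` the age coefficient and `c` an offset.
#' Age is centred at `age_center` so the offset sets the overall retention
#' level. With `strength = 0` (and zero age coefficient) every individual
#' is retained.
#'
#' @param strength Non-negative log-odds of non-retention per unit
#'   liability (before the group multiplier).
#' @param group_gradient Numeric vector of per-group multipliers, one per
#'   group in the cohort the configuration will be applied to.
#' @param age_coefficient Extra log-odds of non-retention per year of age
#'   above `age_center`. Default 0.
#' @param age_center Age at which the age term vanishes. Default 55.
#' @param offset Baseline log-odds of non-retention. Default -2 (roughly
#'   88% retention for an average individual).
#' @param seed Integer seed for the retention draws.
#' @return An object of class `bias_config`.
#' @export
bias_config <- function(strength,
                        group_gradient,
                        age_coefficient = 0,
                        age_center = 55,
                        offset = -2,
                        seed = 1L) {
  if (!is.numeric(strength) || length(strength) != 1 || strength < 0) {
    stop_bad_arg("`strength` must be a single non-negative number")
  }
  structure(list(
    strength = strength,
    group_gradient = as.numeric(group_gradient),
    age_coefficient = age_coefficient,
    age_center = age_center,
    offset = offset,
    seed = as.integer(seed)
  ), class = "bias_config")
}

#' Subsample a cohort under liability- and age-dependent retention
#'
#' Emulates differential survival/participation: individuals with high
#' disease liability (and, optionally, higher age) are less likely to
#' appear in the analyzed sample, with per-group gradient multipliers so
#' that the selection strength varies between groups. Strong group-varying
#' selection produces the ascertainment-bias signature in which the
#' individual-level correlation between PRS and outcome is positive while
#' the correlation across group means is negative.
#'
#' @param cohort A cohort from [generate_base_cohort()] (must retain the
#'   hidden `.liability` column).
#' @param bias A [bias_config()]; `group_gradient` must have one entry per
#'   group present in `cohort`.
#' @return The retained subset of `cohort`, with a hidden `.retain_prob`
#'   column. With `strength = 0` and `age_coefficient = 0` the input is
#'   returned unchanged.
#' @export
apply_participation_bias <- function(cohort, bias) {
  if (!inherits(bias, "bias_config")) {
    stop_bad_arg("`bias` must be created with bias_config()")
  }
  if (!all(c(".liability", "group", "age") %in% names(cohort))) {
    stop_bad_arg("`cohort` must have `.liability`, `group` and `age` columns")
  }
  groups <- sort(unique(cohort$group))
  if (length(bias$group_gradient) != length(groups)) {
    stop_bad_arg("`group_gradient` has length ", length(bias$group_gradient),
                 " but the cohort has ", length(groups), " groups")
  }
  if (bias$strength == 0 && bias$age_coefficient == 0) {
    return(cohort)
  }
  g_idx <- match(cohort$group, groups)
  lp <- bias$strength * bias$group_gradient[g_idx] * cohort$.liability +
    bias$age_coefficient * (cohort$age - bias$age_center) +
    bias$offset
  p_retain <- plogis(-lp)
  keep <- withr::with_seed(derive_seed(bias$seed, 2L),
                           runif(nrow(cohort)) < p_retain)
  out <- cohort[keep, , drop = FALSE]
  out$.retain_prob <- p_retain[keep]
  lost <- setdiff(groups, unique(out$group))
  if (length(lost) > 0) {
    stop_bad_arg("participation bias emptied group(s): ",
                 paste(lost, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Configuration for structured (quantile-based) group assignment
#'
#' Defines the hidden variable \eqn{y_j \sim N(\mu_j, 1)} with
#' \eqn{\mu_j = \alpha_1 PRS_j + \alpha_2 PCE_j} used by
#' [assign_quantile_groups()] to replace observed group labels with
#' equal-sized quantile groups of \eqn{y}. The signs and sizes of
#' \eqn{\alpha_1, \alpha_2} control whether group assignment aligns the
#' two risk scores (same signs) or opposes them (opposite signs, the
#' regime that creates Simpson's paradox for a model using only one
#' score).
#'
#' @param alpha1 Weight on the PRS.
#' @param alpha2 Weight on the non-genetic score.
#' @param n_groups Number of quantile groups (at least 2).
#' @param seed Integer seed for the \eqn{y_j} draws.
#' @return An object of class `structured_permutation_config`.
#' @export
structured_permutation_config <- function(alpha1, alpha2, n_groups = 21,
                                          seed = 1L) {
  if (n_groups < 2) stop_bad_arg("`n_groups` must be at least 2")
  structure(list(
    alpha1 = alpha1, alpha2 = alpha2,
    n_groups = as.integer(n_groups), seed = as.integer(seed)
  ), class = "structured_permutation_config")
}

#' Replace group labels by quantile groups of a hidden risk combination
#'
#' Draws \eqn{y_j \sim N(\alpha_1 PRS_j + \alpha_2 PCE_j, 1)}, ranks the
#' \eqn{y_j} ascending (ties broken by row order) and assigns equal-sized
#' groups `1..n_groups` along the ranking; group sizes differ by at most
#' one, with any remainder going to the lowest-index groups. The original
#' `group` column is overwritten.
#'
#' @param cohort A data frame with numeric `prs` and `pce` columns.
#' @param spc A [structured_permutation_config()].
#' @return `cohort` with its `group` column replaced and a hidden
#'   `.hidden_y` column holding the drawn \eqn{y_j}.
#' @export
assign_quantile_groups <- function(cohort, spc) {
  if (!inherits(spc, "structured_permutation_config")) {
    stop_bad_arg("`spc` must be created with structured_permutation_config()")
  }
  if (!all(c("prs", "pce") %in% names(cohort))) {
    stop_bad_arg("`cohort` must have `prs` and `pce` columns")
  }
  n <- nrow(cohort)
  if (spc$n_groups > n) {
    stop_bad_arg("`n_groups` (", spc$n_groups, ") exceeds the number of rows (",
                 n, ")")
  }
  y <- withr::with_seed(
    derive_seed(spc$seed, 3L),
    rnorm(n, mean = spc$alpha1 * cohort$prs + spc$alpha2 * cohort$pce, sd = 1)
  )
  ord <- order(y)  # stable: ties keep row order
  base <- n %/% spc$n_groups
  extra <- n %% spc$n_groups
  sizes <- rep(base, spc$n_groups) + c(rep(1L, extra),
                                       rep(0L, spc$n_groups - extra))
  labels <- rep.int(seq_len(spc$n_groups), sizes)
  cohort$group <- integer(n)
  cohort$group[ord] <- labels
  cohort$.hidden_y <- y
  cohort
}

#' Write or read a cohort as CSV
#'
#' Hidden columns (names starting with `.`, e.g. `.liability`) are dropped
#' on write unless `keep_latent = TRUE`.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @param keep_latent Keep hidden columns in the file? Default `FALSE`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a data frame.
#' @export
write_cohort <- function(cohort, path, keep_latent = FALSE) {
  if (!keep_latent) {
    cohort <- cohort[, !startsWith(names(cohort), "."), drop = FALSE]
  }
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
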