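#' Structured-permutation experiment: create and resolve Simpson's paradox
#'
#' Replaces the cohort's group labels by equal-sized quantile groups of the
#' hidden variable \eqn{y_j \sim N(\alpha_1 PRS_j + \alpha_2 PCE_j, 1)} and
#' compares leave-one-group-out group-rate prediction for a standard GLM and
#' a Mundlak GLM, both regressed on the PRS only. With same-sign weights the
#' grouping aligns both risk scores and both models rank the groups
#' correctly (the Mundlak model more sharply). With opposite-sign weights
#' (e.g. \eqn{\alpha_1 = -0.5}, \eqn{\alpha_2 = 0.5}) high-rate groups have
#' low mean PRS, so the PRS-only GLM ranks the groups backwards while the
#' Mundlak model recovers the ranking through the group-mean PRS column,
#' which proxies the unobserved non-genetic gradient.
#'
#' @param cohort Data frame with `prs`, `pce` and binary `outcome` columns.
#' @param alpha1,alpha2 Weights on PRS and the non-genetic score in the
#'   hidden grouping variable.
#' @param n_groups Number of quantile groups (default 21).
#' @param covariates Regression covariates (default `"prs"` only).
#' @param seed Integer seed for the hidden-variable draw.
#' @return A list of class `structured_permutation_result`: `config`,
#'   `rates` (per group: `n`, `observed_rate`, GLM and Mundlak predicted
#'   rates), `glm_correlation`, `mundlak_correlation`, and the two
#'   `lococv_result` objects.
#' @export
run_structured_permutation_experiment <- function(cohort, alpha1, alpha2,
                                                  n_groups = 21,
                                                  covariates = "prs",
                                                  seed = 1L) {
  spc <- structured_permutation_config(alpha1, alpha2, n_groups, seed)
  grouped <- assign_quantile_groups(cohort, spc)
  cv_glm <- lococv(grouped, covariates, model = "glm")
  cv_mun <- lococv(grouped, covariates, model = "mundlak")
  rates <- cv_glm$rates
  names(rates)[names(rates) == "predicted_rate"] <- "glm_predicted_rate"
  rates$mundlak_predicted_rate <- cv_mun$rates$predicted_rate
  structure(list(
    config = list(alpha1 = alpha1, alpha2 = alpha2, n_groups = n_groups,
                  covariates = covariates, seed = seed,
                  cohort_n = nrow(cohort)),
    rates = rates,
    glm_correlation = cv_glm$correlation,
    mundlak_correlation = cv_mun$correlation,
    glm_cv = cv_glm,
    mundlak_cv = cv_mun
  ), class = "structured_permutation_result")
}

#' @export
print.structured_permutation_result <- function(x, ...) {
  cat("Structured-permutation experiment (alpha1 = ", x$config$alpha1,
      ", alpha2 = ", x$config$alpha2, ", ", x$config$n_groups,
      " groups, n = ", x$config$cohort_n, ")\n", sep = "")
  cat("LOCOCV correlation, GLM:     ",
      format(x$glm_correlation, digits = 4), "\n")
  cat("LOCOCV correlation, Mundlak: ",
      format(x$mundlak_correlation, digits = 4), "\n")
  invisible(x)
}

#' Covariate subset search over Mundlak GLMs
#'
#' `mode = "exhaustive"` fits one Mundlak GLM per non-empty subset of the
#' candidate covariates (\eqn{2^k - 1} models) and ranks them by in-sample
#' AUC. `mode = "greedy"` reproduces a forward-selection path: the best
#' single covariate, then the best addition to it, and so on until all
#' candidates are included, returning the nested chain of k models. Fit
#' failures are recorded per subset and the search continues.
#'
#' @param cohort Data frame with the candidate covariates and an outcome
#'   column.
#' @param candidate_variables Character vector of covariate names
#'   (exhaustive mode caps at 20).
#' @param mode `"exhaustive"` or `"greedy"`.
#' @param outcome Binary outcome column name.
#' @param model `"mundlak"` (default) or `"glm"`.
#' @return Data frame of class `subset_search_result`, one row per fitted
#'   model: `covariates` (comma-joined), `n_covariates`, `auc`,
#'   `auc_lower`, `auc_upper`, `log_likelihood`, `converged`, `error`
#'   (`NA` when the fit succeeded); exhaustive results are sorted by
#'   decreasing AUC, greedy results are in path order.
#' @export
covariate_subset_search <- function(cohort, candidate_variables,
                                    mode = c("exhaustive", "greedy"),
                                    outcome = "outcome",
                                    model = c("mundlak", "glm")) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  k <- length(candidate_variables)
  if (k == 0) stop_bad_arg("`candidate_variables` must be non-empty")
  if (mode == "exhaustive" && k > 20) {
    stop_bad_arg("exhaustive mode is capped at 20 candidates (got ", k, ")")
  }
  fit_one <- function(vars) {
    res <- tryCatch({
      fit <- if (model == "mundlak") fit_mundlak(cohort, vars, outcome)
             else fit_glm(cohort, vars, outcome)
      p <- predict_probabilities(fit, cohort)
      a <- auc_with_ci(p, cohort[[outcome]])
      data.frame(covariates = paste(vars, collapse = ","),
                 n_covariates = length(vars),
                 auc = a$auc, auc_lower = a$lower, auc_upper = a$upper,
                 log_likelihood = fit$log_likelihood,
                 converged = fit$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(covariates = paste(vars, collapse = ","),
                 n_covariates = length(vars),
                 auc = NA_real_, auc_lower = NA_real_, auc_upper = NA_real_,
                 log_likelihood = NA_real_, converged = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  }
  if (mode == "exhaustive") {
    subsets <- unlist(lapply(seq_len(k), function(m) {
      combn(candidate_variables, m, simplify = FALSE)
    }), recursive = FALSE)
    out <- do.call(rbind, lapply(subsets, fit_one))
    out <- out[order(-out$auc, out$n_covariates, na.last = TRUE), ,
               drop = FALSE]
  } else {
    chosen <- character(0)
    remaining <- candidate_variables
    rows <- list()
    while (length(remaining) > 0) {
      step_fits <- lapply(remaining, function(v) fit_one(c(chosen, v)))
      aucs <- vapply(step_fits, function(r) r$auc, numeric(1))
      if (all(is.na(aucs))) {
        # every extension failed; record them and stop the path
        rows <- c(rows, step_fits)
        break
      }
      best <- which.max(aucs)
      chosen <- c(chosen, remaining[best])
      remaining <- remaining[-best]
      rows[[length(rows) + 1]] <- step_fits[[best]]
    }
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("subset_search_result", class(out))
  out
}

#' Assemble a reproducible experiment report
#'
#' Collects structured-permutation results, per-group Wilson intervals on
#' the predicted rates and an optional AUC table into one list whose
#' `config` snapshot suffices to regenerate every number. The JSON
#' serialization of the report is deterministic given identical inputs.
#'
#' @param structured A `structured_permutation_result` (or a list of
#'   them), or `NULL`.
#' @param subset_search A `subset_search_result`, or `NULL`.
#' @param z Normal quantile for the Wilson intervals (default 1.96).
#' @return A list of class `experiment_report` with fields `config`,
#'   `rates` (including Wilson bounds per group for each model), `lococv`,
#'   `subset_search`.
#' @export
make_report <- function(structured = NULL, subset_search = NULL, z = 1.96) {
  if (is.null(structured) && is.null(subset_search)) {
    stop_bad_arg("nothing to report")
  }
  rates <- NULL
  config <- list()
  lococv_tab <- NULL
  if (!is.null(structured)) {
    if (!inherits(structured, "structured_permutation_result")) {
      stop_bad_arg("`structured` must come from ",
                   "run_structured_permutation_experiment()")
    }
    config$structured <- structured$config
    rates <- structured$rates
    add_wilson <- function(col, prefix) {
      lo <- numeric(nrow(rates)); hi <- numeric(nrow(rates))
      for (i in seq_len(nrow(rates))) {
        w <- wilson_interval(rates[[col]][i], rates$n[i], z = z)
        lo[i] <- w$lower; hi[i] <- w$upper
      }
      rates[[paste0(prefix, "_lower")]] <<- lo
      rates[[paste0(prefix, "_upper")]] <<- hi
    }
    add_wilson("glm_predicted_rate", "glm")
    add_wilson("mundlak_predicted_rate", "mundlak")
    lococv_tab <- data.frame(
      model = c("glm", "mundlak"),
      correlation = c(structured$glm_correlation,
                      structured$mundlak_correlation)
    )
  }
  if (!is.null(subset_search)) {
    config$subset_search <- list(n_models = nrow(subset_search))
  }
  structure(list(config = config, rates = rates, lococv = lococv_tab,
                 subset_search = subset_search),
            class = "experiment_report")
}

#' Serialize an experiment report to JSON
#'
#' @param report An [make_report()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "experiment_report")) {
    stop_bad_arg("`report` must come from make_report()")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE,
                       na = "null")
  invisible(path)
}
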