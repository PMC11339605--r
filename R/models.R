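#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression via `stats::glm.fit` with tight
#' convergence control (relative deviance change below 1e-10, at most 100
#' iterations), plus explicit diagnostics: a rank-deficient design is an
#' error naming the collinear columns, complete separation is an error,
#' and non-convergence is reported in the result rather than silently
#' ignored.
#'
#' @param design_matrix Numeric matrix including the intercept column
#'   (named columns; use [mundlak_design()] for the within-between
#'   parameterization).
#' @param outcomes Binary 0/1 vector.
#' @param column_map Optional list with integer indices `within` and
#'   `between` identifying coefficient roles (attached to the result).
#' @return An object of class `grouprisk_fit`: `coefficients`,
#'   `standard_errors`, `log_likelihood`, `n_iterations`, `converged`,
#'   `column_map`, `n`.
#' @export
fit_logistic <- function(design_matrix, outcomes, column_map = NULL) {
  X <- as.matrix(design_matrix)
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop_bad_arg("`outcomes` must be binary 0/1")
  if (nrow(X) != length(y)) stop_bad_arg("design and outcomes differ in rows")
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_bad_arg("rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-10, maxit = 100))
  )
  mu <- fit$fitted.values
  eps <- 1e-7
  if (all(mu[y == 1] > 1 - eps) && all(mu[y == 0] < eps)) {
    stop_bad_arg("complete separation: fitted probabilities are numerically ",
                 "0/1 for every observation; coefficients diverge")
  }
  w <- mu * (1 - mu)
  xtwx <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(xtwx)))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(X)),
    standard_errors = setNames(se, colnames(X)),
    log_likelihood = ll,
    n_iterations = fit$iter,
    converged = fit$converged,
    column_map = column_map,
    n = length(y)
  ), class = "grouprisk_fit")
}

#' @export
print.grouprisk_fit <- function(x, ...) {
  cat("Logistic fit (", x$n, " observations, logLik ",
      format(x$log_likelihood, digits = 6), ", ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iterations, " iterations)\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$standard_errors)
  print(round(tab, 4))
  invisible(x)
}

#' Within-between (Mundlak) design matrix
#'
#' For each covariate emits a group-demeaned column (`<name>_within`,
#' carrying the within-group effect \eqn{\beta}) and a group-mean column
#' (`<name>_between`, carrying the between-group effect \eqn{\gamma}),
#' plus an intercept. Within-group means of every demeaned column are
#' exactly zero by construction. Including the group means relaxes the
#' random-effects assumption that covariates are uncorrelated with
#' unobserved group-level characteristics: the group mean acts as a proxy
#' for unseen group-specific behaviour.
#'
#' @param cohort Data frame with a `group` column.
#' @param covariates Character vector of numeric covariate column names.
#' @param group_means Optional named list/data frame of group means to use
#'   instead of means computed from `cohort` (used when applying a fitted
#'   model to a new group). Must have a `group` column and one column per
#'   covariate.
#' @return List with the design `matrix` (intercept, within and between
#'   columns) and `column_map` (indices of `within` and `between`
#'   columns).
#' @export
mundlak_design <- function(cohort, covariates, group_means = NULL) {
  if (!"group" %in% names(cohort)) stop_bad_arg("`cohort` needs a `group` column")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0) {
    stop_bad_arg("unknown covariate(s): ", paste(miss, collapse = ", "))
  }
  groups <- unique(cohort$group)
  if (length(groups) < 2 && is.null(group_means)) {
    stop_bad_arg("a single group makes the group-mean column collinear ",
                 "with the intercept; need at least 2 groups")
  }
  sizes <- table(cohort$group)
  if (any(sizes == 1)) {
    warning("group(s) of size 1 (demeaned values are 0 there): ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  }
  if (is.null(group_means)) {
    gm <- aggregate(cohort[covariates], by = list(group = cohort$group), mean)
  } else {
    gm <- as.data.frame(group_means)
    if (!all(c("group", covariates) %in% names(gm))) {
      stop_bad_arg("`group_means` must have `group` and all covariate columns")
    }
  }
  idx <- match(cohort$group, gm$group)
  if (anyNA(idx)) stop_bad_arg("`group_means` missing some cohort groups")
  n <- nrow(cohort)
  k <- length(covariates)
  X <- matrix(0, n, 1 + 2 * k)
  X[, 1] <- 1
  cn <- c("(Intercept)", paste0(covariates, "_within"),
          paste0(covariates, "_between"))
  for (j in seq_len(k)) {
    v <- cohort[[covariates[j]]]
    mj <- gm[[covariates[j]]][idx]
    X[, 1 + j] <- v - mj
    X[, 1 + k + j] <- mj
  }
  colnames(X) <- cn
  list(matrix = X,
       column_map = list(within = 1 + seq_len(k),
                         between = 1 + k + seq_len(k)),
       group_means = gm)
}

#' Fit a Mundlak (within-between) logistic regression
#'
#' Composition of [mundlak_design()] and [fit_logistic()]:
#' \deqn{\mathrm{logit}(p_{gn}) = \beta_0 + \sum_j \beta_j (x_{gnj} -
#'   \bar{x}_{gj}) + \sum_j \gamma_j \bar{x}_{gj},}
#' where each \eqn{\beta} is a within-group effect and each \eqn{\gamma}
#' a between-group effect. A covariate constant within every group makes
#' its demeaned column all zero and is an error naming the covariate.
#'
#' @inheritParams mundlak_design
#' @param outcome Name of the binary outcome column (default
#'   `"outcome"`).
#' @return A `grouprisk_fit` whose `column_map` separates within
#'   (\eqn{\beta}) from between (\eqn{\gamma}) coefficients, with the
#'   design's `group_means` attached.
#' @export
fit_mundlak <- function(cohort, covariates, outcome = "outcome") {
  des <- mundlak_design(cohort, covariates)
  allzero <- vapply(des$column_map$within, function(j) {
    all(abs(des$matrix[, j]) < 1e-12)
  }, logical(1))
  if (any(allzero)) {
    stop_bad_arg("covariate(s) constant within every group: ",
                 paste(covariates[allzero], collapse = ", "))
  }
  fit <- fit_logistic(des$matrix, cohort[[outcome]],
                      column_map = des$column_map)
  fit$covariates <- covariates
  fit$group_means <- des$group_means
  fit$model <- "mundlak"
  fit
}

#' Fit a standard logistic GLM on raw covariates
#'
#' @inheritParams fit_mundlak
#' @return A `grouprisk_fit` with `model = "glm"`.
#' @export
fit_glm <- function(cohort, covariates, outcome = "outcome") {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0) {
    stop_bad_arg("unknown covariate(s): ", paste(miss, collapse = ", "))
  }
  X <- cbind("(Intercept)" = 1,
             as.matrix(cohort[, covariates, drop = FALSE]))
  fit <- fit_logistic(X, cohort[[outcome]])
  fit$covariates <- covariates
  fit$model <- "glm"
  fit
}

#' Predicted probabilities for a fitted model on a cohort
#'
#' For a Mundlak fit, the design is rebuilt with group means computed from
#' the supplied cohort's own covariates (so a new group's rate can be
#' predicted from its covariates alone; outcomes are never used).
#'
#' @param fit A `grouprisk_fit` from [fit_glm()] or [fit_mundlak()].
#' @param cohort Data frame with the fit's covariate columns (and a
#'   `group` column for Mundlak fits).
#' @return Numeric vector of per-individual probabilities.
#' @export
predict_probabilities <- function(fit, cohort) {
  miss <- setdiff(fit$covariates, names(cohort))
  if (length(miss) > 0) {
    stop_bad_arg("cohort lacks covariate(s): ", paste(miss, collapse = ", "))
  }
  X <- if (identical(fit$model, "mundlak")) {
    gm <- aggregate(cohort[fit$covariates], by = list(group = cohort$group),
                    mean)
    mundlak_design(cohort, fit$covariates, group_means = gm)$matrix
  } else {
    cbind("(Intercept)" = 1, as.matrix(cohort[, fit$covariates, drop = FALSE]))
  }
  as.numeric(plogis(X %*% fit$coefficients))
}

#' Per-group predicted case rates
#'
#' The group-level predicted rate is the mean of the per-individual
#' predicted probabilities within each group.
#'
#' @inheritParams predict_probabilities
#' @return Data frame with `group` and `predicted_rate`.
#' @export
predict_group_rates <- function(fit, cohort) {
  p <- predict_probabilities(fit, cohort)
  out <- aggregate(list(predicted_rate = p),
                   by = list(group = cohort$group), mean)
  out[order(out$group), , drop = FALSE]
}

#' Per-group summaries
#'
#' @param cohort Data frame with `group` and outcome columns.
#' @param covariates Covariate columns to average per group.
#' @param outcome Binary outcome column name.
#' @return Data frame with `group`, `n`, `observed_rate` and one mean
#'   column per covariate.
#' @export
group_summary <- function(cohort, covariates = NULL, outcome = "outcome") {
  cols <- c(outcome, covariates)
  gm <- aggregate(cohort[cols], by = list(group = cohort$group), mean)
  names(gm)[names(gm) == outcome] <- "observed_rate"
  n_g <- as.data.frame(table(group = cohort$group), stringsAsFactors = FALSE)
  names(n_g)[2] <- "n"
  n_g$group <- type.convert(n_g$group, as.is = TRUE)
  out <- merge(n_g, gm, by = "group")
  out[order(out$group), , drop = FALSE]
}

#' Leave-one-group-out cross-validation of group-rate prediction
#'
#' Fits the model on all groups but one, predicts the held-out group's
#' case rate as the mean predicted probability of its members, and
#' repeats for every group. For the Mundlak model the held-out group's
#' group-mean columns are computed from its own covariates (its outcomes
#' are never used), matching the target scenario of predicting the rate
#' of a new group for which only covariates are observed. Returns the
#' Pearson correlation between observed and predicted group rates.
#'
#' @param cohort Data frame with `group`, covariates and outcome columns.
#' @param covariates Covariate column names.
#' @param model `"glm"` or `"mundlak"`.
#' @param outcome Binary outcome column name.
#' @return List of class `lococv_result`: data frame `rates` (`group`,
#'   `n`, `observed_rate`, `predicted_rate`), `correlation`, `model`,
#'   `failed_folds` (character vector of groups whose fold failed;
#'   `correlation` is `NA` unless all folds succeed).
#' @export
lococv <- function(cohort, covariates, model = c("mundlak", "glm"),
                   outcome = "outcome") {
  model <- match.arg(model)
  groups <- sort(unique(cohort$group))
  if (length(groups) < 3) stop_bad_arg("need at least 3 groups")
  obs <- group_summary(cohort, outcome = outcome)
  pred <- rep(NA_real_, length(groups))
  failed <- character(0)
  for (i in seq_along(groups)) {
    g <- groups[i]
    train <- cohort[cohort$group != g, , drop = FALSE]
    test <- cohort[cohort$group == g, , drop = FALSE]
    fit <- tryCatch(
      if (model == "mundlak") fit_mundlak(train, covariates, outcome)
      else fit_glm(train, covariates, outcome),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed <- c(failed, as.character(g))
      next
    }
    pred[i] <- mean(predict_probabilities(fit, test))
  }
  rates <- data.frame(group = groups,
                      n = obs$n,
                      observed_rate = obs$observed_rate,
                      predicted_rate = pred)
  corr <- if (length(failed) == 0) {
    cor(rates$observed_rate, rates$predicted_rate)
  } else {
    NA_real_
  }
  structure(list(rates = rates, correlation = corr, model = model,
                 covariates = covariates, failed_folds = failed),
            class = "lococv_result")
}

#' @export
print.lococv_result <- function(x, ...) {
  cat("Leave-one-group-out CV (", x$model, " on ",
      paste(x$covariates, collapse = ", "), ")\n", sep = "")
  cat("correlation(observed, predicted) =",
      format(x$correlation, digits = 4), "\n")
  if (length(x$failed_folds) > 0) {
    cat("failed folds:", paste(x$failed_folds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wilson score interval by damped fixed-point iteration
#'
#' Solves the two fixed-point equations
#' \eqn{p = \hat{p} \pm z\sqrt{p(1-p)/n}} by damped iteration starting
#' from \eqn{\hat{p}}; their solutions are exactly the closed-form Wilson
#' score bounds (both satisfy \eqn{(p-\hat{p})^2 = z^2 p(1-p)/n}). Used
#' for uncertainty intervals on group-mean predicted probabilities, with
#' `n` the group size.
#'
#' @param point_estimate Proportion \eqn{\hat{p}} in \eqn{[0, 1]}.
#' @param n Effective count (at least 1).
#' @param z Normal quantile (default 1.96 for 95%).
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Maximum iterations before erroring.
#' @return List of class `wilson_interval`: `point`, `lower`, `upper`,
#'   `z`, `n`, `iterations_to_converge`.
#' @export
wilson_interval <- function(point_estimate, n, z = 1.96, tol = 1e-10,
                            max_iter = 200) {
  p_hat <- point_estimate
  if (is.na(p_hat) || p_hat < 0 || p_hat > 1) {
    stop_bad_arg("`point_estimate` must be in [0, 1]")
  }
  if (n < 1) stop_bad_arg("`n` must be at least 1")
  solve_side <- function(dir) {
    # start strictly inside (0,1) so the opposite bound is not captured by
    # the degenerate boundary root of p = p_hat +/- z*sqrt(p(1-p)/n)
    p <- min(max(p_hat, 1e-4), 1 - 1e-4)
    if (p_hat == 0 && dir < 0) return(list(value = 0, iter = 1L))
    if (p_hat == 1 && dir > 0) return(list(value = 1, iter = 1L))
    # damped iteration with secant acceleration on the residual
    # r(p) = (p_hat +/- z*sqrt(p(1-p)/n)) - p, whose zero is the bound
    p_prev <- NA_real_
    res_prev <- NA_real_
    residual_at <- function(p) {
      target <- p_hat + dir * z * sqrt(p * (1 - p) / n)
      min(max(target, 0), 1) - p
    }
    lo <- NA_real_  # residual > 0 here (left of the root)
    hi <- NA_real_  # residual < 0 here (right of the root)
    for (k in seq_len(max_iter)) {
      res <- residual_at(p)
      if (abs(res) < tol) {
        return(list(value = p, iter = k))
      }
      if (res > 0) lo <- p else hi <- p
      slope <- if (!is.na(p_prev) && p != p_prev) {
        (res - res_prev) / (p - p_prev)
      } else {
        NA_real_
      }
      p_prev <- p
      res_prev <- res
      p <- if (is.finite(slope) && slope < -1e-12) {
        min(max(p - res / slope, 0), 1)  # secant step toward the root
      } else {
        p + 0.5 * res                    # damped fixed-point step
      }
      # once the root is bracketed, keep iterates inside (bisect if not)
      if (!is.na(lo) && !is.na(hi) && (p <= min(lo, hi) ||
                                       p >= max(lo, hi))) {
        p <- (lo + hi) / 2
      }
    }
    stop_bad_arg("Wilson fixed point did not converge within ", max_iter,
                 " iterations (last iterate ", format(p), ")")
  }
  lo <- solve_side(-1)
  hi <- solve_side(+1)
  structure(list(point = p_hat, lower = lo$value, upper = hi$value,
                 z = z, n = n,
                 iterations_to_converge = max(lo$iter, hi$iter)),
            class = "wilson_interval")
}

#' Closed-form Wilson score bounds
#'
#' Reference implementation used to validate the fixed-point solver.
#'
#' @inheritParams wilson_interval
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_closed_form <- function(point_estimate, n, z = 1.96) {
  p <- point_estimate
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' AUC with a DeLong-variance confidence interval
#'
#' The area under the ROC curve equals the Mann-Whitney U statistic
#' divided by \eqn{n_1 n_0} (mid-rank tie handling). Its variance is
#' estimated with the placement-value (structural components) estimator:
#' with case placements \eqn{V_{10,i}} and control placements
#' \eqn{V_{01,j}}, \eqn{SE^2 = \mathrm{var}(V_{10})/n_1 +
#' \mathrm{var}(V_{01})/n_0}. The interval is
#' \eqn{AUC \pm z\,SE} clipped to \eqn{[0, 1]}.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary 0/1 (or logical) class labels; both classes must
#'   be present.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `lower`, `upper`, `se`, `n_cases`,
#'   `n_controls`, `variance_method = "placement-values"`.
#' @export
auc_with_ci <- function(scores, labels, level = 0.95) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop_bad_arg("`labels` must be binary 0/1")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_bad_arg("both classes must be present")
  r <- rank(scores)            # mid-ranks in the combined sample
  r1 <- rank(scores[y == 1])   # mid-ranks among cases
  r0 <- rank(scores[y == 0])   # mid-ranks among controls
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  v10 <- (r[y == 1] - r1) / n0         # placement of each case
  v01 <- 1 - (r[y == 0] - r0) / n1     # placement of each control
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       lower = max(0, auc - z * se),
       upper = min(1, auc + z * se),
       se = se, n_cases = n1, n_controls = n0,
       variance_method = "placement-values")
}
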