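#' Centre and variance-standardize a polygenic risk score
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return `values` shifted to mean 0 and scaled to sample variance 1.
#' @examples
#' standardize_prs(c(1, 2, 3))  # -1 0 1
#' @export
standardize_prs <- function(values) {
  if (!is.numeric(values)) stop_bad_arg("`values` must be numeric")
  if (length(values) < 2 || length(unique(values)) < 2) {
    stop_bad_arg("standardization needs at least 2 distinct values")
  }
  s <- sd(values)
  if (s == 0) stop_bad_arg("zero variance input")
  (values - mean(values)) / s
}

# ---------------------------------------------------------------------------
# Pooled-cohort-equation style scoring.
#
# The scoring contract: per-stratum coefficient maps over transformed
# covariate terms, a mean linear predictor, and a baseline survival S0;
# risk = 1 - S0 ^ exp(xb - mean_lp). Published coefficient tables plug in
# through the same schema; the shipped fixture is synthetic.
# ---------------------------------------------------------------------------

#' Load a PCE-style coefficient table
#'
#' The JSON schema is a `strata` object keyed by stratum name (by default
#' the `sex` value, e.g. `"female"`, `"male"`), each with fields
#' `coefficients` (named map over term names), `mean_lp` (mean linear
#' predictor in the source population) and `s0` (baseline survival in
#' (0,1)). Recognised term names: `log_age`, `log_total_chol`, `log_hdl`,
#' `log_sbp_treated`, `log_sbp_untreated`, `smoking`, `diabetes`, and
#' products of these written with `:` (e.g. `log_age:log_total_chol`).
#'
#' A synthetic example table (not the published coefficients) ships at
#' `system.file("extdata", "pce_coefficients_synthetic.json",
#' package = "grouprisk")`.
#'
#' @param path Path to a JSON file, or a list already in the schema.
#' @return An object of class `pce_coefficients`.
#' @export
pce_coefficients <- function(path) {
  spec <- if (is.character(path)) jsonlite::read_json(path) else path
  if (is.null(spec$strata) || length(spec$strata) == 0) {
    stop_bad_arg("coefficient table must have a non-empty `strata` field")
  }
  for (nm in names(spec$strata)) {
    st <- spec$strata[[nm]]
    s0 <- st$s0
    if (is.null(s0) || s0 <= 0 || s0 >= 1) {
      stop_bad_arg("stratum '", nm, "': `s0` must be in (0, 1)")
    }
    if (is.null(st$mean_lp)) {
      stop_bad_arg("stratum '", nm, "': missing `mean_lp`")
    }
    spec$strata[[nm]]$coefficients <-
      unlist(st$coefficients %||% list())
  }
  structure(spec, class = "pce_coefficients")
}

# Term values for one record; interaction terms are ':'-joined products.
pce_term_value <- function(term, record) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  vals <- vapply(parts, function(p) pce_base_term(p, record), numeric(1))
  prod(vals)
}

pce_base_term <- function(name, record) {
  need_log <- function(field) {
    v <- record[[field]]
    if (is.null(v) || is.na(v)) {
      stop_bad_arg("record is missing `", field, "` needed for term `",
                   name, "`")
    }
    if (v <= 0) {
      stop_bad_arg("`", field, "` = ", v,
                   " is non-positive under a log transform")
    }
    log(v)
  }
  switch(name,
    log_age = need_log("age"),
    log_total_chol = need_log("total_chol"),
    log_hdl = need_log("hdl"),
    log_sbp_treated = if (isTRUE(record$htn_med == 1 | record$htn_med == TRUE))
      need_log("sbp") else 0,
    log_sbp_untreated = if (isTRUE(record$htn_med == 1 | record$htn_med == TRUE))
      0 else need_log("sbp"),
    smoking = as.numeric(record$smoking),
    diabetes = as.numeric(record$diabetes),
    stop_bad_arg("unknown coefficient term `", name, "`")
  )
}

#' Compute a PCE-style absolute risk for one individual
#'
#' Applies the stratum's coefficient map to the individual's transformed
#' covariates and returns `1 - s0 ^ exp(xb - mean_lp)`, the proportional
#' hazards absolute-risk formula.
#'
#' @param record A one-row data frame or named list with fields `sex`,
#'   `age`, `total_chol`, `hdl`, `sbp`, `smoking`, `htn_med`, `diabetes`
#'   (only the fields named by the stratum's terms are required).
#' @param coef A [pce_coefficients()] table.
#' @return Risk in (0, 1).
#' @export
compute_pce <- function(record, coef) {
  if (!inherits(coef, "pce_coefficients")) {
    stop_bad_arg("`coef` must be created with pce_coefficients()")
  }
  stratum_name <- as.character(record$sex %||% NA)
  st <- coef$strata[[stratum_name]]
  if (is.null(st)) {
    stop_bad_arg("no stratum for sex = '", stratum_name, "'; available: ",
                 paste(names(coef$strata), collapse = ", "))
  }
  cf <- st$coefficients
  xb <- 0
  for (term in names(cf)) {
    xb <- xb + cf[[term]] * pce_term_value(term, record)
  }
  1 - st$s0^exp(xb - st$mean_lp)
}

#' Vectorized PCE scoring over a cohort
#'
#' @param cohort Data frame of individual records.
#' @param coef A [pce_coefficients()] table.
#' @return Numeric vector of risks, one per row.
#' @export
compute_pce_cohort <- function(cohort, coef) {
  vapply(seq_len(nrow(cohort)),
         function(i) compute_pce(cohort[i, , drop = FALSE], coef),
         numeric(1))
}

#' Eligibility for PCE-style risk scoring
#'
#' Applies the standard exclusions: extreme total cholesterol (>320 or
#' <130 mg/dl), extreme HDL (>100 or <20 mg/dl), extreme systolic blood
#' pressure (>200 or <90 mm Hg), prior ASCVD, LDL-C >= 190 mg/dl, and
#' current statin use. Boundary values are eligible ("extreme" is strict).
#' All violated rules are reported, not just the first; a missing required
#' field is itself a reason (`"missing:<field>"`).
#'
#' @param records Data frame with columns among `total_chol`, `hdl`,
#'   `sbp`, `ascvd_status` (one of `"prevalence"`, `"incidence"`,
#'   `"none"`), `ldl`, `statin_user`. Absent optional columns
#'   (`ascvd_status`, `ldl`, `statin_user`) are treated as passing.
#' @return Data frame with logical `eligible` and character `reasons`
#'   (`";"`-joined, `""` when eligible), one row per record.
#' @export
pce_eligibility <- function(records) {
  n <- nrow(records)
  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  check_range <- function(field, low, high, label) {
    if (!field %in% names(records)) {
      add(rep(TRUE, n), paste0("missing:", field))
      return(invisible())
    }
    v <- records[[field]]
    add(is.na(v), paste0("missing:", field))
    ok <- !is.na(v)
    add(ok & (v > high | v < low), label)
  }
  check_range("total_chol", 130, 320, "total_cholesterol_extreme")
  check_range("hdl", 20, 100, "hdl_extreme")
  check_range("sbp", 90, 200, "sbp_extreme")
  if ("ascvd_status" %in% names(records)) {
    add(!is.na(records$ascvd_status) & records$ascvd_status == "prevalence",
        "prior_ascvd")
  }
  if ("ldl" %in% names(records)) {
    add(!is.na(records$ldl) & records$ldl >= 190, "ldl_high")
  }
  if ("statin_user" %in% names(records)) {
    add(!is.na(records$statin_user) & as.logical(records$statin_user),
        "statin")
  }
  reason_str <- vapply(reasons, function(r) paste(r, collapse = ";"),
                       character(1))
  data.frame(eligible = reason_str == "", reasons = reason_str,
             stringsAsFactors = FALSE)
}

#' Statin names triggering the statin-use exclusion
#' @return Character vector of the five statins checked.
#' @export
statin_names <- function() {
  c("atorvastatin", "simvastatin", "fluvastatin", "pravastatin",
    "rosuvastatin")
}

# ---------------------------------------------------------------------------
# Event classification: prevalence vs incidence with earliest-event rule.
# ---------------------------------------------------------------------------

date_categories <- c("ICD-10", "ICD-9", "OPCS-4")
age_categories <- c("self-report-illness", "self-report-operation",
                    "vascular-heart-field")

#' Classify disease events into prevalence / incidence per individual
#'
#' Event records come in six categories; `ICD-10`, `ICD-9` and `OPCS-4`
#' carry a calendar date, while the self-report and vascular/heart-field
#' categories carry an integer age at onset. Age-coded events are
#' converted to an approximate date as July 1 of `birth_year + age`
#' (mid-year convention; the half-year ambiguity is surfaced via the
#' `approx_date` flag). The chronologically earliest event per individual
#' is kept; its status is `"prevalence"` if it strictly precedes the
#' individual's enrolment date and `"incidence"` otherwise. Individuals
#' with no events get status `"none"`.
#'
#' @param events Data frame with columns `individual_id`, `category`,
#'   `code`, and exactly one of `date` (coercible with `as.Date`) or
#'   `age` (integer) non-missing per row.
#' @param individuals Data frame with columns `individual_id`,
#'   `enrollment_date`, and `birth_year` (needed only when age-coded
#'   events exist for that individual).
#' @return Data frame with one row per individual: `individual_id`,
#'   `status`, `event_date`, `category`, `code`, `approx_date`.
#' @export
classify_events <- function(events, individuals) {
  req <- c("individual_id", "enrollment_date")
  if (!all(req %in% names(individuals))) {
    stop_bad_arg("`individuals` needs columns: ", paste(req, collapse = ", "))
  }
  individuals$enrollment_date <- as.Date(individuals$enrollment_date)

  if (nrow(events) > 0) {
    has_date <- !is.na(events$date %||% rep(NA, nrow(events)))
    has_age <- !is.na(events$age %||% rep(NA, nrow(events)))
    bad <- !xor(has_date, has_age)
    if (any(bad)) {
      stop_bad_arg("event records must carry exactly one of date/age; ",
                   "offending individual(s): ",
                   paste(unique(events$individual_id[bad]), collapse = ", "))
    }
    wrong_cat <- (events$category %in% date_categories & has_age) |
      (events$category %in% age_categories & has_date)
    if (any(wrong_cat)) {
      stop_bad_arg("category/date-age mismatch for individual(s): ",
                   paste(unique(events$individual_id[wrong_cat]),
                         collapse = ", "))
    }
    by <- match(events$individual_id, individuals$individual_id)
    if (anyNA(by)) {
      stop_bad_arg("events reference unknown individual(s): ",
                   paste(unique(events$individual_id[is.na(by)]),
                         collapse = ", "))
    }
    ev_date <- as.Date(rep(NA, nrow(events)))
    ev_date[has_date] <- as.Date(events$date[has_date])
    if (any(has_age)) {
      byear <- individuals$birth_year[by]
      if (any(has_age & is.na(byear))) {
        stop_bad_arg("age-coded events need `birth_year` for individual(s): ",
                     paste(unique(events$individual_id[has_age & is.na(byear)]),
                           collapse = ", "))
      }
      ev_date[has_age] <- as.Date(paste0(byear[has_age] +
                                           events$age[has_age], "-07-01"))
    }
    events$.event_date <- ev_date
    events$.approx <- has_age
  }

  out <- data.frame(
    individual_id = individuals$individual_id,
    status = "none",
    event_date = as.Date(rep(NA, nrow(individuals))),
    category = NA_character_,
    code = NA_character_,
    approx_date = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(events) > 0) {
    # earliest event per individual; ties keep the first record seen after
    # a stable sort by date
    ord <- order(events$individual_id, events$.event_date)
    ev <- events[ord, , drop = FALSE]
    first <- ev[!duplicated(ev$individual_id), , drop = FALSE]
    idx <- match(first$individual_id, out$individual_id)
    out$event_date[idx] <- first$.event_date
    out$category[idx] <- first$category
    out$code[idx] <- first$code
    out$approx_date[idx] <- first$.approx
    enrol <- individuals$enrollment_date[idx]
    out$status[idx] <- ifelse(first$.event_date < enrol,
                              "prevalence", "incidence")
  }
  out
}
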