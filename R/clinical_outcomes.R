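DAYS_PER_MONTH <- 30.4375

#' Recurrence-free survival time in months
#'
#' Months from an origin (surgery or first vaccination) to recurrence or
#' censoring, using a 30.4375-day month (365.25 / 12).
#'
#' @param origin `Date` of the time origin.
#' @param endpoint `Date` of recurrence or last follow-up.
#' @return Months, a non-negative number.
#' @export
rfs_months <- function(origin, endpoint) {
  origin <- as.Date(origin)
  endpoint <- as.Date(endpoint)
  d <- as.numeric(endpoint - origin)
  if (any(d < 0)) abort("origin date is after the endpoint date")
  d / DAYS_PER_MONTH
}

#' Kaplan-Meier median survival time
#'
#' The smallest time at which the product-limit survivor estimate drops to
#' 0.5 or below; `NA` when the curve never reaches 0.5 (heavy censoring).
#' Computed with [survival::survfit()].
#'
#' @param times Non-negative event/censoring times.
#' @param events Event indicators (1 = recurrence, 0 = censored).
#' @return The median survival time, or `NA`.
#' @export
km_median <- function(times, events) {
  if (length(times) == 0) abort("no survival times supplied")
  if (length(times) != length(events)) {
    abort("times and events must have equal length")
  }
  if (any(times < 0)) abort("survival times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  cross <- fit$time[fit$surv <= 0.5 + 1e-12]
  if (length(cross) == 0) NA_real_ else min(cross)
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank chi-square test across two or more groups, via
#' [survival::survdiff()].
#'
#' @inheritParams km_median
#' @param groups Group labels, one per observation (>= 2 distinct values).
#' @return List with `chisq`, `df` and `p_value`.
#' @export
logrank_compare <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("log-rank comparison needs at least two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Standardized mean differences between treated and control
#'
#' `(mean_t - mean_c) / sqrt((var_t + var_c) / 2)` per covariate; the usual
#' balance diagnostic before/after matching.
#'
#' @param data Data frame holding the covariates.
#' @param treated Logical vector, `TRUE` for treated rows.
#' @param covariates Character vector of (numeric or 0/1) covariate columns.
#' @return Named numeric vector of absolute SMDs.
#' @export
standardized_mean_diff <- function(data, treated, covariates) {
  vapply(covariates, function(v) {
    x <- as.numeric(data[[v]])
    mt <- mean(x[treated]); mc <- mean(x[!treated])
    s <- sqrt((stats::var(x[treated]) + stats::var(x[!treated])) / 2)
    if (s == 0) return(0)
    abs(mt - mc) / s
  }, numeric(1))
}

#' Propensity-score matching of controls to treated patients
#'
#' Fits a logistic propensity model on the covariates, then matches each
#' treated patient to up to `ratio` controls by greedy nearest-neighbor
#' search on the logit of the propensity score, without replacement, within
#' a caliper. Following the common convention, `caliper = 0.2` means 0.2
#' standard deviations of the logit propensity (set
#' `caliper_scale = "probability"` for a raw probability-scale caliper).
#' Treated patients are processed in a seeded random order; treated patients
#' with no eligible control within the caliper are reported unmatched.
#'
#' @param data Data frame with one row per subject.
#' @param treated Logical vector, `TRUE` for treated (vaccinated) rows.
#' @param covariates Character vector of covariate column names; constant
#'   columns are dropped with a warning.
#' @param ratio Controls per treated patient (default 2).
#' @param caliper Caliper width (default 0.2).
#' @param caliper_scale `"logit"` (default) or `"probability"`.
#' @param seed Seed for the match order.
#' @return List with `matches` (tibble `treated_row, control_row, distance`),
#'   `unmatched_treated` (row indices), `propensity` (fitted scores) and
#'   `caliper_width` (on the matching scale).
#' @export
propensity_match <- function(data, treated, covariates, ratio = 2,
                             caliper = 0.2, caliper_scale = c("logit",
                                                              "probability"),
                             seed = 1L) {
  caliper_scale <- match.arg(caliper_scale)
  stopifnot(length(treated) == nrow(data))
  keep <- vapply(covariates, function(v) {
    length(unique(as.numeric(data[[v]]))) > 1
  }, logical(1))
  if (any(!keep)) {
    warn(paste0("dropping constant covariate(s): ",
                paste(covariates[!keep], collapse = ", ")))
  }
  covariates <- covariates[keep]
  if (length(covariates) == 0) abort("no usable covariates for matching")

  form <- stats::as.formula(paste(".treated ~",
                                  paste(covariates, collapse = " + ")))
  mdat <- data[, covariates, drop = FALSE]
  mdat$.treated <- as.integer(treated)
  fit <- stats::glm(form, family = stats::binomial(), data = mdat)
  ps <- stats::predict(fit, type = "response")
  eps <- 1e-12
  lps <- stats::qlogis(pmin(pmax(ps, eps), 1 - eps))
  score <- if (caliper_scale == "logit") lps else ps
  cal_width <- if (caliper_scale == "logit") caliper * stats::sd(lps) else
    caliper

  t_idx <- which(treated)
  c_free <- which(!treated)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  order_t <- sample(t_idx)

  matches <- list()
  unmatched <- integer()
  for (ti in order_t) {
    got <- 0L
    for (r in seq_len(ratio)) {
      if (length(c_free) == 0) break
      d <- abs(score[c_free] - score[ti])
      j <- which.min(d)
      if (d[j] <= cal_width) {
        matches[[length(matches) + 1L]] <- tibble::tibble(
          treated_row = ti, control_row = c_free[j], distance = d[j])
        c_free <- c_free[-j]
        got <- got + 1L
      } else break
    }
    if (got == 0L) unmatched <- c(unmatched, ti)
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(treated_row = integer(), control_row = integer(),
                   distance = numeric())
  list(matches = matches, unmatched_treated = sort(unmatched),
       propensity = ps, caliper_width = cal_width)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
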