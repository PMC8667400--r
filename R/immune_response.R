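#' ELISpot positivity of one stimulated well set
#'
#' A stimulus (peptide pool or single peptide) is called positive against its
#' matched negative control when the mean spot count is at least `fold` times
#' the control mean *and* exceeds it by at least `min_excess` spots. Both
#' margins are conventional empirical ELISpot criteria and are configurable.
#'
#' @param stim_spots Replicate spot counts for the stimulated wells.
#' @param nc_spots Replicate spot counts for the matched negative control
#'   (same patient and timepoint).
#' @param fold Minimum fold change over control (default 2).
#' @param min_excess Minimum absolute excess in spots (default 10).
#' @return `TRUE` or `FALSE`.
#' @examples
#' response_positive(c(55, 60, 65), c(4, 5, 6))  # TRUE
#' @export
response_positive <- function(stim_spots, nc_spots, fold = 2.0,
                              min_excess = 10) {
  if (length(stim_spots) < 1 || length(nc_spots) < 1) {
    abort("at least one replicate is required for stimulus and control")
  }
  if (any(stim_spots < 0) || any(nc_spots < 0)) {
    abort("spot counts must be non-negative")
  }
  ms <- mean(stim_spots)
  mn <- mean(nc_spots)
  ms >= fold * mn && (ms - mn) >= min_excess
}

#' Call ELISpot responses for a whole measurement table
#'
#' Pairs each pool/peptide stimulus with the negative control of the same
#' patient and timepoint and applies [response_positive()].
#'
#' @param elispot Data frame `patient, timepoint, stimulus, replicate, spots`;
#'   negative-control wells have `stimulus == "NC"` (positive controls
#'   `"PC"` are ignored for calling).
#' @inheritParams response_positive
#' @return Tibble `patient, timepoint, stimulus, mean_spots, nc_mean,
#'   positive`.
#' @export
call_responses <- function(elispot, fold = 2.0, min_excess = 10) {
  elispot <- tibble::as_tibble(elispot)
  nc <- elispot[elispot$stimulus == "NC", ] |>
    dplyr::group_by(.data$patient, .data$timepoint) |>
    dplyr::summarize(nc_mean = mean(.data$spots), .groups = "drop")
  stim <- elispot[!elispot$stimulus %in% c("NC", "PC"), ] |>
    dplyr::group_by(.data$patient, .data$timepoint, .data$stimulus) |>
    dplyr::summarize(mean_spots = mean(.data$spots), .groups = "drop")
  out <- dplyr::inner_join(stim, nc, by = c("patient", "timepoint"))
  if (nrow(out) < nrow(stim)) {
    abort("stimulated wells without a matched negative control")
  }
  out$positive <- out$mean_spots >= fold * out$nc_mean &
    (out$mean_spots - out$nc_mean) >= min_excess
  out
}

post_boost_timepoints <- c("post_boost", "follow_up")

#' Did a patient develop responsive neoantigens?
#'
#' A patient counts as having responsive neoantigens when at least one pool
#' or peptide stimulus is positive at a post-boost timepoint (including
#' follow-up). Pre-existing reactivity that disappears after the boost phase
#' does not qualify. Only patients who completed the boost phase can be
#' classified; prime-only patients form a separate clinical group.
#'
#' @param calls Response-call tibble from [call_responses()] for one patient,
#'   with `timepoint` in `pre, post_prime, post_boost, follow_up`.
#' @param completed_boost Did the patient receive the boost vaccinations?
#' @return `TRUE` or `FALSE`.
#' @export
patient_responsive <- function(calls, completed_boost = TRUE) {
  if (!completed_boost) {
    abort("response status is undefined for prime-only patients")
  }
  any(calls$positive & calls$timepoint %in% post_boost_timepoints)
}

#' Peptide-level immune response rate
#'
#' @param n_positive Number of peptides with a positive response.
#' @param n_tested Number of peptides tested (>= 1).
#' @return Percent, rounded to one decimal.
#' @examples
#' peptide_response_rate(36, 51)  # 70.6
#' @export
peptide_response_rate <- function(n_positive, n_tested) {
  if (any(n_tested < 1)) abort("n_tested must be at least 1")
  if (any(n_positive > n_tested)) abort("n_positive cannot exceed n_tested")
  round(100 * n_positive / n_tested, 1)
}

#' Response durability summary
#'
#' Mean spots per pool at each timepoint for one patient — the reporting
#' style used for long-term follow-up (e.g. "average 67.8 spots in 2
#' neoantigen pools"). No decay model is fitted.
#'
#' @param elispot ELISpot table for one patient (see [call_responses()]).
#' @return Tibble `timepoint, n_pools, mean_spots`.
#' @export
durability_summary <- function(elispot) {
  elispot <- tibble::as_tibble(elispot)
  pools <- elispot[!elispot$stimulus %in% c("NC", "PC"), ]
  pools |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarize(n_pools = length(unique(.data$stimulus)),
                     mean_spots = mean(.data$spots), .groups = "drop")
}
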