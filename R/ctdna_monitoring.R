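#' Plasma site detection call
#'
#' A panel site is called detected in a plasma sample when at least
#' `min_alt_reads` mutant reads are observed. Plasma positivity has no
#' community-standard definition; the >= 2 mutant-read default is this
#' package's choice and every caller exposes it.
#'
#' @param alt_reads Mutant read counts (vectorized).
#' @param min_alt_reads Detection threshold (default 2).
#' @return Logical vector.
#' @export
site_detected <- function(alt_reads, min_alt_reads = 2) {
  if (any(alt_reads < 0, na.rm = TRUE)) abort("alt_reads must be non-negative")
  out <- alt_reads >= min_alt_reads
  out[is.na(out)] <- FALSE
  out
}

subset_plasma <- function(sample, subset = c("target", "other", "all")) {
  subset <- match.arg(subset)
  if (!all(c("alt_reads", "total_reads") %in% names(sample))) {
    abort("plasma sample needs alt_reads and total_reads columns")
  }
  if (any(sample$alt_reads > sample$total_reads)) {
    abort("alt_reads cannot exceed total_reads")
  }
  out <- switch(subset,
    target = sample[sample$is_target, , drop = FALSE],
    other = sample[!sample$is_target, , drop = FALSE],
    all = sample
  )
  if (nrow(out) == 0) abort(paste0("no panel sites in subset \"", subset, "\""))
  out
}

#' Fraction of panel sites detected in one plasma sample
#'
#' @param sample Plasma observations at one timepoint: a data frame with
#'   `alt_reads`, `total_reads` and logical `is_target`.
#' @param subset Which panel sites to use: vaccine-targeted neoantigen sites
#'   (`"target"`), other somatic sites (`"other"`), or all.
#' @inheritParams site_detected
#' @return Detected sites / panel sites in the subset, a fraction.
#' @export
positive_rate <- function(sample, subset = c("target", "other", "all"),
                          min_alt_reads = 2) {
  s <- subset_plasma(sample, subset)
  mean(site_detected(s$alt_reads, min_alt_reads))
}

#' Mean VAF across a plasma panel subset
#'
#' Per-site VAF is `alt_reads / total_reads`. Under the default `"zero"`
#' policy undetected sites contribute a VAF of 0, keeping timepoints with
#' different detection comparable; `"exclude"` averages detected sites only
#' (and is 0 when nothing is detected).
#'
#' @inheritParams positive_rate
#' @param undetected_policy `"zero"` or `"exclude"`.
#' @return Mean VAF, a fraction.
#' @export
mean_vaf <- function(sample, subset = c("target", "other", "all"),
                     undetected_policy = c("zero", "exclude"),
                     min_alt_reads = 2) {
  undetected_policy <- match.arg(undetected_policy)
  s <- subset_plasma(sample, subset)
  vaf <- ifelse(s$total_reads > 0, s$alt_reads / s$total_reads, 0)
  det <- site_detected(s$alt_reads, min_alt_reads)
  if (undetected_policy == "zero") {
    mean(ifelse(det, vaf, 0))
  } else {
    if (!any(det)) return(0)
    mean(vaf[det])
  }
}

#' Percent decline between two VAF measurements
#'
#' `100 * (v_before - v_after) / v_before`; negative values indicate an
#' increase.
#'
#' @param v_before,v_after VAFs (or any positive burden measure) at the
#'   earlier and later timepoint.
#' @return Percent decline.
#' @examples
#' percent_decline(0.200, 0.022)  # 89
#' @export
percent_decline <- function(v_before, v_after) {
  if (any(v_before <= 0)) abort("percent decline undefined for v_before <= 0")
  100 * (v_before - v_after) / v_before
}

#' Mean-VAF trajectories of targeted vs other panel sites
#'
#' Collapses longitudinal plasma observations for one patient into per-day
#' mean VAFs, split into vaccine-targeted neoantigen sites and other somatic
#' sites.
#'
#' @param plasma Data frame of one patient's observations: `day, alt_reads,
#'   total_reads, is_target` (a `patient` column, if present, must be
#'   constant).
#' @inheritParams mean_vaf
#' @return Tibble `day, mean_vaf_target, mean_vaf_other, n_detected_target,
#'   n_detected_other`, ordered by day, with attributes `n_sites_target` and
#'   `n_sites_other`.
#' @export
panel_trajectory <- function(plasma, undetected_policy = c("zero", "exclude"),
                             min_alt_reads = 2) {
  undetected_policy <- match.arg(undetected_policy)
  if ("patient" %in% names(plasma) && length(unique(plasma$patient)) > 1) {
    abort("panel_trajectory expects a single patient's observations")
  }
  if (!any(plasma$is_target) || all(plasma$is_target)) {
    abort("panel needs both targeted and other sites")
  }
  days <- sort(unique(plasma$day))
  rows <- lapply(days, function(d) {
    s <- plasma[plasma$day == d, , drop = FALSE]
    tibble::tibble(
      day = d,
      mean_vaf_target = mean_vaf(s, "target", undetected_policy, min_alt_reads),
      mean_vaf_other = mean_vaf(s, "other", undetected_policy, min_alt_reads),
      n_detected_target = sum(site_detected(s$alt_reads[s$is_target],
                                            min_alt_reads)),
      n_detected_other = sum(site_detected(s$alt_reads[!s$is_target],
                                           min_alt_reads))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_sites_target") <- length(unique(
    plasma$site[plasma$is_target %in% TRUE]))
  attr(out, "n_sites_other") <- length(unique(
    plasma$site[plasma$is_target %in% FALSE]))
  out
}

#' Classify the ctDNA dynamic pattern of a patient
#'
#' Two qualitative patterns are seen when tracking targeted neoantigen sites
#' against the rest of the somatic panel: a *concordant* pattern where both
#' mean-VAF series move together (low tumor heterogeneity: most cells carry
#' the targeted mutations) and a *divergent* pattern where only the targeted
#' sites decline while other mutations keep rising (preferential killing of
#' vaccine-targeted clones). Patients whose panel is rarely detected in
#' plasma are *untrackable*.
#'
#' Classification: untrackable if fewer than `min_timepoints` timepoints have
#' any detected site; otherwise concordant when the Spearman rank correlation
#' between the two series is at least `rho_threshold`, else divergent.
#' Constant series (no rank information) are treated as concordant, since a
#' flat series gives no evidence of divergence.
#'
#' @param traj Trajectory tibble from [panel_trajectory()].
#' @param min_timepoints Minimum informative timepoints (default 3).
#' @param rho_threshold Spearman correlation cut point (default 0.7).
#' @return One of `"concordant"`, `"divergent"`, `"untrackable"`.
#' @export
classify_pattern <- function(traj, min_timepoints = 3, rho_threshold = 0.7) {
  informative <- traj$n_detected_target + traj$n_detected_other > 0
  if (sum(informative) < min_timepoints) return("untrackable")
  x <- traj$mean_vaf_target[informative]
  y <- traj$mean_vaf_other[informative]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return("concordant")
  rho <- stats::cor(x, y, method = "spearman")
  if (rho >= rho_threshold) "concordant" else "divergent"
}

#' Plot targeted vs other mean-VAF trajectories
#'
#' @param traj Trajectory tibble from [panel_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  long <- tidyr::pivot_longer(
    traj[, c("day", "mean_vaf_target", "mean_vaf_other")],
    cols = c("mean_vaf_target", "mean_vaf_other"),
    names_to = "panel", values_to = "mean_vaf"
  )
  long$panel <- ifelse(long$panel == "mean_vaf_target",
                       "treated neoantigen mutations", "other somatic mutations")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mean_vaf,
                                     color = .data$panel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days from first vaccination", y = "mean ctDNA VAF",
                  color = NULL) +
    ggplot2::theme_minimal()
}
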