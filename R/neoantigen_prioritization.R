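#' Median IC50 over predictors for one peptide-allele pair
#'
#' Several predictors score the same peptide-allele pair; the decision
#' statistic is their sample median (even counts average the two central
#' values). With a single predictor (the usual class II case) the median is
#' that value.
#'
#' @param ic50 Numeric vector of IC50 predictions (nM, > 0) for one pair.
#' @return The median IC50 in nM.
#' @export
median_ic50 <- function(ic50) {
  if (length(ic50) == 0) abort("median IC50 undefined for an empty record set")
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("IC50 values must be finite and positive")
  }
  stats::median(ic50)
}

#' Per-mutation best class I / class II binding summary
#'
#' For each mutation: every (peptide, allele) pair gets a median IC50 across
#' predictors, and the mutation's best class I (resp. class II) affinity is
#' the minimum of those pair medians over class I (resp. class II) pairs.
#' A class with no records yields `NA` for that class.
#'
#' @param affinities Data frame of predictions with columns
#'   `key, peptide, hla_allele, hla_class (\"I\"/\"II\"), predictor, ic50_nM`.
#'   May cover many mutations.
#' @param genotype Character vector of the patient's HLA alleles; every
#'   record's allele must belong to it.
#' @param rna Optional data frame `key, rna_vaf` used to attach the RNA VAF
#'   each summary carries into prioritization.
#' @return A tibble with one row per mutation key: `key, best_classI_ic50,
#'   best_classII_ic50, rna_vaf`.
#' @export
summarize_mutations <- function(affinities, genotype, rna = NULL) {
  affinities <- tibble::as_tibble(affinities)
  if (nrow(affinities) == 0) {
    return(tibble::tibble(key = character(), best_classI_ic50 = numeric(),
                          best_classII_ic50 = numeric(), rna_vaf = numeric()))
  }
  bad <- setdiff(unique(affinities$hla_allele), genotype)
  if (length(bad) > 0) {
    abort(paste0("allele(s) not in patient genotype: ",
                 paste(bad, collapse = ", ")))
  }
  if (!all(affinities$hla_class %in% c("I", "II"))) {
    abort("hla_class must be \"I\" or \"II\"")
  }

  pair <- affinities |>
    dplyr::group_by(.data$key, .data$hla_class, .data$peptide,
                    .data$hla_allele) |>
    dplyr::summarize(pair_median = median_ic50(.data$ic50_nM),
                     .groups = "drop")
  best <- pair |>
    dplyr::group_by(.data$key, .data$hla_class) |>
    dplyr::summarize(best = min(.data$pair_median), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "hla_class", values_from = "best",
                       names_prefix = "class")
  if (!"classI" %in% names(best)) best$classI <- NA_real_
  if (!"classII" %in% names(best)) best$classII <- NA_real_
  out <- tibble::tibble(key = best$key,
                        best_classI_ic50 = best$classI,
                        best_classII_ic50 = best$classII)
  if (!is.null(rna)) {
    out <- dplyr::left_join(out, tibble::as_tibble(rna)[, c("key", "rna_vaf")],
                            by = "key")
  } else {
    out$rna_vaf <- NA_real_
  }
  out
}

#' Predicted-neoantigen call
#'
#' A mutation is a predicted neoantigen when its best median IC50 is strictly
#' below `threshold` for HLA class I *or* class II.
#'
#' @param summary Tibble from [summarize_mutations()] (vectorized over rows).
#' @param threshold IC50 cut point in nM (default 500).
#' @return Logical vector.
#' @examples
#' s <- tibble::tibble(best_classI_ic50 = c(499, 500, NA),
#'                     best_classII_ic50 = c(600, 500, 450))
#' is_predicted_neoantigen(s)  # TRUE FALSE TRUE
#' @export
is_predicted_neoantigen <- function(summary, threshold = 500) {
  ci <- summary$best_classI_ic50 < threshold
  cii <- summary$best_classII_ic50 < threshold
  ci[is.na(ci)] <- FALSE
  cii[is.na(cii)] <- FALSE
  ci | cii
}

#' Priority tier of a predicted neoantigen
#'
#' Tiers encode the selection rank order: (1) strong binding (IC50 < 150 nM)
#' to both HLA class I and class II; (2) strong binding to exactly one class;
#' (3) modest binding (150 < IC50 <= 500) to both classes; (4) the remaining
#' predicted neoantigens. An IC50 of exactly 150 nM is neither strong nor
#' modest. An absent class never counts as strong or modest.
#'
#' @param summary Tibble of predicted neoantigens (vectorized over rows).
#' @param strong Strong-binder cut point (default 150 nM).
#' @param threshold Neoantigen cut point (default 500 nM).
#' @return Integer vector of tiers in `1:4`.
#' @export
assign_tier <- function(summary, strong = 150, threshold = 500) {
  if (!all(is_predicted_neoantigen(summary, threshold))) {
    abort("assign_tier called on a mutation that is not a predicted neoantigen")
  }
  ci <- summary$best_classI_ic50
  cii <- summary$best_classII_ic50
  strong_i <- !is.na(ci) & ci < strong
  strong_ii <- !is.na(cii) & cii < strong
  modest_i <- !is.na(ci) & ci > strong & ci <= threshold
  modest_ii <- !is.na(cii) & cii > strong & cii <= threshold
  tier <- rep(4L, nrow(summary))
  tier[modest_i & modest_ii] <- 3L
  tier[xor(strong_i, strong_ii)] <- 2L
  tier[strong_i & strong_ii] <- 1L
  tier
}

#' Rank and cap vaccine candidate mutations
#'
#' All predicted neoantigens are retained when there are at most `cap` of
#' them; otherwise the top `cap` under the total order: tier ascending, then
#' RNA VAF descending, then best class I IC50 ascending (missing class I
#' last), then locus key lexicographic. The output is always sorted in this
#' order, so the function is deterministic and input-order invariant.
#'
#' @param summaries Tibble of predicted neoantigens with `key,
#'   best_classI_ic50, best_classII_ic50, rna_vaf` (tier is recomputed if
#'   absent).
#' @param cap Maximum number of candidates (default 30).
#' @inheritParams assign_tier
#' @return The ranked candidate tibble with a `tier` column, at most `cap`
#'   rows.
#' @export
prioritize <- function(summaries, cap = 30, strong = 150, threshold = 500) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) == 0) return(dplyr::mutate(summaries, tier = integer()))
  summaries$tier <- assign_tier(summaries, strong = strong,
                                threshold = threshold)
  ci <- summaries$best_classI_ic50
  ci[is.na(ci)] <- Inf
  vaf <- summaries$rna_vaf
  vaf[is.na(vaf)] <- -Inf
  ord <- order(summaries$tier, -vaf, ci, summaries$key)
  utils::head(summaries[ord, , drop = FALSE], cap)
}
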