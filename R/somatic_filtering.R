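#' Variant allele frequency from read counts
#'
#' VAF is the fraction of reads supporting the alternate allele,
#' `alt / (alt + ref)`.
#'
#' @param alt_reads,ref_reads Non-negative read counts (vectorized).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_vaf(5, 95)   # 0.05
#' compute_vaf(37, 63)  # 0.37
#' @export
compute_vaf <- function(alt_reads, ref_reads) {
  if (any(alt_reads < 0, na.rm = TRUE) || any(ref_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  total <- alt_reads + ref_reads
  if (any(total == 0, na.rm = TRUE)) {
    abort("VAF undefined: zero total reads at one or more sites")
  }
  alt_reads / total
}

check_variant_calls <- function(calls, name = "call-set") {
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0(name, " lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(calls$pos < 1)) abort(paste0(name, ": positions must be >= 1"))
  if (any(calls$ref == calls$alt)) abort(paste0(name, ": ref must differ from alt"))
  indel <- nchar(calls$ref) != 1L | nchar(calls$alt) != 1L
  if (any(indel)) {
    abort(paste0(
      name, ": only SNVs are supported; indel record(s) at ",
      paste(utils::head(mutation_key(calls$chrom[indel], calls$pos[indel],
                                     calls$ref[indel], calls$alt[indel]), 3),
            collapse = ", ")
    ))
  }
  key <- mutation_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0(name, ": duplicate locus ", dup[1]))
  }
  invisible(calls)
}

#' Consensus somatic calls across callers
#'
#' A locus is retained iff it is called by both primary callers and also
#' present in the confirmer's call-set (two-caller intersection, then
#' confirmation). Input call-sets are per-caller data frames of SNVs with
#' columns `chrom, pos, ref, alt` and optionally `gene, protein_change,
#' tumor_alt_reads, tumor_ref_reads`.
#'
#' @param callsets Named list of three data frames; names must include the two
#'   `primary` callers and the `confirmer`.
#' @param primary Character vector of length 2: names of the primary callers.
#' @param confirmer Name of the confirming caller.
#' @return A tibble of consensus variants sorted by (chrom, pos, ref, alt) with
#'   columns `chrom, pos, ref, alt, key, gene, protein_change, dna_vaf,
#'   caller_support, origin`. Annotation columns (gene, counts) are taken from
#'   the first primary caller's records.
#' @export
consensus_somatic_calls <- function(callsets,
                                    primary = c("mutect2", "somaticsniper"),
                                    confirmer = "deepsnv") {
  needed <- c(primary, confirmer)
  missing_sets <- setdiff(needed, names(callsets))
  if (length(missing_sets) > 0) {
    abort(paste0("missing call-set(s): ", paste(missing_sets, collapse = ", ")))
  }
  for (nm in needed) check_variant_calls(callsets[[nm]], nm)

  keys <- lapply(callsets[needed], function(cs) {
    mutation_key(cs$chrom, cs$pos, cs$ref, cs$alt)
  })
  keep <- Reduce(intersect, keys)

  a <- tibble::as_tibble(callsets[[primary[1]]])
  a$key <- mutation_key(a$chrom, a$pos, a$ref, a$alt)
  out <- a[a$key %in% keep, , drop = FALSE]
  if (!"gene" %in% names(out)) out$gene <- NA_character_
  if (!"protein_change" %in% names(out)) out$protein_change <- NA_character_
  if (all(c("tumor_alt_reads", "tumor_ref_reads") %in% names(out)) &&
      nrow(out) > 0) {
    out$dna_vaf <- compute_vaf(out$tumor_alt_reads, out$tumor_ref_reads)
  } else {
    out$dna_vaf <- NA_real_
  }
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  tibble::tibble(
    chrom = out$chrom, pos = out$pos, ref = out$ref, alt = out$alt,
    key = out$key, gene = out$gene, protein_change = out$protein_change,
    dna_vaf = out$dna_vaf,
    caller_support = paste(needed, collapse = ","),
    origin = "DNA"
  )
}

#' Admit RNA-editing-derived candidates
#'
#' Tumor-specific nonsynonymous RNA-editing sites have no DNA-level somatic
#' call, so they bypass the caller consensus and enter directly as consensus
#' records with `origin = "RNA-editing"` and support from the confirmer only.
#' They remain subject to [rna_validate()] like any other variant.
#'
#' @param calls Data frame of editing-site records (`chrom, pos, ref, alt`,
#'   optionally `gene, protein_change`).
#' @param confirmer Label recorded as the supporting caller.
#' @return Tibble with the same columns as [consensus_somatic_calls()].
#' @export
rna_editing_calls <- function(calls, confirmer = "deepsnv") {
  check_variant_calls(calls, "RNA-editing set")
  calls <- tibble::as_tibble(calls)
  if (!"gene" %in% names(calls)) calls$gene <- NA_character_
  if (!"protein_change" %in% names(calls)) calls$protein_change <- NA_character_
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ]
  tibble::tibble(
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    key = mutation_key(calls$chrom, calls$pos, calls$ref, calls$alt),
    gene = calls$gene, protein_change = calls$protein_change,
    dna_vaf = NA_real_,
    caller_support = confirmer,
    origin = "RNA-editing"
  )
}

#' RNA-level validation of somatic variants
#'
#' A variant is expression-validated when its site has at least `min_depth`
#' RNA-seq coverage and RNA VAF of at least `min_vaf` (both boundaries
#' inclusive). Sites with missing RNA data fail validation.
#'
#' @param rna_depth,rna_vaf RNA-seq depth and variant allele frequency
#'   (vectorized).
#' @param min_depth Minimum RNA depth (default 20).
#' @param min_vaf Minimum RNA VAF (default 0.05).
#' @return Logical vector.
#' @examples
#' rna_validate(20, 0.05)   # TRUE: boundaries are inclusive
#' rna_validate(19, 0.50)   # FALSE: insufficient depth
#' @export
rna_validate <- function(rna_depth, rna_vaf, min_depth = 20, min_vaf = 0.05) {
  n_missing <- sum(is.na(rna_depth) | is.na(rna_vaf))
  if (n_missing > 0) {
    rlang::inform(paste0(n_missing, " site(s) without RNA data fail validation"))
  }
  ok <- rna_depth >= min_depth & rna_vaf >= min_vaf
  ok[is.na(ok)] <- FALSE
  ok
}

#' Join RNA evidence onto consensus variants and flag validated ones
#'
#' @param variants Consensus variant tibble (from [consensus_somatic_calls()]
#'   and/or [rna_editing_calls()]).
#' @param rna Data frame with `chrom, pos, ref, alt, rna_depth, rna_vaf`.
#' @inheritParams rna_validate
#' @return `variants` with `rna_depth`, `rna_vaf` and logical `rna_validated`
#'   columns appended.
#' @export
annotate_rna <- function(variants, rna, min_depth = 20, min_vaf = 0.05) {
  rna <- tibble::as_tibble(rna)
  rna$key <- mutation_key(rna$chrom, rna$pos, rna$ref, rna$alt)
  out <- dplyr::left_join(variants,
                          rna[, c("key", "rna_depth", "rna_vaf")],
                          by = "key")
  out$rna_validated <- rna_validate(out$rna_depth, out$rna_vaf,
                                    min_depth = min_depth, min_vaf = min_vaf)
  out
}
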