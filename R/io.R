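# File formats: per-caller VCF (tumor/normal sample columns, AD in FORMAT),
# TSV for RNA validation / affinities / plasma, FASTA + sidecar TSV for
# protein contexts, CSV for ELISpot and outcomes, YAML for the config.

#' Write one caller's call-set as a VCF
#'
#' Emits a minimal two-sample (TUMOR/NORMAL) VCF with allelic depths in the
#' `AD` FORMAT field and gene/protein-change annotations in INFO.
#'
#' @param calls Data frame of SNVs (`chrom, pos, ref, alt`, optional `gene,
#'   protein_change, tumor_alt_reads, tumor_ref_reads, normal_alt_reads,
#'   normal_ref_reads`).
#' @param path Output path; vcfR appends `.gz` when absent.
#' @return The path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_caller_vcf <- function(calls, path) {
  n <- nrow(calls)
  gene <- if ("gene" %in% names(calls)) calls$gene else rep(NA, n)
  pch <- if ("protein_change" %in% names(calls)) calls$protein_change else
    rep(NA, n)
  info <- paste0(
    ifelse(is.na(gene), "", paste0("GENE=", gene, ";")),
    ifelse(is.na(pch), "", paste0("PCHANGE=", pch, ";")),
    "ORIGIN=DNA")
  ta <- calls$tumor_alt_reads %||% rep(0L, n)
  tr <- calls$tumor_ref_reads %||% rep(0L, n)
  na_ <- calls$normal_alt_reads %||% rep(0L, n)
  nr <- calls$normal_ref_reads %||% rep(0L, n)
  ord <- order(calls$chrom, calls$pos)
  fix <- cbind(CHROM = calls$chrom, POS = as.character(calls$pos), ID = ".",
               REF = calls$ref, ALT = calls$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)[ord, , drop = FALSE]
  gt <- cbind(FORMAT = "GT:AD",
              TUMOR = paste0("0/1:", tr, ",", ta),
              NORMAL = paste0("0/0:", nr, ",", na_))[ord, , drop = FALSE]
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"DNA or RNA-editing\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt depths\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_ad <- function(ad) {
  parts <- strsplit(unname(ad), ",", fixed = TRUE)
  list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
       alt = vapply(parts, function(p) as.integer(p[2]), integer(1)))
}

#' Read one caller's VCF into a call-set table
#'
#' @param path VCF path (plain or gzipped).
#' @return Tibble `chrom, pos, ref, alt, gene, protein_change,
#'   tumor_alt_reads, tumor_ref_reads, normal_alt_reads, normal_ref_reads,
#'   origin`.
#' @export
read_caller_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gene <- vcfR::extract.info(v, "GENE")
  pch <- vcfR::extract.info(v, "PCHANGE")
  origin <- vcfR::extract.info(v, "ORIGIN")
  ad <- vcfR::extract.gt(v, "AD")
  tu <- parse_ad(ad[, "TUMOR"])
  no <- parse_ad(ad[, "NORMAL"])
  tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = unname(gene), protein_change = unname(pch),
    tumor_alt_reads = tu$alt, tumor_ref_reads = tu$ref,
    normal_alt_reads = no$alt, normal_ref_reads = no$ref,
    origin = unname(origin %||% rep("DNA", nrow(fix)))
  )
}

#' Write protein contexts as FASTA plus sidecar TSV
#'
#' @param contexts Tibble `patient, key, gene, sequence, mutant_position,
#'   mutant_residue`.
#' @param fasta_path,tsv_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_protein_contexts <- function(contexts, fasta_path, tsv_path) {
  seqs <- Biostrings::AAStringSet(contexts$sequence)
  names(seqs) <- paste(contexts$patient, contexts$key, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(contexts[, c("patient", "key", "gene", "mutant_position",
                                "mutant_residue")], tsv_path)
  invisible(fasta_path)
}

#' Read protein contexts from FASTA plus sidecar TSV
#'
#' @param fasta_path,tsv_path Paths written by [write_protein_contexts()].
#' @return Tibble matching the writer's input.
#' @export
read_protein_contexts <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  side <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  id <- paste(side$patient, side$key, sep = "|")
  side$sequence <- unname(as.character(seqs[id]))
  side[, c("patient", "key", "gene", "sequence", "mutant_position",
           "mutant_residue")]
}

#' Write a cohort bundle to disk
#'
#' Materializes a [generate_cohort()] bundle in the formats the module
#' readers consume: per-patient per-caller VCFs under `callsets/`, TSVs for
#' RNA validation, HLA, affinities and plasma, FASTA + TSV protein contexts,
#' CSVs for ELISpot and outcomes, and the config as YAML.
#'
#' @param cohort A `neovax_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "callsets"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(cohort$callsets)) {
    for (caller in names(cohort$callsets[[id]])) {
      write_caller_vcf(cohort$callsets[[id]][[caller]],
                       file.path(dir, "callsets",
                                 paste0(id, "_", caller, ".vcf.gz")))
    }
  }
  readr::write_tsv(cohort$rna, file.path(dir, "rna_validation.tsv"))
  readr::write_tsv(cohort$hla, file.path(dir, "hla_genotypes.tsv"))
  readr::write_tsv(cohort$affinities, file.path(dir, "affinities.tsv"))
  write_protein_contexts(cohort$contexts,
                         file.path(dir, "protein_contexts.fasta"),
                         file.path(dir, "protein_contexts.tsv"))
  readr::write_tsv(cohort$plasma, file.path(dir, "plasma.tsv"))
  readr::write_csv(cohort$elispot, file.path(dir, "elispot.csv"))
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  cfg <- unclass(cohort$config)
  cfg$recurrence_hazard <- as.list(cfg$recurrence_hazard)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulation config written by [write_cohort()]
#'
#' @param path YAML path.
#' @return A validated `neovax_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$recurrence_hazard <- unlist(cfg$recurrence_hazard)
  for (f in c("mutation_range", "timepoint_days", "tumor_fraction_curve")) {
    cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  }
  do.call(simulation_config, cfg)
}

#' @rdname read_tables
#' @export
read_rna_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Readers for the package's tabular formats
#'
#' Thin readr wrappers fixing the column types of each artifact: RNA
#' validation table, HLA genotypes, affinity predictions, plasma read
#' counts (TSV) and ELISpot / clinical outcome tables (CSV).
#'
#' @param path File path.
#' @return A tibble.
#' @name read_tables
#' @export
read_affinity_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(ic50_nM = readr::col_double()))
}

#' @rdname read_tables
#' @export
read_hla_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_tables
#' @export
read_plasma_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(is_target = readr::col_logical()))
}

#' @rdname read_tables
#' @export
read_elispot_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_tables
#' @export
read_outcomes_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
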