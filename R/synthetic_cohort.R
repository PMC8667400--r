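AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")
CALLERS <- c("mutect2", "somaticsniper", "deepsnv")
CLASS_I_PREDICTORS <- c("NetMHCpan", "NetMHC", "NetMHCcons", "PickPocket",
                        "MHCflurry")
CLASS_II_PREDICTOR <- "NetMHCpanII"
HLA_I_POOL <- list(
  A = c("HLA-A*02:01", "HLA-A*11:01", "HLA-A*24:02", "HLA-A*33:03"),
  B = c("HLA-B*40:01", "HLA-B*46:01", "HLA-B*58:01", "HLA-B*13:01"),
  C = c("HLA-C*01:02", "HLA-C*07:02", "HLA-C*03:04", "HLA-C*08:01")
)
HLA_II_POOL <- c("HLA-DRB1*09:01", "HLA-DRB1*15:01", "HLA-DRB1*12:02",
                 "HLA-DRB1*08:03")
GENE_POOL <- c("TP53", "KALRN", "CTNNB1", "ARID1A", "AXIN1", "ALB", "RB1",
               "TERT", "OBSCN", "MUC16", "TTN", "PCLO", "RYR2", "CSMD3",
               "LRP1B", "FAT3", "USH2A", "SPTA1", "DNAH7", "FLG")

#' Simulation configuration for a synthetic vaccine-trial cohort
#'
#' Bundles and validates every tunable of the cohort generator. Defaults
#' reflect the trial setting the package models: ~78 somatic SNVs per
#' patient (clamped to 7-148), about a third of mutations expression-
#' validated *and* predicted as neoantigens, log-scale IC50s straddling the
#' 150/500 nM cut points, clone-structured plasma VAFs with optional
#' preferential killing of vaccine-targeted clones, Poisson ELISpot counts,
#' and group-dependent exponential recurrence hazards (median RFS from
#' surgery of roughly 19.3 /
#' 6.7 / 4.8 months for responsive / non-responsive / control).
#'
#' @param n_patients Number of vaccinated patients.
#' @param mutation_mean,mutation_dispersion Negative-binomial mean and size
#'   for per-patient somatic mutation counts.
#' @param mutation_range Clamp range for mutation counts (low >= 1).
#' @param expressed_fraction Probability a mutation passes RNA validation.
#' @param neoantigen_fraction_target Expected fraction of all mutations that
#'   are predicted neoantigens (must not exceed `expressed_fraction`; every
#'   simulated neoantigen is expressed).
#' @param ic50_sdlog Log-scale predictor noise around each pair's median.
#' @param n_clones Tumor clones per patient.
#' @param clone_concentration Gamma shape controlling clone CCF skew.
#' @param clone_total_ccf Total cancer-cell fraction carried by the clones
#'   (<= 1).
#' @param neo_clone_fraction Fraction of clones (largest first) in which
#'   neoantigen mutations arise; the remaining clones carry no vaccine
#'   target, so under a positive `vaccine_kill_rate` they escape killing —
#'   the tumor-heterogeneity structure behind the divergent ctDNA pattern.
#' @param timepoint_days Plasma sampling days relative to first vaccination
#'   (negative = pre-vaccination baseline).
#' @param tumor_fraction_curve Plasma tumor fraction at each timepoint, in
#'   `[0, 1]`, same length as `timepoint_days`.
#' @param vaccine_kill_rate Per-interval multiplicative CCF decay applied,
#'   after day 0, to clones carrying at least one vaccine-targeted mutation
#'   (0 = no vaccine effect).
#' @param plasma_depth Mean total reads per site per plasma sample.
#' @param elispot_baseline_mean,elispot_response_mean Poisson means for
#'   negative-control/unresponsive wells and responsive post-boost wells.
#' @param elispot_replicates Replicate wells per stimulus.
#' @param responsive_fraction Probability a boosted patient mounts a
#'   T-cell response.
#' @param recurrence_hazard Named per-month exponential hazards for groups
#'   `responsive`, `non_responsive`, `control`. Vaccinated-group hazards run
#'   from first vaccination (defaults give medians of 16.5 and 3.9 months,
#'   i.e. roughly 19.3 and 6.7 months from surgery once the typical
#'   2.8-month surgery-to-vaccination gap is added); the control hazard runs
#'   from surgery (median 4.8 months).
#' @param followup_horizon_months Administrative censoring horizon.
#' @param n_control_pool Size of the unvaccinated control pool generated for
#'   propensity matching.
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A validated `neovax_config` list.
#' @export
simulation_config <- function(
    n_patients = 10,
    mutation_mean = 78, mutation_dispersion = 8,
    mutation_range = c(7, 148),
    expressed_fraction = 0.55,
    neoantigen_fraction_target = 0.335,
    ic50_sdlog = 0.35,
    n_clones = 3, clone_concentration = 1.5, clone_total_ccf = 0.9,
    neo_clone_fraction = 1 / 3,
    timepoint_days = c(-30, 0, 30, 60, 90, 140, 200, 270),
    tumor_fraction_curve = c(0.020, 0.004, 0.006, 0.008, 0.010, 0.012,
                             0.015, 0.018),
    vaccine_kill_rate = 0.35,
    plasma_depth = 5000,
    elispot_baseline_mean = 5, elispot_response_mean = 60,
    elispot_replicates = 3,
    responsive_fraction = 0.5,
    recurrence_hazard = c(responsive = log(2) / 16.5,
                          non_responsive = log(2) / 3.9,
                          control = log(2) / 4.8),
    followup_horizon_months = 33,
    n_control_pool = 100,
    seed = 1L) {
  cfg <- list(
    n_patients = n_patients, mutation_mean = mutation_mean,
    mutation_dispersion = mutation_dispersion,
    mutation_range = mutation_range,
    expressed_fraction = expressed_fraction,
    neoantigen_fraction_target = neoantigen_fraction_target,
    ic50_sdlog = ic50_sdlog, n_clones = n_clones,
    clone_concentration = clone_concentration,
    clone_total_ccf = clone_total_ccf,
    neo_clone_fraction = neo_clone_fraction,
    timepoint_days = timepoint_days,
    tumor_fraction_curve = tumor_fraction_curve,
    vaccine_kill_rate = vaccine_kill_rate, plasma_depth = plasma_depth,
    elispot_baseline_mean = elispot_baseline_mean,
    elispot_response_mean = elispot_response_mean,
    elispot_replicates = elispot_replicates,
    responsive_fraction = responsive_fraction,
    recurrence_hazard = recurrence_hazard,
    followup_horizon_months = followup_horizon_months,
    n_control_pool = n_control_pool,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "neovax_config"
  cfg
}

bad_field <- function(field, why) {
  abort(paste0("invalid config field `", field, "`: ", why))
}

validate_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      bad_field(field, "must be a probability in [0, 1]")
    }
  }
  if (cfg$n_patients < 1) bad_field("n_patients", "must be >= 1")
  if (cfg$mutation_mean <= 0) bad_field("mutation_mean", "must be > 0")
  if (cfg$mutation_dispersion <= 0) {
    bad_field("mutation_dispersion", "must be > 0")
  }
  if (length(cfg$mutation_range) != 2 || cfg$mutation_range[1] < 1 ||
      cfg$mutation_range[2] < cfg$mutation_range[1]) {
    bad_field("mutation_range", "must be c(low, high) with low >= 1")
  }
  chk_prob("expressed_fraction")
  chk_prob("neoantigen_fraction_target")
  if (cfg$neoantigen_fraction_target > cfg$expressed_fraction) {
    bad_field("neoantigen_fraction_target",
              "cannot exceed expressed_fraction (neoantigens are expressed)")
  }
  if (cfg$ic50_sdlog <= 0) bad_field("ic50_sdlog", "must be > 0")
  if (cfg$n_clones < 1) bad_field("n_clones", "must be >= 1")
  if (cfg$clone_concentration <= 0) {
    bad_field("clone_concentration", "must be > 0")
  }
  chk_prob("clone_total_ccf")
  if (cfg$neo_clone_fraction <= 0 || cfg$neo_clone_fraction > 1) {
    bad_field("neo_clone_fraction", "must be in (0, 1]")
  }
  chk_prob("tumor_fraction_curve")
  if (length(cfg$tumor_fraction_curve) != length(cfg$timepoint_days)) {
    bad_field("tumor_fraction_curve",
              "must have one value per timepoint day")
  }
  if (is.unsorted(cfg$timepoint_days, strictly = TRUE)) {
    bad_field("timepoint_days", "must be strictly increasing")
  }
  chk_prob("vaccine_kill_rate")
  if (cfg$plasma_depth <= 0) bad_field("plasma_depth", "must be > 0")
  if (cfg$elispot_baseline_mean < 0 || cfg$elispot_response_mean < 0) {
    bad_field("elispot_baseline_mean", "ELISpot means must be >= 0")
  }
  if (cfg$elispot_replicates < 1) {
    bad_field("elispot_replicates", "must be >= 1")
  }
  chk_prob("responsive_fraction")
  if (!all(c("responsive", "non_responsive", "control") %in%
           names(cfg$recurrence_hazard)) ||
      any(cfg$recurrence_hazard <= 0)) {
    bad_field("recurrence_hazard",
              "needs positive named hazards: responsive, non_responsive, control")
  }
  if (cfg$followup_horizon_months <= 0) {
    bad_field("followup_horizon_months", "must be > 0")
  }
  if (cfg$n_control_pool < 0) bad_field("n_control_pool", "must be >= 0")
  if (is.na(cfg$seed)) bad_field("seed", "must be an integer")
  invisible(cfg)
}

random_aa <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

#' Simulate per-site plasma read counts from clone trajectories
#'
#' The expected VAF of a copy-neutral diploid site at time *t* is
#' `tumor_fraction(t) * CCF_clone(t) / 2`. Total reads per site and sample
#' are Poisson around `depth`; mutant reads are binomial at the expected VAF.
#'
#' @param clone_ccf Matrix of cancer-cell fractions, clones x timepoints,
#'   values in `[0, 1]`.
#' @param site_to_clone Named integer vector mapping each site key to a
#'   clone (row of `clone_ccf`).
#' @param tumor_fraction Plasma tumor fraction per timepoint, in `[0, 1]`.
#' @param days Timepoint labels (days), one per column of `clone_ccf`.
#' @param depth Mean total reads per site per sample (> 0).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Tibble `site, day, clone, expected_vaf, alt_reads, total_reads`.
#' @export
simulate_plasma_series <- function(clone_ccf, site_to_clone, tumor_fraction,
                                   days, depth, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  clone_ccf <- as.matrix(clone_ccf)
  if (any(clone_ccf < 0) || any(clone_ccf > 1)) {
    abort("clone CCFs must lie in [0, 1]")
  }
  if (any(tumor_fraction < 0) || any(tumor_fraction > 1)) {
    abort("tumor fractions must lie in [0, 1]")
  }
  if (depth <= 0) abort("plasma depth must be > 0")
  if (length(days) != ncol(clone_ccf) ||
      length(tumor_fraction) != ncol(clone_ccf)) {
    abort("days, tumor_fraction and clone_ccf columns must align")
  }
  if (any(site_to_clone < 1) || any(site_to_clone > nrow(clone_ccf))) {
    bad <- names(site_to_clone)[site_to_clone < 1 |
                                  site_to_clone > nrow(clone_ccf)]
    abort(paste0("site(s) mapped to unknown clone: ",
                 paste(utils::head(bad, 3), collapse = ", ")))
  }
  n_sites <- length(site_to_clone)
  n_t <- length(days)
  site <- rep(names(site_to_clone), times = n_t)
  clone <- rep(unname(site_to_clone), times = n_t)
  day <- rep(days, each = n_sites)
  tf <- rep(tumor_fraction, each = n_sites)
  ccf <- clone_ccf[cbind(clone, rep(seq_len(n_t), each = n_sites))]
  expected_vaf <- tf * ccf / 2
  total_reads <- stats::rpois(n_sites * n_t, depth)
  alt_reads <- stats::rbinom(n_sites * n_t, total_reads, expected_vaf)
  tibble::tibble(site = site, day = day, clone = clone,
                 expected_vaf = expected_vaf,
                 alt_reads = alt_reads, total_reads = total_reads)
}

simulate_patient_mutations <- function(cfg, patient) {
  rng <- cfg$mutation_range
  n_mut <- min(max(stats::rnbinom(1, mu = cfg$mutation_mean,
                                  size = cfg$mutation_dispersion),
                   rng[1]), rng[2])
  chrom <- paste0("chr", sample(1:22, n_mut, replace = TRUE))
  pos <- sample(1e6:5e7, n_mut)
  ref <- sample(BASES, n_mut, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                       character(1)))
  key <- mutation_key(chrom, pos, ref, alt)
  gene <- sample(GENE_POOL, n_mut, replace = TRUE)
  protein_change <- paste0("p.", sample(AA20, n_mut, replace = TRUE),
                           sample(30:900, n_mut, replace = TRUE),
                           sample(AA20, n_mut, replace = TRUE))

  is_neo <- stats::runif(n_mut) < cfg$neoantigen_fraction_target
  min_neo <- min(6L, n_mut)
  if (sum(is_neo) < min_neo) {
    promote <- sample(which(!is_neo), min_neo - sum(is_neo))
    is_neo[promote] <- TRUE
  }
  p_extra <- (cfg$expressed_fraction - cfg$neoantigen_fraction_target) /
    max(1 - cfg$neoantigen_fraction_target, 1e-9)
  is_expressed <- is_neo | (stats::runif(n_mut) < p_extra)

  clone_w <- sort(stats::rgamma(cfg$n_clones, cfg$clone_concentration),
                  decreasing = TRUE)
  clone_ccf0 <- clone_w / sum(clone_w) * cfg$clone_total_ccf
  # Neoantigen mutations are confined to a leading subset of clones
  # (tumor heterogeneity): the remaining clones carry no vaccine target and
  # escape vaccine-driven killing.
  n_neo_clones <- max(1L, round(cfg$neo_clone_fraction * cfg$n_clones))
  clone <- sample(cfg$n_clones, n_mut, replace = TRUE)
  clone[is_neo] <- sample(n_neo_clones, sum(is_neo), replace = TRUE)

  purity <- 0.6
  tumor_total <- stats::rpois(n_mut, 200)
  true_dna_vaf <- pmin(0.5, purity * clone_ccf0[clone] / 2 + 0.05)
  tumor_alt <- stats::rbinom(n_mut, tumor_total, true_dna_vaf)
  normal_total <- stats::rpois(n_mut, 200)
  normal_alt <- stats::rbinom(n_mut, normal_total, 0.001)

  tibble::tibble(
    patient = patient, chrom = chrom, pos = pos, ref = ref, alt = alt,
    key = key, gene = gene, protein_change = protein_change,
    clone = clone, is_neoantigen = is_neo, is_expressed = is_expressed,
    tumor_alt_reads = tumor_alt,
    tumor_ref_reads = tumor_total - tumor_alt,
    normal_alt_reads = normal_alt,
    normal_ref_reads = normal_total - normal_alt,
    clone_ccf0 = clone_ccf0[clone]
  )
}

private_noise_calls <- function(muts, n_extra) {
  if (n_extra == 0) return(muts[0, c("chrom", "pos", "ref", "alt")])
  chrom <- paste0("chr", sample(1:22, n_extra, replace = TRUE))
  pos <- sample(5e7:9e7, n_extra)
  ref <- sample(BASES, n_extra, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                       character(1)))
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

simulate_patient_rna <- function(muts, cfg) {
  n <- nrow(muts)
  depth <- integer(n)
  vaf <- numeric(n)
  exp_idx <- muts$is_expressed
  depth[exp_idx] <- 20L + stats::rnbinom(sum(exp_idx), mu = 100, size = 3)
  vaf[exp_idx] <- pmin(0.95, 0.05 + 0.9 * stats::rbeta(sum(exp_idx), 1.5, 3))
  n_off <- sum(!exp_idx)
  low_depth <- stats::runif(n_off) < 0.5
  depth[!exp_idx] <- ifelse(low_depth, stats::rpois(n_off, 8),
                            20L + stats::rpois(n_off, 80))
  vaf[!exp_idx] <- ifelse(low_depth,
                          stats::runif(n_off, 0, 0.3),
                          stats::runif(n_off, 0, 0.049))
  tibble::tibble(patient = muts$patient, chrom = muts$chrom, pos = muts$pos,
                 ref = muts$ref, alt = muts$alt, key = muts$key,
                 rna_depth = depth, rna_vaf = round(vaf, 4))
}

simulate_patient_hla <- function(patient) {
  class_i <- c(sample(HLA_I_POOL$A, 2), sample(HLA_I_POOL$B, 2),
               sample(HLA_I_POOL$C, 2))
  class_ii <- sample(HLA_II_POOL, 2)
  tibble::tibble(patient = patient,
                 allele = c(class_i, class_ii),
                 hla_class = rep(c("I", "II"), c(6, 2)))
}

draw_band <- function(band) {
  switch(band,
    strong = exp(stats::runif(1, log(25), log(120))),
    modest = exp(stats::runif(1, log(170), log(450))),
    weak = exp(stats::runif(1, log(700), log(15000)))
  )
}

peptide_with_residue <- function(len, residue) {
  p <- sample(AA20, len, replace = TRUE)
  p[sample(len, 1)] <- residue
  paste(p, collapse = "")
}

# Predictor draws rescaled so the pair median equals the drawn band target:
# keeps the realized strong/modest/non-binder composition exactly as designed
# while the individual predictor values stay log-normally dispersed.
predictor_values <- function(target, n, sdlog) {
  noise <- stats::rlnorm(n, 0, sdlog)
  target * noise / stats::median(noise)
}

simulate_patient_affinities <- function(muts, hla, cfg) {
  expressed <- muts[muts$is_expressed, , drop = FALSE]
  if (nrow(expressed) == 0) {
    return(tibble::tibble(patient = character(), key = character(),
                          peptide = character(), length = integer(),
                          hla_allele = character(), hla_class = character(),
                          predictor = character(), ic50_nM = numeric()))
  }
  alleles_i <- hla$allele[hla$hla_class == "I"]
  alleles_ii <- hla$allele[hla$hla_class == "II"]
  rows <- vector("list", nrow(expressed))
  for (i in seq_len(nrow(expressed))) {
    m <- expressed[i, ]
    mut_res <- substr(sub("^p\\.", "", m$protein_change), 1, 1)
    if (m$is_neoantigen) {
      cat_ <- sample(c("strong_both", "strong_one", "modest_both",
                       "modest_one"), 1, prob = c(0.2, 0.3, 0.3, 0.2))
      bands <- switch(cat_,
        strong_both = c("strong", "strong"),
        strong_one = sample(c("strong", sample(c("modest", "weak"), 1))),
        modest_both = c("modest", "modest"),
        modest_one = sample(c("modest", "weak"))
      )
    } else {
      bands <- c("weak", "weak")
    }
    t_i <- draw_band(bands[1])
    t_ii <- draw_band(bands[2])

    len_best <- sample(8:11, 1)
    pep_best <- peptide_with_residue(len_best, mut_res)
    al_best <- sample(alleles_i, 1)
    vals <- predictor_values(t_i, length(CLASS_I_PREDICTORS), cfg$ic50_sdlog)
    class_i <- tibble::tibble(
      peptide = pep_best, length = len_best, hla_allele = al_best,
      hla_class = "I", predictor = CLASS_I_PREDICTORS, ic50_nM = vals)

    n_decoy <- 2L
    decoys <- lapply(seq_len(n_decoy), function(j) {
      len_d <- sample(8:11, 1)
      lo <- max(700, t_i * 1.5)
      t_d <- exp(stats::runif(1, log(lo), log(max(2e4, lo * 3))))
      tibble::tibble(
        peptide = peptide_with_residue(len_d, mut_res), length = len_d,
        hla_allele = sample(alleles_i, 1), hla_class = "I",
        predictor = CLASS_I_PREDICTORS,
        ic50_nM = predictor_values(t_d, length(CLASS_I_PREDICTORS),
                                   cfg$ic50_sdlog))
    })
    class_ii <- tibble::tibble(
      peptide = peptide_with_residue(15, mut_res), length = 15L,
      hla_allele = sample(alleles_ii, 1), hla_class = "II",
      predictor = CLASS_II_PREDICTOR, ic50_nM = t_ii)

    rec <- dplyr::bind_rows(c(list(class_i), decoys, list(class_ii)))
    rec$patient <- m$patient
    rec$key <- m$key
    rows[[i]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  out$ic50_nM <- round(out$ic50_nM, 2)
  out[, c("patient", "key", "peptide", "length", "hla_allele", "hla_class",
          "predictor", "ic50_nM")]
}

simulate_patient_contexts <- function(muts) {
  neo <- muts[muts$is_neoantigen, , drop = FALSE]
  if (nrow(neo) == 0) {
    return(tibble::tibble(patient = character(), key = character(),
                          gene = character(), sequence = character(),
                          mutant_position = integer(),
                          mutant_residue = character()))
  }
  len <- sample(60:600, nrow(neo), replace = TRUE)
  pos <- vapply(len, function(l) sample.int(l, 1), integer(1))
  res <- substr(sub("^p\\.", "", neo$protein_change), 1, 1)
  seqs <- vapply(seq_along(len), function(i) {
    s <- sample(AA20, len[i], replace = TRUE)
    s[pos[i]] <- res[i]
    paste(s, collapse = "")
  }, character(1))
  tibble::tibble(patient = neo$patient, key = neo$key, gene = neo$gene,
                 sequence = seqs, mutant_position = pos,
                 mutant_residue = res)
}

clone_ccf_matrix <- function(muts, targets, cfg) {
  ccf0 <- vapply(seq_len(cfg$n_clones), function(k) {
    v <- muts$clone_ccf0[muts$clone == k]
    if (length(v)) v[1] else 0
  }, numeric(1))
  n_t <- length(cfg$timepoint_days)
  mat <- matrix(rep(ccf0, n_t), nrow = cfg$n_clones)
  targeted_clones <- unique(muts$clone[muts$key %in% targets])
  post <- which(cfg$timepoint_days > 0)
  if (length(post) > 0 && cfg$vaccine_kill_rate > 0) {
    decay <- (1 - cfg$vaccine_kill_rate)^seq_along(post)
    for (k in targeted_clones) {
      mat[k, post] <- mat[k, post] * decay
    }
  }
  mat
}

simulate_patient_elispot <- function(patient, n_pools, responsive, cfg) {
  timepoints <- c("pre", "post_prime", "post_boost", "follow_up")
  stimuli <- c(paste0("pool", seq_len(n_pools)), "NC", "PC")
  grid <- expand.grid(timepoint = timepoints, stimulus = stimuli,
                      replicate = seq_len(cfg$elispot_replicates),
                      stringsAsFactors = FALSE)
  base <- cfg$elispot_baseline_mean
  resp <- cfg$elispot_response_mean
  tp_rate <- if (responsive) {
    c(pre = base, post_prime = (base + resp) / 2, post_boost = resp,
      follow_up = resp / 2)
  } else {
    c(pre = base, post_prime = base, post_boost = base, follow_up = base)
  }
  rate <- ifelse(grid$stimulus == "NC", base,
          ifelse(grid$stimulus == "PC", 150,
                 unname(tp_rate[grid$timepoint])))
  tibble::tibble(patient = patient, timepoint = grid$timepoint,
                 stimulus = grid$stimulus, replicate = grid$replicate,
                 spots = stats::rpois(nrow(grid), rate))
}

simulate_patient_outcome <- function(patient, group, cfg) {
  surgery <- as.Date("2018-11-26") + sample(0:400, 1)
  first_vacc <- surgery + sample(59:159, 1)
  t_rec <- stats::rexp(1, cfg$recurrence_hazard[[group]])
  event <- as.integer(t_rec <= cfg$followup_horizon_months)
  t_obs <- min(t_rec, cfg$followup_horizon_months)
  end <- first_vacc + round(t_obs * DAYS_PER_MONTH)
  tibble::tibble(
    patient = patient, role = "vaccinated", group = group,
    surgery_date = surgery, first_vaccination_date = first_vacc,
    end_date = end, event = event,
    sex = stats::rbinom(1, 1, 0.8), age = round(stats::rnorm(1, 52, 10)),
    vascular_invasion = 1L,
    hemoglobin = round(stats::rnorm(1, 135, 12), 1),
    platelet = round(stats::rnorm(1, 180, 50), 1), tace = 1L
  )
}

simulate_control_pool <- function(cfg) {
  n <- cfg$n_control_pool
  if (n == 0) return(NULL)
  surgery <- as.Date("2018-11-26") + sample(0:400, n, replace = TRUE)
  t_rec <- stats::rexp(n, cfg$recurrence_hazard[["control"]])
  event <- as.integer(t_rec <= cfg$followup_horizon_months)
  t_obs <- pmin(t_rec, cfg$followup_horizon_months)
  tibble::tibble(
    patient = sprintf("C%02d", seq_len(n)), role = "control_pool",
    group = "control", surgery_date = surgery,
    first_vaccination_date = as.Date(NA),
    end_date = surgery + round(t_obs * DAYS_PER_MONTH), event = event,
    sex = stats::rbinom(n, 1, 0.75),
    age = round(stats::rnorm(n, 54, 11)), vascular_invasion = 1L,
    hemoglobin = round(stats::rnorm(n, 132, 13), 1),
    platelet = round(stats::rnorm(n, 172, 55), 1), tace = 1L
  )
}

#' Generate a complete synthetic vaccine-trial cohort
#'
#' Produces every input the downstream modules consume: per-caller somatic
#' call-sets (consensus calls plus caller-private noise), an RNA validation
#' table, HLA genotypes, a predicted-affinity table, protein contexts for
#' neoantigen mutations, designed peptides and pools, longitudinal plasma
#' read counts, ELISpot counts and clinical outcomes with an unvaccinated
#' control pool. Identical configs (including seed) generate identical
#' cohorts.
#'
#' @param config A `neovax_config` from [simulation_config()].
#' @return A `neovax_cohort` list with elements `config, patients, callsets,
#'   mutations, rna, hla, affinities, contexts, candidates, pools, plasma,
#'   elispot, outcomes`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  ids <- sprintf("N%02d", seq_len(config$n_patients))
  callsets <- list()
  acc <- list(mutations = list(), rna = list(), hla = list(),
              affinities = list(), contexts = list(), candidates = list(),
              pools = list(), plasma = list(), elispot = list(),
              outcomes = list())
  patients <- list()

  for (p in seq_along(ids)) {
    id <- ids[p]
    muts <- simulate_patient_mutations(config, id)
    rna <- simulate_patient_rna(muts, config)
    hla <- simulate_patient_hla(id)
    aff <- simulate_patient_affinities(muts, hla, config)
    ctx <- simulate_patient_contexts(muts)

    base_calls <- muts[, c("chrom", "pos", "ref", "alt", "gene",
                           "protein_change", "tumor_alt_reads",
                           "tumor_ref_reads", "normal_alt_reads",
                           "normal_ref_reads")]
    cs <- list()
    for (caller in CALLERS) {
      extra <- private_noise_calls(muts, stats::rpois(1, 8))
      if (nrow(extra) > 0) {
        extra$gene <- NA_character_
        extra$protein_change <- NA_character_
        extra$tumor_alt_reads <- stats::rpois(nrow(extra), 15)
        extra$tumor_ref_reads <- stats::rpois(nrow(extra), 180)
        extra$normal_alt_reads <- 0L
        extra$normal_ref_reads <- stats::rpois(nrow(extra), 200)
      }
      cs[[caller]] <- dplyr::bind_rows(base_calls, extra)[
        sample(nrow(base_calls) + nrow(extra)), ]
    }
    callsets[[id]] <- cs

    consensus <- consensus_somatic_calls(cs)
    validated <- annotate_rna(consensus, rna)
    validated <- validated[validated$rna_validated, , drop = FALSE]
    summaries <- summarize_mutations(
      aff[aff$key %in% validated$key, , drop = FALSE],
      genotype = hla$allele,
      rna = rna[, c("key", "rna_vaf")])
    summaries <- summaries[is_predicted_neoantigen(summaries), , drop = FALSE]
    cand <- prioritize(summaries)
    n_synth <- min(nrow(cand), sample(6:20, 1))
    targets <- utils::head(cand$key, n_synth)

    pools <- if (n_synth >= 3) {
      cbind(patient = id, partition_pools(targets))
    } else NULL

    ccf_mat <- clone_ccf_matrix(muts, targets, config)
    site_map <- stats::setNames(muts$clone, muts$key)
    plasma <- simulate_plasma_series(ccf_mat, site_map,
                                     config$tumor_fraction_curve,
                                     config$timepoint_days,
                                     config$plasma_depth)
    plasma <- dplyr::mutate(plasma, patient = id,
                            is_target = .data$site %in% targets,
                            .before = 1)

    responsive <- stats::runif(1) < config$responsive_fraction
    n_pools <- if (is.null(pools)) 2L else max(pools$pool)
    elispot <- simulate_patient_elispot(id, n_pools, responsive, config)
    group <- if (responsive) "responsive" else "non_responsive"
    outcome <- simulate_patient_outcome(id, group, config)

    patients[[p]] <- tibble::tibble(
      patient = id, n_mutations = nrow(muts),
      n_expressed = sum(muts$is_expressed),
      n_predicted = nrow(summaries),
      n_neoantigens = nrow(cand), n_synthesized = n_synth,
      responsive = responsive, group = group)
    cand$patient <- id
    acc$mutations[[p]] <- muts
    acc$rna[[p]] <- rna
    acc$hla[[p]] <- hla
    acc$affinities[[p]] <- aff
    acc$contexts[[p]] <- ctx
    acc$candidates[[p]] <- cand
    acc$pools[[p]] <- pools
    acc$plasma[[p]] <- plasma
    acc$elispot[[p]] <- elispot
    acc$outcomes[[p]] <- outcome
  }

  outcomes <- dplyr::bind_rows(c(acc$outcomes, list(simulate_control_pool(
    config))))
  structure(list(
    config = config,
    patients = dplyr::bind_rows(patients),
    callsets = callsets,
    mutations = dplyr::bind_rows(acc$mutations),
    rna = dplyr::bind_rows(acc$rna),
    hla = dplyr::bind_rows(acc$hla),
    affinities = dplyr::bind_rows(acc$affinities),
    contexts = dplyr::bind_rows(acc$contexts),
    candidates = dplyr::bind_rows(acc$candidates),
    pools = dplyr::bind_rows(acc$pools),
    plasma = dplyr::bind_rows(acc$plasma),
    elispot = dplyr::bind_rows(acc$elispot),
    outcomes = outcomes
  ), class = "neovax_cohort")
}

#' @export
print.neovax_cohort <- function(x, ...) {
  cat("Synthetic vaccine-trial cohort\n")
  cat("  patients:        ", nrow(x$patients), "\n")
  cat("  somatic SNVs:    ", nrow(x$mutations),
      sprintf(" (mean %.1f/patient)\n", mean(x$patients$n_mutations)))
  cat("  neoantigens:     ", sum(x$patients$n_neoantigens), "\n")
  cat("  plasma samples:  ",
      nrow(unique(x$plasma[, c("patient", "day")])), "\n")
  cat("  control pool:    ", sum(x$outcomes$role == "control_pool"), "\n")
  invisible(x)
}

#' Simulate a confounded cohort for propensity-matching checks
#'
#' Covariates drive both treatment assignment (logistic model) and nothing
#' else; the treated and control covariate distributions therefore differ
#' before matching, which caliper matching should repair.
#'
#' @param n Total subjects.
#' @param treated_target Approximate number of treated subjects.
#' @param seed Seed.
#' @return Tibble with `treated` plus covariates `age, sex, hemoglobin,
#'   platelet, afp_log`.
#' @export
simulate_matching_cohort <- function(n = 300, treated_target = 30,
                                     seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  age <- stats::rnorm(n, 55, 11)
  sex <- stats::rbinom(n, 1, 0.75)
  hemoglobin <- stats::rnorm(n, 133, 14)
  platelet <- stats::rnorm(n, 175, 55)
  afp_log <- stats::rnorm(n, 5, 2)
  lin <- -0.05 * (age - 55) + 0.6 * sex + 0.03 * (hemoglobin - 133) -
    0.005 * (platelet - 175) + 0.25 * (afp_log - 5)
  p <- stats::plogis(lin + stats::qlogis(treated_target / n))
  tibble::tibble(treated = stats::runif(n) < p, age = age, sex = sex,
                 hemoglobin = hemoglobin, platelet = platelet,
                 afp_log = afp_log)
}
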