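test_that("config validation names the offending field", {
  expect_error(simulation_config(expressed_fraction = 1.2),
               "`expressed_fraction`")
  expect_error(simulation_config(mutation_range = c(0, 100)),
               "`mutation_range`")
  expect_error(simulation_config(vaccine_kill_rate = -0.1),
               "`vaccine_kill_rate`")
  expect_error(simulation_config(tumor_fraction_curve = c(0.1, 0.2)),
               "`tumor_fraction_curve`")
  expect_error(simulation_config(neoantigen_fraction_target = 0.8,
                                 expressed_fraction = 0.5),
               "`neoantigen_fraction_target`")
})

test_that("identical seeds give identical cohorts", {
  cfg <- simulation_config(n_patients = 2, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a)[names(a) != "config"],
                   unclass(b)[names(b) != "config"])
  c2 <- generate_cohort(simulation_config(n_patients = 2, seed = 14))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("mutation counts respect the clamp range and configured mean", {
  co <- generate_cohort(simulation_config(n_patients = 50, seed = 3))
  n <- co$patients$n_mutations
  expect_true(all(n >= 7 & n <= 148))
  # clamped negative binomial: empirical mean within 3 SE of the target
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - 78), 3 * se + 8)  # clamping shifts the mean a little
})

test_that("cohort structure is internally consistent", {
  co <- generate_cohort(simulation_config(n_patients = 3, seed = 5))
  expect_equal(nrow(co$patients), 3)
  # neoantigen candidates are capped and synthesized peptides pooled 3-5
  expect_true(all(co$patients$n_neoantigens <= 30))
  expect_true(all(co$patients$n_synthesized <= 20))
  sizes <- table(co$pools$patient, co$pools$pool)
  expect_true(all(sizes[sizes > 0] >= 3 & sizes[sizes > 0] <= 5))
  # plasma panel flags exactly the synthesized mutations as targets
  for (p in co$patients$patient) {
    targets <- unique(co$plasma$site[co$plasma$patient == p &
                                       co$plasma$is_target])
    expect_setequal(targets, co$pools$peptide_id[co$pools$patient == p])
  }
  expect_true(all(co$plasma$alt_reads <= co$plasma$total_reads))
})

test_that("the generated bundle flows through the analysis modules", {
  co <- generate_cohort(simulation_config(n_patients = 2, seed = 9))
  id <- "N01"
  consensus <- consensus_somatic_calls(co$callsets[[id]])
  ann <- annotate_rna(consensus, co$rna[co$rna$patient == id, ])
  expect_gt(sum(ann$rna_validated), 0)
  hla <- co$hla$allele[co$hla$patient == id]
  summ <- summarize_mutations(
    co$affinities[co$affinities$patient == id, ], hla,
    rna = co$rna[co$rna$patient == id, c("key", "rna_vaf")])
  cand <- prioritize(summ[is_predicted_neoantigen(summ), ])
  expect_gte(nrow(cand), 6)
  ctx <- co$contexts[co$contexts$patient == id, ]
  pep <- design_long_peptide(ctx$sequence[1], ctx$mutant_position[1],
                             ctx$mutant_residue[1])
  expect_lte(nchar(pep$sequence), 27)
  traj <- panel_trajectory(co$plasma[co$plasma$patient == id, ])
  expect_true(classify_pattern(traj) %in%
                c("concordant", "divergent", "untrackable"))
  calls <- call_responses(co$elispot[co$elispot$patient == id, ])
  expect_type(patient_responsive(calls), "logical")
})

test_that("plasma simulation follows the expected-VAF model", {
  # zero tumor fraction: nothing to sample
  z <- simulate_plasma_series(matrix(0.5, 1, 3), c(s1 = 1, s2 = 1),
                              c(0, 0, 0), c(0, 30, 60), 1000, seed = 1)
  expect_true(all(z$alt_reads == 0))

  # single clone, CCF 1, tumor fraction 0.2: VAF converges to 0.10
  deep <- simulate_plasma_series(matrix(1, 1, 1), c(s1 = 1), 0.2, 0,
                                 1e6, seed = 2)
  expect_equal(deep$alt_reads / deep$total_reads, 0.10, tolerance = 0.01)

  expect_error(
    simulate_plasma_series(matrix(1, 1, 1), c(s1 = 2), 0.2, 0, 100),
    "unknown clone")
})

test_that("a positive kill rate drives targeted-site VAFs down over time", {
  set.seed(44)
  days <- c(0, 30, 60, 90)
  declines <- replicate(100, {
    ccf <- matrix(rep(c(0.5, 0.3), 4), nrow = 2)
    ccf[1, ] <- ccf[1, ] * 0.6^(0:3)  # clone 1 targeted, killed
    sim <- simulate_plasma_series(
      ccf, c(t1 = 1, t2 = 1, o1 = 2, o2 = 2),
      rep(0.02, 4), days, 5000)
    first <- mean(sim$alt_reads[sim$day == 0 & sim$clone == 1] /
                    sim$total_reads[sim$day == 0 & sim$clone == 1])
    last <- mean(sim$alt_reads[sim$day == 90 & sim$clone == 1] /
                   sim$total_reads[sim$day == 90 & sim$clone == 1])
    last < first
  })
  expect_gte(mean(declines), 0.95)
})

test_that("with no vaccine effect targeted and other declines are alike", {
  set.seed(45)
  days <- c(0, 30, 60, 90)
  diffs <- replicate(200, {
    ccf <- matrix(rep(c(0.5, 0.3), 4), nrow = 2)
    tf <- c(0.02, 0.015, 0.01, 0.008)
    sim <- simulate_plasma_series(
      ccf, c(t1 = 1, t2 = 1, o1 = 2, o2 = 2), tf, days, 5000)
    vaf <- sim$alt_reads / sim$total_reads
    dec <- function(cl) {
      100 * (mean(vaf[sim$day == 0 & sim$clone == cl]) -
               mean(vaf[sim$day == 90 & sim$clone == cl])) /
        mean(vaf[sim$day == 0 & sim$clone == cl])
    }
    dec(1) - dec(2)
  })
  # both clones share the tumor-fraction trajectory: mean decline gap ~ 0
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1)
})
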