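test_that("compute_vaf is alt/(alt+ref) and rejects zero coverage", {
  expect_equal(compute_vaf(5, 95), 0.05)
  expect_equal(compute_vaf(0, 100), 0)
  expect_equal(compute_vaf(37, 63), 0.37)
  expect_equal(compute_vaf(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(compute_vaf(0, 0), "zero total reads")
  expect_error(compute_vaf(-1, 10), "non-negative")
})

make_calls <- function(pos, ...) {
  tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T", ...)
}

test_that("consensus keeps loci called by both primaries and the confirmer", {
  cs <- list(mutect2 = make_calls(c(1, 2, 3)),
             somaticsniper = make_calls(c(2, 3, 4)),
             deepsnv = make_calls(c(3, 4, 5)))
  out <- consensus_somatic_calls(cs)
  expect_equal(out$pos, 3)
  expect_equal(out$caller_support, "mutect2,somaticsniper,deepsnv")
  expect_equal(out$origin, "DNA")

  only_a <- list(mutect2 = make_calls(1), somaticsniper = make_calls(2),
                 deepsnv = make_calls(1))
  expect_equal(nrow(consensus_somatic_calls(only_a)), 0)
})

test_that("consensus rejects bad input: missing sets, duplicates, indels", {
  cs <- list(mutect2 = make_calls(1), somaticsniper = make_calls(1))
  expect_error(consensus_somatic_calls(cs), "missing call-set.*deepsnv")
  dup <- list(mutect2 = make_calls(c(1, 1)), somaticsniper = make_calls(1),
              deepsnv = make_calls(1))
  expect_error(consensus_somatic_calls(dup), "duplicate locus chr1:1:A:T")
  indel <- list(
    mutect2 = tibble::tibble(chrom = "chr1", pos = 1, ref = "AT", alt = "A"),
    somaticsniper = make_calls(1), deepsnv = make_calls(1))
  expect_error(consensus_somatic_calls(indel), "only SNVs")
})

test_that("consensus matches set-algebra oracle and ignores input order", {
  set.seed(42)
  for (rep in 1:20) {
    cs <- random_callset_triple(200)
    out <- consensus_somatic_calls(cs)
    oracle <- sort(intersect(intersect(key_of(cs$mutect2),
                                       key_of(cs$somaticsniper)),
                             key_of(cs$deepsnv)))
    expect_setequal(out$key, oracle)

    shuffled <- lapply(cs, function(x) x[sample(nrow(x)), ])
    expect_identical(consensus_somatic_calls(shuffled), out)
  }
})

test_that("consensus output loci are a subset of every input call-set", {
  set.seed(7)
  cs <- random_callset_triple(300)
  out <- consensus_somatic_calls(cs)
  for (nm in names(cs)) expect_true(all(out$key %in% key_of(cs[[nm]])))
})

test_that("RNA validation applies inclusive depth and VAF boundaries", {
  expect_true(rna_validate(20, 0.05))
  expect_false(rna_validate(19, 0.50))
  expect_false(rna_validate(200, 0.049))
  expect_true(rna_validate(200, 0.05))
  expect_message(out <- rna_validate(NA, 0.5), "without RNA data")
  expect_false(out)
})

test_that("raising RNA thresholds never grows the surviving set", {
  set.seed(1)
  depth <- rpois(200, 25)
  vaf <- runif(200, 0, 0.2)
  base <- sum(rna_validate(depth, vaf))
  for (d in c(25, 30)) {
    expect_lte(sum(rna_validate(depth, vaf, min_depth = d)), base)
  }
  for (v in c(0.08, 0.12)) {
    expect_lte(sum(rna_validate(depth, vaf, min_vaf = v)), base)
  }
})

test_that("RNA-editing candidates enter with confirmer-only support", {
  calls <- tibble::tibble(chrom = "chr2", pos = c(10, 5), ref = "A",
                          alt = "G", gene = "AZIN1",
                          protein_change = "p.S367G")
  out <- rna_editing_calls(calls)
  expect_equal(out$origin, rep("RNA-editing", 2))
  expect_equal(out$caller_support, rep("deepsnv", 2))
  expect_equal(out$pos, c(5, 10))
  rna <- tibble::tibble(chrom = "chr2", pos = c(5, 10), ref = "A", alt = "G",
                        rna_depth = c(100, 10), rna_vaf = c(0.3, 0.3))
  ann <- annotate_rna(out, rna)
  expect_equal(ann$rna_validated, c(TRUE, FALSE))
})
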