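test_that("median_ic50 is the sample median with even-count averaging", {
  expect_equal(median_ic50(c(100, 200, 300, 400, 500)), 300)
  expect_equal(median_ic50(320), 320)
  expect_equal(median_ic50(c(100, 400)), 250)
  expect_error(median_ic50(numeric()), "empty")
  expect_error(median_ic50(c(100, -5)), "positive")
})

aff_row <- function(key, peptide, allele, class, predictor, ic50) {
  tibble::tibble(key = key, peptide = peptide, hla_allele = allele,
                 hla_class = class, predictor = predictor, ic50_nM = ic50)
}

test_that("summarize_mutations takes min over pair medians per class", {
  geno <- c("HLA-A*02:01", "HLA-B*40:01", "HLA-DRB1*09:01")
  aff <- dplyr::bind_rows(
    aff_row("m1", "PEPTIDEA", "HLA-A*02:01", "I", c("p1", "p2", "p3"),
            c(400, 600, 800)),                            # median 600
    aff_row("m1", "PEPTIDEB", "HLA-B*40:01", "I", c("p1", "p2", "p3"),
            c(350, 450, 900)),                            # median 450
    aff_row("m1", "PEPTIDELONGERII15", "HLA-DRB1*09:01", "II", "pII", 320)
  )
  s <- summarize_mutations(aff, geno)
  expect_equal(s$best_classI_ic50, 450)
  expect_equal(s$best_classII_ic50, 320)

  s2 <- summarize_mutations(aff[aff$hla_class == "I", ], geno)
  expect_true(is.na(s2$best_classII_ic50))

  expect_error(summarize_mutations(aff, geno[-1]), "not in patient genotype")
})

test_that("summarize_mutations equals exhaustive enumeration on random tables", {
  set.seed(11)
  geno <- c("A1", "A2", "B1", "DR1")
  for (rep in 1:20) {
    n <- 20
    aff <- tibble::tibble(
      key = sample(c("m1", "m2"), n, replace = TRUE),
      peptide = sample(c("P1", "P2", "P3"), n, replace = TRUE),
      hla_allele = sample(geno, n, replace = TRUE),
      hla_class = NA_character_,
      predictor = paste0("pred", seq_len(n)),
      ic50_nM = exp(runif(n, log(30), log(3000)))
    )
    aff$hla_class <- ifelse(aff$hla_allele == "DR1", "II", "I")
    s <- summarize_mutations(aff, geno)
    for (k in unique(aff$key)) {
      for (cl in c("I", "II")) {
        sub <- aff[aff$key == k & aff$hla_class == cl, ]
        want <- if (nrow(sub) == 0) NA_real_ else {
          pairs <- unique(sub[c("peptide", "hla_allele")])
          min(apply(pairs, 1, function(p) {
            stats::median(sub$ic50_nM[sub$peptide == p[["peptide"]] &
                                        sub$hla_allele == p[["hla_allele"]]])
          }))
        }
        col <- if (cl == "I") "best_classI_ic50" else "best_classII_ic50"
        expect_equal(s[[col]][s$key == k], want)
      }
    }
  }
})

test_that("neoantigen call uses strict < 500 on either class", {
  s <- tibble::tibble(
    best_classI_ic50 = c(499, 500, NA, 600),
    best_classII_ic50 = c(600, 500, 450, 700))
  expect_equal(is_predicted_neoantigen(s), c(TRUE, FALSE, TRUE, FALSE))
  # threshold monotonicity: enlarging the cut never removes a candidate
  for (th in c(600, 1000, 5000)) {
    expect_true(all(is_predicted_neoantigen(s, th) |
                      !is_predicted_neoantigen(s)))
  }
})

test_that("tiers follow the strong/modest rank order with 150 nM edge", {
  s <- tibble::tibble(
    best_classI_ic50 = c(100, 100, 300, 499, 150, NA),
    best_classII_ic50 = c(120, 900, 400, NA, 150, 100))
  expect_equal(assign_tier(s), c(1L, 2L, 3L, 4L, 4L, 2L))
  bad <- tibble::tibble(best_classI_ic50 = 700, best_classII_ic50 = 900)
  expect_error(assign_tier(bad), "not a predicted neoantigen")
})

test_that("prioritize keeps everything under the cap and is deterministic", {
  set.seed(5)
  s <- random_summaries(40)[1:7, ]
  out <- prioritize(s)
  expect_equal(nrow(out), 7)
  expect_setequal(out$key, s$key)

  big <- random_summaries(200)
  out <- prioritize(big, cap = 30)
  expect_equal(nrow(out), 30)
})

test_that("prioritize matches the comparator-sort oracle", {
  set.seed(23)
  for (rep in 1:50) {
    s <- random_summaries(sample(10:60, 1))
    if (nrow(s) == 0) next
    expect_identical(prioritize(s, cap = 30)$key,
                     prioritize_oracle(s, cap = 30))
  }
})

test_that("prioritize is a projection, permutation-invariant, tier-ordered", {
  set.seed(31)
  s <- random_summaries(80)
  once <- prioritize(s, cap = 30)
  expect_identical(prioritize(once, cap = 30), once)
  shuf <- prioritize(s[sample(nrow(s)), ], cap = 30)
  expect_identical(shuf, once)
  expect_true(!is.unsorted(once$tier))
})
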