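test_that("site detection thresholds mutant reads and is monotone", {
  expect_false(site_detected(0))
  expect_true(site_detected(2))
  set.seed(3)
  alt <- rpois(500, 3)
  counts <- sapply(0:10, function(th) sum(site_detected(alt, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("positive rate is detected/panel sites and matches counting oracle", {
  s <- tibble::tibble(alt_reads = c(3, 5, rep(0, 11)),
                      total_reads = rep(1000, 13),
                      is_target = rep(TRUE, 13))
  expect_equal(round(positive_rate(s, "target"), 3), 0.154)
  expect_error(positive_rate(s, "other"), "no panel sites")

  set.seed(8)
  for (rep in 1:20) {
    panel <- random_plasma_sample(sample(5:60, 1))
    for (sub in c("target", "other")) {
      rows <- if (sub == "target") panel$is_target else !panel$is_target
      oracle <- sum(panel$alt_reads[rows] >= 2) / sum(rows)
      expect_equal(positive_rate(panel, sub), oracle)
    }
  }
})

test_that("mean VAF honors the undetected-site policy", {
  s <- tibble::tibble(alt_reads = c(100, 200, 300),
                      total_reads = 1000, is_target = TRUE)
  expect_equal(mean_vaf(s, "target"), 0.2)

  s2 <- tibble::tibble(alt_reads = c(200, 0), total_reads = 1000,
                       is_target = TRUE)
  expect_equal(mean_vaf(s2, "target", "zero"), 0.10)
  expect_equal(mean_vaf(s2, "target", "exclude"), 0.20)

  set.seed(12)
  for (rep in 1:20) {
    panel <- random_plasma_sample(50)
    vaf <- panel$alt_reads / panel$total_reads
    det <- panel$alt_reads >= 2
    tgt <- panel$is_target
    expect_equal(mean_vaf(panel, "target", "zero"),
                 mean(ifelse(det[tgt], vaf[tgt], 0)))
    # zero policy never exceeds exclude policy
    expect_lte(mean_vaf(panel, "target", "zero"),
               mean_vaf(panel, "target", "exclude") + 1e-12)
  }
})

test_that("percent decline reproduces the closed form and sign convention", {
  expect_equal(percent_decline(0.200, 0.022), 89)
  expect_equal(percent_decline(0.1, 0.1), 0)
  expect_equal(percent_decline(0.1, 0.15), -50)
  expect_error(percent_decline(0, 0.1), "undefined")
})

make_traj <- function(target, other, detected = NULL) {
  n <- length(target)
  tibble::tibble(day = seq(0, by = 30, length.out = n),
                 mean_vaf_target = target, mean_vaf_other = other,
                 n_detected_target = detected %||% rep(5L, n),
                 n_detected_other = detected %||% rep(5L, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pattern classification separates concordant/divergent/untrackable", {
  x <- c(0.05, 0.02, 0.03, 0.04, 0.01)
  expect_equal(classify_pattern(make_traj(x, x)), "concordant")
  expect_equal(classify_pattern(
    make_traj(c(0.05, 0.04, 0.03, 0.02, 0.01),
              c(0.01, 0.02, 0.03, 0.04, 0.05))), "divergent")
  expect_equal(classify_pattern(
    make_traj(x, x, detected = rep(0L, 5))), "untrackable")
  expect_equal(classify_pattern(make_traj(rep(0, 5), rep(0, 5))),
               "concordant")
})

test_that("panel_trajectory aggregates per day and feeds classification", {
  set.seed(2)
  plasma <- tibble::tibble(
    patient = "N01",
    day = rep(c(0, 30, 60), each = 4),
    site = rep(paste0("s", 1:4), 3),
    alt_reads = c(10, 12, 9, 11, 5, 6, 20, 22, 2, 3, 30, 33),
    total_reads = 1000,
    is_target = rep(c(TRUE, TRUE, FALSE, FALSE), 3))
  traj <- panel_trajectory(plasma)
  expect_equal(traj$day, c(0, 30, 60))
  expect_equal(traj$mean_vaf_target, c(0.011, 0.0055, 0.0025))
  expect_equal(traj$mean_vaf_other, c(0.010, 0.021, 0.0315))
  expect_equal(classify_pattern(traj), "divergent")
  expect_error(panel_trajectory(plasma[plasma$is_target, ]),
               "both targeted and other")
})
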