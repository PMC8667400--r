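# Independent oracles: deliberately coded from first principles, not via the
# package's own code paths.

# Product-limit survivor curve by direct enumeration; median = smallest time
# with S(t) <= 0.5.
km_median_oracle <- function(times, events) {
  ord <- order(times)
  t <- times[ord]
  e <- events[ord]
  event_times <- sort(unique(t[e == 1]))
  s <- 1
  for (x in event_times) {
    at_risk <- sum(t >= x)
    d <- sum(t == x & e == 1)
    s <- s * (1 - d / at_risk)
    if (s <= 0.5 + 1e-12) return(x)
  }
  NA_real_
}

# Tier rules restated row-by-row with plain conditionals.
tier_oracle <- function(ci, cii) {
  strong_i <- !is.na(ci) && ci < 150
  strong_ii <- !is.na(cii) && cii < 150
  modest_i <- !is.na(ci) && ci > 150 && ci <= 500
  modest_ii <- !is.na(cii) && cii > 150 && cii <= 500
  if (strong_i && strong_ii) return(1L)
  if (strong_i || strong_ii) return(2L)
  if (modest_i && modest_ii) return(3L)
  4L
}

# Brute-force comparator sort: count, for each candidate, how many others it
# beats under the full lexicographic comparator, then rank by wins.
prioritize_oracle <- function(s, cap = 30) {
  n <- nrow(s)
  tier <- mapply(tier_oracle, s$best_classI_ic50, s$best_classII_ic50)
  vaf <- ifelse(is.na(s$rna_vaf), -Inf, s$rna_vaf)
  ci <- ifelse(is.na(s$best_classI_ic50), Inf, s$best_classI_ic50)
  beats <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      beats[i, j] <-
        if (tier[i] != tier[j]) tier[i] < tier[j] else
          if (vaf[i] != vaf[j]) vaf[i] > vaf[j] else
            if (ci[i] != ci[j]) ci[i] < ci[j] else s$key[i] < s$key[j]
    }
  }
  wins <- rowSums(beats)
  head(s$key[order(wins, decreasing = TRUE)], cap)
}

# Random affinity summaries with values straddling the 150/500 cut points;
# non-neoantigens (both classes >= 500) filtered out as prioritize requires.
random_summaries <- function(n) {
  s <- tibble::tibble(
    key = paste0("chr1:", sample(1e6, n), ":A:T"),
    best_classI_ic50 = ifelse(runif(n) < 0.1, NA,
                              exp(runif(n, log(20), log(5000)))),
    best_classII_ic50 = ifelse(runif(n) < 0.3, NA,
                               exp(runif(n, log(20), log(5000)))),
    rna_vaf = round(runif(n), sample(1:3, n, replace = TRUE))
  )
  s[neovax::is_predicted_neoantigen(s), , drop = FALSE]
}

# Random caller call-set triple over a shared locus pool.
random_callset_triple <- function(n_pool = 500) {
  pool <- tibble::tibble(
    chrom = paste0("chr", sample(1:22, n_pool, replace = TRUE)),
    pos = sample(1e7, n_pool),
    ref = "A", alt = "T"
  )
  pool <- pool[!duplicated(pool[c("chrom", "pos")]), ]
  pick <- function() pool[sample(nrow(pool), sample(50:nrow(pool), 1)), ]
  list(mutect2 = pick(), somaticsniper = pick(), deepsnv = pick())
}

key_of <- function(cs) neovax::mutation_key(cs$chrom, cs$pos, cs$ref, cs$alt)

random_plasma_sample <- function(n_sites) {
  total <- rpois(n_sites, 2000)
  tibble::tibble(
    site = paste0("s", seq_len(n_sites)),
    alt_reads = rbinom(n_sites, total, runif(n_sites, 0, 0.01)),
    total_reads = total,
    is_target = seq_len(n_sites) <= max(1, n_sites %/% 3)
  )
}
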