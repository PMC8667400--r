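---
title: "From somatic calls to vaccine pools and ctDNA monitoring: the neovax pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic calls to vaccine pools and ctDNA monitoring: the neovax pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

neovax implements the analysis chain behind personalized neoantigen
long-peptide vaccination of resected hepatocellular carcinoma (HCC) patients
at high recurrence risk: select vaccine targets from tumor sequencing,
design the peptide product, and then read out the vaccine's effect through
ELISpot immunology, circulating tumor DNA (ctDNA), and recurrence-free
survival (RFS). Patient sequencing data from such trials is controlled
access, so the package ships a synthetic-cohort generator that reproduces
the *statistical structure* of every input; all downstream code is agnostic
to whether its inputs are real or simulated.

## Somatic filtering

Somatic SNVs enter as three per-caller call-sets (two primary callers and a
confirmatory caller). `consensus_somatic_calls()` retains a locus iff both
primary callers report it and the confirmer supports it — plain set algebra
`(A ∩ B) ∩ C` on `chrom:pos:ref:alt` keys. Only SNVs are accepted: the
vaccine products are missense-mutation peptides, and an indel in a call-set
is treated as a data error rather than silently dropped. Candidates derived
from tumor-specific RNA editing have no DNA-level call at all; they bypass
the consensus through `rna_editing_calls()` with confirmer-only support, a
deliberate asymmetry that mirrors how editing-derived antigens reach the
pipeline in practice.

Expression validation then requires RNA-seq depth ≥ 20× and RNA variant
allele frequency (VAF) ≥ 0.05 at the site, both boundaries inclusive.
Missing RNA evidence fails validation (and is reported), because an
unexpressed neoantigen cannot be presented.

## Neoantigen calling and prioritization

Binding affinities are *inputs*: per (mutation, peptide, HLA allele,
predictor) IC50 values in nM from external class I predictors (five tools
is typical) and a single class II predictor. For each (peptide, allele)
pair the decision statistic is the median IC50 across predictors; a
mutation's best class I (class II) affinity is the minimum of its pair
medians. A mutation is a predicted neoantigen when either best value is
strictly below 500 nM.

When more than 30 candidates survive, they are ranked by a four-criterion
order: (1) strong binding (IC50 < 150 nM) to both classes; (2) strong
binding to exactly one class; (3) higher RNA VAF; (4) modest binding
(150 < IC50 ≤ 500) to both classes. Criteria 1, 2 and 4 name affinity
*categories* while 3 is *comparative*; the only reading that makes the four
a single total order is to treat 1/2/4 as tiers and RNA VAF as the
within-tier sort key. That is what `prioritize()` does, with best class I
IC50 and then the locus key as final deterministic tie-breaks. Two edge
cases are worth stating: an IC50 of exactly 150 nM is neither "strong"
(< 150) nor "modest" (> 150), so such a class contributes to neither tier 1/2
nor tier 3; and a mutation with modest binding to only one class falls into
tier 4, since only "modest to both" is named a category. Enlarging the
500 nM threshold can only add candidates, never remove them.

## Vaccine design

`design_long_peptide()` cuts a 27-residue window from the protein context
with the mutant residue at position 14 whenever 13 residues flank it on both
sides. Near a terminus the window slides to stay inside the protein at full
length, and proteins shorter than 27 residues are used whole. Centering is
standard long-peptide practice — the published protocols state only the
length — so the window and the convention are both configurable.

Peptides are partitioned into `clamp(ceil(n/5), 1, 4)` dose pools of 3–5
peptides (0.3 mg/peptide, 0.5 mg poly-IC adjuvant per injection), filled
round-robin by priority rank so that top-tier peptides spread across pools
rather than concentrating in pool 1; the grouping rule is not specified in
the source protocols and round-robin is this package's choice. Between 3
and 20 peptides can be pooled — fewer than 3 cannot form a pool, and more
than 20 exceeds what is realistically synthesized in time. The prime-boost
schedule is fixed: doses on days 1, 4, 8, 15, 22 (prime) and 90, 140
(boost), with boost doses allowed up to 15 days late.

## ctDNA monitoring

Longitudinal plasma samples report per-site mutant/total read counts over
the personalized panel, split into vaccine-targeted neoantigen sites and
other somatic sites. Three conventions matter and all are exposed as
arguments:

* **Detection.** A site is detected with ≥ 2 mutant reads. Plasma
  positivity has no community-standard rule; 2 reads is this package's
  default.
* **Mean VAF.** Undetected sites contribute VAF 0 by default (`zero`
  policy), keeping timepoints with different detection comparable; an
  `exclude` policy averaging only detected sites is provided, and the zero-
  policy mean never exceeds the exclude-policy mean.
* **Pattern.** `classify_pattern()` calls a patient *untrackable* when
  fewer than 3 timepoints have any detected site; otherwise *concordant*
  when the Spearman correlation between the targeted and other mean-VAF
  series is ≥ 0.7 and *divergent* below that. Concordance suggests low
  tumor heterogeneity (most cells carry the targeted mutations); divergence
  — targeted sites falling while others rise — is the signature of
  preferential killing of vaccine-targeted clones with escape of the rest.
  Constant series carry no rank information and are classified concordant,
  as a flat series is no evidence of divergence.

## ELISpot response calling

A stimulus well set is positive when its mean spot count is at least twice
the matched negative control *and* exceeds it by ≥ 10 spots — a
conventional empirical criterion (the source protocols give none); both
margins are arguments. Under a Poisson null with triplicate wells at a
baseline of 5 spots this fires in well under 5% of replicates, while a
3×-plus-20-spots responsive signal is detected in over 90% — both rates are
recomputed in the test suite and the acceptance script rather than quoted.
A patient has *responsive neoantigens* only if some pool or peptide is
positive at a post-boost timepoint: pre-existing reactivity (e.g. antigen
release after embolization) that fades before the boost does not count, and
patients who never completed the boost phase are a separate clinical group
for which the call is refused.

## Survival and matched controls

RFS is computed in 30.4375-day months (365.25/12; the convention is ours)
from either surgery or first vaccination. The Kaplan–Meier median is the
smallest time at which the product-limit estimate reaches 0.5, computed via
the survival package; group comparisons use the standard log-rank
chi-square. Unvaccinated controls are selected by 1:2 nearest-neighbor
propensity matching: logistic propensity on the baseline covariates, greedy
matching without replacement on the logit scale in seeded random order,
within a caliper of 0.2 standard deviations of the logit propensity (the
standard reading of "caliper 0.2"; a raw-probability caliper is available
by flag). Constant covariates are dropped with a warning; unmatched treated
subjects are reported, not silently discarded.

## What the synthetic cohort emulates

`simulation_config()` defaults encode the study conditions the package
models:

* **Mutation burden.** Per-patient somatic SNV counts are negative binomial
  (mean 78, dispersion 8) clamped to [7, 148] — matching the printed mean
  and range without asserting an unstated distribution. The clamp pulls the
  realized mean down by a point or two; the dispersion was chosen so the
  clamp is rarely binding.
* **Neoantigen yield.** Each mutation is expression-validated with
  probability 0.55 and a predicted neoantigen with probability 0.335 (the
  observed fraction of all mutations that were both expressed and
  predicted binders); every simulated neoantigen is expressed, since an
  unexpressed one could never have been called. Each patient is floored at
  6 predicted neoantigens so that a vaccine (6–20 synthesized peptides,
  like the trial's products) can always be formed; at the 7-mutation clamp
  floor this raises the realized neoantigen fraction above 0.335.
* **Affinities.** Per-pair IC50 band targets are drawn log-uniform within
  strong (25–120 nM), modest (170–450 nM) or non-binder (700 nM–20 µM)
  bands, with per-predictor log-normal scatter (σ = 0.35) rescaled so the
  pair median equals the band draw — the tier composition is therefore
  exactly as designed while individual predictions stay noisy.
* **Clonal structure and plasma.** Each tumor has 3 clones with
  Dirichlet-like CCFs summing to 0.9; neoantigen mutations arise only in
  the leading third of clones (`neo_clone_fraction = 1/3`), the
  heterogeneity structure under which vaccine pressure produces the
  divergent ctDNA pattern. The expected VAF of a copy-neutral diploid site
  is `tumor_fraction(t) × CCF(t) / 2`; copy-number-affected sites are
  excluded from the model just as they are excluded from clonal analyses of
  such trials. Reads are Poisson (mean 5,000 per site — plasma panel
  depth is never published for this trial; the default is typical of deep
  ctDNA panels and configurable) with binomial mutant draws. The default
  tumor-fraction trajectory falls after surgery and rises towards
  recurrence. A `vaccine_kill_rate` of 0.35 multiplies the CCF of every
  clone carrying ≥ 1 vaccine-targeted mutation by 0.65 per post-vaccination
  interval; 0 switches the vaccine effect off (the null used in
  calibration checks).
* **Immunology and outcomes.** ELISpot counts are Poisson with triplicate
  wells (baseline 5, responsive 60 spots); half of boosted patients respond
  (5 of 10 in the modeled trial). Recurrence is exponential per group —
  medians 16.5 / 3.9 months from first vaccination for
  responsive / non-responsive (≈ 19.3 / 6.7 months from surgery after the
  typical 2.8-month gap) and 4.8 months from surgery for controls — with
  administrative censoring at 33 months. A 100-subject unvaccinated pool
  with mildly shifted covariates supports propensity matching.

What it does **not** emulate: read-level artifacts (no FASTQ/BAM),
sequencing error beyond binomial sampling, copy-number variation, subclonal
evolution other than the kill-rate decay, HLA-specific binding preferences
(peptide sequences are random strings containing the mutant residue), and
any correlation between immunogenicity and affinity tier. Passing tests on
this cohort therefore demonstrate that the *statistics* are computed
correctly under the stated model, not that the thresholds would select
immunogenic peptides from real tumors.

## Numerical choices and problem sizes

Identical configs are bit-identical (one seed drives the whole cohort;
`simulate_plasma_series()` accepts its own seed when used standalone).
Degenerate inputs are errors, not guesses: zero-coverage VAFs, empty
affinity sets, percent decline from zero, single-group log-rank, pool sizes
outside 3–20. The automated checks run the pattern-recovery experiment at
100 single-patient replicates per arm, ELISpot calibration at 1,000
replicates, the Kaplan–Meier oracle comparison at 500 random censored
samples plus one n = 5,000 exponential sample (3% tolerance on ln 2/λ),
log-rank power at 500 simulations of 200 per arm, and matching balance on a
300-subject confounded cohort — sizes chosen to hold Monte-Carlo error
comfortably below the margins being asserted.

## Known limitations

The consensus rule is fixed at two-primary-plus-confirmer; other caller
topologies need a thin wrapper. Multi-allelic records must be split
upstream. The pattern classifier compares exactly two series; panels with
no targeted (or no other) sites are rejected rather than classified. The
matching implementation is greedy, not optimal, and the log-rank test is
asymptotic — both standard, both stated. Clinical numbers computed on a
10-patient synthetic cohort (medians, log-rank p) carry the sampling noise
of n = 10 by design; they characterize the trial-scale behavior of the
estimators, not population truth.
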