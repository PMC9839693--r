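---
title: "Methods: paired case-control microbiome and metabolome inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired case-control microbiome and metabolome inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircohort)
```

## The design problem

In a paired case-control study of a rare disease, each patient is matched to
one or more cohabitating, healthy relatives, which controls for shared
environment, diet and half of the genetic background. Matching is imperfect
in practice: some patients contribute no usable relative sample, others have
two or three relatives (or repeated samples), and samples drift apart in
time. A single paired t-test is therefore ill-defined — which relative is
"the" pair?

`paircohort`'s central statistic resolves this by permutation over pairings
rather than by choosing pairs once. Eligibility is determined first:
`build_pair_graph()` admits every relative sample from the patient's family
collected within 90 days (inclusive) of the patient's sample; patients with
no eligible relative are excluded and recorded. Each of `n_perm`
permutations then draws, independently and uniformly, one eligible relative
per patient, forms the patient-minus-relative differences, and computes an
ordinary paired t-test. The reported quantities are the across-permutation
arithmetic means of the t statistic, the two-sided p-value, the mean
difference and the 95% CI bounds, with fixed `df = n_pairs - 1`. When every
patient has exactly one eligible relative there is no randomness and the
output is exactly the closed-form paired t-test; the test suite also checks
Monte-Carlo convergence to the exhaustive average over all pairing
assignments on small graphs.

Conventions worth stating explicitly:

* Differences are always patient − relative, so deficits (richness, alpha
  diversity) come out negative.
* The aggregated CI is the mean of the per-permutation CI bounds — a "mean
  95% CI" — not a CI of the aggregated mean.
* Draws run over patients in sorted-id order with sorted relative lists, so
  results are invariant to input row order at a fixed seed.
* A relative sample shared by two patients (one household, two cases) may be
  drawn by both; draws are independent per patient and the condition is
  flagged in the result (`relative_reuse`).
* When some eligible relatives lack an endpoint, the patient stays in as
  long as one measured relative remains; patients with none are dropped
  with a warning and `n_pairs` (hence `df`) shrinks before permuting.
* Benjamini–Hochberg FDR is applied to the mean p-values within one table
  family (e.g. all metabolites of one biofluid), via `paired_test_table()`.

The shared-OTU endpoint needs its own loop (`shared_fraction_test()`)
because its value is pair-specific: the per-pair difference is the
patient's shared percentage toward the drawn relative minus that relative's
percentage toward the patient. `shared_fraction(a, b)` is deliberately
asymmetric — `100 |A∩B| / |A|` with A the first argument's presence set — so
a species-poor patient whose taxa form a subset of the relative's scores
high toward the relative while the relative scores low toward the patient.

## Diversity computations

The OTU-table pipeline is conventional and implemented from first
principles so each step is transparent to test: dataset-wide rare-OTU
filtering (features with fewer than 100 reads in the whole table are
removed), single-draw rarefaction without replacement (multivariate
hypergeometric; samples below the target depth are dropped and reported,
and the default depth is the smallest library so nothing is dropped),
inverse Simpson alpha diversity `1/Σp²`, and Bray–Curtis dissimilarity
`Σ|x−y| / Σ(x+y)` on the rarefied counts. Rarefaction is a single seeded
draw, not an average over draws, matching the convention of the standard
16S toolchain; at equal depths Bray–Curtis on counts and on proportions
coincide. Presence for richness and shared-OTU sets means count ≥ 1 after
rarefaction; whether the richness/shared contrasts use the rarefied or
merely filtered table is exposed as a flag (`contrasts_on`), defaulting to
rarefied.

Group spread is summarized by `centroid_distances()`: the distance matrix
is embedded by principal-coordinates decomposition keeping
negative-eigenvalue axes, and each sample's squared distance to its group
centroid is the real-axis part minus the imaginary-axis part, floored at
zero — the standard multivariate-dispersion correction for semi-metric
distances like Bray–Curtis. On Euclidean-embeddable input this equals the
plain centroid distance (checked against a coordinate-space oracle and
against `vegan::betadisper(type = "centroid")`).

`permanova()` implements the one-way pseudo-F directly from the squared
distances (`SS_total = (1/n) Σ_{i<j} d²`, within-group terms analogously)
with the +1 permutation convention, so p is never zero. For two groups an
`exhaustive = TRUE` mode enumerates all label assignments, which both
serves tiny designs exactly and anchors the sampled mode in tests. Samples
are put in sorted-id order before permuting so the p-value, not just F and
R², is reproducible regardless of input order.

## Enterotypes and association

Community types are found by partitioning around medoids on the Bray–Curtis
matrix (the same distance as the rest of the beta-diversity analysis, by
design; the distance is a parameter). `pam_cluster()` runs the BUILD
greedy seeding followed by best-improvement SWAP, with deterministic
lowest-index tie-breaking. SWAP terminates in a local optimum that can miss
the global medoid-subset optimum even at n = 7 (reference implementations
share this property), so instances with at most 1000 candidate medoid
subsets are additionally refined by exhaustive enumeration — small problems
are provably optimal, large ones get the usual heuristic. `select_k()`
chooses k by maximal average silhouette width (ties to the smaller k) and
flags the result when even the best average silhouette is below 0.25, the
customary "no substantial structure" threshold.

Association between enterotype and case status uses the exact conditional
test on the 2×2 subject-by-cluster table: two-sided p by hypergeometric
enumeration, odds ratio as the conditional MLE with an exact 95% CI (the
convention of standard exact-test implementations). Because PAM's cluster
numbering is arbitrary, the pipeline orients the table on the cluster with
the highest patient share — "cluster 1" is the case-associated enterotype,
following the field's naming convention — otherwise the reported OR would
randomly flip between x and 1/x across seeds. Cluster-defining OTUs are
ranked by permutation importance from a 500-tree random forest (√m features
per split) classifying cluster labels from relative abundances,
out-of-bag-validated and seeded.

## Metabolite preprocessing and PLS-DA validation

Concentration tables are preprocessed per biofluid: mouse stool is first
sum-normalized per sample; all modes then take natural logs and autoscale
each metabolite to mean 0, sd 1. Zeros are replaced before the log by half
the smallest positive value of that metabolite — the common
minimum-replacement rule, chosen because the measurement floor, not true
absence, is the usual cause — and constant metabolites are dropped with a
warning. Per-metabolite paired testing operates on the log concentrations
(not the autoscaled matrix, which would erase the scale of the mean
difference); the autoscaled matrix feeds the multivariate diagnostics.

`plsda_validate()` fits a two-class PLS by NIPALS (iterative latent-variable
extraction with deflation, class coded 0/1, default 2 components to match
two-axis ordinations) and reports the standard validation battery: R² on
the training fit, Q² = 1 − PRESS/TSS under leave-one-out (each fold refits
everything, including centering and scaling), leave-one-out accuracy and
CER, AUROC of the leave-one-out scores, and two label-permutation p-values
with the +1 convention. The separation-distance null uses the
between-centroid over within-class variance ratio of the full-fit scores;
the accuracy null uses leave-one-out accuracy, because training accuracy
saturates for wide matrices and its permutation null would be
uninformative. First-component scores are cross-checked against mixOmics
in the test suite.

## Mouse colony analyses

The eight-factor pathology score sums ordinal bins (hind limb clasping,
grooming, cataracts, kyphosis, motor function, tremors, jumping, body
condition). Bin widths are configuration: the default gives four factors a
0–2 range and four a 0–1 range so the total spans 0 (no disease) to 12
(severe disease); studies with different scoring-sheet bin definitions can
pass their own maxima. Gut transit is the time from gavage to first
observation of red stool on a 10-minute check grid; a detection within the
first interval reports as one full interval, and assays with no detection
by session end are flagged censored, never imputed.

`divergence_trajectory()` composes the primitives per housing stratum and
timepoint: Bray–Curtis, PERMANOVA of FD vs control, and a Welch test on
the centroid-distance dispersions, with BH correction across timepoints
within each stratum. Cage is recorded and reported but not modeled as a
random effect; the tests are sample-level by design.

## The synthetic cohort generator

The generator is first-class, tested code: it produces data with the
statistical structure the analyses assume, so every downstream stage is
exercisable end to end without external downloads.

Human cohorts: 30 families by default, each with one patient and 0–3
relatives drawn with weights (7, 27, 13, 1)/48 — the enrollment mix of a
rare-disease cohort where most families contribute a single relative. Two
enterotype base compositions over 200 taxa are power-law communities whose
dominance ranking differs by a half-cycle rotation mixed back toward the
first composition (weight 0.75): well separated but overlapping, which is
what makes two-cluster PAM recovery a meaningful check rather than a
triviality. Each family draws independent latent enterotypes for its
patient (probability odds/(1+odds) of enterotype 1, default odds 3, so the
planted patient-vs-relative odds ratio is 9) and for its relatives (the
inverse odds). Communities are Dirichlet-multinomial draws (concentration
60) at negative-binomial library sizes (mean 15,000, size 10) — the
overdispersed depths deliberately stress rarefaction. Patients host only a
random subset of taxa: a dropout mask (default 25% per taxon) zeroes the
composition *before* sampling, producing structural zeros, lower expected
richness by the factor (1 − dropout), and the asymmetric shared-OTU
pattern. The patient's collection date anchors the family and relative
dates are jittered uniformly within ±100 days, so roughly one relative
sample in ten violates the 90-day window and the exclusion logic is
genuinely exercised.

Metabolites are log-normal: per-metabolite baselines (log-sd 0.5), a family
random effect (sd 0.3), and multiplicative patient fold-changes — by
default a 2-fold choline elevation against a 20-metabolite panel. Under
these conditions the planted effect is detected at q < 0.05 in roughly 90%
of cohorts of 30 families, comfortably above the 80% design target, while
a fold-change of 1 rejects at the nominal 5%.

Mouse colonies: FD communities drift from the control baseline with mixing
weight `min(1, rate × (1 − attenuation_if_cohoused) × DPW)` (default rate
0.012/day, cohousing attenuation 0.85), pathology bins are binomial draws
centered on a housing-specific progression, and transit times are
log-normal around housing/genotype means (FD separately housed slowest,
cohousing restoring most of the deficit).

Every generator call uses a single explicit RNG stream (`withr::local_seed`)
and is byte-deterministic given its seed; no function reads or leaves state
in the global RNG.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: taxon-taxon correlation beyond the Dirichlet's,
sequencing artifacts (chimeras, contamination, batch effects), repeated
samples per subject, covariate-driven structure (age, G-tube, antibiotics
are carried as opaque metadata only), metabolite-metabolite correlation,
and cage effects in mice. Results on synthetic cohorts validate the
statistical machinery, not any biological claim.

### A note on calibration nulls

Type-I calibration runs on cohorts with one relative per family, dropout 0
and symmetric enterotype odds. With several relatives per family the shared
family-level enterotype makes relatives positively correlated within
groups; free label permutation does not preserve that structure and
PERMANOVA's size inflates (we measure ~12% at nominal 5%) even though no
patient effect is planted. That inflation is a property of permutation
tests under cluster correlation, not an implementation defect, so the
calibration harness uses the exchangeable one-relative design (measured
rejection 3–5% for both the paired test and PERMANOVA at n = 200
replicates).

## Numerical choices and degenerate inputs

* Zero-variance differences in a paired test: t = ±Inf, p → 0, flagged;
  all-zero differences give t = 0, p = 1. Welch tests behave analogously.
* Distance matrices are symmetrized (average with the transpose) and
  validated: zero diagonal, nonnegative, matching ids.
* PERMANOVA tie handling counts permuted F within 1e-12 of the observed F
  as exceeding, so exact relabelings of the observed partition are ties,
  not wins.
* PCoA axes with |eigenvalue| below 1e-10 of the spectrum's magnitude are
  treated as numerically zero.
* Dropout masks that would zero a patient's entire composition are redrawn
  (bounded retries, then an error).
* Singleton groups get centroid distance 0 and are flagged rather than
  dropped.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at deliberately modest sizes
chosen as representative rather than exhaustive: calibration and power use
200 replicate cohorts (15 and 30 families respectively) with 300–400
pairing permutations per test and 199 PERMANOVA permutations; exhaustive
oracles run at n ≤ 7 (medoid subsets), n ≤ 40 (2×2 tables) and n = 6
(label assignments); the end-to-end pipeline examples use the default
30-family cohort with 1000 pairing permutations, 9999 PERMANOVA
permutations and 1000 PLS-DA permutations — the same permutation budgets
recommended for real analyses.
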