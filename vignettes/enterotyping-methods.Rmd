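---
title: "Enterotyping twin cohorts: models, parameters and design choices"
author: "enterotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotyping twin cohorts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enterotyper)
```

## The analysis

`enterotyper` implements an enterotyping-and-association analysis for a
monozygotic (MZ) twin gut-microbiome cohort. Starting from genus-level and
KEGG-pathway relative-abundance tables, a twin design (sample, subject,
pair, time point) and a host metadata table, it

1. clusters community profiles into enterotypes with partitioning around
   medoids (PAM) on Jensen–Shannon (JS), Bray–Curtis (BC) and Euclidean
   (EU) distances, selecting the cluster number by the Calinski–Harabasz
   (CH) pseudo F-statistic and qualifying it with the silhouette index (SI);
2. measures twin-pair enterotype **concordance** (share of
   pair-at-a-time-point observations where co-twins share the enterotype)
   and longitudinal **persistency** (share of twice-sampled subjects who
   keep their enterotype);
3. compares relationship-stratified community distances (same subject over
   time, co-twins, unrelated individuals) with two-sample permutation
   tests;
4. finds enterotype-enriched genera and KEGG features with an LDA-effect-size
   (LEfSe-style) procedure, re-implemented in full; and
5. associates enterotypes with clinical traits, food-group intakes and
   energy-adjusted nutrient intakes, including hierarchical clustering of
   nutrient profiles and a signed-rank screen within enterotype-discordant
   pairs.

Because the motivating study's sequence data are not deposited anywhere we
can reach, the package carries a first-class synthetic cohort generator
(`generate_twin_cohort()`) whose defaults encode the study's design, so
every stage is testable end-to-end against known ground truth.

## Distances and normalization

Profiles are renormalized by `normalize_profiles()`: a pseudocount
(default `1e-6`) is added to every entry and rows are closed to sum 1.
The pseudocount exists for the JS distance, whose KL terms are undefined
at zero; BC and EU tolerate zeros, and with pseudocount 0 the operation is
plain closure and is idempotent. Whether the upstream profiling output
should be re-closed after extracting genus rows is ambiguous in practice;
we always re-close, which is harmless for already-normalized input.

The JS distance is \(d(p,q)=\sqrt{\tfrac12 KL(p\|m)+\tfrac12 KL(q\|m)}\),
\(m=(p+q)/2\), with **base-2 logarithms** so \(d\in[0,1]\) (configurable;
base \(e\) rescales the bound to \(\sqrt{\ln 2}\)). The square root makes
it a true metric, which the test suite verifies on random triples. BC is
\(\sum|p_i-q_i|/\sum(p_i+q_i)\) (via `vegan::vegdist`) and EU is computed
on relative abundances with no transform, since no transform is standard
in this protocol. Principal coordinates (`pcoa()`) use classical scaling;
negative eigenvalues from non-Euclidean JS/BC matrices are clamped to zero
and their total magnitude reported rather than corrected, because the
ordination is display-only.

## PAM, CH and SI

`pam_cluster()` minimizes the k-medoid objective — the total distance of
every sample to its nearest medoid. Two deterministic solvers share this
objective. The classical Kaufman–Rousseeuw **BUILD+SWAP** performs greedy
seeding followed by the best strictly-improving (medoid, non-medoid)
exchange until none exists, with all ties broken toward the lowest sample
index. BUILD+SWAP is a local search: on a small fraction of instances it
terminates in a swap-local optimum strictly above the true minimum (we
exhibit such an instance at n = 6, k = 2 in the tests, where the reference
`cluster::pam` lands in the same local optimum). For that reason the
default solver **enumerates all medoid sets exactly** whenever
\(\binom{n}{k}\le 20000\) — which covers the cohort-scale scans at small k
— and falls back to BUILD+SWAP otherwise. Both paths are exposed and
tested; the local search is additionally checked for equivalence against
`cluster::pam` and for bounding the exact optimum from above.

The CH index is computed in a medoid-centrotype form suited to arbitrary
distance matrices: \(W=\sum_i d(x_i, m_{c(i)})^2\) over cluster medoids,
\(B=\sum_j n_j\,d(m_j, m_0)^2\) with \(m_0\) the overall medoid, and
\(CH=(B/(k-1))/(W/(n-k))\); perfectly tight clusters return an `Inf`
sentinel. The literature contains several CH variants for distance
matrices and the exact one behind the motivating analysis is not
recoverable, so this form is adopted as the package's definition. The
silhouette is the standard \(s(i)=(b_i-a_i)/\max(a_i,b_i)\) with
singleton-cluster widths set to 0, and the mean width is mapped to the
Kaufman–Rousseeuw support categories (none \(\le 0.25\) < weak \(\le 0.5\)
< reasonable \(\le 0.75\) < strong).

`select_k()` scans k = 2 up to `min(10, n-1)` by default and selects the
CH-argmax, breaking ties toward smaller k (parsimony). SI is reported
prominently but **never vetoes** the CH choice: weak silhouette support
for k = 2 is an expected outcome on gradient-like community data and is a
statement about cluster discreteness, not an error. Clusters are then
relabeled by marker dominance (`label_enterotypes()`): the cluster with
the highest mean *Bacteroides* abundance becomes enterotype 1, the
highest-mean *Prevotella* cluster enterotype 2, earlier markers winning
conflicts, with a size-ordered fallback (and warning) when markers are
absent.

## LEfSe re-implementation

`lefse_run()` composes two stages. The screen is the two-sided Wilcoxon
rank-sum test per feature (for two classes this is the Kruskal–Wallis rank
test), with the exact small-sample null when both groups have at most 10
samples and no ties, and the tie-corrected normal approximation otherwise;
constant features get p = 1. Features passing `alpha` (default 0.01) move
to effect sizing: profiles are scaled to a per-sample sum of \(10^6\) (the
conventional scaling that puts log10 scores on the familiar 2–6 range),
and over `n_boot = 30` iterations a fraction (2/3) of each class is
subsampled and a two-class linear discriminant is fitted on the pooled
covariance with diagonal loading (fraction 0.1 of the mean diagonal; the
identity when the subsample is degenerate), which keeps the solve
well-posed in the many-features/few-samples regime. The published LEfSe
description is informal, so the package fixes the per-feature effect as

\[ \text{effect}_f = \tfrac12\left(|\Delta\mu_f| + |w_f|\cdot s\right), \]

where \(\Delta\mu_f\) is the class-mean gap of feature \(f\) on the scaled
data, \(w\) is the unit-norm discriminant direction and
\(s=|w^\top\Delta\mu|\) is the class separation along it. The score is
\(\log_{10}\max(\text{effect},1)\) averaged over bootstrap iterations and
signed by the full-data class-mean direction: **negative = enriched in
class 1** (the *Bacteroides* enterotype), positive = class 2. Features
with \(|score|\ge\) `lda_threshold` (default 2) are reported. The
motivating design has no subclasses, so the within-class subclass stage of
the original procedure is a no-op and is omitted.

## Twin statistics

Concordance uses pair-at-a-time-point observations as the denominator
(a pair sampled twice contributes two observations), matching how such
cohorts are conventionally tabulated. Persistency is computed over
subjects with two time points and returns the 2×2 transition table.
Percentages print with half-away-from-zero rounding (13/16 prints as
81.3, not banker's 81.2).

`relationship_distance_sets()` places every unordered sample pair in
exactly one stratum: same subject across times, co-twins at the same time,
co-twins across times, or unrelated (different pairs).
`permutation_test()` compares two strata by the difference of means, with
the null built by re-assigning pooled values to sets of the original
sizes; p-values use the add-one estimator \((1+\#\{\text{extreme}\})/(1+B)\)
and so are never zero. The default alternative is one-sided ("related
distances are shorter"), the directional hypothesis of interest; the
default \(B\) is 10000. The permutation unit is the individual distance,
which ignores the dependence among distances sharing a sample — the
standard caveat for this test; `permutation_test_subjects()` is provided
as an alternative that permutes whole samples across design slots and
rebuilds the strata, respecting that dependence.

## Host associations

Traits, food groups and nutrients are tested with two-sided Wilcoxon
rank-sum tests between enterotypes, exact when both groups have \(\le 10\)
untied values. Benjamini–Hochberg adjustment is applied **within family**
(traits, foods, nutrients separately): each family corresponds to one
reported analysis, and pooling across families would couple unrelated
hypothesis sets. Nutrients are first energy-adjusted: each nutrient is
regressed on total energy intake (OLS with intercept, complete cases
only), and the standardized residuals (mean 0, sd 1) carry the analysis;
nutrients that are exact multiples of energy give all-zero residual
columns with a warning. Missing diet blocks are masked, never imputed;
analyses use complete cases and report n.

Nutrient-profile clustering is UPGMA (average linkage) on Euclidean
distances over the residual columns, cut at a fixed 2 groups (the number
observed in this kind of analysis) rather than a height threshold, and the
cluster–enterotype association uses Fisher's exact test with the two-sided
probability-mass rule. The discordant-twin screen computes within-pair
differences (enterotype-2 co-twin minus enterotype-1 co-twin) per
discordant pair-at-a-time-point observation and applies the signed-rank
test, dropping zero differences (standard Wilcoxon convention; all-zero
variables get p = 1 with a warning), with BH at FDR 5%.

## The synthetic cohort generator

`generate_twin_cohort()` draws from the model the analyses assume:

* the index twin's enterotype at time 1 is Bernoulli(`pi2` = 0.583,
  the enterotype-2 share of samples in the motivating cohort);
* the co-twin copies it with probability `rho_conc` = 0.722, else flips;
* a twice-sampled subject keeps its state at time 2 with probability
  `rho_pers` = 0.813, else flips (a symmetric two-state Markov step —
  only the marginal persistency is identified, not direction-specific
  switch rates);
* genus and KEGG profiles are exact Dirichlet draws from the latent
  enterotype's alpha vector; traits are Gaussian with an enterotype-2 mean
  shift; nutrients are `slope * energy + shift * 1[enterotype 2] + noise`
  with Gaussian energy; food intakes are log-normal.

The default design is study-shaped: 10 MZ pairs, the first 8 longitudinal
(`round(p_longitudinal * n_pairs)` pairs, deterministically, so the
design is reproducible), 36 samples, 4 with the diet block masked.

Two modeling notes follow directly from this construction. First, the
co-twin flip model implies the co-twin marginal is
\(\pi_2\rho + (1-\pi_2)(1-\rho) \approx 0.537\), so the all-subject
enterotype-2 frequency is slightly below \(\pi_2\); convergence tests
therefore target the index twins, where Bernoulli(\(\pi_2\)) holds
exactly. Second, pooled pair concordance at time 2 is attenuated by the
two independent persistence flips (analytically
\(\rho(p^2+(1-p)^2)+(1-\rho)\cdot 2p(1-p)\approx 0.59\) at the defaults),
so recovery checks of `rho_conc` use single-time cohorts
(`p_longitudinal = 0`), where every paired observation is a direct
Bernoulli(`rho_conc`) draw, and recovery of `rho_pers` uses fully
longitudinal cohorts.

Free parameters the source material does not pin down were fixed once:

* **Dirichlet total concentration 50** — within-enterotype dispersion is
  unreported; 50 gives realistic overlap (weak-to-no silhouette support
  under JS at k = 2, as observed on real cohorts) while keeping the two
  components recoverable.
* **Community weights** — 30 genera; enterotype 1 is *Bacteroides*-heavy
  (mean 0.50) with *Catenibacterium* elevated, enterotype 2
  *Prevotella*-heavy (0.35) with *Lactobacillus*, *Dorea*, *Coprococcus*
  elevated; the remainder is uniform filler. 20 KEGG pathway ids with a
  five-feature enriched block per enterotype.
* **Effect sizes** — uric acid +2.0 mg/dL in enterotype 2 (baseline
  5.0 ± 1.2) and +1.5 residual-sd on the nine diet-associated nutrients
  (fiber, potassium, iron, vitamins A/C/E, folate, carotene, retinol).
  These are calibrated to the package's stated recovery property: on
  default-sized cohorts the adjusted-p < 0.05 hit set averages
  sensitivity ≥ 0.8 with false-discovery proportion ≤ 0.2 over seeds
  (measured 0.945 and 0.033 over 20 seeds). Detectability at n = 36 is
  itself informative about the magnitude of the real effects: shifts much
  below one residual-sd would not have produced the reported adjusted
  p-values at this sample size.
* Traits and nutrients are Gaussian. The downstream tests are rank-based,
  so distributional shape is not load-bearing.

What the generator deliberately does **not** emulate: sequencing count
noise is off by default (profiles are exact compositions; an optional
multinomial `read_depth` layer adds it), there is no phylogenetic or
taxon-correlation structure, no gradient between community types (the
latent classes are discrete by construction), and no longitudinal drift
beyond the one-step flip. Passing recovery tests therefore demonstrate
that the estimators and the pipeline are correct under the assumed model
— they cannot settle whether real enterotypes are discrete, which remains
contested on real data.

## Numerical and reproducibility choices

* All label/medoid ties break toward the lowest sample index; no stage
  needs a seed except the LEfSe bootstrap and the permutation tests.
* A single run seed fans out to per-stage streams via `derive_seed()`
  (a stable string hash below \(2^{31}\)), so stages can be re-run in
  isolation and whole runs are byte-identical given the same config and
  seed.
* The rank tests take the exact enumeration path whenever it is defined
  (small samples, no ties) so that p-values match brute-force enumeration
  to machine precision; otherwise the tie-corrected normal approximation
  with continuity correction is used.
* Degenerate inputs fail loudly with the offending sample or column named:
  all-zero profiles under pseudocount 0, non-symmetric distance matrices,
  single-class screens, pairs without two subjects, probabilities outside
  \([0,1]\).

## Problem sizes used by the checks

The shipped analysis scripts and the verification suite run on cohorts of
10–25 pairs (36–90 samples) for pipeline recovery, 500 pairs for
estimator-convergence checks, 1000 random triples for the JS metric
property, 1000 null replicates (500 permutations each) for permutation
calibration, and 50 random instances (n ≤ 8) for the exact-optimizer
oracle. These sizes give the binomial/CI margins the checks assert while
keeping a full run in the order of a minute.

## Known limitations

* CH-based selection never scans k = 1, so "no cluster structure" cannot
  be concluded, only weak silhouette support reported.
* The naive distance-pooling permutation test treats dependent distances
  as exchangeable units; use the design-slot variant when that matters.
* The LEfSe effect formula is this package's fixed definition of an
  informally published procedure; scores are comparable within runs of
  this package, not necessarily to other implementations beyond sign and
  threshold semantics.
* The discordant-twin screen at realistic cohort sizes (≈5 discordant
  observations) has a minimum attainable two-sided p of \(2/2^5\), so
  single-variable significance at FDR 5% is effectively out of reach —
  matching the null result such analyses report.
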