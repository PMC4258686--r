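# enterotyper

Enterotype clustering and host-association analysis for twin gut-microbiome
cohorts.

## The problem

Human gut communities are often summarized as *enterotypes* — clusters of
community profiles dominated by different genera, classically
*Bacteroides* (enterotype 1) versus *Prevotella* (enterotype 2). For a
cohort of monozygotic (MZ) twins sampled at up to two time points, three
questions follow:

1. **Do the profiles cluster, and into how many enterotypes?**
2. **Are enterotypes heritable and stable** — do co-twins share them, and
   do individuals keep them over ~2 years?
3. **What host properties track them** — clinical biomarkers, food-group
   intakes, energy-adjusted nutrient intakes?

`enterotyper` implements this analysis as a tested R package: every
computation lives in package functions; numbered driver scripts under
`analysis/` narrate the workflow; and a synthetic twin-cohort generator
with known ground truth stands in for cohort data so the whole pipeline is
verifiable offline.

## Methods at the core

* **Clustering.** Partitioning around medoids (PAM) on Jensen–Shannon
  distance `d(p,q) = sqrt(JSD(p,q))` (base-2 logs, so `d ∈ [0,1]`), with
  Bray–Curtis and Euclidean as sensitivity metrics. The number of clusters
  maximizes the Calinski–Harabasz pseudo F-statistic
  `CH = (B/(k−1))/(W/(n−k))` in a medoid-based form; the silhouette index
  `s(i) = (b−a)/max(a,b)` qualifies support (Kaufman–Rousseeuw categories)
  but never overrides CH. The medoid solver is exact (full enumeration)
  whenever `choose(n,k) ≤ 20000` and classical BUILD+SWAP otherwise; both
  are deterministic.
* **Twin statistics.** Concordance = % of pair-at-a-time-point
  observations with both co-twins in the same enterotype; persistency =
  % of twice-sampled subjects keeping their enterotype. Community
  distances stratified by relationship (self over time, co-twins,
  unrelated) are compared with two-sample permutation tests
  (add-one p-values, one-sided "related is shorter" by default).
* **Differential abundance.** A re-implemented LDA-effect-size (LEfSe)
  procedure: Wilcoxon rank-sum screen at α = 0.01, then a bootstrapped,
  regularized linear discriminant; per-feature effect
  `(|Δμ| + |w|·separation)/2` on 1e6-scaled profiles, reported as a signed
  log10 score (negative = enterotype 1, positive = enterotype 2),
  thresholded at |score| ≥ 2.
* **Host associations.** Wilcoxon rank-sum per variable
  (exact small-sample path), Benjamini–Hochberg within family (traits /
  foods / nutrients); nutrients energy-adjusted as standardized residuals
  of nutrient ~ energy; UPGMA clustering of nutrient-residual profiles
  with Fisher's exact test against enterotypes; signed-rank screen within
  enterotype-discordant pairs at FDR 5%.

See `vignettes/enterotyping-methods.Rmd` for the full model description,
parameter defaults and design rationale.

## Worked example

The five scripts under `analysis/` run the whole study on a synthetic
study-shaped cohort (10 MZ pairs, 8 longitudinal, 36 samples):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_enterotype.R
Rscript analysis/03_differential_abundance.R
Rscript analysis/04_twin_stability.R
Rscript analysis/05_host_associations.R
```

Stage 2 prints (seed 20140):

```
js: selected k = 2 (CH = 64.2, SI = 0.453, support: weak)
bc: selected k = 2 (CH = 114.7, SI = 0.583, support: reasonable)
eu: selected k = 2 (CH = 183.9, SI = 0.722, support: reasonable)
js vs bc assignment agreement: 1.000 (identical partitions)
js vs eu assignment agreement: 1.000 (identical partitions)
enterotype split: E1 = 21/36 (58.3%), E2 = 15/36 (41.7%)
agreement with latent truth after label alignment: 1.000
```

All three distance metrics select two enterotypes; assignments agree
exactly across metrics and recover the generator's latent classes
perfectly, with the characteristic weak silhouette support under JS.
Stage 3 recovers the planted marker genera with the documented sign
convention:

```
genus LEfSe: 6 enriched features
  Bacteroides        enterotype 1  LDA = -5.70
  Prevotella         enterotype 2  LDA = +5.55
  Catenibacterium    enterotype 1  LDA = -5.32
  ...
```

Stage 4 quantifies stability — on this draw 11/18 paired observations are
concordant (61.1%) and 16/16 subjects are stable (a single 10-pair cohort
has wide binomial spread around the design rates 72.2% / 81.3%; the
acceptance script shows convergence at 500 pairs) — and finds that the
same individual's communities are closer over time than unrelated
individuals' (permutation P = 0.0001). Stage 5 flags uric acid as the
only enterotype-associated trait (adj. P = 0.0012, higher in
enterotype 2) and exactly the nine planted energy-adjusted nutrients
(fiber, potassium, iron, vitamins A/C/E, folate, carotene, retinol), and
shows that clustering samples on those nine residuals — but not on all
23 — aligns with the enterotypes (Fisher's exact test).

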