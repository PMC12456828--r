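---
title: "Designing MRD capture panels with mrdpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing MRD capture panels with mrdpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdpanel)
```

## The problem

Tumor-informed MRD (minimal residual disease) assays track a handful of a
patient's somatic mutations in plasma cell-free DNA after treatment. The
assay is only as good as the capture panel: a fixed hotspot panel is cheap
but misses patients whose tumors mutate elsewhere, while exome-scale
personalization is sensitive but expensive. `mrdpanel` implements a
middle course — start from recurrently mutated hotspot exons and expand the
panel with compact exonic regions that statistically resemble the hotspots,
so that as many patients as possible carry at least `N` (default 4)
trackable mutations inside a small captured footprint.

## The selection model, step by step

### Hotspot seeding

Every exon is scored with a Recurrence Index,

$$\mathrm{RI} = \frac{1000 \, n_{\text{cov}}}{L \, n},$$

where $n_{\text{cov}}$ is the number of patients with at least one filtered
variant overlapping the exon, $L$ the exon length in bp and $n$ the total
sample count (including variant-free patients). A patient covers an exon if
any shared base exists, so splice variants on the first or last exon base
count. Exons are ranked by RI descending (ties: more covered patients, then
coordinate) and the top set — by count (`top_k`) or threshold (`ri_min`) —
becomes the hotspot baseline. Curated seed-gene lists (guideline and trial
genes) are a user input that restricts the eligible exons; curation itself
is expert knowledge, not computation.

Before any scoring, the cohort is filtered: records classified RNA,
3'Flank, 5'Flank or IGR are removed, as are intronic records more than 50
bp (configurable) from an exon boundary. Clonal labels come from
clonal-deconvolution output (cluster id + cellular prevalence per variant):
each patient's cluster with maximum prevalence is clonal, everything else
subclonal. Prevalence ties are broken toward the lexicographically smallest
cluster id purely for determinism.

### Candidate regions and features

Within each exon, variants are aggregated left to right into clusters
anchored at the first variant: a variant joins the open cluster only if its
reference span ends within 40 bp (the probe-sized window) of the anchor, so
no cluster exceeds 40 bp. We anchor at the first variant rather than chain
gap-wise because gap-chaining can grow unbounded spans, which defeats
probe-sized regions. Each cluster of length $l_e$ gets four features:

* **RIe** — the windowed recurrence index, $1000\,n_{wp}/(40\,n)$. The
  denominator is fixed at 40 even when the cluster is shorter, so the
  feature is comparable across clusters.
* **RII** — the recurrence improvement index. For each patient with
  $N_{\text{cover}}$ variants already covered by the base panel and
  $N_{\text{only}}$ new variants in this cluster, the gain toward the
  per-patient target $N$ is 0 if $N_{\text{cover}} \ge N$, capped at
  $N - N_{\text{cover}}$ if the cluster overshoots, else $N_{\text{only}}$.
  RII is the patient sum divided by $l_e$ — a per-bp efficiency. The
  cluster's own span $l_e$ (not 40) is the denominator here because it is
  the length of probe actually added.
* **Clonal RII** and **Functional RII** — the same gain restricted to
  clonal and to non-benign variants.

Coverage is computed against the hotspot baseline in a single pass by
default. An `iterative = TRUE` mode re-derives the coverage state after
each accepted expansion, so later candidates are scored against the growing
panel; it is slower and changes results only when candidates compete for
the same patients.

### Informativity rates

Raw features live on incomparable scales, so each is mapped to a
probability by reference to the hotspot regions, which are treated as
informative instances by definition. The mapping — the one step the
selection model leaves genuinely open — is a Laplace-smoothed empirical
CDF: a candidate value that exceeds $r$ of the $n_h$ hotspot values gets
$p = (r+1)/(n_h+2)$. Smoothing keeps $p$ strictly inside $(0,1)$ so the
downstream count model never degenerates, and the rule is isolated in
`estimate_pij()` so it can be swapped. The candidate plus its $n_{is}$
surrounding hotspot instances (same exon by default, or a base-pair flank)
form a set of independent Bernoulli indicators whose sum follows a
Poisson-Binomial distribution; the feature informativity rate is the upper
tail $P(N_i \ge l)$ with $l = n_{is} + 1$ by default. With certain
surroundings this reduces to the candidate's own $p$, which is exactly the
intended default behavior; the general machinery matters when an
`l_override` or partially informative neighborhoods are configured. The
independence assumption is adopted for tractability — features such as RIe
and Clonal RII are correlated in truth.

### Gaussian screening

The hotspot regions' informativity vectors (d = 4) are modeled as a
multivariate Gaussian: mean = column means, covariance = unbiased sample
covariance plus $\epsilon I$ ($\epsilon = 10^{-6}$), which guarantees a
Cholesky factorization even with collinear features or fewer hotspot
clusters than dimensions. Each candidate's squared Mahalanobis distance
$D^2$ is chi-squared with d degrees of freedom under the model, so
candidates with $D^2 \le \chi^2_{1-\alpha, d}$ (α = 0.05 by default) are
accepted and the rest rejected as outliers. Note the direction: as α
shrinks the threshold grows and the screen loosens; a near-unit α collapses
the acceptance region to the mean. An exponential-decay score
$\exp(-D / T)$ with $T = \chi^2_{1-\alpha,d}$ ranks the accepted
candidates — and drives the optional base-pair budget — but never decides
acceptance. The mixed scale (unsquared distance over a squared-scale
normalizer) is kept as the method defines it; a `sqrt(T)` variant would
merely rescale a ranking that only the order of matters. All distances are
computed via triangular solves against the stored Cholesky factor; no
covariance matrix is ever inverted explicitly.

### The limit-of-detection model

Independently of region selection, a binomial sampling model links assay
inputs to sensitivity. A cfDNA mass of $M$ ng contains
$G = \mathrm{round}(1000 M / 3.3)$ haploid genome equivalents (3.3
pg/haploid genome). At tumor fraction $f$, one tracked site yields at least
one mutant molecule with probability $1-(1-f)^G$; with $m$ tracked sites
and positivity at $\ge k$ detected, the positivity probability is a
binomial tail, and the LOD is the smallest grid VAF reaching the required
confidence. The defaults — $m = 4$, $k = 2$, 95% confidence, a 0.005%-step
grid — give LODs of 0.02% at 30 ng and 0.01% at 60 ng, the operating points
usually quoted for tumor-informed assays. The model is mass-limited only:
sequencing depth, error suppression and UMI consensus are out of scope.

```{r lod}
lod_search(30)$lod_pct
lod_search(60)$lod_pct
```

## The synthetic cohort generator

Real multi-patient WES cohorts cannot ship with a package, so
`simulate_exome()` / `simulate_cohort()` generate the structure the method
consumes: a compact exome (25 genes x 4 exons x 150 bp by default, two
chromosomes), a designated 15% of exons as true hotspots, per-(patient,
exon) variant counts Poisson with hotspot exons at `hotspot_rate = 1.0`
versus `background_rate = 0.1` — a 10x enrichment, the regime in which
recurrence-driven selection is meaningful — plus three clonal clusters per
patient with prevalences uniform on (0.1, 0.9), 30% benign labels, and
about two non-trackable records per patient to exercise the filter. A
Poisson count model is the simplest one consistent with "recurrence"
semantics. One seed governs every draw; the same seed reproduces the
cohort byte for byte.

What the generator does **not** emulate: trinucleotide mutational
signatures, copy number, structural variants, indel alignment ambiguity,
inter-gene mutation-rate covariance, or cohort-level batch structure.
Passing tests therefore demonstrate the algorithm's internal correctness
and its directional behavior under recurrence enrichment — not clinical
performance on real tumors.

```{r pipeline}
cfg <- simulation_config(seed = 7)
exome <- simulate_exome(cfg)
cohort <- simulate_cohort(cfg, exome)
design <- design_panel(cohort, exome$exons)
design

variant_density(design$panel, design$cohort)
variant_density(exome$exons, design$cohort)     # whole-exome comparison
patient_coverage(design$panel, design$cohort, k = 4)
```

## Numerical and design choices

* Internal coordinates are 1-based inclusive (the MAF convention); BED
  files convert at the I/O boundary, and a sorted merged BED3 round-trips
  byte-identically.
* `n_total` is user-suppliable because cohorts include variant-free
  patients; it defaults to the distinct-patient count.
* Hotspot selection defaults to the top 10% of exons (at least 2) when
  neither `top_k` nor `ri_min` is given; at least two hotspot clusters are
  required to fit the Gaussian, otherwise the design aborts with an
  explicit error.
* Degenerate inputs: identical training rows give $\Sigma = \epsilon I$
  exactly; clusters with a single variant have $l_e = 1$; an empty
  candidate set yields the merged hotspot panel unchanged.
* Ties are broken deterministically everywhere (clonal clusters by id,
  exon ranking by coverage then coordinate, screening by prior then
  coordinate), so a design is a pure function of its inputs.
* Validation problem sizes: the distributional checks use 500 training
  vectors with 10,000 sampled candidates for screen calibration, 200
  random probability vectors (n <= 15) against exhaustive enumeration for
  the Poisson-Binomial recursion, and 100 seeded end-to-end runs at the
  generator defaults for the directional panel-quality checks.

## Limitations

The screen asks whether a candidate *resembles* the hotspot distribution,
so its quality is bounded by the seed set: a biased seed panel propagates
its bias. All four features enter unweighted; the upstream RI-driven seed
selection implicitly favors recurrence-like candidates. The LOD model
ignores sequencing error, and the evaluation metrics count post-filter
patient-variant records — they quantify panel efficiency, not calling
accuracy.
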