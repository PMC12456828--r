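# mrdpanel

Targeted-capture panel design and evaluation for tumor-informed ctDNA
minimal residual disease (MRD) assays.

MRD assays track a set of a patient's somatic mutations in plasma cfDNA.
Their sensitivity depends on how many of each patient's mutations the
capture panel covers: fixed hotspot panels are cheap but leave many
patients with too few trackable sites, while exome-scale personalization is
sensitive but costly. `mrdpanel` designs compact panels that seed from
recurrently mutated hotspot exons and expand with small exonic regions that
statistically resemble those hotspots, aiming to give as many patients as
possible at least N (default 4) trackable mutations per captured kilobase.

## The method

For a cohort of `n` samples, every exon is scored by its Recurrence Index

    RI = 1000 * n_covered / (L * n)

(variant-carrying patients per kb per sample); the top exons seed the
panel. Within exons, variants are aggregated into clusters of at most 40 bp
(anchored at each cluster's first variant) and each cluster receives four
features: the windowed recurrence index RIe = 1000 * n_wp / (40 * n), and
three recurrence-improvement indices (all / clonal / functional variants)
measuring the per-bp gain in patients' tracked-mutation counts toward the
target N, given what the seed panel already covers. Features are converted
to informativity rates through a Poisson-Binomial model over Bernoulli
"informative instance" indicators calibrated on the hotspot regions, and
candidates are screened against a regularized multivariate Gaussian
(Σ + εI, ε = 1e-6) fitted to the hotspot vectors: a candidate is accepted
when its squared Mahalanobis distance satisfies D² ≤ χ²(1−α, d) (α = 0.05,
d = 4), with an exponential-decay score exp(−D/χ²) ranking acceptances for
optional base-pair budgeting.

A companion binomial sampling model links cfDNA input mass, tracked-variant
count and limit of detection: with G = round(mass·1000/3.3) genome
equivalents, per-site detection 1−(1−f)^G, and positivity at ≥2 of 4 sites
with 95% confidence, the LOD is 0.02% VAF at 30 ng and 0.01% at 60 ng.

## Worked example

```r
library(mrdpanel)

cfg    <- simulation_config(seed = 7)   # 100 patients, 10x hotspot enrichment
exome  <- simulate_exome(cfg)
cohort <- simulate_cohort(cfg, exome)

design <- design_panel(cohort, exome$exons)
design
#> <mrd_design>
#>   hotspot exons: 10
#>   candidates screened: 280 ( accepted: 280 )
#> <mrd_panel> 283 regions, 8464 bp (10 hotspot / 273 expanded)

variant_density(design$panel, design$cohort)   # variants per kb of panel
#> [1] 280.1276
variant_density(exome$exons, design$cohort)    # whole-exome comparison
#> [1] 158.0667
patient_coverage(design$panel, design$cohort, k = 4)
#> [1] 1
patient_coverage(design$hotspots, design$cohort, k = 4)  # seed-only baseline
#> [1] 0.99

lod_search(60)$lod_pct   # % VAF detectable at 60 ng, 4 tracked variants
#> [1] 0.01
```

The designed 8.5-kb panel concentrates 280 variants/kb versus 158 for the
whole synthetic exome, and lifts every patient to ≥4 trackable mutations
(the hotspot-only baseline leaves 1% short). On this small, strongly
enriched cohort all 280 candidate clusters resemble the hotspot
distribution and are accepted; on sparser cohorts the χ² screen prunes
outlying candidates.

A command-line wrapper is installed as `exec/mrdpanel` with subcommands
`simulate`, `design`, `evaluate` and `lod`, e.g.

```sh
mrdpanel design --variants cohort.maf.tsv --exons exome.bed --out panel/
mrdpanel lod --mass-ng 60 --m 4 --k 2
```

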