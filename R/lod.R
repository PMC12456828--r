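#' Binomial cfDNA limit-of-detection model
#'
#' A plasma draw of `mass_ng` nanograms of cell-free DNA contains about
#' `G = mass_ng * 1000 / 3.3` haploid genome equivalents (3.3 pg per
#' haploid genome). At tumor fraction (VAF) `f`, each tracked site
#' independently yields at least one mutant molecule with probability
#' `1 - (1 - f)^G`; calling MRD positive when at least `k` of `m` tracked
#' sites are detected gives a binomial positivity probability, and the
#' limit of detection is the smallest VAF on a grid reaching a required
#' confidence. Mass-limited sampling only: sequencing depth and error are
#' assumed non-limiting.
#'
#' @name lod_model
NULL

#' Haploid genome equivalents in a cfDNA mass
#'
#' @param mass_ng cfDNA input mass in nanograms, > 0.
#' @param pg_per_genome picograms per haploid genome (default 3.3).
#' @return integer copy number, `round(mass_ng * 1000 / pg_per_genome)`.
#' @export
genome_equivalents <- function(mass_ng, pg_per_genome = 3.3) {
  if (any(mass_ng <= 0)) stop("mass_ng must be > 0")
  as.integer(round(mass_ng * 1000 / pg_per_genome))
}

#' Per-site detection probability
#'
#' Probability of sampling at least one mutant molecule at one tracked site
#' when `G` genome equivalents are drawn at variant allele fraction `vaf`.
#'
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param G genome equivalents, >= 1.
#' @return `1 - (1 - vaf)^G`.
#' @export
per_site_detection_prob <- function(vaf, G) {
  if (any(vaf < 0) || any(vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(G < 1)) stop("G must be >= 1")
  1 - (1 - vaf)^G
}

#' MRD positivity probability
#'
#' P(X >= k) for X ~ Binomial(m, p_site): the chance that at least `k` of
#' `m` independently tracked sites are detected.
#'
#' @param p_site per-site detection probability.
#' @param m number of tracked variants, >= 1.
#' @param k minimum detected sites for positivity, `1 <= k <= m`.
#' @return probability.
#' @export
mrd_positive_prob <- function(p_site, m, k) {
  if (any(k > m)) stop("k must be <= m")
  if (any(k < 1) || any(m < 1)) stop("m and k must be >= 1")
  stats::pbinom(k - 1, size = m, prob = p_site, lower.tail = FALSE)
}

#' Limit of detection over a VAF grid
#'
#' Smallest VAF on the grid whose MRD positivity probability reaches
#' `confidence`. Defaults reflect the standard assay configuration: four
#' tracked variants, positivity at >= 2 detected sites, 95% confidence, a
#' 0.005% - 0.1% grid in 0.005% steps.
#'
#' @param mass_ng cfDNA input mass in ng.
#' @param m_tracked number of tracked variants.
#' @param k_min_sites minimum detected sites for positivity.
#' @param confidence required positivity probability in (0, 1).
#' @param grid_pct ascending VAF grid, in percent.
#' @param pg_per_genome picograms per haploid genome.
#' @return list with `lod_pct` (smallest qualifying VAF in percent, `NA` if
#'   none), `above_grid` (TRUE when no grid point qualifies), `G`, and
#'   `curve` (data.frame of `vaf_pct`, `p_site`, `positive_prob`).
#' @export
lod_search <- function(mass_ng, m_tracked = 4L, k_min_sites = 2L,
                       confidence = 0.95,
                       grid_pct = seq(0.005, 0.1, by = 0.005),
                       pg_per_genome = 3.3) {
  if (confidence < 0 || confidence >= 1) {
    stop("confidence must lie in [0, 1)")
  }
  if (is.unsorted(grid_pct, strictly = TRUE)) {
    stop("grid_pct must be strictly ascending")
  }
  G <- genome_equivalents(mass_ng, pg_per_genome)
  p_site <- per_site_detection_prob(grid_pct / 100, G)
  positive <- mrd_positive_prob(p_site, m_tracked, k_min_sites)
  qualifying <- which(positive >= confidence)
  list(
    lod_pct = if (length(qualifying) > 0L) grid_pct[qualifying[1L]] else
      NA_real_,
    above_grid = length(qualifying) == 0L,
    G = G,
    curve = data.frame(vaf_pct = grid_pct, p_site = p_site,
                       positive_prob = positive)
  )
}
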