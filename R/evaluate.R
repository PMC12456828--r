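#' Panel evaluation metrics
#'
#' Variant density (variants per kb of panel), per-patient trackable-variant
#' counts, patient coverage at a tracked-count threshold, and side-by-side
#' panel comparison.
#'
#' @name panel_evaluation
NULL

# Internal: accept an mrd_panel or a plain interval data.frame.
panel_regions <- function(panel) {
  if (inherits(panel, "mrd_panel")) panel$regions else panel
}

#' Variant density of a panel
#'
#' `1000 * n_variants_in_panel / panel_length_bp`: the average number of
#' (post-filter, deduplicated) patient-variant records per kilobase of
#' captured territory.
#'
#' @param panel an `mrd_panel` or interval data.frame.
#' @param cohort an `mrd_cohort`.
#' @return non-negative real.
#' @export
variant_density <- function(panel, cohort) {
  regions <- panel_regions(panel)
  if (nrow(regions) == 0L) stop("variant_density: empty panel")
  total_bp <- sum(interval_length(regions))
  v <- cohort$variants
  n_in <- if (nrow(v) == 0L) 0L else
    sum(overlaps_any(variants_granges(v), as_granges(regions)))
  1000 * n_in / total_bp
}

#' Per-patient trackable-variant counts
#'
#' Number of distinct variants per patient overlapping any panel region
#' (a variant spanning two merged regions counts once).
#'
#' @param panel an `mrd_panel` or interval data.frame.
#' @param cohort labeled `mrd_cohort`.
#' @param category `"all"` or `"clonal"`.
#' @return named integer vector over all `cohort$patients` (zeros included).
#' @export
trackable_counts <- function(panel, cohort, category = c("all", "clonal")) {
  category <- match.arg(category)
  regions <- panel_regions(panel)
  v <- cohort$variants
  counts <- stats::setNames(integer(length(cohort$patients)),
                            cohort$patients)
  if (nrow(v) == 0L || nrow(regions) == 0L) return(counts)
  hit <- overlaps_any(variants_granges(v), as_granges(regions))
  if (category == "clonal") hit <- hit & !is.na(v$is_clonal) & v$is_clonal
  tab <- table(v$patient_id[hit])
  m <- match(names(counts), names(tab))
  counts[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
  counts
}

#' Patient coverage at a trackable-count threshold
#'
#' Fraction of all `n_total` samples with at least `k` trackable variants
#' in the panel. Variant-free patients (n_total minus observed patients)
#' count in the denominator and can never reach `k >= 1`.
#'
#' @param panel an `mrd_panel` or interval data.frame.
#' @param cohort labeled cohort.
#' @param k minimum trackable variants (default 4).
#' @param category `"all"` or `"clonal"`.
#' @return fraction in `[0, 1]`.
#' @export
patient_coverage <- function(panel, cohort, k = 4L,
                             category = c("all", "clonal")) {
  category <- match.arg(category)
  if (k == 0L) return(1)
  counts <- trackable_counts(panel, cohort, category)
  sum(counts >= k) / cohort$n_total
}

#' Compare two panels on the same cohort
#'
#' @param panel_a,panel_b panels to compare (A is typically the expanded
#'   design, B the hotspot-only baseline).
#' @param cohort labeled cohort.
#' @param k coverage threshold.
#' @return list: per-panel totals and per-patient counts (all and clonal),
#'   variant densities, patient coverage at `k`, number and fraction of
#'   patients where A exceeds B, and the median per-patient difference.
#' @export
compare_panels <- function(panel_a, panel_b, cohort, k = 4L) {
  counts_a <- trackable_counts(panel_a, cohort, "all")
  counts_b <- trackable_counts(panel_b, cohort, "all")
  clonal_a <- trackable_counts(panel_a, cohort, "clonal")
  clonal_b <- trackable_counts(panel_b, cohort, "clonal")
  diff <- counts_a - counts_b
  list(
    per_patient = data.frame(
      patient_id = names(counts_a),
      n_a = as.integer(counts_a), n_b = as.integer(counts_b),
      clonal_a = as.integer(clonal_a), clonal_b = as.integer(clonal_b),
      stringsAsFactors = FALSE
    ),
    total_variants = c(a = sum(counts_a), b = sum(counts_b)),
    total_clonal = c(a = sum(clonal_a), b = sum(clonal_b)),
    density = c(a = variant_density(panel_a, cohort),
                b = variant_density(panel_b, cohort)),
    coverage_at_k = c(a = patient_coverage(panel_a, cohort, k),
                      b = patient_coverage(panel_b, cohort, k)),
    n_patients_a_gt_b = sum(diff > 0),
    frac_patients_a_gt_b = if (length(diff) > 0L) mean(diff > 0) else NA_real_,
    median_diff = if (length(diff) > 0L) stats::median(diff) else NA_real_
  )
}
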