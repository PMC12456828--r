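#' End-to-end panel design
#'
#' Composes the full workflow: cohort filtering, clonal labeling, hotspot
#' seeding by exon Recurrence Index, 40-bp candidate clustering and feature
#' extraction against the hotspot baseline, Poisson-Binomial informativity,
#' regularized-Gaussian / Mahalanobis screening, and panel assembly.
#'
#' @param cohort an `mrd_cohort` (raw; filtering is applied internally).
#' @param exons exon interval data.frame (with optional `gene` column).
#' @param seed_genes optional character vector restricting hotspot seeding
#'   to curated genes (requires a `gene` column in `exons`).
#' @param top_k,ri_min hotspot selection rule; if both `NULL`, the top 10%
#'   of exons by Recurrence Index (at least 2) are seeded.
#' @param window candidate cluster window in bp (default 40).
#' @param alpha significance level of the chi-squared acceptance threshold.
#' @param epsilon covariance regularization.
#' @param N per-patient tracked-mutation target for the improvement
#'   features (default 4).
#' @param budget_bp optional cap on expansion bases added beyond hotspots.
#' @param intron_flank_bp intron flank retained by the cohort filter.
#' @param neighborhood_mode,flank_bp surrounding-hotspot neighborhood for
#'   the informativity model.
#' @param iterative recompute features and re-screen after each accepted
#'   expansion (greedy refinement) instead of a single screening pass.
#' @return an `mrd_design`: list with `panel` (an `mrd_panel`), `hotspots`
#'   (ranked seed exons), `decisions` (screened candidates), `model` (the
#'   fitted `mrd_gaussian`), `cohort` (filtered), and `params`.
#' @export
design_panel <- function(cohort, exons, seed_genes = NULL,
                         top_k = NULL, ri_min = NULL,
                         window = 40L, alpha = 0.05, epsilon = 1e-6,
                         N = 4L, budget_bp = NULL, intron_flank_bp = 50L,
                         neighborhood_mode = c("exon", "flank"),
                         flank_bp = 1000L, iterative = FALSE) {
  neighborhood_mode <- match.arg(neighborhood_mode)
  fcohort <- filter_variants(cohort, intron_flank_bp)
  v <- fcohort$variants
  if (all(!is.na(v$cluster_id)) && all(!is.na(v$cellular_prevalence))) {
    if (any(is.na(v$is_clonal))) fcohort <- label_clonal(fcohort)
  } else if (any(is.na(v$is_clonal))) {
    # no clonal deconvolution available: track every variant as clonal
    fcohort$variants$is_clonal <- TRUE
  }

  # hotspot seeding
  seed_pool <- exons
  if (!is.null(seed_genes)) {
    if (!"gene" %in% names(exons)) {
      stop("seed_genes given but exons carry no 'gene' column")
    }
    seed_pool <- exons[exons$gene %in% seed_genes, , drop = FALSE]
  }
  if (is.null(top_k) && is.null(ri_min)) {
    top_k <- max(2L, ceiling(0.10 * nrow(seed_pool)))
  }
  hotspots <- rank_hotspot_exons(seed_pool, fcohort, top_k = top_k,
                                 ri_min = ri_min)
  if (nrow(hotspots) == 0L) stop("no hotspot exons selected; lower ri_min")
  base_state <- coverage_state(fcohort, hotspots)

  # candidate segmentation and features against the hotspot baseline
  clusters <- candidate_clusters(fcohort, exons, window)
  if (nrow(clusters) == 0L) stop("cohort yields no mutation clusters")
  in_hotspot <- overlaps_any(as_granges(clusters), as_granges(hotspots))
  feats <- featurize_clusters(clusters, fcohort, base_state, N, window)
  feat_cols <- c("rie", "rii", "riic", "riif")
  hot_feats <- as.matrix(feats[in_hotspot, feat_cols, drop = FALSE])
  if (nrow(hot_feats) < 2L) {
    stop("fewer than 2 hotspot mutation clusters; cannot fit the ",
         "known-region Gaussian (enlarge top_k)")
  }
  hot_clusters <- clusters[in_hotspot, , drop = FALSE]
  nis_all <- count_surrounding_hotspots(clusters, hot_clusters,
                                        mode = neighborhood_mode,
                                        flank_bp = flank_bp)

  fir_all <- informativity_matrix(as.matrix(feats[, feat_cols]), hot_feats,
                                  nis = nis_all)
  model <- fit_gaussian(fir_all[in_hotspot, , drop = FALSE],
                        epsilon = epsilon, alpha = alpha)
  cand_idx <- which(!in_hotspot)
  candidates <- feats[cand_idx, , drop = FALSE]

  if (!iterative || length(cand_idx) == 0L) {
    decisions <- screen_candidates(model, candidates,
                                   fir_all[cand_idx, , drop = FALSE])
  } else {
    decisions <- screen_iterative(model, candidates, hotspots, fcohort,
                                  hot_feats, nis_all[cand_idx], N, window)
  }
  panel <- assemble_panel(hotspots, decisions, budget_bp = budget_bp)
  structure(list(
    panel = panel, hotspots = hotspots, decisions = decisions,
    model = model, cohort = fcohort,
    params = list(window = window, alpha = alpha, epsilon = epsilon,
                  N = N, budget_bp = budget_bp,
                  intron_flank_bp = intron_flank_bp,
                  top_k = top_k, ri_min = ri_min,
                  neighborhood_mode = neighborhood_mode,
                  flank_bp = flank_bp, iterative = iterative)
  ), class = "mrd_design")
}

# Greedy refinement: after each accepted expansion the coverage state (and
# therefore the improvement features of the remaining candidates) is
# recomputed, so later acceptances reflect what the growing panel already
# tracks.
screen_iterative <- function(model, candidates, hotspots, fcohort,
                             hot_feats, nis, N, window) {
  feat_cols <- c("rie", "rii", "riic", "riif")
  panel_now <- hotspots[, c("chrom", "start", "end")]
  remaining <- seq_len(nrow(candidates))
  taken <- list()
  while (length(remaining) > 0L) {
    state <- coverage_state(fcohort, panel_now)
    feats <- featurize_clusters(candidates[remaining, , drop = FALSE],
                                fcohort, state, N, window)
    fir <- informativity_matrix(as.matrix(feats[, feat_cols]), hot_feats,
                                nis = nis[remaining])
    d2 <- mahalanobis_sq(fir, model)
    ok <- which(d2 <= model$chi2_threshold)
    if (length(ok) == 0L) break
    prior <- prior_score(d2, model$chi2_threshold)
    best <- ok[which.max(prior[ok])]
    row <- candidates[remaining[best], , drop = FALSE]
    row$d2 <- d2[best]
    row$prior <- prior[best]
    row$accepted <- TRUE
    taken[[length(taken) + 1L]] <- row
    panel_now <- rbind(panel_now, row[, c("chrom", "start", "end")])
    remaining <- remaining[-best]
  }
  # final pass scores the rejected remainder against the last state
  rejected <- NULL
  if (length(remaining) > 0L) {
    state <- coverage_state(fcohort, panel_now)
    feats <- featurize_clusters(candidates[remaining, , drop = FALSE],
                                fcohort, state, N, window)
    fir <- informativity_matrix(as.matrix(feats[, feat_cols]), hot_feats,
                                nis = nis[remaining])
    rejected <- candidates[remaining, , drop = FALSE]
    rejected$d2 <- mahalanobis_sq(fir, model)
    rejected$prior <- prior_score(rejected$d2, model$chi2_threshold)
    rejected$accepted <- FALSE
  }
  out <- rbind(do.call(rbind, taken), rejected)
  out <- out[order(-out$prior, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mrd_design <- function(x, ...) {
  cat("<mrd_design>\n")
  cat("  hotspot exons:", nrow(x$hotspots), "\n")
  cat("  candidates screened:", nrow(x$decisions),
      "( accepted:", sum(x$decisions$accepted), ")\n")
  print(x$panel)
  invisible(x)
}

#' Machine-readable run report
#'
#' @param design an `mrd_design`.
#' @return list (JSON-ready) echoing every parameter plus stage counts.
#' @export
design_report <- function(design) {
  list(
    tool = "mrdpanel",
    version = as.character(utils::packageVersion("mrdpanel")),
    params = design$params,
    alpha = design$model$alpha,
    epsilon = design$model$epsilon,
    d = design$model$d,
    chi2_threshold = design$model$chi2_threshold,
    n_patients = design$cohort$n_total,
    n_variants_filtered = nrow(design$cohort$variants),
    n_hotspot_exons = nrow(design$hotspots),
    n_candidates = nrow(design$decisions),
    n_accepted = sum(design$decisions$accepted),
    n_panel_regions = nrow(design$panel$regions),
    panel_bp = design$panel$total_length_bp
  )
}
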