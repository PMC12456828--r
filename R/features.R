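#' Candidate-region features
#'
#' Exons are segmented into compact mutation clusters of at most `window`
#' (default 40) bp, and each cluster is scored with four features:
#'
#' * `rie`  — recurrence index of the window (patients covered per kb per
#'   sample, denominator fixed at the window size);
#' * `rii`  — recurrence improvement index: the per-bp gain in tracked
#'   mutations toward a per-patient target of `N`, given what the current
#'   base panel already covers;
#' * `riic` — the same gain restricted to clonal variants;
#' * `riif` — the same gain restricted to functional (non-benign) variants.
#'
#' @name candidate_features
NULL

#' Aggregate variants into mutation clusters
#'
#' Greedy left-to-right scan anchored at each cluster's first variant: a
#' variant joins the open cluster iff its (reference-span) end lies within
#' `window` bp of the anchor start, so every cluster spans at most `window`
#' bp. The cluster interval runs from the first member's start to the last
#' member's end.
#'
#' @param variants data.frame of variants within one exon (columns `chrom`,
#'   `pos`, `end`; unsorted input is sorted internally).
#' @param window maximum cluster span in bp.
#' @return interval data.frame of clusters with columns `chrom`, `start`,
#'   `end`, `le` (span in bp) and `n_variants`.
#' @export
cluster_mutations <- function(variants, window = 40L) {
  if (nrow(variants) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), le = integer(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  if (length(unique(variants$chrom)) > 1L) {
    stop("cluster_mutations expects variants from a single exon")
  }
  if (!"end" %in% names(variants)) {
    variants$end <- if ("ref" %in% names(variants)) {
      variants$pos + pmax(nchar(variants$ref), 1L) - 1L
    } else variants$pos
  }
  v <- variants[order(variants$pos, variants$end), , drop = FALSE]
  anchor <- v$pos[1L]
  cluster_id <- integer(nrow(v))
  current <- 1L
  cluster_id[1L] <- current
  for (i in seq_len(nrow(v))[-1L]) {
    if (v$end[i] <= anchor + window - 1L) {
      cluster_id[i] <- current
    } else {
      current <- current + 1L
      anchor <- v$pos[i]
      cluster_id[i] <- current
    }
  }
  starts <- tapply(v$pos, cluster_id, min)
  ends <- tapply(v$end, cluster_id, max)
  data.frame(
    chrom = v$chrom[1L],
    start = as.integer(starts),
    end = as.integer(ends),
    le = pmax(1L, as.integer(ends) - as.integer(starts) + 1L),
    n_variants = as.integer(table(cluster_id)),
    stringsAsFactors = FALSE
  )
}

#' Coverage state of a cohort under a base panel
#'
#' Records, per patient, how many of their variants the current panel
#' already covers — overall, clonal-only and non-benign-only — plus a
#' per-variant covered flag used to count a candidate's *additional*
#' contribution.
#'
#' @param cohort filtered, clonally labeled `mrd_cohort`.
#' @param panel_intervals interval data.frame of the current panel.
#' @return an `mrd_coverage_state`: list with `per_patient` (data.frame of
#'   `patient_id`, `n_cover`, `n_cover_clonal`, `n_cover_nb`) and `covered`
#'   (logical, aligned to `cohort$variants` rows).
#' @export
coverage_state <- function(cohort, panel_intervals) {
  v <- cohort$variants
  covered <- logical(nrow(v))
  if (nrow(v) > 0L && nrow(panel_intervals) > 0L) {
    covered <- overlaps_any(variants_granges(v), as_granges(panel_intervals))
  }
  clonal <- !is.na(v$is_clonal) & v$is_clonal
  functional <- !v$is_benign
  per_patient <- data.frame(patient_id = cohort$patients,
                            stringsAsFactors = FALSE)
  tally <- function(flag) {
    counts <- tapply(flag, v$patient_id, sum)
    out <- integer(nrow(per_patient))
    m <- match(per_patient$patient_id, names(counts))
    out[!is.na(m)] <- as.integer(counts[m[!is.na(m)]])
    out
  }
  per_patient$n_cover <- tally(covered)
  per_patient$n_cover_clonal <- tally(covered & clonal)
  per_patient$n_cover_nb <- tally(covered & functional)
  structure(list(per_patient = per_patient, covered = covered),
            class = "mrd_coverage_state")
}

#' Added coverage toward a per-patient tracking target
#'
#' Piecewise gain in tracked mutations for one patient when a candidate
#' region contributes `n_only` new variants on top of `n_cover` already
#' covered, with the panel aiming to track `N` mutations per patient:
#' 0 if the target is already met; capped at `N - n_cover` if the candidate
#' overshoots it; otherwise the full `n_only`.
#'
#' @param n_cover variants already covered for the patient.
#' @param n_only additional variants the candidate alone would cover.
#' @param N per-patient tracked-mutation target (default 4).
#' @return integer gain(s), vectorized over the inputs.
#' @export
added_coverage <- function(n_cover, n_only, N = 4L) {
  if (any(N < 1L)) stop("N must be >= 1")
  if (any(n_cover < 0L) || any(n_only < 0L)) {
    stop("n_cover and n_only must be >= 0")
  }
  ifelse(n_cover >= N, 0L,
         ifelse(n_only + n_cover >= N, N - n_cover, n_only))
}

# Internal: per-patient counts of a cluster's not-yet-covered variants in a
# category, plus matching per-patient base coverage.
cluster_gain <- function(cluster, cohort, state, N, category) {
  v <- cohort$variants
  in_cluster <- v$chrom == cluster$chrom &
    v$pos <= cluster$end & v$end >= cluster$start
  cat_flag <- switch(category,
    all = rep(TRUE, nrow(v)),
    clonal = !is.na(v$is_clonal) & v$is_clonal,
    functional = !v$is_benign,
    stop("unknown category: ", category)
  )
  new_members <- in_cluster & !state$covered & cat_flag
  pp <- state$per_patient
  n_cover <- switch(category, all = pp$n_cover,
                    clonal = pp$n_cover_clonal,
                    functional = pp$n_cover_nb)
  n_only <- integer(nrow(pp))
  if (any(new_members)) {
    counts <- table(v$patient_id[new_members])
    m <- match(pp$patient_id, names(counts))
    n_only[!is.na(m)] <- as.integer(counts[m[!is.na(m)]])
  }
  sum(added_coverage(n_cover, n_only, N))
}

#' Recurrence Improvement Index of a candidate cluster
#'
#' Sum over patients of [added_coverage()] for the chosen variant
#' category, divided by the cluster length `le` — the per-bp rate at which
#' the candidate moves patients toward the `N`-mutation tracking target.
#'
#' @param cluster one row of a [cluster_mutations()] table (or any list
#'   with `chrom`, `start`, `end`, `le`).
#' @param cohort filtered, labeled cohort.
#' @param state [coverage_state()] of the current base panel.
#' @param N per-patient tracked-mutation target.
#' @param category `"all"`, `"clonal"` or `"functional"` (non-benign).
#' @return non-negative real.
#' @export
improvement_index <- function(cluster, cohort, state, N = 4L,
                              category = c("all", "clonal", "functional")) {
  category <- match.arg(category)
  le <- if (!is.null(cluster$le)) cluster$le else
    max(1L, cluster$end - cluster$start + 1L)
  cluster_gain(cluster, cohort, state, N, category) / le
}

#' Window recurrence index of a candidate cluster
#'
#' Distinct patients with a variant in the cluster per kilobase per sample;
#' the length denominator is the fixed window size (default 40 bp), not the
#' cluster's own span.
#'
#' @inheritParams improvement_index
#' @param window fixed window denominator in bp.
#' @return non-negative real.
#' @export
compute_rie <- function(cluster, cohort, window = 40L) {
  v <- cohort$variants
  in_cluster <- v$chrom == cluster$chrom &
    v$pos <= cluster$end & v$end >= cluster$start
  n_covered <- length(unique(v$patient_id[in_cluster]))
  1000 * n_covered / (window * cohort$n_total)
}

#' Feature vector of a candidate cluster
#'
#' @inheritParams improvement_index
#' @param window fixed window denominator for `rie`.
#' @return named numeric vector `(rie, rii, riic, riif)`.
#' @export
featurize <- function(cluster, cohort, state, N = 4L, window = 40L) {
  c(rie = compute_rie(cluster, cohort, window),
    rii = improvement_index(cluster, cohort, state, N, "all"),
    riic = improvement_index(cluster, cohort, state, N, "clonal"),
    riif = improvement_index(cluster, cohort, state, N, "functional"))
}

#' Feature matrix for a table of candidate clusters
#'
#' @param clusters interval data.frame from [cluster_mutations()].
#' @inheritParams featurize
#' @return `clusters` with columns `rie`, `rii`, `riic`, `riif` appended.
#' @export
featurize_clusters <- function(clusters, cohort, state, N = 4L,
                               window = 40L) {
  feats <- matrix(0, nrow = nrow(clusters), ncol = 4L,
                  dimnames = list(NULL, c("rie", "rii", "riic", "riif")))
  for (i in seq_len(nrow(clusters))) {
    feats[i, ] <- featurize(clusters[i, , drop = FALSE], cohort, state,
                            N, window)
  }
  cbind(clusters, as.data.frame(feats))
}

#' Segment a cohort's exons into candidate clusters
#'
#' Runs [cluster_mutations()] within each exon and tags clusters with their
#' exon of origin.
#'
#' @param cohort filtered cohort.
#' @param exons exon interval data.frame (a `gene` column, if present, is
#'   propagated).
#' @param window maximum cluster span in bp.
#' @return cluster interval data.frame with `exon_idx` (row index into
#'   `exons`) and optionally `gene`.
#' @export
candidate_clusters <- function(cohort, exons, window = 40L) {
  v <- cohort$variants
  out <- vector("list", nrow(exons))
  if (nrow(v) > 0L && nrow(exons) > 0L) {
    hits <- find_overlaps(variants_granges(v), as_granges(exons))
    by_exon <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    for (ex in names(by_exon)) {
      ei <- as.integer(ex)
      cl <- cluster_mutations(v[by_exon[[ex]], , drop = FALSE], window)
      if (nrow(cl) > 0L) {
        cl$exon_idx <- ei
        if ("gene" %in% names(exons)) cl$gene <- exons$gene[ei]
        out[[ei]] <- cl
      }
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    empty <- cluster_mutations(data.frame(chrom = character(),
                                          pos = integer(), end = integer()))
    empty$exon_idx <- integer(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
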