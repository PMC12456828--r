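#' Hotspot (seed) region selection by exon Recurrence Index
#'
#' The seed step of panel design: every exon is scored by its Recurrence
#' Index, RI = 1000 * n_covered / (L * n_total) — the average number of
#' variant-carrying patients per kilobase per sample — and the top exons
#' become the hotspot baseline panel. A patient "covers" an exon when at
#' least one of their filtered variants shares a base with it; splice
#' variants sitting on the exon's first or last base therefore count.
#'
#' @name hotspot
NULL

# Internal: per-exon count of distinct patients with >= 1 overlapping variant.
count_covered_patients <- function(exons, cohort) {
  if (nrow(exons) == 0L) return(integer(0))
  v <- cohort$variants
  n_cov <- integer(nrow(exons))
  if (nrow(v) == 0L) return(n_cov)
  hits <- find_overlaps(variants_granges(v), as_granges(exons))
  if (length(hits) > 0L) {
    pid <- v$patient_id[S4Vectors::queryHits(hits)]
    exon_idx <- S4Vectors::subjectHits(hits)
    counts <- tapply(pid, exon_idx, function(p) length(unique(p)))
    n_cov[as.integer(names(counts))] <- as.integer(counts)
  }
  n_cov
}

#' Compute the Recurrence Index of exons
#'
#' @param exons interval data.frame of exons (any extra columns kept).
#' @param cohort a filtered `mrd_cohort`.
#' @return `exons` with `n_covered_patients` and `ri` columns added;
#'   `ri = 1000 * n_covered_patients / (length * n_total)`.
#' @export
compute_ri <- function(exons, cohort) {
  if (cohort$n_total < 1L) stop("n_total must be >= 1")
  len <- interval_length(exons)
  if (any(len < 1L)) stop("exon length must be >= 1")
  exons$n_covered_patients <- count_covered_patients(exons, cohort)
  exons$ri <- 1000 * exons$n_covered_patients / (len * cohort$n_total)
  exons
}

#' Rank exons by Recurrence Index and select hotspots
#'
#' Sorted descending by RI; ties broken by more covered patients, then by
#' genomic coordinate. Exactly one of `top_k` / `ri_min` must be given
#' (both are allowed, applied jointly).
#'
#' @param exons exon interval data.frame.
#' @param cohort filtered cohort.
#' @param top_k keep the `top_k` highest-RI exons.
#' @param ri_min keep exons with `ri >= ri_min`.
#' @return ranked exon data.frame with `n_covered_patients` and `ri`.
#' @export
rank_hotspot_exons <- function(exons, cohort, top_k = NULL, ri_min = NULL) {
  if (is.null(top_k) && is.null(ri_min)) {
    stop("one of top_k or ri_min must be set")
  }
  scored <- compute_ri(exons, cohort)
  ord <- order(-scored$ri, -scored$n_covered_patients,
               scored$chrom, scored$start)
  scored <- scored[ord, , drop = FALSE]
  if (!is.null(ri_min)) scored <- scored[scored$ri >= ri_min, , drop = FALSE]
  if (!is.null(top_k)) scored <- utils::head(scored, top_k)
  rownames(scored) <- NULL
  scored
}

#' Standardize one transcript per gene
#'
#' Picks a single transcript per gene from an exon-level annotation table:
#' a user-supplied gene-to-transcript map wins; otherwise the transcript
#' with the greatest total exon length is used. Exons are optionally
#' clipped to a probe-coverage BED (intersection), mirroring the refinement
#' of exon sets to probe-covered territory.
#'
#' @param annotation data.frame with columns `gene`, `transcript`, `chrom`,
#'   `start`, `end` (one row per exon; 1-based inclusive).
#' @param gene_map optional named character vector `gene -> transcript`.
#' @param probe_bed optional interval data.frame of probe-covered regions.
#' @return exon interval data.frame with `gene` and `transcript` columns.
#' @export
standardize_transcripts <- function(annotation, gene_map = NULL,
                                    probe_bed = NULL) {
  keep <- logical(nrow(annotation))
  for (g in unique(annotation$gene)) {
    rows <- which(annotation$gene == g)
    txs <- annotation$transcript[rows]
    chosen <- NULL
    if (!is.null(gene_map) && g %in% names(gene_map)) {
      chosen <- gene_map[[g]]
      if (!chosen %in% txs) {
        warning("gene ", g, ": mapped transcript ", chosen,
                " not in annotation; skipping gene")
        next
      }
    } else {
      lens <- tapply(annotation$end[rows] - annotation$start[rows] + 1L,
                     txs, sum)
      chosen <- names(lens)[which.max(lens)]
    }
    keep[rows[txs == chosen]] <- TRUE
  }
  exons <- annotation[keep, , drop = FALSE]
  rownames(exons) <- NULL
  if (!is.null(probe_bed) && nrow(exons) > 0L) {
    exon_gr <- as_granges(exons)
    probe_gr <- GenomicRanges::reduce(as_granges(probe_bed),
                                      ignore.strand = TRUE)
    hits <- find_overlaps(exon_gr, probe_gr)
    if (length(hits) == 0L) return(exons[0L, , drop = FALSE])
    clipped <- IRanges::pintersect(
      exon_gr[S4Vectors::queryHits(hits)],
      probe_gr[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE
    )
    meta <- exons[S4Vectors::queryHits(hits),
                  setdiff(names(exons), c("chrom", "start", "end")),
                  drop = FALSE]
    exons <- cbind(from_granges(clipped), meta)
    rownames(exons) <- NULL
  }
  exons
}

#' Read a seed-gene list (one symbol per line)
#'
#' Seed genes encode the expert-curated cancer-gene review (guideline,
#' regulatory and trial-derived genes); they restrict which exons are
#' eligible as hotspot seeds.
#'
#' @param path text file, one gene symbol per line; `#` comments allowed.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[!grepl("^#", lines) & nzchar(lines)]
}
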