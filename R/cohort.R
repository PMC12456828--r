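#' Somatic variant cohorts
#'
#' A cohort is the unit of input for panel design: one row per
#' patient-variant observation plus the total number of samples `n_total`
#' (which may exceed the number of patients with observed variants, since
#' variant-free patients still count in recurrence denominators).
#'
#' @name cohort
NULL

# Classifications removed outright by the cohort filter.
.dropped_classes <- c("RNA", "3'Flank", "5'Flank", "IGR")

#' Construct a cohort
#'
#' @param variants data.frame with columns `patient_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `classification` and optionally `distance_to_exon`,
#'   `cluster_id`, `cellular_prevalence`, `is_clonal`, `is_benign`.
#'   Duplicate (patient, chrom, pos, ref, alt) rows are collapsed.
#' @param n_total total number of samples; defaults to the number of
#'   distinct patients observed in `variants`.
#' @return an object of class `mrd_cohort`: list with elements `variants`
#'   (deduplicated, with an `end` column spanning the reference allele),
#'   `patients` and `n_total`.
#' @export
new_cohort <- function(variants, n_total = NULL) {
  required <- c("patient_id", "chrom", "pos", "ref", "alt", "classification")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  variants$patient_id <- as.character(variants$patient_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  key <- paste(variants$patient_id, variants$chrom, variants$pos,
               variants$ref, variants$alt, sep = "\r")
  variants <- variants[!duplicated(key), , drop = FALSE]
  # reference-allele span: end = pos for SNVs, pos + nchar(ref) - 1 for dels
  variants$end <- variants$pos + pmax(nchar(variants$ref), 1L) - 1L
  for (col in c("distance_to_exon", "cluster_id", "cellular_prevalence")) {
    if (!col %in% names(variants)) variants[[col]] <- NA
  }
  if (!"is_clonal" %in% names(variants)) variants$is_clonal <- NA
  if (!"is_benign" %in% names(variants)) variants$is_benign <- FALSE
  cp <- variants$cellular_prevalence
  if (any(!is.na(cp) & (cp < 0 | cp > 1))) {
    stop("cellular_prevalence must lie in [0, 1]")
  }
  rownames(variants) <- NULL
  patients <- sort(unique(variants$patient_id))
  if (is.null(n_total)) n_total <- length(patients)
  n_total <- as.integer(n_total)
  if (n_total < 1L) stop("n_total must be >= 1")
  if (n_total < length(patients)) {
    stop("n_total (", n_total, ") is smaller than the number of distinct ",
         "patients observed (", length(patients), ")")
  }
  structure(list(variants = variants, patients = patients,
                 n_total = n_total),
            class = "mrd_cohort")
}

#' @export
print.mrd_cohort <- function(x, ...) {
  cat("<mrd_cohort> ", nrow(x$variants), " variants, ",
      length(x$patients), " patients with variants, n_total = ",
      x$n_total, "\n", sep = "")
  invisible(x)
}

#' Read a MAF-like variant table
#'
#' Expects a tab-separated file with the standard MAF column names
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`, and
#' optionally `Cluster_ID`, `Cellular_Prevalence`, `Benign_Flag`,
#' `Distance_To_Exon`. Lines starting with `#` are comments; a directive
#' `#n_total=<int>` sets the total sample count unless `n_total` is given
#' explicitly.
#'
#' @param path TSV path.
#' @param n_total explicit total sample count (overrides the directive).
#' @param chrom_style passed to [normalize_chrom()].
#' @return an `mrd_cohort`.
#' @export
read_variant_table <- function(path, n_total = NULL,
                               chrom_style = c("keep", "chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("variant table not found: ", path)
  header_lines <- grep("^#", readLines(path, n = 50L), value = TRUE)
  directive <- regmatches(header_lines,
                          regexpr("n_total=[0-9]+", header_lines))
  if (is.null(n_total) && length(directive) > 0L) {
    n_total <- as.integer(sub("n_total=", "", directive[1L]))
  }
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  col_map <- c(
    patient_id = "Tumor_Sample_Barcode", chrom = "Chromosome",
    pos = "Start_Position", ref = "Reference_Allele",
    alt = "Tumor_Seq_Allele2", classification = "Variant_Classification"
  )
  missing_cols <- setdiff(col_map, names(tab))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tab[[col_map[["pos"]]]]))
  bad <- which(is.na(pos) & !is.na(tab[[col_map[["pos"]]]]))
  if (length(bad) > 0L) {
    stop("unparseable Start_Position at data row ", bad[1L],
         " (value '", tab[[col_map[["pos"]]]][bad[1L]], "')")
  }
  variants <- data.frame(
    patient_id = as.character(tab[[col_map[["patient_id"]]]]),
    chrom = normalize_chrom(tab[[col_map[["chrom"]]]], chrom_style),
    pos = pos,
    ref = as.character(tab[[col_map[["ref"]]]]),
    alt = as.character(tab[[col_map[["alt"]]]]),
    classification = as.character(tab[[col_map[["classification"]]]]),
    stringsAsFactors = FALSE
  )
  if ("Cluster_ID" %in% names(tab)) {
    variants$cluster_id <- as.character(tab$Cluster_ID)
  }
  if ("Cellular_Prevalence" %in% names(tab)) {
    variants$cellular_prevalence <- as.numeric(tab$Cellular_Prevalence)
  }
  if ("Benign_Flag" %in% names(tab)) {
    variants$is_benign <- as.logical(tab$Benign_Flag)
  }
  if ("Distance_To_Exon" %in% names(tab)) {
    variants$distance_to_exon <- as.integer(tab$Distance_To_Exon)
  }
  new_cohort(variants, n_total = n_total)
}

#' Write a cohort as a MAF-like TSV
#'
#' Inverse of [read_variant_table()]; embeds `n_total` as a `#n_total=`
#' header directive.
#'
#' @param cohort an `mrd_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path) {
  v <- cohort$variants
  out <- data.frame(
    Tumor_Sample_Barcode = v$patient_id, Chromosome = v$chrom,
    Start_Position = v$pos, Reference_Allele = v$ref,
    Tumor_Seq_Allele2 = v$alt, Variant_Classification = v$classification,
    Cluster_ID = v$cluster_id, Cellular_Prevalence = v$cellular_prevalence,
    Benign_Flag = v$is_benign, Distance_To_Exon = v$distance_to_exon,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#n_total=", cohort$n_total), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a cohort for MRD-trackable variants
#'
#' Removes records whose classification is RNA, 3'Flank, 5'Flank or IGR,
#' and intronic records farther than `intron_flank_bp` from the nearest
#' exon boundary. All other records are retained unchanged. Idempotent.
#'
#' @param cohort an `mrd_cohort`.
#' @param intron_flank_bp retained intron flank around exons, in bp.
#' @return the filtered `mrd_cohort` (same `n_total`).
#' @export
filter_variants <- function(cohort, intron_flank_bp = 50L) {
  v <- cohort$variants
  drop <- v$classification %in% .dropped_classes
  intronic <- v$classification == "Intron"
  if (any(intronic & is.na(v$distance_to_exon))) {
    stop("intronic record(s) with missing distance_to_exon: cannot apply ",
         "the +/- ", intron_flank_bp, " bp rule")
  }
  drop <- drop | (intronic & v$distance_to_exon > intron_flank_bp)
  kept <- v[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(variants = kept,
                 patients = sort(unique(kept$patient_id)),
                 n_total = cohort$n_total),
            class = "mrd_cohort")
}

#' Label clonal variants from clonal-cluster assignments
#'
#' Given per-variant cluster ids and cellular prevalences (as produced by
#' clonal deconvolution tools such as PyClone-VI), marks as clonal exactly
#' the variants in each patient's cluster of maximum cellular prevalence.
#' Prevalence ties are broken toward the lexicographically smallest
#' cluster id so labeling is deterministic.
#'
#' @param cohort an `mrd_cohort` whose variants all carry `cluster_id` and
#'   `cellular_prevalence` (constant within a patient's cluster).
#' @return the cohort with `is_clonal` filled in.
#' @export
label_clonal <- function(cohort) {
  v <- cohort$variants
  if (nrow(v) == 0L) return(cohort)
  if (any(is.na(v$cluster_id)) || any(is.na(v$cellular_prevalence))) {
    stop("label_clonal requires cluster_id and cellular_prevalence for ",
         "every variant")
  }
  is_clonal <- logical(nrow(v))
  for (pid in unique(v$patient_id)) {
    idx <- which(v$patient_id == pid)
    cl <- v$cluster_id[idx]
    cp <- v$cellular_prevalence[idx]
    prev_by_cluster <- tapply(cp, cl, function(x) {
      if (length(unique(x)) > 1L) {
        stop("cellular_prevalence varies within a cluster for patient ", pid)
      }
      x[1L]
    })
    ids <- sort(names(prev_by_cluster))
    prevs <- prev_by_cluster[ids]
    winner <- ids[which.max(prevs)] # which.max takes the first = smallest id
    is_clonal[idx] <- cl == winner
  }
  cohort$variants$is_clonal <- is_clonal
  cohort
}

# Internal: variants -> GRanges over their reference-allele span.
variants_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, end = variants$end)
  )
}
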