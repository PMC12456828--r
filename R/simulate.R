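#' Seeded synthetic cohort generator
#'
#' Emulates the statistical structure panel design assumes: a compact exome
#' with a designated subset of recurrence-enriched (hotspot) exons,
#' per-patient variant counts Poisson per (patient, exon) with the hotspot
#' exons at an elevated rate, per-patient clonal clusters with drawn
#' cellular prevalences, benign/functional labels, and a configurable dose
#' of non-trackable records (RNA / flank / IGR / deep-intron) to exercise
#' the cohort filter. Everything is deterministic given the config seed.
#'
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' Defaults describe a small but structured study: 100 patients over a
#' 25-gene, 4-exon-per-gene, 150-bp-exon synthetic exome, with 15% of exons
#' designated hotspots mutated at 10 times the background intensity —
#' strong, plausibly sized recurrence enrichment for a cancer-gene panel.
#'
#' @param seed integer RNG seed governing every draw.
#' @param n_patients number of patients (equals the cohort's `n_total`).
#' @param n_genes,exons_per_gene,exon_length_bp exome layout.
#' @param hotspot_fraction fraction of exons designated hotspot.
#' @param hotspot_rate,background_rate Poisson mean variant count per
#'   (patient, exon) for hotspot vs other exons.
#' @param clonal_clusters_per_patient number of clonal clusters drawn per
#'   patient.
#' @param prevalence_range uniform range of cluster cellular prevalences.
#' @param benign_fraction Bernoulli probability a variant is benign.
#' @param noncoding_rate Poisson mean count per patient of non-trackable
#'   records (RNA / 3'Flank / 5'Flank / IGR / intronic).
#' @return an `mrd_sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_patients = 100L, n_genes = 25L,
                              exons_per_gene = 4L, exon_length_bp = 150L,
                              hotspot_fraction = 0.15, hotspot_rate = 1.0,
                              background_rate = 0.1,
                              clonal_clusters_per_patient = 3L,
                              prevalence_range = c(0.1, 0.9),
                              benign_fraction = 0.3,
                              noncoding_rate = 2.0) {
  stopifnot(n_patients >= 1L, n_genes >= 1L, exons_per_gene >= 1L,
            exon_length_bp >= 1L,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            hotspot_rate >= 0, background_rate >= 0,
            benign_fraction >= 0, benign_fraction <= 1,
            noncoding_rate >= 0)
  structure(as.list(environment()), class = "mrd_sim_config")
}

#' Simulate a synthetic exome
#'
#' Non-overlapping exons with gene/transcript labels laid along two
#' synthetic chromosomes, plus the designated hotspot truth set.
#'
#' @param config an `mrd_sim_config`.
#' @return list: `exons` (interval data.frame with `gene`, `transcript`),
#'   `hotspot_truth` (the hotspot subset of `exons`), `is_hotspot`
#'   (logical per exon).
#' @export
simulate_exome <- function(config) {
  if (config$n_genes < 1L) stop("config must request at least one gene")
  set.seed(config$seed)
  intron_gap <- 500L
  gene_gap <- 10000L
  rows <- vector("list", config$n_genes)
  cursor <- c(chr1 = 1L, chr2 = 1L)
  for (g in seq_len(config$n_genes)) {
    chrom <- if (g %% 2L == 1L) "chr1" else "chr2"
    gene <- sprintf("GENE%03d", g)
    tx <- sprintf("TX%03d.1", g)
    starts <- cursor[[chrom]] +
      (seq_len(config$exons_per_gene) - 1L) *
        (config$exon_length_bp + intron_gap)
    rows[[g]] <- data.frame(
      chrom = chrom, start = starts,
      end = starts + config$exon_length_bp - 1L,
      gene = gene, transcript = tx, stringsAsFactors = FALSE
    )
    cursor[[chrom]] <- max(rows[[g]]$end) + gene_gap
  }
  exons <- do.call(rbind, rows)
  rownames(exons) <- NULL
  n_hot <- round(config$hotspot_fraction * nrow(exons))
  is_hotspot <- logical(nrow(exons))
  if (n_hot > 0L) is_hotspot[sample.int(nrow(exons), n_hot)] <- TRUE
  list(exons = exons,
       hotspot_truth = exons[is_hotspot, , drop = FALSE],
       is_hotspot = is_hotspot)
}

#' Simulate a somatic variant cohort over a synthetic exome
#'
#' @param config an `mrd_sim_config`.
#' @param exome output of [simulate_exome()] (generated from `config` if
#'   omitted).
#' @return an `mrd_cohort` with clonal labels applied; the variant table
#'   carries a logical `sim_removable` column marking records the cohort
#'   filter is expected to drop (RNA / flank / IGR / intron beyond 50 bp).
#' @export
simulate_cohort <- function(config, exome = simulate_exome(config)) {
  set.seed(config$seed + 1L)
  exons <- exome$exons
  rate <- ifelse(exome$is_hotspot, config$hotspot_rate,
                 config$background_rate)
  exonic_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Splice_Site", "Silent")
  exonic_weights <- c(0.70, 0.12, 0.06, 0.12)
  noncoding_classes <- c("RNA", "3'Flank", "5'Flank", "IGR", "Intron")
  bases <- c("A", "C", "G", "T")
  alt_of <- function(ref) {
    vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  }
  per_patient <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    # clonal structure: constant prevalence per cluster, drawn once
    n_cl <- config$clonal_clusters_per_patient
    prevs <- stats::runif(n_cl, config$prevalence_range[1L],
                          config$prevalence_range[2L])
    cluster_ids <- sprintf("C%d", seq_len(n_cl))
    # exonic variants: Poisson per (patient, exon), positions uniform
    counts <- stats::rpois(nrow(exons), rate)
    e_idx <- rep.int(seq_len(nrow(exons)), counts)
    n_ex <- length(e_idx)
    offs <- if (n_ex > 0L) {
      floor(stats::runif(n_ex) * (exons$end[e_idx] - exons$start[e_idx] + 1L))
    } else integer(0)
    # non-trackable records exercising the filter
    n_nc <- stats::rpois(1L, config$noncoding_rate)
    nc_cls <- sample(noncoding_classes, n_nc, replace = TRUE)
    nc_e <- sample.int(nrow(exons), n_nc, replace = TRUE)
    nc_dist <- sample.int(150L, n_nc, replace = TRUE)
    n <- n_ex + n_nc
    if (n == 0L) next
    ref <- sample(bases, n, replace = TRUE)
    cl <- sample(cluster_ids, n, replace = TRUE)
    per_patient[[p]] <- data.frame(
      patient_id = pid,
      chrom = c(exons$chrom[e_idx], exons$chrom[nc_e]),
      pos = as.integer(c(exons$start[e_idx] + offs, exons$end[nc_e] + nc_dist)),
      ref = ref, alt = alt_of(ref),
      classification = c(
        sample(exonic_classes, n_ex, replace = TRUE, prob = exonic_weights),
        nc_cls
      ),
      distance_to_exon = c(integer(n_ex), nc_dist),
      cluster_id = cl,
      cellular_prevalence = prevs[match(cl, cluster_ids)],
      is_benign = stats::runif(n) < config$benign_fraction,
      sim_removable = c(logical(n_ex), nc_cls != "Intron" | nc_dist > 50L),
      stringsAsFactors = FALSE
    )
  }
  per_patient <- per_patient[!vapply(per_patient, is.null, TRUE)]
  if (length(per_patient) == 0L) {
    stop("simulation produced no variants; increase the rates")
  }
  variants <- do.call(rbind, per_patient)
  label_clonal(new_cohort(variants, n_total = config$n_patients))
}
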