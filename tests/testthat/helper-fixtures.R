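# Small in-code fixtures shared across test files.

# A variant row with sensible defaults.
variant_row <- function(patient_id, pos, chrom = "chr1", ref = "A",
                        alt = "T", classification = "Missense_Mutation",
                        distance_to_exon = 0L, cluster_id = NA,
                        cellular_prevalence = NA, is_benign = FALSE) {
  data.frame(patient_id = patient_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, classification = classification,
             distance_to_exon = distance_to_exon, cluster_id = cluster_id,
             cellular_prevalence = cellular_prevalence,
             is_benign = is_benign, stringsAsFactors = FALSE)
}

variants_at <- function(patient_id, positions, ...) {
  do.call(rbind, lapply(positions, function(p)
    variant_row(patient_id, p, ...)))
}

# Writes a minimal MAF-like TSV; rows = list of character vectors matching
# the header.
write_maf_fixture <- function(path, rows,
                              header = c("Tumor_Sample_Barcode",
                                         "Chromosome", "Start_Position",
                                         "Reference_Allele",
                                         "Tumor_Seq_Allele2",
                                         "Variant_Classification"),
                              directives = character()) {
  lines <- c(directives, paste(header, collapse = "\t"),
             vapply(rows, paste, "", collapse = "\t"))
  writeLines(lines, path)
  path
}

# Three-patient toy cohort exercising the improvement-index arithmetic:
# cluster chr1:100-129 (le = 30) holds new variants for P1 (x2) and P3 (x2);
# a base panel chr1:995-1100 already covers 2, 5 and 3 variants for
# P1, P2, P3 respectively.
toy_improvement_fixture <- function() {
  vars <- rbind(
    variants_at("P1", c(100L, 110L)),
    variants_at("P3", c(105L, 115L)),
    variants_at("P1", c(1000L, 1010L)),
    variants_at("P2", c(1000L, 1010L, 1020L, 1030L, 1040L)),
    variants_at("P3", c(1000L, 1010L, 1020L))
  )
  cohort <- new_cohort(vars)
  base_panel <- genomic_intervals("chr1", 995L, 1100L)
  list(cohort = cohort,
       state = coverage_state(cohort, base_panel),
       cluster = list(chrom = "chr1", start = 100L, end = 129L, le = 30L))
}
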