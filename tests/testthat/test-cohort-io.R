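test_that("read_variant_table parses, deduplicates and counts patients", {
  path <- tempfile(fileext = ".tsv")
  write_maf_fixture(path, list(
    c("P1", "chr1", "100", "A", "T", "Missense_Mutation"),
    c("P1", "chr2", "200", "C", "G", "Nonsense_Mutation"),
    c("P2", "chr1", "100", "A", "T", "Missense_Mutation")
  ))
  cohort <- read_variant_table(path)
  expect_s3_class(cohort, "mrd_cohort")
  expect_equal(nrow(cohort$variants), 3L)
  expect_equal(cohort$patients, c("P1", "P2"))
  expect_equal(cohort$n_total, 2L)

  # duplicated row collapses to one record
  write_maf_fixture(path, list(
    c("P1", "chr1", "100", "A", "T", "Missense_Mutation"),
    c("P1", "chr1", "100", "A", "T", "Missense_Mutation")
  ))
  expect_equal(nrow(read_variant_table(path)$variants), 1L)
})

test_that("read_variant_table honors the n_total directive and argument", {
  path <- tempfile(fileext = ".tsv")
  write_maf_fixture(path,
                    list(c("P1", "chr1", "100", "A", "T", "Silent")),
                    directives = "#n_total=150")
  expect_equal(read_variant_table(path)$n_total, 150L)
  expect_equal(read_variant_table(path, n_total = 200)$n_total, 200L)
})

test_that("read_variant_table reports format errors precisely", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("Tumor_Sample_Barcode\tChromosome\tStart_Position",
               "P1\tchr1\t100"), path)
  expect_error(read_variant_table(path), "Variant_Classification")

  write_maf_fixture(path, list(
    c("P1", "chr1", "100", "A", "T", "Silent"),
    c("P2", "chr1", "abc", "A", "T", "Silent")
  ))
  expect_error(read_variant_table(path), "row 2")
})

test_that("variant-table round trip preserves the cohort", {
  vars <- rbind(
    variant_row("P1", 100L, cluster_id = "C1", cellular_prevalence = 0.8),
    variant_row("P2", 250L, cluster_id = "C2", cellular_prevalence = 0.4,
                is_benign = TRUE, classification = "Silent")
  )
  cohort <- new_cohort(vars, n_total = 5L)
  path <- tempfile(fileext = ".tsv")
  write_variant_table(cohort, path)
  back <- read_variant_table(path)
  expect_equal(back$n_total, 5L)
  expect_equal(back$variants$pos, cohort$variants$pos)
  expect_equal(back$variants$cellular_prevalence,
               cohort$variants$cellular_prevalence)
})

test_that("filter_variants applies the classification and intron rules", {
  vars <- rbind(
    variant_row("P1", 100L, classification = "RNA"),
    variant_row("P1", 200L, classification = "3'Flank"),
    variant_row("P1", 300L, classification = "5'Flank"),
    variant_row("P1", 400L, classification = "IGR"),
    variant_row("P2", 500L, classification = "Intron",
                distance_to_exon = 60L),
    variant_row("P2", 600L, classification = "Intron",
                distance_to_exon = 50L),
    variant_row("P3", 700L, classification = "Missense_Mutation")
  )
  filtered <- filter_variants(new_cohort(vars))
  expect_setequal(filtered$variants$pos, c(600L, 700L))
  expect_equal(filtered$n_total, 3L) # denominator untouched

  # idempotent
  twice <- filter_variants(filtered)
  expect_identical(twice$variants, filtered$variants)
})

test_that("filter_variants rejects intronic records without a distance", {
  vars <- variant_row("P1", 100L, classification = "Intron",
                      distance_to_exon = NA)
  expect_error(filter_variants(new_cohort(vars)), "distance_to_exon")
})

test_that("label_clonal marks the maximum-prevalence cluster", {
  vars <- rbind(
    variant_row("P1", 100L, cluster_id = "A", cellular_prevalence = 0.8),
    variant_row("P1", 200L, cluster_id = "A", cellular_prevalence = 0.8),
    variant_row("P1", 300L, cluster_id = "B", cellular_prevalence = 0.3)
  )
  labeled <- label_clonal(new_cohort(vars))
  expect_equal(labeled$variants$is_clonal, c(TRUE, TRUE, FALSE))

  # a single cluster is trivially clonal
  single <- label_clonal(new_cohort(
    variant_row("P1", 100L, cluster_id = "X", cellular_prevalence = 0.5)))
  expect_true(all(single$variants$is_clonal))
})

test_that("label_clonal breaks prevalence ties toward the smallest id", {
  vars <- rbind(
    variant_row("P1", 100L, cluster_id = "B", cellular_prevalence = 0.5),
    variant_row("P1", 200L, cluster_id = "A", cellular_prevalence = 0.5)
  )
  labeled <- label_clonal(new_cohort(vars))
  expect_equal(labeled$variants$is_clonal[labeled$variants$cluster_id == "A"],
               TRUE)
  expect_equal(labeled$variants$is_clonal[labeled$variants$cluster_id == "B"],
               FALSE)
})

test_that("label_clonal validates cluster-constant prevalence", {
  vars <- rbind(
    variant_row("P1", 100L, cluster_id = "A", cellular_prevalence = 0.8),
    variant_row("P1", 200L, cluster_id = "A", cellular_prevalence = 0.6)
  )
  expect_error(label_clonal(new_cohort(vars)), "varies within a cluster")
})

test_that("every patient with variants gets at least one clonal variant", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    vars <- do.call(rbind, lapply(seq_len(n), function(i) {
      variant_row("P1", 100L * i,
                  cluster_id = sample(c("A", "B", "C"), 1),
                  cellular_prevalence = NA)
    }))
    prev <- stats::setNames(runif(3), c("A", "B", "C"))
    vars$cellular_prevalence <- prev[vars$cluster_id]
    labeled <- label_clonal(new_cohort(vars))
    expect_gte(sum(labeled$variants$is_clonal), 1L)
  }
})

test_that("BED coordinates convert and round-trip byte-identically", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t139", path)
  bed <- read_bed(path)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 139L)
  expect_equal(interval_length(bed), 40L)

  # sorted merged BED3 round trip
  lines <- c("chr1\t0\t100", "chr1\t200\t350", "chr2\t10\t20")
  writeLines(lines, path)
  out <- tempfile(fileext = ".bed")
  write_bed(read_bed(path), out)
  expect_identical(readLines(out), lines)

  writeLines("chr1\t100\t100", path)
  expect_error(read_bed(path), "start >= end")
})
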