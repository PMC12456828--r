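design_fixture <- function(seed = 7L, ...) {
  cfg <- simulation_config(seed = seed, n_patients = 50L, n_genes = 10L)
  exome <- simulate_exome(cfg)
  cohort <- simulate_cohort(cfg, exome)
  list(cfg = cfg, exome = exome, cohort = cohort,
       design = design_panel(cohort, exome$exons, ...))
}

test_that("the designed panel always contains the hotspot seeds", {
  fx <- design_fixture()
  hot_gr <- mrdpanel:::as_granges(fx$design$hotspots)
  panel_gr <- mrdpanel:::as_granges(fx$design$panel$regions)
  covered <- IRanges::overlapsAny(hot_gr, panel_gr, ignore.strand = TRUE)
  expect_true(all(covered))
  expect_gte(sum(fx$design$decisions$accepted), 0L)
})

test_that("a near-unit significance level collapses the acceptance region", {
  fx_loose <- design_fixture(alpha = 0.05)
  fx_tight <- design_fixture(alpha = 0.999999)
  # chi2(1 - alpha, d) -> 0 as alpha -> 1: only near-mean candidates survive
  expect_lt(fx_tight$design$model$chi2_threshold, 0.01)
  expect_lte(sum(fx_tight$design$decisions$accepted),
             sum(fx_loose$design$decisions$accepted))
})

test_that("design is deterministic for fixed inputs", {
  fx1 <- design_fixture()
  fx2 <- design_fixture()
  expect_identical(fx1$design$panel$regions, fx2$design$panel$regions)
  expect_identical(fx1$design$decisions, fx2$design$decisions)
})

test_that("a base-pair budget caps the expansion greedily by prior", {
  fx_all <- design_fixture()
  added_all <- with(fx_all$design$panel,
                    sum(interval_length(regions)[regions$provenance ==
                                                   "expanded"]))
  budget <- max(40L, floor(added_all / 3))
  fx_bud <- design_fixture(budget_bp = budget)
  added_bud <- with(fx_bud$design$panel,
                    sum(interval_length(regions)[regions$provenance ==
                                                   "expanded"]))
  expect_lte(added_bud, budget)
  expect_lte(added_bud, added_all)
})

test_that("iterative refinement yields a valid, hotspot-containing panel", {
  fx <- design_fixture(iterative = TRUE)
  expect_s3_class(fx$design$panel, "mrd_panel")
  dec <- fx$design$decisions
  expect_true(all(dec$d2[dec$accepted] <=
                    fx$design$model$chi2_threshold + 1e-9))
  hot_gr <- mrdpanel:::as_granges(fx$design$hotspots)
  panel_gr <- mrdpanel:::as_granges(fx$design$panel$regions)
  expect_true(all(IRanges::overlapsAny(hot_gr, panel_gr,
                                       ignore.strand = TRUE)))
})

test_that("design_report echoes parameters and stage counts", {
  fx <- design_fixture()
  rep <- design_report(fx$design)
  expect_equal(rep$alpha, 0.05)
  expect_equal(rep$epsilon, 1e-6)
  expect_equal(rep$d, 4L)
  expect_equal(rep$n_candidates, nrow(fx$design$decisions))
  expect_equal(rep$panel_bp, fx$design$panel$total_length_bp)
})

test_that("the CLI subcommands compose over temporary directories", {
  simdir <- file.path(tempfile(), "sim")
  res <- cmd_simulate(simdir, seed = 3L, n_patients = 40L)
  expect_true(file.exists(file.path(simdir, "cohort.maf.tsv")))
  expect_true(file.exists(file.path(simdir, "exome.bed")))

  # rerunning with the same seed reproduces the cohort byte-for-byte
  simdir2 <- file.path(tempfile(), "sim2")
  cmd_simulate(simdir2, seed = 3L, n_patients = 40L)
  expect_identical(readLines(file.path(simdir, "cohort.maf.tsv")),
                   readLines(file.path(simdir2, "cohort.maf.tsv")))

  designdir <- file.path(tempfile(), "design")
  design <- cmd_design(variants = file.path(simdir, "cohort.maf.tsv"),
                       exons = file.path(simdir, "exome.bed"),
                       out = designdir)
  expect_true(file.exists(file.path(designdir, "panel.bed")))
  report <- jsonlite::read_json(file.path(designdir, "report.json"))
  expect_equal(report$n_panel_regions, nrow(design$panel$regions))

  evalout <- tempfile(fileext = ".json")
  ev <- cmd_evaluate(panel = file.path(designdir, "panel.bed"),
                     variants = file.path(simdir, "cohort.maf.tsv"),
                     out = evalout, k = 4L)
  expect_true(file.exists(evalout))
  expect_gte(ev$variant_density, 0)

  # an off-target panel covers nobody at k >= 1
  offbed <- tempfile(fileext = ".bed")
  write_bed(genomic_intervals("chr9", 1L, 100L), offbed)
  ev0 <- cmd_evaluate(panel = offbed,
                      variants = file.path(simdir, "cohort.maf.tsv"),
                      out = tempfile(fileext = ".json"), k = 4L)
  expect_equal(ev0$patient_coverage, 0)

  # lod subcommand delegates to lod_search
  lodout <- tempfile(fileext = ".tsv")
  lod <- cmd_lod(60, out = lodout)
  expect_equal(lod$lod_pct, lod_search(60)$lod_pct)
  expect_true(any(grepl("^#lod_pct=0.01", readLines(lodout))))
})

test_that("mrd_cli dispatches subcommands", {
  out <- tempfile(fileext = ".tsv")
  expect_no_error(mrd_cli(c("lod", "--mass-ng", "30", "--out", out)))
  expect_true(file.exists(out))
  expect_error(mrd_cli(c("frobnicate")), "unknown subcommand")
})
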