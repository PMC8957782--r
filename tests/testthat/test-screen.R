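toy_cohort_loaded <- function(n_decoys = 10, seed = 1) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  p <- make_toy_cohort(d, n_decoys = n_decoys, seed = seed)
  load_cohort(p[["vcf"]], p[["ped"]])
}

test_that("toy-cohort screen reproduces the published recessive call set", {
  co <- toy_cohort_loaded()
  rep <- screen_panel(co)
  rec <- rep$recessive
  ch <- unique(rec$variant_id[rec$gene == "CACNA1H" &
                                rec$model == "compound_het"])
  hemi <- unique(rec$variant_id[rec$gene == "CACNA1F" &
                                  rec$model == "hemizygous"])
  expect_length(ch, 4)
  expect_length(hemi, 2)
  # nothing else reaches the recessive list: all decoys rejected
  expect_setequal(unique(rec$variant_id), c(ch, hemi))
  # hemizygous calls in the expected male probands, maternal origin
  expect_setequal(rec$proband_id[rec$model == "hemizygous"],
                  c("5.3", "112.3"))
  expect_true(all(rec$origin[rec$model == "hemizygous"] == "maternal"))
  # both twins are reported as carriers, but the family is counted once
  twins <- rec$proband_id[rec$variant_id == "chr16:1220303:C>T"]
  expect_setequal(twins, c("22.3", "22.4"))
  fam22 <- rep$counts$per_family$n[rep$counts$per_family$family_id == "22"]
  expect_equal(fam22, 2)  # two distinct variants, not four carrier rows
  # the unaffected sibling 22.5 (single paternal variant) is never called
  expect_false("22.5" %in% rec$proband_id)
})

test_that("no biallelic calls are emitted for parents or unaffected sibs", {
  co <- toy_cohort_loaded()
  rec <- screen_panel(co)$recessive
  probands <- c("105.3", "22.3", "22.4", "5.3", "112.3")
  expect_true(all(rec$proband_id %in% probands))
})

test_that("raising the CADD threshold above the table maximum empties it", {
  co <- toy_cohort_loaded()
  rep <- screen_panel(co, filter_config(cadd_min = 30))
  expect_equal(nrow(rep$recessive), 0)
  # brute force agrees
  cfg <- filter_config(cadd_min = 30)
  expect_equal(nrow(brute_force_recessive(co, cfg)), 0)
})

test_that("panel restriction empties the report for untouched genes", {
  co <- toy_cohort_loaded()
  rep <- screen_panel(co, filter_config(gene_panel = "CACNA1C"))
  expect_equal(nrow(rep$recessive), 0)
  expect_equal(nrow(rep$dominant), 0)
})

test_that("screening is idempotent and deterministic", {
  co <- toy_cohort_loaded()
  r1 <- screen_panel(co)
  r2 <- screen_panel(co)
  expect_identical(r1$recessive, r2$recessive)
  expect_identical(r1$dominant, r2$dominant)
})

test_that("tightening thresholds never adds calls (monotonicity)", {
  co <- toy_cohort_loaded()
  base <- screen_panel(co)
  key <- function(df) paste(df$variant_id, df$proband_id, df$model)
  # lower MAF ceilings
  tighter_maf <- screen_panel(co, filter_config(maf_rare = 0.0001,
                                                maf_ultra_rare = 0.0001))
  expect_true(all(key(tighter_maf$recessive) %in% key(base$recessive)))
  expect_true(all(key(tighter_maf$dominant) %in% key(base$dominant)))
  # higher CADD threshold
  tighter_cadd <- screen_panel(co, filter_config(cadd_min = 20))
  expect_true(all(key(tighter_cadd$recessive) %in% key(base$recessive)))
  expect_true(all(key(tighter_cadd$dominant) %in% key(base$dominant)))
})

test_that("screen matches brute-force enumeration on random cohorts", {
  for (seed in 1:6) {
    d <- withr::local_tempdir()
    f <- random_cohort_files(d, n_variants = 25, seed = seed)
    co <- load_cohort(f$vcf, f$ped)
    rep <- screen_panel(co)
    got <- unique(rep$recessive[, c("variant_id", "proband_id", "model")])
    want <- brute_force_recessive(co)
    key <- function(df) sort(paste(df$variant_id, df$proband_id, df$model))
    expect_identical(key(got), key(want),
                     label = paste("random cohort seed", seed))
  }
})

test_that("screen report files are written with deterministic ordering", {
  co <- toy_cohort_loaded()
  rep <- screen_panel(co)
  d <- withr::local_tempdir()
  paths <- write_screen_report(rep, d)
  expect_true(all(file.exists(paths)))
  rec <- read.delim(paths[["recessive"]])
  expect_false(is.unsorted(rec$pos[rec$chrom == "chr16"]))
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$n_recessive_calls, nrow(rep$recessive))
})
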