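# Minimal in-memory fixtures: a trio (F1) and, where needed, extra members.
trio_ped <- function() {
  structure(data.frame(
    family_id = "F1",
    sample_id = c("F1.1", "F1.2", "F1.3", "F1.4"),
    father_id = c("0", "0", "F1.1", "F1.1"),
    mother_id = c("0", "0", "F1.2", "F1.2"),
    sex = c("M", "F", "M", "F"),
    affected = c("no", "no", "yes", "no"),
    stringsAsFactors = FALSE), class = c("pedigree", "data.frame"))
}

auto_variant <- function() {
  list(variant_id = "chr16:100:A>T", chrom = "chr16", pos = 100L)
}

classify1 <- function(variant, gts, dp = 50, gq = 99, ped = trio_ped()) {
  samples <- names(gts)
  classify_inheritance(variant, unlist(gts),
                       setNames(rep(dp, length.out = length(samples)), samples),
                       setNames(rep(gq, length.out = length(samples)), samples),
                       ped)
}

test_that("trio transmission models are classified correctly", {
  v <- auto_variant()
  mat <- classify1(v, c(F1.1 = "0/0", F1.2 = "0/1", F1.3 = "0/1"))
  expect_identical(mat$model, "inherited_maternal")
  pat <- classify1(v, c(F1.1 = "0/1", F1.2 = "0/0", F1.3 = "0/1"))
  expect_identical(pat$model, "inherited_paternal")
  dn <- classify1(v, c(F1.1 = "0/0", F1.2 = "0/0", F1.3 = "0/1"))
  expect_identical(dn$model, "de_novo")
  amb <- classify1(v, c(F1.1 = "0/1", F1.2 = "0/1", F1.3 = "0/1"))
  expect_identical(amb$model, "inherited_ambiguous")
  hom <- classify1(v, c(F1.1 = "0/1", F1.2 = "0/1", F1.3 = "1/1"))
  expect_identical(hom$model, "homozygous")
  expect_false(hom$mendel_error)
  none <- classify1(v, c(F1.1 = "0/1", F1.2 = "0/1", F1.3 = "0/0"))
  expect_equal(nrow(none), 0)
})

test_that("missing or low-quality parent genotypes yield ambiguous calls", {
  v <- auto_variant()
  # father genotype fails DP -> treated as missing
  res <- classify_inheritance(
    v, c(F1.1 = "0/1", F1.2 = "0/0", F1.3 = "0/1"),
    c(F1.1 = 5, F1.2 = 50, F1.3 = 50),
    c(F1.1 = 99, F1.2 = 99, F1.3 = 99), trio_ped())
  expect_identical(res$model, "inherited_ambiguous")
  expect_match(res$note, "missing or low quality")
  # child genotype fails quality -> no call at all
  res2 <- classify_inheritance(
    v, c(F1.1 = "0/1", F1.2 = "0/0", F1.3 = "0/1"),
    c(F1.1 = 50, F1.2 = 50, F1.3 = 5),
    c(F1.1 = 99, F1.2 = 99, F1.3 = 99), trio_ped())
  expect_equal(nrow(res2), 0)
})

test_that("mendelian impossibilities are flagged, not dropped", {
  v <- auto_variant()
  bad <- classify1(v, c(F1.1 = "0/0", F1.2 = "0/1", F1.3 = "1/1"))
  expect_identical(bad$model, "homozygous")
  expect_true(bad$mendel_error)
})

test_that("male non-PAR chrX calls are hemizygous with maternal origin", {
  v <- list(variant_id = "chrX:49211360:C>T", chrom = "chrX",
            pos = 49211360L)
  hemi <- classify1(v, c(F1.1 = "0", F1.2 = "0/1", F1.3 = "1"))
  expect_identical(hemi$model, "hemizygous")
  expect_identical(hemi$origin, "maternal")
  # female child at the same locus is handled as autosomal
  ped <- trio_ped()
  ped$affected <- c("no", "no", "no", "yes")
  f_het <- classify_inheritance(
    v, c(F1.1 = "0", F1.2 = "0/1", F1.4 = "0/1"),
    setNames(rep(50, 3), c("F1.1", "F1.2", "F1.4")),
    setNames(rep(99, 3), c("F1.1", "F1.2", "F1.4")), ped)
  expect_identical(f_het$model, "inherited_maternal")
  # inside PAR1 a male diploid het is autosomal-like
  vpar <- list(variant_id = "chrX:200000:C>T", chrom = "chrX", pos = 200000L)
  par_call <- classify1(vpar, c(F1.1 = "0/0", F1.2 = "0/1", F1.3 = "0/1"))
  expect_identical(par_call$model, "inherited_maternal")
})

test_that("compound-het pairing needs distinct parental origins in trans", {
  gt <- rbind(
    "chr16:100:A>T" = c(F1.1 = "0/0", F1.2 = "0/1", F1.3 = "0/1",
                        F1.4 = "0/0"),
    "chr16:200:C>G" = c(F1.1 = "0/1", F1.2 = "0/0", F1.3 = "0/1",
                        F1.4 = "0/1"),
    "chr16:300:G>A" = c(F1.1 = "0/0", F1.2 = "0/1", F1.3 = "0/1",
                        F1.4 = "0/0"))
  calls <- data.frame(
    variant_id = c("chr16:100:A>T", "chr16:200:C>G", "chr16:300:G>A"),
    proband_id = "F1.3", gene = "CACNA1H",
    model = c("inherited_maternal", "inherited_paternal",
              "inherited_maternal"),
    n_alt = 1L, stringsAsFactors = FALSE)
  pairs <- find_compound_het(calls, gt, trio_ped())
  # maternal 100 + paternal 200 and maternal 300 + paternal 200
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$variant_id, c("chr16:100:A>T", "chr16:300:G>A"))
  expect_true(all(pairs$partner_id == "chr16:200:C>G"))

  # two maternal-only variants never pair
  mat_only <- calls[c(1, 3), ]
  expect_equal(nrow(find_compound_het(mat_only, gt, trio_ped())), 0)

  # cis configuration (one parent carries both) is excluded
  gt_cis <- rbind(
    "chr16:100:A>T" = c(F1.1 = "0/1", F1.2 = "0/1", F1.3 = "0/1",
                        F1.4 = "0/0"),
    "chr16:200:C>G" = c(F1.1 = "0/1", F1.2 = "0/0", F1.3 = "0/1",
                        F1.4 = "0/0"))
  calls_cis <- data.frame(
    variant_id = c("chr16:100:A>T", "chr16:200:C>G"),
    proband_id = "F1.3", gene = "CACNA1H",
    model = c("inherited_maternal", "inherited_paternal"),
    n_alt = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(find_compound_het(calls_cis, gt_cis, trio_ped())), 0)
})
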