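test_that("toy cohort VCF/PED loads with expected structure", {
  d <- withr::local_tempdir()
  p <- make_toy_cohort(d, n_decoys = 0, seed = 1)
  co <- load_cohort(p[["vcf"]], p[["ped"]])
  expect_equal(nrow(co$variants), 6)  # six published variants, no decoys
  expect_equal(ncol(co$gt), 14)       # four families fully genotyped
  expect_true(all(co$variants$pos >= 1))
  expect_true(all(grepl("^[ACGT]+$", co$variants$ref)))
  # published coordinates and annotations survive the round trip
  k785 <- co$variants[co$variants$pos == 1204361, ]
  expect_identical(k785$gene, "CACNA1H")
  expect_identical(k785$rsid, "rs28365117")
  expect_equal(k785$cadd, 24.7)
  expect_equal(unname(co$mafs[k785$variant_id, "AF_GNOMAD_V3"]), 0.003)
  expect_identical(unname(co$gt[k785$variant_id, "105.2"]), "0/1")
  expect_identical(unname(co$gt[k785$variant_id, "105.1"]), "0/0")
})

test_that("empty VCF body yields empty variant list with pedigree intact", {
  d <- withr::local_tempdir()
  p <- make_toy_cohort(d, n_decoys = 0, seed = 1)
  lines <- readLines(p[["vcf"]])
  empty_vcf <- file.path(d, "empty.vcf")
  writeLines(lines[startsWith(lines, "#")], empty_vcf)
  co <- load_cohort(empty_vcf, p[["ped"]])
  expect_equal(nrow(co$variants), 0)
  expect_equal(nrow(co$pedigree), 14)
})

test_that("multi-allelic records decompose into one variant per ALT", {
  d <- withr::local_tempdir()
  variants <- data.frame(
    chrom = "chr16", pos = 500L, rsid = ".", ref = "A", alt = "T,G",
    gene = "CACNA1H", consequence = "missense,synonymous",
    cadd = NA, af_v3 = NA, af_v2 = NA, stringsAsFactors = FALSE)
  gt <- matrix(c("1/2", "0/1", "0/2"), 1, 3,
               dimnames = list(NULL, c("F1.3", "F1.1", "F1.2")))
  dp <- matrix(50L, 1, 3, dimnames = dimnames(gt))
  gq <- matrix(99L, 1, 3, dimnames = dimnames(gt))
  vcf <- file.path(d, "multi.vcf")
  # hand-build the VCF with a comma-separated per-ALT INFO field
  write_cohort_vcf(variants, gt, dp, gq, vcf)
  raw <- readLines(vcf)
  body <- raw[!startsWith(raw, "#")]
  expect_length(body, 1)
  ped <- file.path(d, "trio.ped")
  writeLines(c("F1\tF1.1\t0\t0\t1\t1", "F1\tF1.2\t0\t0\t2\t1",
               "F1\tF1.3\tF1.1\tF1.2\t1\t2"), ped)
  co <- load_cohort(vcf, ped)
  expect_equal(nrow(co$variants), 2)
  expect_equal(co$variants$pos, c(500L, 500L))
  expect_identical(co$variants$alt, c("T", "G"))
  expect_identical(co$variants$consequence, c("missense", "synonymous"))
  # genotype recoding per ALT: other ALT alleles become reference
  expect_identical(unname(co$gt[1, c("F1.3", "F1.1", "F1.2")]),
                   c("1/0", "0/1", "0/0"))
  expect_identical(unname(co$gt[2, c("F1.3", "F1.1", "F1.2")]),
                   c("0/1", "0/0", "0/1"))
})

test_that("decomposition does not change inheritance calls", {
  # the same trio encoded as one multi-allelic record vs two biallelic
  # records must produce identical calls for the shared ALT
  d <- withr::local_tempdir()
  ped <- file.path(d, "trio.ped")
  writeLines(c("F1\tF1.1\t0\t0\t1\t1", "F1\tF1.2\t0\t0\t2\t1",
               "F1\tF1.3\tF1.1\tF1.2\t1\t2"), ped)
  smp <- c("F1.1", "F1.2", "F1.3")
  mk <- function(alt, gt_vec) {
    v <- data.frame(chrom = "chr16", pos = 900L, rsid = ".", ref = "C",
                    alt = alt, gene = "CACNA1H",
                    consequence = paste(rep("missense",
                                            length(strsplit(alt, ",")[[1]])),
                                        collapse = ","),
                    cadd = NA, af_v3 = NA, af_v2 = NA,
                    stringsAsFactors = FALSE)
    gt <- matrix(gt_vec, 1, 3, dimnames = list(NULL, smp))
    dp <- matrix(50L, 1, 3, dimnames = dimnames(gt))
    gq <- matrix(99L, 1, 3, dimnames = dimnames(gt))
    f <- tempfile(tmpdir = d, fileext = ".vcf")
    write_cohort_vcf(v, gt, dp, gq, f)
    f
  }
  multi <- load_cohort(mk("T,G", c("0/2", "0/0", "0/1")), ped)
  single <- load_cohort(mk("T", c("0/0", "0/0", "0/1")), ped)
  call_multi <- classify_inheritance(multi$variants[1, ], multi$gt[1, ],
                                     multi$dp[1, ], multi$gq[1, ],
                                     multi$pedigree)
  call_single <- classify_inheritance(single$variants[1, ], single$gt[1, ],
                                      single$dp[1, ], single$gq[1, ],
                                      single$pedigree)
  expect_identical(call_multi$model, call_single$model)
  expect_identical(call_multi$proband_id, call_single$proband_id)
})

test_that("input validation errors name the problem", {
  d <- withr::local_tempdir()
  p <- make_toy_cohort(d, n_decoys = 0, seed = 1)
  expect_error(load_cohort(file.path(d, "nope.vcf"), p[["ped"]]),
               "not found")
  # PED lacking a VCF sample
  short_ped <- file.path(d, "short.ped")
  writeLines("105\t105.3\t0\t0\t1\t2", short_ped)
  expect_error(load_cohort(p[["vcf"]], short_ped), "absent from pedigree")
  bad_ped <- file.path(d, "bad.ped")
  writeLines("105\t105.3\t0\t0\t9\t2", bad_ped)
  expect_error(read_pedigree(bad_ped), "invalid sex code")
  cyc_ped <- file.path(d, "cyc.ped")
  writeLines(c("F\tA\tB\t0\t1\t1", "F\tB\tA\t0\t1\t1"), cyc_ped)
  expect_error(read_pedigree(cyc_ped), "ancestor")
})
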