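# Toy cohort generator: four families whose genotypes encode the published
# recessive-acting VGCC findings - two compound-het CACNA1H pairs (trio 105
# and quad family 22 with monozygotic twins) and two hemizygous CACNA1F
# variants in male probands (trios 5 and 112) - embedded among decoy
# variants that each exercise one rejection path of the screen.

# The six true variants with their published hg38 coordinates, CADD scores,
# dbSNP ids and gnomAD v3.0 total allele frequencies.
TOY_TRUE_VARIANTS <- data.frame(
  chrom = c("chr16", "chr16", "chr16", "chr16", "chrX", "chrX"),
  pos = c(1204361L, 1205207L, 1220303L, 1220945L, 49211360L, 49211983L),
  ref = c("A", "C", "C", "C", "C", "C"),
  alt = c("T", "T", "T", "T", "T", "T"),
  rsid = c("rs28365117", "rs370675810", "rs372453886", "rs757713867",
           "rs782741094", "rs782780521"),
  gene = c("CACNA1H", "CACNA1H", "CACNA1H", "CACNA1H",
           "CACNA1F", "CACNA1F"),
  aa_change = c("Lys785Met", "Pro849Ser", "Pro2124Leu", "Ser2338Phe",
                "Ala1419Thr", "Gly1350Ser"),
  consequence = "missense",
  cadd = c(24.7, 18.22, 19.03, 16.99, 18.34, 24.7),
  af_v3 = c(0.003, 0.0000977, 0.00006978, 0.00002792, 0.0002, 0.00002839),
  origin = c("maternal", "paternal", "maternal", "paternal",
             "maternal", "maternal"),
  family = c("105", "105", "22", "22", "5", "112"),
  stringsAsFactors = FALSE)

TOY_PED <- data.frame(
  family_id = c(rep("22", 5), rep("105", 3), rep("5", 3), rep("112", 3)),
  sample_id = c("22.1", "22.2", "22.3", "22.4", "22.5",
                "105.1", "105.2", "105.3",
                "5.1", "5.2", "5.3",
                "112.1", "112.2", "112.3"),
  father_id = c("0", "0", "22.1", "22.1", "22.1",
                "0", "0", "105.1",
                "0", "0", "5.1",
                "0", "0", "112.1"),
  mother_id = c("0", "0", "22.2", "22.2", "22.2",
                "0", "0", "105.2",
                "0", "0", "5.2",
                "0", "0", "112.2"),
  sex_code = c("1", "2", "2", "2", "2",
               "1", "2", "1",
               "1", "2", "1",
               "1", "2", "1"),
  phen_code = c("1", "1", "2", "2", "1",
                "1", "1", "2",
                "1", "1", "2",
                "1", "1", "2"),
  stringsAsFactors = FALSE)

# Decoy templates: each is rejected by exactly one rule of the screen (the
# cis pair additionally exercises the distinct-parental-origin rule). "het"
# lists carriers; males listed under "hemi" get a haploid ALT on chrX.
TOY_DECOYS <- list(
  list(id = "decoy_cis_a", chrom = "chr1", pos = 181452000L, ref = "G",
       alt = "A", gene = "CACNA1E", consequence = "missense", cadd = 22.1,
       af_v3 = 0.005, af_v2 = 0.004, het = c("22.1", "22.3", "22.4"),
       why = "cis pair member (both paternal, not ultra-rare)"),
  list(id = "decoy_cis_b", chrom = "chr1", pos = 181530000L, ref = "C",
       alt = "T", gene = "CACNA1E", consequence = "missense", cadd = 21.4,
       af_v3 = 0.004, af_v2 = 0.006, het = c("22.1", "22.3", "22.4"),
       why = "cis pair member (both paternal, not ultra-rare)"),
  list(id = "decoy_common", chrom = "chr12", pos = 2110000L, ref = "G",
       alt = "T", gene = "CACNA1C", consequence = "missense", cadd = 23.0,
       af_v3 = 0.08, af_v2 = 0.06, het = c("105.2", "105.3"),
       why = "common (MAF > 1%)"),
  list(id = "decoy_synonymous", chrom = "chr17", pos = 50560000L, ref = "C",
       alt = "T", gene = "CACNA1G", consequence = "synonymous", cadd = 2.1,
       af_v3 = 0.0001, het = c("22.2", "22.3"),
       why = "synonymous (excluded consequence)"),
  list(id = "decoy_low_cadd", chrom = "chr19", pos = 13230000L, ref = "A",
       alt = "G", gene = "CACNA1A", consequence = "missense", cadd = 9.5,
       af_v3 = 0.0002, het = c("112.2", "112.3"),
       why = "missense below CADD threshold"),
  list(id = "decoy_low_qual", chrom = "chr3", pos = 53760000L, ref = "T",
       alt = "C", gene = "CACNA1D", consequence = "missense", cadd = 25.0,
       af_v3 = 0.0001, het = c("5.1", "5.3"), low_qual = "5.3",
       why = "proband genotype fails DP/GQ"),
  list(id = "decoy_offpanel", chrom = "chr2", pos = 166010000L, ref = "G",
       alt = "A", gene = "SCN1A", consequence = "missense", cadd = 28.0,
       af_v3 = 0.0001, het = c("105.1", "105.3"),
       why = "gene outside the panel"),
  list(id = "decoy_sibling_only", chrom = "chr10", pos = 18140000L,
       ref = "A", alt = "C", gene = "CACNB2", consequence = "missense",
       cadd = 20.0, af_v3 = 0.0005, het = c("22.1", "22.5"),
       why = "carried only by unaffected members"),
  list(id = "decoy_rare_not_ultra", chrom = "chr7", pos = 81610000L,
       ref = "C", alt = "G", gene = "CACNA2D1", consequence = "missense",
       cadd = 16.0, af_v3 = 0.02, af_v2 = 0.015, het = c("22.2", "22.4"),
       why = "common (MAF > 1% in both sources)"),
  list(id = "decoy_parent_only", chrom = "chr22", pos = 39950000L,
       ref = "G", alt = "T", gene = "CACNA1I", consequence = "stop_gain",
       cadd = 38.0, af_v3 = 0.009, het = c("105.1"),
       why = "LGD carried by a parent only"))

#' Generate the toy cohort VCF/PED fixtures
#'
#' Emits four families: family 22 (parents, affected monozygotic twins
#' 22.3/22.4, unaffected sibling 22.5 who carries only the paternal
#' variant), trio 105, and trios 5 and 112 with male probands carrying
#' maternally transmitted hemizygous chrX variants. The six true variants
#' carry their published coordinates, CADD scores, dbSNP ids and gnomAD
#' v3.0 frequencies; decoy variants each exercise one rejection rule of the
#' screen. A JSON manifest records the expected call set.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_decoys Number of decoy records (0-10); the first two form a
#'   same-parent cis pair.
#' @param seed Integer seed used to jitter DP/GQ values of passing
#'   genotypes.
#' @return Named character vector with paths \code{vcf}, \code{ped},
#'   \code{manifest}.
#' @export
make_toy_cohort <- function(out_dir, n_decoys = 10, seed = 1L) {
  stopifnot(n_decoys >= 0, n_decoys <= length(TOY_DECOYS))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))

  samples <- TOY_PED$sample_id
  sex <- setNames(TOY_PED$sex_code, samples)
  decoys <- TOY_DECOYS[seq_len(n_decoys)]

  n_var <- nrow(TOY_TRUE_VARIANTS) + length(decoys)
  variants <- data.frame(
    chrom = character(n_var), pos = integer(n_var), rsid = character(n_var),
    ref = character(n_var), alt = character(n_var), gene = character(n_var),
    consequence = character(n_var), cadd = numeric(n_var),
    af_v3 = rep(NA_real_, n_var), af_v2 = rep(NA_real_, n_var),
    stringsAsFactors = FALSE)
  gt <- matrix("0/0", n_var, length(samples),
               dimnames = list(NULL, samples))
  dp <- matrix(0L, n_var, length(samples), dimnames = list(NULL, samples))
  gq <- matrix(0L, n_var, length(samples), dimnames = list(NULL, samples))

  fill_qual <- function(row) {
    dp[row, ] <<- sample(30:60, length(samples), replace = TRUE)
    gq[row, ] <<- sample(80:99, length(samples), replace = TRUE)
  }

  for (i in seq_len(nrow(TOY_TRUE_VARIANTS))) {
    tv <- TOY_TRUE_VARIANTS[i, ]
    variants[i, c("chrom", "rsid", "ref", "alt", "gene", "consequence")] <-
      c(tv$chrom, tv$rsid, tv$ref, tv$alt, tv$gene, tv$consequence)
    variants$pos[i] <- tv$pos
    variants$cadd[i] <- tv$cadd
    variants$af_v3[i] <- tv$af_v3
    fill_qual(i)
    if (tv$chrom == "chrX") {
      # males haploid on non-PAR X
      gt[i, samples[sex == "1"]] <- "0"
    }
    carrier_parent <- if (tv$origin == "maternal") "mother" else "father"
    if (tv$family == "105") {
      parent <- if (carrier_parent == "mother") "105.2" else "105.1"
      gt[i, parent] <- "0/1"
      gt[i, "105.3"] <- "0/1"
    } else if (tv$family == "22") {
      parent <- if (carrier_parent == "mother") "22.2" else "22.1"
      gt[i, parent] <- "0/1"
      gt[i, c("22.3", "22.4")] <- "0/1"
      if (tv$origin == "paternal") gt[i, "22.5"] <- "0/1"
    } else {
      # chrX hemizygous trios: carrier mother het, male proband haploid ALT
      mother <- paste0(tv$family, ".2")
      proband <- paste0(tv$family, ".3")
      gt[i, mother] <- "0/1"
      gt[i, proband] <- "1"
    }
  }

  for (k in seq_along(decoys)) {
    d <- decoys[[k]]
    row <- nrow(TOY_TRUE_VARIANTS) + k
    variants[row, c("chrom", "ref", "alt", "gene", "consequence")] <-
      c(d$chrom, d$ref, d$alt, d$gene, d$consequence)
    variants$pos[row] <- d$pos
    variants$rsid[row] <- "."
    variants$cadd[row] <- d$cadd
    variants$af_v3[row] <- d$af_v3
    if (!is.null(d$af_v2)) variants$af_v2[row] <- d$af_v2
    fill_qual(row)
    gt[row, d$het] <- "0/1"
    if (!is.null(d$low_qual)) {
      dp[row, d$low_qual] <- 5L
      gq[row, d$low_qual] <- 12L
    }
  }

  paths <- c(vcf = file.path(out_dir, "toy_cohort.vcf"),
             ped = file.path(out_dir, "toy_cohort.ped"),
             manifest = file.path(out_dir, "toy_cohort_manifest.json"))
  write_cohort_vcf(variants, gt, dp, gq, paths["vcf"])
  write.table(TOY_PED, paths["ped"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  vid <- function(i) paste0(variants$chrom[i], ":", variants$pos[i], ":",
                            variants$ref[i], ">", variants$alt[i])
  true_ids <- vapply(seq_len(nrow(TOY_TRUE_VARIANTS)), vid, character(1))
  jsonlite::write_json(list(
    compound_het_variants = true_ids[TOY_TRUE_VARIANTS$gene == "CACNA1H"],
    hemizygous_variants = true_ids[TOY_TRUE_VARIANTS$gene == "CACNA1F"],
    compound_het_probands = c("105.3", "22.3", "22.4"),
    hemizygous_probands = c("5.3", "112.3"),
    monozygotic_twins = c("22.3", "22.4"),
    expected_recessive_variants = 6,
    decoys = lapply(decoys, function(d) list(id = d$id, why = d$why)),
    seed = as.integer(seed)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a cohort table as a VCF v4.2 file
#'
#' Low-level writer shared by \code{\link{make_toy_cohort}} and tests.
#' INFO keys GENE, CSQ_CLASS, CADD_PHRED, AF_GNOMAD_V3 and
#' AF_GNOMAD_V2_NONNEURO; FORMAT GT:DP:GQ.
#'
#' @param variants data.frame with columns \code{chrom, pos, rsid, ref, alt,
#'   gene, consequence, cadd, af_v3, af_v2} (the last two may be \code{NA}).
#' @param gt Character matrix (variants x samples) of genotypes.
#' @param dp,gq Integer matrices of depth and quality.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort_vcf <- function(variants, gt, dp, gq, path) {
  samples <- colnames(gt)
  chrom_rank <- function(ch) {
    x <- sub("^chr", "", ch)
    suppressWarnings(r <- as.numeric(x))
    r[x == "X"] <- 23; r[x == "Y"] <- 24
    r
  }
  ord <- order(chrom_rank(variants$chrom), variants$pos, variants$alt)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"HGNC gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=AF_GNOMAD_V3,Number=A,Type=Float,Description=\"gnomAD v3.0 total allele frequency\">",
    "##INFO=<ID=AF_GNOMAD_V2_NONNEURO,Number=A,Type=Float,Description=\"gnomAD v2.1 non-neuro allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  fmt_num <- function(x) formatC(x, format = "g", digits = 10)
  body <- vapply(ord, function(i) {
    info <- c(paste0("GENE=", variants$gene[i]),
              paste0("CSQ_CLASS=", variants$consequence[i]))
    if (!is.na(variants$cadd[i])) {
      info <- c(info, paste0("CADD_PHRED=", fmt_num(variants$cadd[i])))
    }
    if (!is.na(variants$af_v3[i])) {
      info <- c(info, paste0("AF_GNOMAD_V3=", fmt_num(variants$af_v3[i])))
    }
    if (!is.na(variants$af_v2[i])) {
      info <- c(info, paste0("AF_GNOMAD_V2_NONNEURO=",
                             fmt_num(variants$af_v2[i])))
    }
    geno <- paste(gt[i, ], dp[i, ], gq[i, ], sep = ":")
    paste(c(variants$chrom[i], variants$pos[i], variants$rsid[i],
            variants$ref[i], variants$alt[i], ".", "PASS",
            paste(info, collapse = ";"), "GT:DP:GQ", geno),
          collapse = "\t")
  }, character(1))

  writeLines(c(hdr, body), path)
  invisible(path)
}
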