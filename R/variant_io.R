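# Cohort input: annotated multi-sample VCF (via vcfR) + 6-column PED.
# Multi-allelic records are decomposed to one variant per ALT allele before
# any filtering, so downstream logic only ever sees biallelic records.

#' Read a 6-column PED pedigree file
#'
#' Columns: family id, sample id, father id, mother id, sex (1 = male,
#' 2 = female, 0 = unknown), phenotype (2 = affected, 1 = unaffected,
#' 0 = unknown). Founders use parent id "0".
#'
#' @param path Path to a whitespace-separated PED file.
#' @return A data.frame of class \code{"pedigree"} with columns
#'   \code{family_id, sample_id, father_id, mother_id, sex, affected}
#'   (sex in \code{M/F/unknown}, affected in \code{yes/no/unknown}).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  ped <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("malformed PED file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(ped) != 6) {
    stop("malformed PED file '", path, "': expected 6 columns, found ",
         ncol(ped))
  }
  names(ped) <- c("family_id", "sample_id", "father_id", "mother_id",
                  "sex_code", "phen_code")
  bad_sex <- !ped$sex_code %in% c("0", "1", "2")
  if (any(bad_sex)) {
    stop("malformed PED file '", path, "': invalid sex code at line ",
         which(bad_sex)[1])
  }
  bad_phen <- !ped$phen_code %in% c("0", "1", "2")
  if (any(bad_phen)) {
    stop("malformed PED file '", path, "': invalid phenotype code at line ",
         which(bad_phen)[1])
  }
  if (anyDuplicated(ped$sample_id)) {
    stop("duplicated sample id in PED: ",
         ped$sample_id[duplicated(ped$sample_id)][1])
  }
  out <- data.frame(
    family_id = ped$family_id,
    sample_id = ped$sample_id,
    father_id = ped$father_id,
    mother_id = ped$mother_id,
    sex = c(`0` = "unknown", `1` = "M", `2` = "F")[ped$sex_code],
    affected = c(`0` = "unknown", `1` = "no", `2` = "yes")[ped$phen_code],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  check_pedigree_cycles(out)
  class(out) <- c("pedigree", "data.frame")
  out
}

# Parent ids must resolve to members or founders, and no sample may be its
# own ancestor.
check_pedigree_cycles <- function(ped) {
  ids <- ped$sample_id
  for (col in c("father_id", "mother_id")) {
    unresolved <- setdiff(ped[[col]], c("0", ids))
    if (length(unresolved) > 0) {
      stop("pedigree parent id not found among samples or founders: ",
           unresolved[1])
    }
  }
  parent_of <- function(id) {
    row <- ped[ped$sample_id == id, , drop = FALSE]
    setdiff(c(row$father_id, row$mother_id), "0")
  }
  for (id in ids) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier) > 0) {
      if (id %in% frontier) stop("pedigree cycle: ", id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(lapply(frontier, parent_of)), seen)
    }
  }
  invisible(ped)
}

#' Load an annotated cohort VCF and its pedigree
#'
#' Parses a VCF v4.2 (plain or bgzipped) carrying per-variant gene symbol,
#' consequence class, CADD score and population allele frequencies as INFO
#' keys, plus GT/DP/GQ FORMAT fields, together with a PED pedigree.
#' Multi-allelic records are decomposed into one variant per ALT allele
#' (other ALT alleles recoded to reference in the genotypes); 1-based
#' coordinates are preserved.
#'
#' @param vcf_path Path to the VCF.
#' @param ped_path Path to the PED file. All VCF samples must appear in it.
#' @param config A \code{\link{filter_config}} naming the INFO keys.
#' @return A list of class \code{"cohort"} with elements:
#'   \describe{
#'     \item{variants}{data.frame: \code{variant_id, chrom, pos, ref, alt,
#'       rsid, gene, consequence, cadd}.}
#'     \item{mafs}{numeric matrix, variants x frequency sources.}
#'     \item{gt, dp, gq}{matrices, variants x samples (GT character,
#'       DP/GQ numeric).}
#'     \item{pedigree}{the \code{\link{read_pedigree}} result.}
#'   }
#' @export
load_cohort <- function(vcf_path, ped_path, config = filter_config()) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  ped <- read_pedigree(ped_path)

  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)

  if (is.null(fix) || nrow(vcf@fix) == 0) {
    return(empty_cohort(ped, config))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(samples, ped$sample_id)
  if (length(missing_samples) > 0) {
    stop("VCF sample(s) absent from pedigree: ",
         paste(missing_samples, collapse = ", "))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  info_get <- function(key) vcfR::extract.info(vcf, element = key)

  gene <- info_get(config$gene_key)
  csq <- info_get(config$csq_key)
  cadd <- info_get(config$cadd_key)
  maf_raw <- lapply(config$maf_sources, info_get)
  names(maf_raw) <- config$maf_sources

  rows <- list()
  n_alt_total <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    pos_i <- as.integer(fix$POS[i])
    if (is.na(pos_i) || pos_i < 1) {
      stop("malformed VCF '", vcf_path, "': invalid POS at record ", i)
    }
    for (k in seq_along(alts)) {
      n_alt_total <- n_alt_total + 1L
      rows[[n_alt_total]] <- list(
        src = i, alt_index = k,
        chrom = fix$CHROM[i], pos = pos_i,
        ref = toupper(fix$REF[i]), alt = toupper(alts[k]),
        rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_
               else fix$ID[i],
        gene = gene[i],
        consequence = nth_or_single(csq[i], k, i, vcf_path),
        cadd = as_num(nth_or_single(cadd[i], k, i, vcf_path)))
    }
  }

  variants <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               rsid = r$rsid, gene = r$gene, consequence = r$consequence,
               cadd = r$cadd, stringsAsFactors = FALSE)
  }))
  variants$variant_id <- paste0(variants$chrom, ":", variants$pos, ":",
                                variants$ref, ">", variants$alt)
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                           "rsid", "gene", "consequence", "cadd")]

  bad_allele <- !grepl("^[ACGT]+$", variants$ref) |
    !grepl("^[ACGT]+$", variants$alt)
  if (any(bad_allele)) {
    stop("malformed VCF '", vcf_path, "': non-ACGT allele at record ",
         rows[[which(bad_allele)[1]]]$src)
  }

  mafs <- matrix(NA_real_, nrow = length(rows), ncol = length(config$maf_sources),
                 dimnames = list(variants$variant_id, config$maf_sources))
  for (s in config$maf_sources) {
    vals <- maf_raw[[s]]
    for (j in seq_along(rows)) {
      r <- rows[[j]]
      mafs[j, s] <- as_num(nth_or_single(vals[r$src], r$alt_index,
                                         r$src, vcf_path))
    }
  }
  if (any(mafs < 0 | mafs > 1, na.rm = TRUE)) {
    stop("malformed VCF '", vcf_path, "': allele frequency outside [0, 1]")
  }

  gt_out <- matrix(NA_character_, nrow = length(rows), ncol = length(samples),
                   dimnames = list(variants$variant_id, samples))
  dp_out <- gq_out <- matrix(NA_real_, nrow = length(rows),
                             ncol = length(samples),
                             dimnames = list(variants$variant_id, samples))
  for (j in seq_along(rows)) {
    r <- rows[[j]]
    gt_out[j, ] <- vapply(gt[r$src, samples], recode_gt_for_alt,
                          character(1), alt_index = r$alt_index)
    dp_out[j, ] <- dp[r$src, samples]
    gq_out[j, ] <- gq[r$src, samples]
  }

  structure(list(variants = variants, mafs = mafs,
                 gt = gt_out, dp = dp_out, gq = gq_out,
                 pedigree = ped, config = config),
            class = "cohort")
}

empty_cohort <- function(ped, config) {
  variants <- data.frame(variant_id = character(0), chrom = character(0),
                         pos = integer(0), ref = character(0),
                         alt = character(0), rsid = character(0),
                         gene = character(0), consequence = character(0),
                         cadd = numeric(0), stringsAsFactors = FALSE)
  empty <- matrix(NA_real_, 0, 0)
  structure(list(variants = variants,
                 mafs = matrix(NA_real_, 0, length(config$maf_sources),
                               dimnames = list(NULL, config$maf_sources)),
                 gt = matrix(NA_character_, 0, 0), dp = empty, gq = empty,
                 pedigree = ped, config = config),
            class = "cohort")
}

as_num <- function(x) suppressWarnings(as.numeric(x))

# Per-ALT INFO fields (Number=A) are comma-separated; scalar fields apply to
# every ALT of the record.
nth_or_single <- function(x, k, record, path) {
  if (is.na(x)) return(NA_character_)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(parts)
  if (k > length(parts)) {
    stop("malformed VCF '", path, "': fewer INFO entries than ALT alleles ",
         "at record ", record)
  }
  parts[k]
}

# Decomposition rule: allele indices matching this ALT become 1, reference
# and any other ALT become 0, missing stays missing. Phasing separators are
# preserved.
recode_gt_for_alt <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  sep <- if (grepl("|", gt, fixed = TRUE)) "|" else "/"
  alleles <- strsplit(gt, "[/|]")[[1]]
  recoded <- vapply(alleles, function(a) {
    if (a == ".") "." else if (a == as.character(alt_index)) "1" else "0"
  }, character(1))
  paste(recoded, collapse = sep)
}

# Allele-count helper shared by the inheritance logic. Returns list(n_alt,
# ploidy, missing).
parse_gt <- function(gt) {
  if (is.na(gt)) return(list(n_alt = NA_integer_, ploidy = NA_integer_,
                             missing = TRUE))
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) {
    return(list(n_alt = NA_integer_, ploidy = length(alleles), missing = TRUE))
  }
  list(n_alt = sum(alleles == "1"), ploidy = length(alleles), missing = FALSE)
}
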