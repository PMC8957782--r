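# Inheritance-model classification per affected child, and compound-het
# pairing with distinct parental origins.

X_CHROMS <- c("X", "chrX", "23")

is_nonpar_x <- function(chrom, pos, config) {
  if (!chrom %in% X_CHROMS) return(FALSE)
  !any(vapply(config$par_regions,
              function(r) pos >= r[1] && pos <= r[2], logical(1)))
}

#' Classify the inheritance model of one variant
#'
#' For each affected child carrying the ALT allele, determines the
#' transmission model from the trio genotypes:
#' \itemize{
#'   \item heterozygous child, exactly one parent carrying ->
#'     \code{inherited_maternal} / \code{inherited_paternal};
#'   \item both parents carrying -> \code{inherited_ambiguous};
#'   \item neither parent carrying -> \code{de_novo};
#'   \item child 1/1 -> \code{homozygous};
#'   \item male child with the ALT on non-pseudoautosomal chrX ->
#'     \code{hemizygous} (origin maternal when the mother carries).
#' }
#' A missing or ungenotyped parent yields \code{inherited_ambiguous} with a
#' note. Mendelian impossibilities other than de novo (e.g. a homozygous
#' child with a non-carrier genotyped parent) are flagged, not dropped.
#' Genotypes failing the DP/GQ quality filter are treated as missing.
#'
#' @param variant One-row slice of \code{cohort$variants} (or any list with
#'   \code{chrom}, \code{pos}, \code{variant_id}).
#' @param gt,dp,gq Named vectors (by sample) of genotype, depth, quality for
#'   this variant.
#' @param pedigree A \code{\link{read_pedigree}} result.
#' @param config A \code{\link{filter_config}}.
#' @return data.frame with one row per call: \code{variant_id, proband_id,
#'   model, origin, n_alt, mendel_error, note}.
#' @export
classify_inheritance <- function(variant, gt, dp, gq, pedigree,
                                 config = filter_config()) {
  children <- pedigree[pedigree$affected == "yes", , drop = FALSE]
  calls <- list()
  qual_ok <- function(id) {
    id %in% names(gt) && quality_pass(dp[[id]], gq[[id]], config)
  }
  geno <- function(id) {
    if (!id %in% names(gt) || !qual_ok(id)) {
      return(list(n_alt = NA_integer_, ploidy = NA_integer_, missing = TRUE))
    }
    parse_gt(gt[[id]])
  }

  for (i in seq_len(nrow(children))) {
    child <- children[i, ]
    cg <- geno(child$sample_id)
    if (cg$missing || cg$n_alt == 0) next

    on_x <- is_nonpar_x(variant$chrom, variant$pos, config)
    fg <- geno(child$father_id)
    mg <- geno(child$mother_id)
    f_carrier <- if (fg$missing) NA else fg$n_alt > 0
    m_carrier <- if (mg$missing) NA else mg$n_alt > 0

    model <- NULL; origin <- NA_character_
    mendel <- FALSE; note <- NA_character_

    if (on_x && child$sex == "M") {
      model <- "hemizygous"
      if (isTRUE(m_carrier)) origin <- "maternal"
      if (isFALSE(m_carrier) && isFALSE(f_carrier)) {
        model <- "de_novo"
        origin <- NA_character_
      }
    } else if (cg$ploidy >= 2 && cg$n_alt >= 2) {
      model <- "homozygous"
      if (isFALSE(f_carrier) || isFALSE(m_carrier)) mendel <- TRUE
    } else {
      # heterozygous child
      if (is.na(f_carrier) || is.na(m_carrier)) {
        model <- "inherited_ambiguous"
        note <- "parent genotype missing or low quality"
      } else if (f_carrier && m_carrier) {
        model <- "inherited_ambiguous"
        note <- "both parents carry the allele"
      } else if (m_carrier) {
        model <- "inherited_maternal"; origin <- "maternal"
      } else if (f_carrier) {
        model <- "inherited_paternal"; origin <- "paternal"
      } else {
        model <- "de_novo"
      }
    }

    calls[[length(calls) + 1L]] <- data.frame(
      variant_id = variant$variant_id, proband_id = child$sample_id,
      model = model, origin = origin, n_alt = cg$n_alt,
      mendel_error = mendel, note = note, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0) {
    return(data.frame(variant_id = character(0), proband_id = character(0),
                      model = character(0), origin = character(0),
                      n_alt = integer(0), mendel_error = logical(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Find compound-heterozygous pairs within a gene
#'
#' Pairs two heterozygous calls in the same proband and gene when one is
#' maternally and the other paternally inherited, excluding cis
#' configurations in which a single parent carries both alleles (parents
#' here are unaffected, so a trans configuration is required). A variant may
#' participate in several pairs; a sibling carrying only one member of a
#' pair yields no call.
#'
#' @param calls data.frame of inheritance calls (as from
#'   \code{\link{classify_inheritance}}) joined with a \code{gene} column;
#'   callers should pre-filter to quality/frequency/damaging-passing
#'   heterozygous calls.
#' @param gt Genotype matrix (variants x samples) of the cohort.
#' @param pedigree A \code{\link{read_pedigree}} result.
#' @return data.frame with one row per pair: \code{proband_id, gene,
#'   variant_id, partner_id, origin, partner_origin}.
#' @export
find_compound_het <- function(calls, gt, pedigree) {
  empty <- data.frame(proband_id = character(0), gene = character(0),
                      variant_id = character(0), partner_id = character(0),
                      origin = character(0), partner_origin = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  het <- calls[calls$model %in% c("inherited_maternal", "inherited_paternal") &
                 calls$n_alt == 1, , drop = FALSE]
  if (nrow(het) == 0) return(empty)

  carries <- function(sample_id, variant_id) {
    if (!sample_id %in% colnames(gt)) return(FALSE)
    g <- parse_gt(gt[variant_id, sample_id])
    !g$missing && g$n_alt > 0
  }

  pairs <- list()
  for (key in unique(paste(het$proband_id, het$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    proband <- parts[1]; gene <- parts[2]
    grp <- het[het$proband_id == proband & het$gene == gene, , drop = FALSE]
    mat <- grp[grp$model == "inherited_maternal", , drop = FALSE]
    pat <- grp[grp$model == "inherited_paternal", , drop = FALSE]
    if (nrow(mat) == 0 || nrow(pat) == 0) next
    ped_row <- pedigree[pedigree$sample_id == proband, ]
    parents <- setdiff(c(ped_row$father_id, ped_row$mother_id), "0")
    for (i in seq_len(nrow(mat))) {
      for (j in seq_len(nrow(pat))) {
        vm <- mat$variant_id[i]; vp <- pat$variant_id[j]
        if (vm == vp) next
        cis <- any(vapply(parents, function(p) {
          carries(p, vm) && carries(p, vp)
        }, logical(1)))
        if (cis) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          proband_id = proband, gene = gene,
          variant_id = vm, partner_id = vp,
          origin = "maternal", partner_origin = "paternal",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pairs) == 0) return(empty)
  do.call(rbind, pairs)
}
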