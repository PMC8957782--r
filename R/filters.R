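# Filter cascade: genotype quality, population frequency, deleteriousness.
# Boundary semantics follow the screen's stated rules: genotypes with DP < 10
# or GQ < 20 are removed (equality passes), variants are kept at MAF <= the
# threshold, and missense calls are damaging at CADD >= 15.

#' Default VGCC gene panel
#'
#' The 18 genes encoding voltage-gated calcium-channel subunits: the ten
#' alpha-1 pore-forming subunit genes (CACNA1A-CACNA1I, CACNA1S) and the
#' eight auxiliary-subunit genes (CACNA2D1-4, CACNB1-4).
#'
#' @return Character vector of HGNC symbols.
#' @export
vgcc_panel <- function() {
  c("CACNA1A", "CACNA1B", "CACNA1C", "CACNA1D", "CACNA1E",
    "CACNA1F", "CACNA1G", "CACNA1H", "CACNA1I", "CACNA1S",
    "CACNA2D1", "CACNA2D2", "CACNA2D3", "CACNA2D4",
    "CACNB1", "CACNB2", "CACNB3", "CACNB4")
}

#' Filter configuration for the variant screen
#'
#' Bundles every threshold of the screening cascade, with the screen's
#' published values as defaults.
#'
#' @param dp_min Minimum read depth; genotypes with DP below this are removed.
#' @param gq_min Minimum genotype quality; genotypes with GQ below are removed.
#' @param maf_rare MAF ceiling for "rare" variants (recessive-model screen).
#' @param maf_ultra_rare MAF ceiling for "ultra-rare" variants (dominant-model
#'   screen). Must not exceed \code{maf_rare}.
#' @param cadd_min CADD phred threshold above which a missense variant counts
#'   as damaging.
#' @param maf_sources Ordered character vector of VCF INFO keys holding
#'   population allele frequencies; the effective MAF is the maximum over
#'   sources, with missing entries treated as 0 (novel).
#' @param gene_panel HGNC symbols to which the screen is restricted.
#' @param gene_key,csq_key,cadd_key INFO keys for gene symbol, consequence
#'   class and CADD phred score.
#' @param missing_qual_pass Should genotypes with missing DP or GQ pass the
#'   quality filter? Default \code{FALSE} (fail, logged by the screen).
#' @param par_regions GRCh38 pseudoautosomal regions on chrX as a list of
#'   \code{c(start, end)}; male X calls outside these are hemizygous.
#' @return A list of class \code{"filter_config"}.
#' @export
filter_config <- function(dp_min = 10, gq_min = 20,
                          maf_rare = 0.01, maf_ultra_rare = 0.001,
                          cadd_min = 15,
                          maf_sources = c("AF_GNOMAD_V3",
                                          "AF_GNOMAD_V2_NONNEURO"),
                          gene_panel = vgcc_panel(),
                          gene_key = "GENE", csq_key = "CSQ_CLASS",
                          cadd_key = "CADD_PHRED",
                          missing_qual_pass = FALSE,
                          par_regions = list(PAR1 = c(10001, 2781479),
                                             PAR2 = c(155701383, 156030895))) {
  stopifnot(maf_ultra_rare >= 0, maf_ultra_rare <= maf_rare, maf_rare <= 1,
            dp_min >= 0, gq_min >= 0, cadd_min >= 0)
  structure(list(dp_min = dp_min, gq_min = gq_min,
                 maf_rare = maf_rare, maf_ultra_rare = maf_ultra_rare,
                 cadd_min = cadd_min, maf_sources = maf_sources,
                 gene_panel = gene_panel, gene_key = gene_key,
                 csq_key = csq_key, cadd_key = cadd_key,
                 missing_qual_pass = missing_qual_pass,
                 par_regions = par_regions),
            class = "filter_config")
}

#' Genotype quality filter
#'
#' A genotype passes when both DP >= dp_min and GQ >= gq_min; the screen
#' removes strictly-below values, so equality passes. Missing DP or GQ fails
#' by default (\code{config$missing_qual_pass}).
#'
#' @param dp,gq Numeric vectors (recycled) of read depth and genotype quality;
#'   \code{NA} marks missing.
#' @param config A \code{\link{filter_config}}.
#' @return Logical vector.
#' @export
quality_pass <- function(dp, gq, config = filter_config()) {
  ok <- dp >= config$dp_min & gq >= config$gq_min
  ok[is.na(ok)] <- config$missing_qual_pass
  ok
}

#' Population-frequency class of a variant
#'
#' The effective MAF is the maximum over the configured frequency sources;
#' sources without an entry contribute 0, so a variant absent everywhere is
#' ultra-rare (novel). Class boundaries are inclusive: \code{ultra_rare} at
#' MAF <= \code{maf_ultra_rare}, \code{rare} at MAF <= \code{maf_rare},
#' otherwise \code{common}.
#'
#' @param mafs Numeric vector (or single-row matrix) of allele frequencies,
#'   \code{NA} = absent from that source.
#' @param config A \code{\link{filter_config}}.
#' @return One of \code{"ultra_rare"}, \code{"rare"}, \code{"common"}.
#' @export
frequency_class <- function(mafs, config = filter_config()) {
  eff <- effective_maf(mafs)
  if (eff <= config$maf_ultra_rare) "ultra_rare"
  else if (eff <= config$maf_rare) "rare"
  else "common"
}

effective_maf <- function(mafs) {
  mafs <- as.numeric(mafs)
  mafs <- mafs[!is.na(mafs)]
  if (length(mafs) == 0) return(0)
  if (any(mafs < 0 | mafs > 1)) stop("allele frequencies must lie in [0, 1]")
  max(mafs)
}

LGD_CLASSES <- c("stop_gain", "stop_loss", "frameshift", "splice")

#' Deleteriousness class of a variant
#'
#' Likely gene-disrupting (LGD) classes - stop-gain, stop-loss, frameshift,
#' splice - are damaging regardless of CADD. Missense variants are damaging
#' at CADD >= \code{cadd_min}; synonymous, sub-threshold missense, and
#' missense without a CADD score are excluded.
#'
#' @param consequence Consequence class string (one of \code{missense},
#'   \code{stop_gain}, \code{stop_loss}, \code{frameshift}, \code{splice},
#'   \code{synonymous}, \code{other}).
#' @param cadd CADD phred score, \code{NA} if unavailable.
#' @param config A \code{\link{filter_config}}.
#' @return One of \code{"LGD"}, \code{"damaging_missense"}, \code{"excluded"}.
#' @export
damaging_class <- function(consequence, cadd = NA_real_,
                           config = filter_config()) {
  if (consequence %in% LGD_CLASSES) return("LGD")
  if (identical(consequence, "missense") && !is.na(cadd) &&
      cadd >= config$cadd_min) {
    return("damaging_missense")
  }
  "excluded"
}
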