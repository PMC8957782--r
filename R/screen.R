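# Panel screen: quality -> frequency -> deleteriousness cascade, then
# inheritance-model classification and dominant/recessive candidate lists.

#' Screen a cohort over the gene panel
#'
#' Applies the full filter cascade to every (variant, affected child) pair
#' restricted to \code{config$gene_panel}:
#' \enumerate{
#'   \item genotype quality (DP/GQ; failing genotypes treated as missing);
#'   \item population frequency (effective MAF = max over sources,
#'     missing = 0);
#'   \item deleteriousness (LGD, or missense with CADD >= threshold);
#'   \item inheritance-model classification, including compound heterozygotes
#'     with distinct parental origins.
#' }
#' The dominant-model candidate list keeps ultra-rare damaging heterozygous
#' inherited or de novo calls; the recessive-model list keeps rare damaging
#' homozygous, hemizygous and compound-heterozygous calls. Every emitted call
#' carries its filter trail. De novo calls are reported but flagged, and
#' Mendelian-error records are retained with a flag.
#'
#' @param cohort A \code{\link{load_cohort}} result.
#' @param config A \code{\link{filter_config}}; defaults to
#'   \code{cohort$config}.
#' @return A list of class \code{"screen_report"}:
#'   \describe{
#'     \item{all_calls}{every classified call with filter-trail columns.}
#'     \item{dominant}{ultra-rare damaging het inherited/de-novo calls.}
#'     \item{recessive}{rare damaging homozygous/hemizygous/compound-het
#'       calls (one row per call; compound-het rows carry
#'       \code{partner_id}).}
#'     \item{counts}{per-gene, per-family and per-individual call counts
#'       (families counted once even when monozygotic twins both carry).}
#'   }
#' @export
screen_panel <- function(cohort, config = NULL) {
  if (is.null(config)) config <- cohort$config
  v <- cohort$variants
  ped <- cohort$pedigree

  keep <- which(v$gene %in% config$gene_panel)
  calls <- list()
  for (i in keep) {
    freq_cl <- frequency_class(cohort$mafs[i, ], config)
    dmg_cl <- damaging_class(v$consequence[i], v$cadd[i], config)
    ci <- classify_inheritance(v[i, ], cohort$gt[i, ], cohort$dp[i, ],
                               cohort$gq[i, ], ped, config)
    if (nrow(ci) == 0) next
    ci$gene <- v$gene[i]
    ci$chrom <- v$chrom[i]
    ci$pos <- v$pos[i]
    ci$alt <- v$alt[i]
    ci$frequency_class <- freq_cl
    ci$damaging_class <- dmg_cl
    ci$effective_maf <- effective_maf(cohort$mafs[i, ])
    ci$cadd <- v$cadd[i]
    calls[[length(calls) + 1L]] <- ci
  }
  all_calls <- if (length(calls) == 0) {
    data.frame(variant_id = character(0), proband_id = character(0),
               model = character(0), origin = character(0),
               n_alt = integer(0), mendel_error = logical(0),
               note = character(0), gene = character(0),
               chrom = character(0), pos = integer(0), alt = character(0),
               frequency_class = character(0), damaging_class = character(0),
               effective_maf = numeric(0), cadd = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, calls)
  }
  all_calls$damaging <- all_calls$damaging_class != "excluded"
  all_calls$de_novo_flag <- ifelse(
    all_calls$model == "de_novo",
    "de novo: not part of the inherited-variant screen", NA_character_)

  # Dominant model: ultra-rare + damaging + heterozygous inherited/de novo.
  dom <- all_calls[all_calls$frequency_class == "ultra_rare" &
                     all_calls$damaging &
                     all_calls$model %in% c("inherited_maternal",
                                            "inherited_paternal",
                                            "inherited_ambiguous",
                                            "de_novo") &
                     all_calls$n_alt == 1 & !all_calls$mendel_error, ,
                   drop = FALSE]

  # Recessive model: rare (incl. ultra-rare) + damaging, homozygous /
  # hemizygous directly, compound het via distinct-parental-origin pairing.
  rare_dmg <- all_calls[all_calls$frequency_class %in%
                          c("ultra_rare", "rare") &
                          all_calls$damaging & !all_calls$mendel_error, ,
                        drop = FALSE]
  rec_single <- rare_dmg[rare_dmg$model %in% c("homozygous", "hemizygous"), ,
                         drop = FALSE]
  rec_single$partner_id <- rep(NA_character_, nrow(rec_single))

  pairs <- find_compound_het(rare_dmg, cohort$gt, ped)
  if (nrow(pairs) > 0) {
    comp_rows <- list()
    for (p in seq_len(nrow(pairs))) {
      for (side in c("variant_id", "partner_id")) {
        vid <- pairs[[side]][p]
        partner <- pairs[[if (side == "variant_id") "partner_id"
                          else "variant_id"]][p]
        row <- rare_dmg[rare_dmg$variant_id == vid &
                          rare_dmg$proband_id == pairs$proband_id[p], ,
                        drop = FALSE][1, , drop = FALSE]
        row$model <- "compound_het"
        row$partner_id <- partner
        comp_rows[[length(comp_rows) + 1L]] <- row
      }
    }
    comp <- unique(do.call(rbind, comp_rows))
    recessive <- rbind(rec_single, comp)
  } else {
    recessive <- rec_single
  }
  recessive <- order_calls(recessive)
  dom <- order_calls(dom)
  all_calls <- order_calls(all_calls)

  counts <- list(
    per_gene = table_df(recessive$gene, "gene"),
    per_family = table_df(
      unique(merge_family(recessive, ped)[, c("family_id", "variant_id")])$family_id,
      "family_id"),
    per_individual = table_df(recessive$proband_id, "proband_id"))

  structure(list(all_calls = all_calls, dominant = dom,
                 recessive = recessive, counts = counts,
                 compound_het_pairs = pairs, config = config),
            class = "screen_report")
}

order_calls <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- df[order(df$chrom, df$pos, df$alt, df$proband_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

merge_family <- function(calls, ped) {
  if (nrow(calls) == 0) {
    calls$family_id <- character(0)
    return(calls)
  }
  calls$family_id <- ped$family_id[match(calls$proband_id, ped$sample_id)]
  calls
}

table_df <- function(x, name) {
  if (length(x) == 0) {
    out <- data.frame(key = character(0), n = integer(0),
                      stringsAsFactors = FALSE)
    names(out)[1] <- name
    return(out)
  }
  tab <- table(x)
  out <- data.frame(key = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  names(out)[1] <- name
  out
}

#' Write a screen report to disk
#'
#' Emits a TSV with one row per call (variant key, gene, proband, model,
#' partner and filter trail; rows ordered by chrom, pos, alt, proband) for
#' each of the dominant and recessive lists, plus a JSON count summary.
#'
#' @param report A \code{\link{screen_panel}} result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_screen_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("variant_id", "chrom", "pos", "alt", "gene", "proband_id",
            "model", "partner_id", "origin", "frequency_class",
            "damaging_class", "effective_maf", "cadd", "mendel_error",
            "note")
  rec <- report$recessive
  dom <- report$dominant
  dom$partner_id <- rep(NA_character_, nrow(dom))
  paths <- c(recessive = file.path(out_dir, "recessive_calls.tsv"),
             dominant = file.path(out_dir, "dominant_calls.tsv"),
             summary = file.path(out_dir, "screen_summary.json"))
  write.table(rec[, intersect(cols, names(rec))], paths["recessive"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dom[, intersect(cols, names(dom))], paths["dominant"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_recessive_calls = nrow(rec),
         n_dominant_calls = nrow(dom),
         n_compound_het_pairs = nrow(report$compound_het_pairs),
         counts = report$counts),
    paths["summary"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
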