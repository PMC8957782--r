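# End-to-end orchestration: fixtures -> variant screen -> simulated
# recordings -> per-cell parameters -> group statistics, with a hashed
# output manifest for reproducibility checks.

#' Configuration for a full pipeline run
#'
#' @param out_dir Output directory.
#' @param seed Master seed recorded in every output.
#' @param vcf_path,ped_path Optional existing cohort inputs; when omitted
#'   the toy cohort is generated into \code{out_dir}.
#' @param filter A \code{\link{filter_config}}.
#' @param genotypes Genotypes to simulate (built-in labels).
#' @param n_cells Cells per genotype (recycled to \code{genotypes}).
#' @param cap_median_pf,cap_cv,gmax_cv,noise_sigma_pa Cohort-spec knobs, see
#'   \code{\link{cohort_spec}}.
#' @param conductance_mode \code{"chord_at_-40"} or \code{"fitted_gmax"}.
#' @param contrast_adjust \code{"none"} or \code{"holm"}.
#' @param n_decoys Decoy count for the generated toy cohort.
#' @param verbose Emit per-stage messages.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(out_dir, seed = 1L, vcf_path = NULL, ped_path = NULL,
                       filter = filter_config(),
                       genotypes = c("WT", "Lys785Met", "Pro849Ser",
                                     "Pro2124Leu", "Ser2338Phe"),
                       n_cells = 16, cap_median_pf = 15, cap_cv = 0.25,
                       gmax_cv = 0.15, noise_sigma_pa = 5,
                       conductance_mode = "chord_at_-40",
                       contrast_adjust = "none", n_decoys = 10,
                       verbose = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 vcf_path = vcf_path, ped_path = ped_path, filter = filter,
                 genotypes = genotypes,
                 n_cells = setNames(rep_len(n_cells, length(genotypes)),
                                    genotypes),
                 cap_median_pf = cap_median_pf, cap_cv = cap_cv,
                 gmax_cv = gmax_cv, noise_sigma_pa = noise_sigma_pa,
                 conductance_mode = conductance_mode,
                 contrast_adjust = contrast_adjust, n_decoys = n_decoys,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full screening + electrophysiology pipeline
#'
#' Stages: (1) load (or generate) the cohort VCF/PED and run the panel
#' screen, logging each filter's input/output counts; (2) simulate
#' per-genotype recording cohorts under both voltage protocols and write
#' trace/metadata files; (3) per-cell analysis and mean-curve fits;
#' (4) per-genotype summaries and contrasts vs WT. Outputs are
#' deterministic given the seed; a manifest lists every file with its MD5
#' content hash.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with \code{outputs} (paths), \code{screen},
#'   \code{cell_params}, \code{comparisons}, \code{manifest_path}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(...)
  outputs <- character(0)

  # stage 1: variant screen
  if (is.null(config$vcf_path)) {
    fx <- make_toy_cohort(file.path(config$out_dir, "fixtures"),
                          n_decoys = config$n_decoys, seed = config$seed)
    vcf_path <- fx[["vcf"]]; ped_path <- fx[["ped"]]
    outputs <- c(outputs, fx)
  } else {
    vcf_path <- config$vcf_path
    ped_path <- if (is.null(config$ped_path)) {
      stop("ped_path must accompany vcf_path")
    } else config$ped_path
    if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  }
  cohort <- load_cohort(vcf_path, ped_path, config$filter)
  log_msg("screen: ", nrow(cohort$variants), " variants, ",
          ncol(cohort$gt), " samples in")
  screen <- screen_panel(cohort)
  log_msg("screen: ", nrow(screen$all_calls), " panel calls -> ",
          nrow(screen$dominant), " dominant, ", nrow(screen$recessive),
          " recessive out")
  screen_dir <- file.path(config$out_dir, "screen")
  outputs <- c(outputs, write_screen_report(screen, screen_dir))

  # stage 2: simulation
  spec <- cohort_spec(n_cells = config$n_cells,
                      cap_median_pf = config$cap_median_pf,
                      cap_cv = config$cap_cv, gmax_cv = config$gmax_cv,
                      noise_sigma_pa = config$noise_sigma_pa,
                      seed = config$seed)
  recs <- simulate_cohort(spec, list(activation = activation_protocol(),
                                     inactivation = inactivation_protocol()))
  log_msg("simulate: ", length(recs$activation), " cells x 2 protocols")
  ephys_dir <- file.path(config$out_dir, "ephys")
  dir.create(ephys_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- c(outputs,
               write_recordings(recs$activation,
                                file.path(ephys_dir, "activation_traces.csv"),
                                file.path(ephys_dir, "activation_meta.json")),
               write_recordings(recs$inactivation,
                                file.path(ephys_dir, "inactivation_traces.csv"),
                                file.path(ephys_dir, "inactivation_meta.json")))

  # stage 3: analysis
  cell_params <- analyze_recordings(recs$activation, recs$inactivation)
  params_path <- file.path(ephys_dir, "cell_params.tsv")
  write.table(cell_params, params_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  outputs <- c(outputs, params_path)

  mean_fits <- lapply(setNames(nm = config$genotypes), function(g) {
    cells <- Filter(function(r) r$genotype == g, recs$activation)
    fit <- fit_activation(mean_iv(lapply(cells, build_iv)))
    icurves <- lapply(Filter(function(r) r$genotype == g,
                             recs$inactivation), inactivation_curve)
    mean_curve <- icurves[[1]]
    mean_curve$i_over_imax <- rowMeans(sapply(icurves, `[[`, "i_over_imax"))
    ifit <- fit_inactivation(mean_curve)
    list(vh = fit$vh, s = fit$s, erev = fit$erev, gmax = fit$gmax,
         vi = ifit$vi, z = ifit$z)
  })

  # stage 4: group statistics
  params <- c("vh", "vi", "ttp_ms", "tau_ms", "q2_pc_pf", "q10_pc_pf",
              "q100_pc_pf",
              if (config$conductance_mode == "chord_at_-40") "g_chord"
              else "g_fitted")
  comparisons <- lapply(setNames(nm = params), function(p) {
    tryCatch(
      contrasts_vs_wt(cell_params[[p]], cell_params$genotype,
                      adjust = config$contrast_adjust, parameter = p),
      error = function(e) NULL)
  })
  summaries <- do.call(rbind, lapply(params, function(p) {
    summarize_by_genotype(cell_params[[p]], cell_params$genotype, p)
  }))
  stats_dir <- file.path(config$out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(stats_dir, "group_summaries.tsv")
  write.table(summaries, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stats_json <- file.path(stats_dir, "comparisons.json")
  jsonlite::write_json(
    list(seed = config$seed, mean_fits = mean_fits,
         comparisons = lapply(Filter(Negate(is.null), comparisons),
                              function(cr) {
                                list(anova = cr$anova,
                                     contrasts = cr$contrasts)
                              })),
    stats_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  outputs <- c(outputs, summary_path, stats_json)

  # manifest with content hashes
  manifest_path <- file.path(config$out_dir, "manifest.json")
  rel <- sub(paste0("^", normalizePath(config$out_dir), "/?"), "",
             normalizePath(unname(outputs)))
  jsonlite::write_json(
    list(seed = config$seed,
         files = setNames(as.list(unname(tools::md5sum(unname(outputs)))),
                          rel)),
    manifest_path, auto_unbox = TRUE, digits = NA)
  log_msg("manifest: ", length(outputs), " files hashed")

  invisible(list(outputs = unname(outputs), screen = screen,
                 cell_params = cell_params, comparisons = comparisons,
                 mean_fits = mean_fits, manifest_path = manifest_path))
}
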