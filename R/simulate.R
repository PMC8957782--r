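# Whole-cell current simulator. Hodgkin-Huxley-style two-gate model:
#   I(t) = C * gmax_density * m(t) * h(t) * (V(t) - Erev)   [pF * nS/pF * mV = pA]
# with first-order gates dm/dt = (m_inf - m)/tau_m, dh/dt = (h_inf - h)/tau_h.
# The command voltage is piecewise constant, so within each epoch the gate
# trajectories are exact exponentials toward their steady states; the
# simulator evaluates that closed form at the sample times (exact for this
# protocol class). Inward current is negative; units are mV, pA, ms, pF.

#' Simulate one whole-cell recording
#'
#' Gates are initialized at the holding-potential steady state at each sweep
#' start (complete inter-sweep recovery). Independent Gaussian noise of the
#' given standard deviation is added to every current sample.
#'
#' @param params A \code{\link{channel_params}}.
#' @param protocol A \code{\link{voltage_protocol}}.
#' @param capacitance Cell capacitance (pF), > 0.
#' @param noise_sigma Recording-noise standard deviation (pA).
#' @param seed Integer seed for the noise stream (\code{NULL} = do not seed).
#' @param gmax_multiplier Per-cell conductance scale factor (cell-to-cell
#'   expression variability), > 0.
#' @param cell_id Identifier stored in the recording.
#' @return A list of class \code{"cell_recording"}: \code{cell_id},
#'   \code{genotype}, \code{capacitance_pf}, \code{protocol},
#'   \code{sweeps} (data.frame \code{sweep, t_ms, v_mv, i_pa}),
#'   \code{noise_sigma_pa}, \code{seed}, \code{gmax_multiplier}.
#' @export
simulate_cell <- function(params, protocol, capacitance, noise_sigma = 0,
                          seed = NULL, gmax_multiplier = 1,
                          cell_id = params$genotype) {
  if (!is.numeric(capacitance) || capacitance <= 0) {
    stop("capacitance must be positive (pF)")
  }
  stopifnot(gmax_multiplier > 0, noise_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)

  dt <- protocol$dt_ms
  n_sweeps <- length(protocol$sweep_epochs)
  m0 <- m_inf(params, protocol$holding_mv)
  h0 <- h_inf(params, protocol$holding_mv)
  g_cell <- capacitance * params$gmax_density * gmax_multiplier

  sweep_tabs <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    eps <- protocol$sweep_epochs[[s]]
    t_all <- seq(0, sum(eps$duration_ms), by = dt)
    v_all <- numeric(length(t_all))
    m <- numeric(length(t_all)); h <- numeric(length(t_all))
    m[1] <- m0; h[1] <- h0; v_all[1] <- eps$v_mv[1]

    t_start <- 0; m_cur <- m0; h_cur <- h0
    for (e in seq_len(nrow(eps))) {
      t_end <- t_start + eps$duration_ms[e]
      vv <- eps$v_mv[e]
      idx <- which(t_all > t_start + dt / 2 & t_all <= t_end + dt / 2)
      if (length(idx) > 0) {
        rel <- t_all[idx] - t_start
        mi <- m_inf(params, vv); hi <- h_inf(params, vv)
        tm <- tau_m(params, vv); th <- tau_h(params, vv)
        m[idx] <- mi + (m_cur - mi) * exp(-rel / tm)
        h[idx] <- hi + (h_cur - hi) * exp(-rel / th)
        v_all[idx] <- vv
        m_cur <- m[idx[length(idx)]]
        h_cur <- h[idx[length(idx)]]
      }
      t_start <- t_end
    }

    i_pa <- g_cell * m * h * (v_all - params$erev)
    if (noise_sigma > 0) i_pa <- i_pa + rnorm(length(i_pa), 0, noise_sigma)
    if (any(!is.finite(i_pa))) {
      stop("non-finite current in sweep ", s, " of protocol '",
           protocol$name, "'")
    }
    sweep_tabs[[s]] <- data.frame(sweep = s, t_ms = t_all, v_mv = v_all,
                                  i_pa = i_pa)
  }

  structure(list(cell_id = cell_id, genotype = params$genotype,
                 capacitance_pf = capacitance, protocol = protocol,
                 sweeps = do.call(rbind, sweep_tabs),
                 noise_sigma_pa = noise_sigma, seed = seed,
                 gmax_multiplier = gmax_multiplier),
            class = "cell_recording")
}

#' Specification of a synthetic recording cohort
#'
#' Encodes the study conditions under which synthetic cells are drawn:
#' per-genotype gating parameters and cell counts, a log-normal capacitance
#' distribution, log-normal cell-to-cell conductance variability (mean 1),
#' and additive Gaussian recording noise.
#'
#' @param params_by_genotype Named list of \code{\link{channel_params}};
#'   defaults to the five built-in fixture genotypes.
#' @param n_cells Named integer vector of cells per genotype (names must
#'   match \code{params_by_genotype}); all >= 1.
#' @param cap_median_pf Median cell capacitance (pF).
#' @param cap_cv Coefficient of variation of capacitance (>= 0).
#' @param gmax_cv Coefficient of variation of the per-cell conductance
#'   multiplier (>= 0).
#' @param noise_sigma_pa Recording noise SD (pA).
#' @param seed Master seed; per-cell noise seeds derive from it
#'   deterministically.
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(params_by_genotype = NULL,
                        n_cells = c(WT = 16), cap_median_pf = 15,
                        cap_cv = 0.25, gmax_cv = 0.15, noise_sigma_pa = 5,
                        seed = 1L) {
  if (is.null(params_by_genotype)) {
    params_by_genotype <- lapply(setNames(nm = names(n_cells)),
                                 builtin_params)
  }
  stopifnot(all(n_cells >= 1), cap_cv >= 0, gmax_cv >= 0,
            noise_sigma_pa >= 0, cap_median_pf > 0,
            all(names(n_cells) %in% names(params_by_genotype)))
  structure(list(params_by_genotype = params_by_genotype,
                 n_cells = n_cells, cap_median_pf = cap_median_pf,
                 cap_cv = cap_cv, gmax_cv = gmax_cv,
                 noise_sigma_pa = noise_sigma_pa, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of cells
#'
#' Draws capacitances and per-cell conductance multipliers from the spec's
#' distributions and simulates each cell under the given protocol(s).
#' Reproducible: the same spec and seed yield bit-identical recordings.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param protocol A \code{\link{voltage_protocol}}, or a list of protocols
#'   (each cell is then recorded under every protocol with the same
#'   capacitance/conductance draw).
#' @return List of \code{cell_recording} objects (for a list of protocols, a
#'   named list of such lists, one per protocol).
#' @export
simulate_cohort <- function(spec, protocol = activation_protocol()) {
  multi <- !inherits(protocol, "voltage_protocol")
  protocols <- if (multi) protocol else list(protocol)
  if (is.null(names(protocols))) {
    names(protocols) <- vapply(protocols, `[[`, character(1), "name")
  }

  set.seed(spec$seed)
  draws <- list()
  for (g in names(spec$n_cells)) {
    n <- spec$n_cells[[g]]
    # log-normal with the given median and CV
    sdlog_cap <- sqrt(log(1 + spec$cap_cv^2))
    caps <- rlnorm(n, meanlog = log(spec$cap_median_pf), sdlog = sdlog_cap)
    sdlog_g <- sqrt(log(1 + spec$gmax_cv^2))
    mults <- rlnorm(n, meanlog = -sdlog_g^2 / 2, sdlog = sdlog_g)
    seeds <- sample.int(.Machine$integer.max - 16L, n)
    draws[[g]] <- data.frame(
      cell_id = sprintf("%s_%02d", g, seq_len(n)),
      capacitance = caps, mult = mults, seed = seeds,
      stringsAsFactors = FALSE)
  }

  out <- lapply(seq_along(protocols), function(pi) {
    prot <- protocols[[pi]]
    cells <- list()
    for (g in names(spec$n_cells)) {
      d <- draws[[g]]
      params <- spec$params_by_genotype[[g]]
      for (i in seq_len(nrow(d))) {
        cells[[length(cells) + 1L]] <- simulate_cell(
          params, prot, capacitance = d$capacitance[i],
          noise_sigma = spec$noise_sigma_pa,
          seed = d$seed[i] + pi - 1L,
          gmax_multiplier = d$mult[i], cell_id = d$cell_id[i])
      }
    }
    cells
  })
  names(out) <- names(protocols)
  if (multi) out else out[[1]]
}

#' Write a recording cohort as trace CSV plus metadata JSON
#'
#' Trace table columns: \code{cell_id, sweep, t_ms, v_mv, i_pa}. The
#' metadata sidecar maps cell id to capacitance, genotype, seed and noise
#' sigma.
#'
#' @param recordings List of \code{cell_recording} objects.
#' @param traces_path CSV output path.
#' @param meta_path JSON output path.
#' @return Invisibly, the two paths.
#' @export
write_recordings <- function(recordings, traces_path, meta_path) {
  tabs <- lapply(recordings, function(r) {
    cbind(cell_id = r$cell_id, r$sweeps, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, tabs), traces_path, sep = ",",
              quote = FALSE, row.names = FALSE)
  meta <- lapply(recordings, function(r) {
    list(capacitance_pf = r$capacitance_pf, genotype = r$genotype,
         seed = r$seed, noise_sigma_pa = r$noise_sigma_pa)
  })
  names(meta) <- vapply(recordings, `[[`, character(1), "cell_id")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(traces = traces_path, meta = meta_path))
}
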