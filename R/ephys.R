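# Recording analysis: peak currents, I-V relations, Boltzmann activation
# and inactivation fits, kinetics at -40 mV and charge transfer. All peak
# measurements subtract a pre-step baseline (mean current over the 10 ms
# before step onset) and skip the first two samples after onset, where real
# recordings carry capacitive transients.

sweep_table <- function(recording, s) {
  recording$sweeps[recording$sweeps$sweep == s, , drop = FALSE]
}

#' Measure the peak inward current of one sweep
#'
#' Baseline is the mean current over the \code{baseline_ms} preceding
#' \code{onset_ms}, subtracted before the search; the peak is the most
#' negative baseline-subtracted sample in the test window, excluding the
#' first \code{skip_samples} samples after onset.
#'
#' @param sweep data.frame with columns \code{t_ms}, \code{i_pa} covering
#'   the test epoch.
#' @param onset_ms Test-step onset time (ms).
#' @param end_ms End of the test epoch (ms); default = last sample.
#' @param baseline_ms Baseline window length (ms).
#' @param skip_samples Samples excluded immediately after onset.
#' @param smooth_samples Width of the centered running mean applied before
#'   the peak search (odd integer; 1 disables). Smoothing suppresses the
#'   upward bias that picking the extremum of a noisy trace would otherwise
#'   put on small peaks; T-type peaks are broad (tens of ms) so a 1 ms
#'   window leaves the true peak essentially untouched.
#' @return List: \code{peak_pa} (signed; negative = inward),
#'   \code{magnitude_pa}, \code{t_peak_ms}, \code{baseline_pa}.
#' @export
measure_peak <- function(sweep, onset_ms, end_ms = max(sweep$t_ms),
                         baseline_ms = 10, skip_samples = 2,
                         smooth_samples = 5) {
  in_test <- sweep$t_ms > onset_ms & sweep$t_ms <= end_ms
  if (!any(in_test)) stop("sweep does not cover the test epoch")
  base_idx <- sweep$t_ms > onset_ms - baseline_ms & sweep$t_ms <= onset_ms
  baseline <- if (any(base_idx)) mean(sweep$i_pa[base_idx]) else 0
  idx <- which(in_test)
  if (length(idx) > skip_samples) idx <- idx[-seq_len(skip_samples)]
  i_corr <- sweep$i_pa[idx] - baseline
  i_sm <- i_corr
  if (smooth_samples > 1 && length(i_corr) > smooth_samples) {
    sm <- stats::filter(i_corr, rep(1 / smooth_samples, smooth_samples),
                        sides = 2)
    i_sm <- ifelse(is.na(sm), i_corr, as.numeric(sm))
  }
  k <- which.min(i_sm)
  peak <- i_sm[k]
  if (peak > 0) peak <- 0  # no inward deflection
  list(peak_pa = peak, magnitude_pa = abs(peak),
       t_peak_ms = sweep$t_ms[idx[k]], baseline_pa = baseline)
}

#' Build the peak current-voltage relation of one cell
#'
#' One entry per protocol test potential: baseline-subtracted peak inward
#' current (pA) and current density (pA/pF, peak normalized by the cell
#' capacitance).
#'
#' @param recording A \code{cell_recording} under an activation protocol.
#' @return data.frame of class \code{"iv_curve"}: \code{v_mv, peak_pa,
#'   density_pa_pf}, with attributes \code{cell_id}, \code{capacitance_pf},
#'   \code{n} (= 1).
#' @export
build_iv <- function(recording) {
  prot <- recording$protocol
  if (recording$capacitance_pf <= 0) stop("capacitance must be positive")
  peaks <- vapply(seq_along(prot$sweep_epochs), function(s) {
    measure_peak(sweep_table(recording, s), prot$test_onset_ms,
                 prot$test_end_ms)$peak_pa
  }, numeric(1))
  out <- data.frame(v_mv = prot$step_voltages, peak_pa = peaks,
                    density_pa_pf = peaks / recording$capacitance_pf)
  structure(out, class = c("iv_curve", "data.frame"),
            cell_id = recording$cell_id,
            capacitance_pf = recording$capacitance_pf, n = 1L)
}

#' Average I-V curves across cells
#'
#' Averages current densities per test potential (mean +/- SEM across
#' cells); all curves must share the same voltage grid.
#'
#' @param curves List of \code{\link{build_iv}} results.
#' @return data.frame of class \code{"iv_curve"}: \code{v_mv, peak_pa,
#'   density_pa_pf, sem_pa_pf}, with attributes \code{cell_id = "mean"},
#'   \code{n}.
#' @export
mean_iv <- function(curves) {
  stopifnot(length(curves) >= 1)
  v <- curves[[1]]$v_mv
  for (cu in curves) stopifnot(identical(cu$v_mv, v))
  dens <- sapply(curves, `[[`, "density_pa_pf")
  peaks <- sapply(curves, `[[`, "peak_pa")
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(v))
  if (is.null(dim(peaks))) peaks <- matrix(peaks, nrow = length(v))
  n <- ncol(dens)
  sem <- if (n >= 2) apply(dens, 1, sd) / sqrt(n) else rep(NA_real_, length(v))
  out <- data.frame(v_mv = v, peak_pa = rowMeans(peaks),
                    density_pa_pf = rowMeans(dens), sem_pa_pf = sem)
  structure(out, class = c("iv_curve", "data.frame"), cell_id = "mean",
            n = n)
}

boltzmann_iv <- function(v, erev, gmax, vh, s) {
  (v - erev) * gmax / (1 + exp((vh - v) / s))
}

#' Fit the modified Boltzmann equation to an I-V relation
#'
#' Least-squares fit of
#' \deqn{I_{peak}(V) = (V - E_{rev}) \, G_{max} \, / \,
#'   (1 + \exp((V_h - V)/S))}
#' to the current-density-voltage relation. Starting values: Erev = +30 mV,
#' Vh at the voltage of half-maximal chord conductance, S = 5 mV, Gmax from
#' the maximal chord conductance; bounds Erev in [0, 80], Vh in [-90, 0],
#' S in [1, 15] mV, Gmax > 0. The fit is flagged unconverged when the
#' optimizer fails or a parameter sits at a bound.
#'
#' @param iv An \code{\link{build_iv}}/\code{\link{mean_iv}} curve with at
#'   least 6 voltage points.
#' @param on Fit target column, \code{"density_pa_pf"} (default) or
#'   \code{"peak_pa"}.
#' @return List of class \code{"activation_fit"}: \code{erev, gmax, vh, s,
#'   rss, converged, n_points} (gmax in conductance-density units, nS/pF,
#'   when fit on densities).
#' @export
fit_activation <- function(iv, on = "density_pa_pf") {
  v <- iv$v_mv
  y <- iv[[on]]
  keep <- is.finite(v) & is.finite(y)
  v <- v[keep]; y <- y[keep]
  if (length(v) < 6) {
    stop("fit_activation needs at least 6 voltage points, got ", length(v))
  }

  erev0 <- 30
  chord <- ifelse(abs(v - erev0) < 1e-9, NA, y / (v - erev0))
  chord[chord < 0] <- 0
  gmax0 <- max(chord, na.rm = TRUE)
  if (!is.finite(gmax0) || gmax0 <= 0) gmax0 <- 1e-3
  half <- which(chord >= gmax0 / 2)[1]
  vh0 <- if (is.na(half)) -45 else v[half]
  vh0 <- min(max(vh0, -89), -1)

  lower <- c(erev = 0, gmax = 1e-9, vh = -90, s = 1)
  upper <- c(erev = 80, gmax = Inf, vh = 0, s = 15)
  dat <- data.frame(v = v, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (v - erev) * gmax / (1 + exp((vh - v) / s)), data = dat,
      start = list(erev = erev0, gmax = gmax0, vh = vh0, s = 5),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(erev = NA_real_, gmax = NA_real_, vh = NA_real_,
                          s = NA_real_, rss = NA_real_, converged = FALSE,
                          n_points = length(v)),
                     class = "activation_fit"))
  }
  cf <- coef(fit)
  at_bound <- function(par, eps = 1e-6) {
    lo <- lower[par]; hi <- upper[par]
    (is.finite(lo) && abs(cf[par] - lo) < eps) ||
      (is.finite(hi) && abs(cf[par] - hi) < eps)
  }
  sane <- cf["vh"] >= -90 && cf["vh"] <= 0 && cf["erev"] >= 0 &&
    cf["erev"] <= 80 && !at_bound("vh") && !at_bound("erev") &&
    !at_bound("s")
  structure(list(erev = unname(cf["erev"]), gmax = unname(cf["gmax"]),
                 vh = unname(cf["vh"]), s = unname(cf["s"]),
                 rss = sum(residuals(fit)^2),
                 converged = isTRUE(sane), n_points = length(v)),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf(
    "<activation_fit> Vh %.2f mV, S %.2f mV, Erev %.1f mV, Gmax %.4g (rss %.3g, %s)\n",
    x$vh, x$s, x$erev, x$gmax, x$rss,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Normalized activation (conductance) curve
#'
#' Chord conductance G(V) = density(V)/(V - Erev) normalized by the fitted
#' Gmax. Test potentials within 2 mV of the reversal potential are excluded
#' (attribute \code{excluded_v}). The fitted curve equals 0.5 at V = Vh.
#'
#' @param iv An I-V curve (densities).
#' @param fit A converged \code{\link{fit_activation}} result.
#' @return data.frame \code{v_mv, g_norm} with attributes \code{fit} and
#'   \code{excluded_v}; the fitted Boltzmann is available as
#'   \code{attr(, "curve")}, a function of voltage.
#' @export
normalize_activation <- function(iv, fit) {
  if (!isTRUE(fit$converged)) stop("activation fit did not converge")
  keep <- abs(iv$v_mv - fit$erev) >= 2
  v <- iv$v_mv[keep]
  g <- iv$density_pa_pf[keep] / (v - fit$erev)
  out <- data.frame(v_mv = v, g_norm = g / fit$gmax)
  structure(out, fit = fit, excluded_v = iv$v_mv[!keep],
            curve = function(vv) 1 / (1 + exp((fit$vh - vv) / fit$s)))
}

#' Steady-state inactivation curve of one cell
#'
#' Peak inward current at the -40 mV test pulse for each conditioning
#' potential, normalized by the maximal peak over sweeps (I/Imax). Peaks
#' are referenced to the holding-epoch baseline rather than the 10 ms
#' preceding the test pulse: at depolarized conditioning potentials the
#' channel carries a steady window current, which a pre-test baseline
#' would wrongly subtract from the peak.
#'
#' @param recording A \code{cell_recording} under an inactivation protocol.
#' @return data.frame: \code{v_mv} (conditioning potential),
#'   \code{peak_pa}, \code{i_over_imax}.
#' @export
inactivation_curve <- function(recording) {
  prot <- recording$protocol
  peaks <- vapply(seq_along(prot$sweep_epochs), function(s) {
    sw <- sweep_table(recording, s)
    hold_end <- prot$sweep_epochs[[s]]$duration_ms[1]
    base <- mean(sw$i_pa[sw$t_ms <= hold_end])
    sw$i_pa <- sw$i_pa - base
    measure_peak(sw, prot$test_onset_ms, prot$test_end_ms,
                 baseline_ms = 0)$magnitude_pa
  }, numeric(1))
  imax <- max(peaks)
  if (imax == 0) stop("no inward current at the test pulse (Imax = 0)")
  data.frame(v_mv = prot$step_voltages, peak_pa = -peaks,
             i_over_imax = peaks / imax)
}

#' Fit the steady-state inactivation Boltzmann
#'
#' Two-parameter least-squares fit of
#' \deqn{I/I_{max} = 1 / (1 + \exp(z (V - V_i)/25.6))}
#' with the thermal scale fixed at 25.6 mV. Accepts either a
#' \code{cell_recording} under the inactivation protocol (the I/Imax curve
#' is computed first) or a data.frame with columns \code{v_mv},
#' \code{i_over_imax} (e.g. a mean curve across cells).
#'
#' @param x Recording or curve data.frame.
#' @param ... Unused.
#' @return List of class \code{"inactivation_fit"}: \code{vi, z, rss,
#'   converged, thermal_mv} (= 25.6).
#' @export
fit_inactivation <- function(x, ...) UseMethod("fit_inactivation")

#' @export
fit_inactivation.cell_recording <- function(x, ...) {
  fit_inactivation(inactivation_curve(x))
}

#' @export
fit_inactivation.data.frame <- function(x, ...) {
  v <- x$v_mv
  y <- x$i_over_imax
  stopifnot(length(v) >= 3)
  vh0 <- approx_midpoint(v, y)
  lower <- c(vi = min(v) - 20, z = 0.1)
  upper <- c(vi = max(v) + 20, z = 40)
  dat <- data.frame(v = v, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(z * (v - vi) / 25.6)), data = dat,
                      start = list(vi = vh0, z = 4),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(vi = NA_real_, z = NA_real_, rss = NA_real_,
                          converged = FALSE, thermal_mv = THERMAL_MV),
                     class = "inactivation_fit"))
  }
  cf <- coef(fit)
  sane <- cf["z"] > 0 && cf["vi"] > lower["vi"] + 1e-6 &&
    cf["vi"] < upper["vi"] - 1e-6
  structure(list(vi = unname(cf["vi"]), z = unname(cf["z"]),
                 rss = sum(residuals(fit)^2), converged = isTRUE(sane),
                 thermal_mv = THERMAL_MV),
            class = "inactivation_fit")
}

approx_midpoint <- function(v, y) {
  ord <- order(v)
  v <- v[ord]; y <- y[ord]
  below <- which(y <= 0.5)[1]
  if (is.na(below) || below == 1) return(median(v))
  y1 <- y[below - 1]; y2 <- y[below]
  v1 <- v[below - 1]; v2 <- v[below]
  if (y1 == y2) return((v1 + v2) / 2)
  v1 + (0.5 - y1) * (v2 - v1) / (y2 - y1)
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("<inactivation_fit> Vi %.2f mV, z %.2f (rss %.3g, %s)\n",
              x$vi, x$z, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Current kinetics at the test pulse
#'
#' Time to peak is measured from the test-step onset to the peak inward
#' current; the decay is fitted with a single exponential
#' \eqn{A \exp(-(t - t_{peak})/\tau) + C} on the baseline-subtracted
#' current from the peak sample to the end of the test epoch. When the peak
#' falls at the end of the epoch (no decay phase) tau is absent and
#' flagged.
#'
#' @param sweep data.frame \code{t_ms}, \code{i_pa}.
#' @param onset_ms,end_ms Test-epoch bounds (ms).
#' @return List of class \code{"kinetics"}: \code{time_to_peak_ms},
#'   \code{tau_decay_ms}, \code{amplitude_pa}, \code{offset_pa},
#'   \code{decay_fitted} (logical), \code{peak_pa}.
#' @export
measure_kinetics <- function(sweep, onset_ms, end_ms = max(sweep$t_ms)) {
  pk <- measure_peak(sweep, onset_ms, end_ms)
  ttp <- pk$t_peak_ms - onset_ms

  decay_idx <- which(sweep$t_ms >= pk$t_peak_ms & sweep$t_ms <= end_ms)
  out <- list(time_to_peak_ms = ttp, tau_decay_ms = NA_real_,
              amplitude_pa = NA_real_, offset_pa = NA_real_,
              decay_fitted = FALSE, peak_pa = pk$peak_pa)
  # need a real decay phase: at least 10 samples and 5% of the epoch left
  if (length(decay_idx) < 10 ||
      (end_ms - pk$t_peak_ms) < 0.05 * (end_ms - onset_ms)) {
    class(out) <- "kinetics"
    return(out)
  }
  t_rel <- sweep$t_ms[decay_idx] - pk$t_peak_ms
  y <- sweep$i_pa[decay_idx] - pk$baseline_pa
  a0 <- y[1] - y[length(y)]
  tau0 <- max((end_ms - pk$t_peak_ms) / 3, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t_rel / tau) + C,
                      data = data.frame(t_rel = t_rel, y = y),
                      start = list(A = a0, tau = tau0, C = y[length(y)]),
                      lower = c(A = -Inf, tau = 1e-3, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    out$tau_decay_ms <- unname(cf["tau"])
    out$amplitude_pa <- unname(cf["A"])
    out$offset_pa <- unname(cf["C"])
    out$decay_fitted <- TRUE
  }
  class(out) <- "kinetics"
  out
}

#' Charge transfer during a depolarizing step
#'
#' Trapezoidal integral of the baseline-subtracted inward current magnitude
#' from step onset to each requested time point; a proxy for total calcium
#' entry. Reported in pC, and pC/pF when a capacitance is supplied.
#'
#' @param sweep data.frame \code{t_ms}, \code{i_pa}.
#' @param onset_ms Step onset (ms).
#' @param times_ms Integration endpoints, ms after onset.
#' @param capacitance_pf Optional cell capacitance for normalization.
#' @return data.frame of class \code{"charge_transfer"}: \code{t_ms, q_pc,
#'   q_pc_pf}.
#' @export
charge_transfer <- function(sweep, onset_ms, times_ms = c(2, 10, 100),
                            capacitance_pf = NULL) {
  base_idx <- sweep$t_ms > onset_ms - 10 & sweep$t_ms < onset_ms
  baseline <- if (any(base_idx)) mean(sweep$i_pa[base_idx]) else 0
  inward <- pmax(0, -(sweep$i_pa - baseline))  # pA, inward magnitude

  q <- vapply(times_ms, function(T_ms) {
    t_end <- onset_ms + T_ms
    idx <- which(sweep$t_ms >= onset_ms & sweep$t_ms <= t_end)
    if (length(idx) < 2) return(0)
    tt <- sweep$t_ms[idx]; yy <- inward[idx]
    qq <- pracma::trapz(tt, yy)
    # partial trailing interval when the endpoint is off the sample grid
    if (max(tt) < t_end) {
      nxt <- idx[length(idx)] + 1L
      if (nxt <= nrow(sweep)) {
        y_end <- approx(sweep$t_ms[c(nxt - 1L, nxt)],
                        inward[c(nxt - 1L, nxt)], xout = t_end)$y
        qq <- qq + (t_end - max(tt)) * (yy[length(yy)] + y_end) / 2
      }
    }
    qq / 1000  # pA*ms -> pC
  }, numeric(1))

  out <- data.frame(t_ms = times_ms, q_pc = q,
                    q_pc_pf = if (is.null(capacitance_pf)) NA_real_
                              else q / capacitance_pf)
  class(out) <- c("charge_transfer", "data.frame")
  out
}

#' Conductance density of one cell
#'
#' Two definitions are exposed: the chord conductance at the -40 mV test
#' potential, density(-40)/(-40 - Erev), and the fitted Gmax of the
#' activation Boltzmann (both in nS/pF when computed on densities).
#'
#' @param iv An I-V curve (densities) containing a -40 mV point (chord
#'   mode).
#' @param fit An \code{\link{fit_activation}} result (source of Erev, and
#'   of Gmax in fitted mode).
#' @param mode \code{"chord_at_-40"} or \code{"fitted_gmax"}.
#' @param erev Optional reversal-potential override for chord mode.
#' @param at_mv Chord voltage (default -40).
#' @return Scalar conductance density (nS/pF).
#' @export
conductance_density <- function(iv = NULL, fit = NULL,
                                mode = c("chord_at_-40", "fitted_gmax"),
                                erev = NULL, at_mv = -40) {
  mode <- match.arg(mode)
  if (mode == "fitted_gmax") {
    stopifnot(!is.null(fit))
    return(fit$gmax)
  }
  stopifnot(!is.null(iv))
  if (is.null(erev)) {
    stopifnot(!is.null(fit))
    erev <- fit$erev
  }
  k <- which(abs(iv$v_mv - at_mv) < 1e-9)
  if (length(k) != 1) stop("I-V curve has no ", at_mv, " mV point")
  iv$density_pa_pf[k] / (at_mv - erev)
}

#' Per-cell electrophysiological parameter table
#'
#' Convenience wrapper running the full single-cell analysis over a cohort:
#' activation fit (Vh, S, Erev, Gmax), inactivation fit (Vi, z), kinetics
#' and charge transfer at the -40 mV test potential, and both conductance-
#' density definitions.
#'
#' @param act_recordings List of recordings under the activation protocol.
#' @param inact_recordings Optional list of recordings (same cells) under
#'   the inactivation protocol.
#' @return data.frame, one row per cell: \code{cell_id, genotype,
#'   capacitance_pf, vh, s, erev, gmax, vi, z, ttp_ms, tau_ms, q2_pc_pf,
#'   q10_pc_pf, q100_pc_pf, g_chord, g_fitted}.
#' @export
analyze_recordings <- function(act_recordings, inact_recordings = NULL) {
  inact_by_cell <- list()
  if (!is.null(inact_recordings)) {
    names(inact_recordings) <- vapply(inact_recordings, `[[`,
                                      character(1), "cell_id")
    inact_by_cell <- inact_recordings
  }
  rows <- lapply(act_recordings, function(r) {
    iv <- build_iv(r)
    fit <- fit_activation(iv)
    prot <- r$protocol
    s40 <- match(-40, prot$step_voltages)
    ttp <- tau <- NA_real_
    q <- rep(NA_real_, 3)
    if (!is.na(s40)) {
      sw <- sweep_table(r, s40)
      kin <- measure_kinetics(sw, prot$test_onset_ms, prot$test_end_ms)
      ttp <- kin$time_to_peak_ms; tau <- kin$tau_decay_ms
      q <- charge_transfer(sw, prot$test_onset_ms,
                           capacitance_pf = r$capacitance_pf)$q_pc_pf
    }
    vi <- z <- NA_real_
    ir <- inact_by_cell[[r$cell_id]]
    if (!is.null(ir)) {
      ifit <- fit_inactivation(ir)
      vi <- ifit$vi; z <- ifit$z
    }
    g_chord <- if (isTRUE(fit$converged) && !is.na(s40)) {
      conductance_density(iv, fit, mode = "chord_at_-40")
    } else NA_real_
    data.frame(cell_id = r$cell_id, genotype = r$genotype,
               capacitance_pf = r$capacitance_pf,
               vh = fit$vh, s = fit$s, erev = fit$erev, gmax = fit$gmax,
               vi = vi, z = z, ttp_ms = ttp, tau_ms = tau,
               q2_pc_pf = q[1], q10_pc_pf = q[2], q100_pc_pf = q[3],
               g_chord = g_chord, g_fitted = fit$gmax,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
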