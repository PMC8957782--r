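# Voltage-clamp protocols. Command voltages are piecewise constant; each
# sweep starts from the holding steady state (the 10 s inter-sweep recovery
# is modeled as exact re-equilibration).

#' Construct a voltage protocol
#'
#' @param name Protocol label.
#' @param holding_mv Holding potential (mV).
#' @param sweep_epochs List (one element per sweep) of data.frames with
#'   columns \code{duration_ms}, \code{v_mv}; all sweeps must share the
#'   same epoch structure (same number and durations of epochs).
#' @param dt_ms Sampling interval (ms); 0.2 ms matches 5 kHz digitization.
#' @param test_epoch Index of the epoch in which currents are measured.
#' @param step_voltages Per-sweep label voltage (the test potential for an
#'   activation protocol, the conditioning potential for an inactivation
#'   protocol).
#' @return A list of class \code{"voltage_protocol"} with the above fields
#'   plus \code{test_onset_ms} / \code{test_end_ms} derived from the epochs.
#' @export
voltage_protocol <- function(name, holding_mv, sweep_epochs, dt_ms = 0.2,
                             test_epoch = length(sweep_epochs[[1]]$duration_ms),
                             step_voltages = NULL) {
  stopifnot(length(sweep_epochs) >= 1, dt_ms > 0)
  durs <- sweep_epochs[[1]]$duration_ms
  for (ep in sweep_epochs) {
    stopifnot(all(ep$duration_ms > 0), identical(ep$duration_ms, durs))
  }
  bounds <- cumsum(durs)
  structure(list(name = name, holding_mv = holding_mv,
                 sweep_epochs = sweep_epochs, dt_ms = dt_ms,
                 test_epoch = test_epoch,
                 test_onset_ms = if (test_epoch == 1) 0
                                 else bounds[test_epoch - 1],
                 test_end_ms = bounds[test_epoch],
                 total_ms = bounds[length(bounds)],
                 step_voltages = step_voltages),
            class = "voltage_protocol")
}

#' Current-voltage (activation) protocol
#'
#' From a holding potential of -120 mV, steps to test potentials from
#' -110 mV to +20 mV in 10 mV increments (14 sweeps), each 100 ms in
#' duration, preceded by a baseline epoch at holding. The membrane returns
#' to holding between sweeps long enough for complete recovery from
#' inactivation, modeled as exact re-equilibration.
#'
#' @param holding_mv Holding potential (mV).
#' @param test_from,test_to,test_by Test-potential range and increment (mV).
#' @param test_ms Test-epoch duration (ms).
#' @param baseline_ms Pre-step baseline epoch at holding (ms).
#' @param dt_ms Sampling interval (ms).
#' @return A \code{\link{voltage_protocol}}.
#' @export
activation_protocol <- function(holding_mv = -120, test_from = -110,
                                test_to = 20, test_by = 10, test_ms = 100,
                                baseline_ms = 20, dt_ms = 0.2) {
  stopifnot(baseline_ms >= 20)
  tests <- seq(test_from, test_to, by = test_by)
  epochs <- lapply(tests, function(v) {
    data.frame(duration_ms = c(baseline_ms, test_ms),
               v_mv = c(holding_mv, v))
  })
  voltage_protocol("activation", holding_mv, epochs, dt_ms,
                   test_epoch = 2, step_voltages = tests)
}

#' Steady-state inactivation protocol
#'
#' From -120 mV holding, applies 1 s conditioning potentials from -120 to
#' -60 mV in 10 mV increments (7 sweeps) followed by a 100 ms test pulse to
#' -40 mV, from which peak currents are measured.
#'
#' @param holding_mv Holding potential (mV).
#' @param cond_from,cond_to,cond_by Conditioning-potential range and
#'   increment (mV).
#' @param cond_ms Conditioning duration (ms).
#' @param test_mv,test_ms Test-pulse voltage (mV) and duration (ms).
#' @param baseline_ms Pre-conditioning baseline at holding (ms).
#' @param dt_ms Sampling interval (ms).
#' @return A \code{\link{voltage_protocol}}.
#' @export
inactivation_protocol <- function(holding_mv = -120, cond_from = -120,
                                  cond_to = -60, cond_by = 10,
                                  cond_ms = 1000, test_mv = -40,
                                  test_ms = 100, baseline_ms = 20,
                                  dt_ms = 0.2) {
  conds <- seq(cond_from, cond_to, by = cond_by)
  epochs <- lapply(conds, function(v) {
    data.frame(duration_ms = c(baseline_ms, cond_ms, test_ms),
               v_mv = c(holding_mv, v, test_mv))
  })
  voltage_protocol("inactivation", holding_mv, epochs, dt_ms,
                   test_epoch = 3, step_voltages = conds)
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol '%s'>\n", x$name))
  cat(sprintf("  holding %g mV, %d sweeps, dt %g ms\n", x$holding_mv,
              length(x$sweep_epochs), x$dt_ms))
  cat(sprintf("  test epoch %d: %g-%g ms\n", x$test_epoch, x$test_onset_ms,
              x$test_end_ms))
  if (!is.null(x$step_voltages)) {
    cat("  step voltages:", paste(x$step_voltages, collapse = ", "), "mV\n")
  }
  invisible(x)
}
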