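# Genotype-specific gating parameter sets. The steady-state curves use the
# same functional forms the analysis fits: activation
# m_inf(V) = 1/(1 + exp((vh_act - V)/s_act)) and inactivation
# h_inf(V) = 1/(1 + exp(z_inact (V - vi_inact)/25.6)), with the thermal
# scale fixed at 25.6 mV. Time constants are positive bell-shaped functions
# of voltage (baseline + Gaussian bump).

THERMAL_MV <- 25.6

#' Gating/conductance parameter set for one channel genotype
#'
#' @param genotype Genotype label.
#' @param gmax_density Maximal conductance density (nS/pF), > 0.
#' @param erev Reversal potential (mV).
#' @param vh_act Half-activation voltage (mV).
#' @param s_act Activation slope factor (mV), > 0.
#' @param vi_inact Half-inactivation voltage (mV).
#' @param z_inact Effective inactivation gating charge (dimensionless), > 0.
#' @param tau_m_params,tau_h_params Numeric length-4 vectors
#'   \code{c(base, amp, vmid, width)} (ms, ms, mV, mV) of the bell-shaped
#'   voltage-dependent time constants
#'   \code{tau(V) = base + amp * exp(-((V - vmid)/width)^2)}; must be
#'   strictly positive over [-120, +20] mV.
#' @return A list of class \code{"channel_params"}.
#' @export
channel_params <- function(genotype, gmax_density, erev, vh_act, s_act,
                           vi_inact, z_inact, tau_m_params, tau_h_params) {
  stopifnot(gmax_density > 0, s_act > 0, z_inact > 0,
            length(tau_m_params) == 4, length(tau_h_params) == 4)
  vgrid <- seq(-120, 20, by = 1)
  if (any(tau_bell(vgrid, tau_m_params) <= 0) ||
      any(tau_bell(vgrid, tau_h_params) <= 0)) {
    stop("time-constant functions must be strictly positive over ",
         "[-120, +20] mV")
  }
  structure(list(genotype = genotype, gmax_density = gmax_density,
                 erev = erev, vh_act = vh_act, s_act = s_act,
                 vi_inact = vi_inact, z_inact = z_inact,
                 tau_m_params = tau_m_params, tau_h_params = tau_h_params),
            class = "channel_params")
}

tau_bell <- function(v, p) p[1] + p[2] * exp(-((v - p[3]) / p[4])^2)

#' Steady-state activation and inactivation
#'
#' @param params A \code{\link{channel_params}}.
#' @param v Voltage(s), mV.
#' @return Open probability of the respective gate in [0, 1].
#' @export
m_inf <- function(params, v) {
  1 / (1 + exp((params$vh_act - v) / params$s_act))
}

#' @rdname m_inf
#' @export
h_inf <- function(params, v) {
  1 / (1 + exp(params$z_inact * (v - params$vi_inact) / THERMAL_MV))
}

#' Voltage-dependent gating time constants
#'
#' @param params A \code{\link{channel_params}}.
#' @param v Voltage(s), mV.
#' @return Time constant(s), ms.
#' @export
tau_m <- function(params, v) tau_bell(v, params$tau_m_params)

#' @rdname tau_m
#' @export
tau_h <- function(params, v) tau_bell(v, params$tau_h_params)

# Built-in fixture parameter sets. Vh/Vi midpoints are the per-genotype
# fitted values from whole-cell characterization of the four Cav3.2
# variants; conductance, reversal potential, slopes and kinetics are
# simulator conventions (see the methods vignette). tau_h is a fixed
# multiple of tau_m per genotype (same bell shape), which keeps the peak of
# m*h proportional to m_inf across voltages and the round-trip Vh recovery
# unbiased. Kinetic scaling: Lys785Met and Ser2338Phe carry a 1.5x slower
# tau_m; Pro849Ser a faster tau_h (faster decay) and a 3x slower tau_m, so
# its time to peak stays detectably slower than WT despite the quicker
# decay (magnitudes sized by power analysis at the reported cell counts).
BUILTIN_PARAMS <- list(
  WT = list(gmax = 1.0, vh = -45.5, vi = -78.9,
            tau_m = c(2, 10, -60, 30), tau_h = c(6, 30, -60, 30)),
  Lys785Met = list(gmax = 1.6, vh = -50.1, vi = -77.1,
                   tau_m = c(3, 15, -60, 30), tau_h = c(6, 30, -60, 30)),
  Pro849Ser = list(gmax = 1.0, vh = -49.5, vi = -75.3,
                   tau_m = c(6, 30, -60, 30), tau_h = c(4.32, 21.6, -60, 30)),
  Pro2124Leu = list(gmax = 1.0, vh = -49.3, vi = -79.5,
                    tau_m = c(2, 10, -60, 30), tau_h = c(6, 30, -60, 30)),
  Ser2338Phe = list(gmax = 1.0, vh = -43.4, vi = -78.2,
                    tau_m = c(3, 15, -60, 30), tau_h = c(6, 30, -60, 30)))

#' Built-in fixture parameter sets per genotype
#'
#' Returns the parameter set for the wild-type channel or one of the four
#' characterized variants. Half-activation (\code{vh_act}) and
#' half-inactivation (\code{vi_inact}) voltages equal the fitted values for
#' each genotype: Vh -45.5 (WT), -50.1 (Lys785Met), -49.5 (Pro849Ser),
#' -49.3 (Pro2124Leu), -43.4 (Ser2338Phe) mV; Vi -78.9 (WT), -77.1
#' (Lys785Met), -75.3 (Pro849Ser), -79.5 (Pro2124Leu), -78.2 (Ser2338Phe)
#' mV. Lys785Met carries an elevated conductance density (1.6 vs 1.0
#' nS/pF, a gain of function); Ser2338Phe, Pro849Ser and Lys785Met have
#' slowed activation kinetics (longer time to peak at -40 mV) and
#' Pro849Ser a faster decay. Erev (+30 mV), slope factors (S = 5 mV,
#' z = 4) and kinetic magnitudes are fixture conventions.
#'
#' @param genotype One of \code{"WT"}, \code{"Lys785Met"},
#'   \code{"Pro849Ser"}, \code{"Pro2124Leu"}, \code{"Ser2338Phe"}.
#' @return A \code{\link{channel_params}}.
#' @export
builtin_params <- function(genotype) {
  if (!genotype %in% names(BUILTIN_PARAMS)) {
    stop("unknown genotype '", genotype, "'; valid labels: ",
         paste(names(BUILTIN_PARAMS), collapse = ", "))
  }
  p <- BUILTIN_PARAMS[[genotype]]
  channel_params(genotype = genotype, gmax_density = p$gmax, erev = 30,
                 vh_act = p$vh, s_act = 5, vi_inact = p$vi, z_inact = 4,
                 tau_m_params = p$tau_m, tau_h_params = p$tau_h)
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf("<channel_params '%s'>\n", x$genotype))
  cat(sprintf("  gmax %g nS/pF, Erev %g mV\n", x$gmax_density, x$erev))
  cat(sprintf("  activation: Vh %g mV, S %g mV\n", x$vh_act, x$s_act))
  cat(sprintf("  inactivation: Vi %g mV, z %g (thermal scale %g mV)\n",
              x$vi_inact, x$z_inact, THERMAL_MV))
  invisible(x)
}
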