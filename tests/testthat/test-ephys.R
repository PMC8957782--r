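# Synthetic sweeps for the measurement primitives: 10 ms baseline at -120,
# then a 100 ms test epoch, sampled at 0.2 ms.
flat_sweep <- function(level = 0, baseline = 0, onset = 10, end = 110,
                       dt = 0.2) {
  t <- seq(0, end, by = dt)
  data.frame(t_ms = t, i_pa = ifelse(t > onset, level + baseline, baseline))
}

test_that("peak measurement subtracts baseline and ignores outward noise", {
  zero <- flat_sweep(0)
  expect_equal(measure_peak(zero, 10)$peak_pa, 0)
  # constant baseline offset is removed entirely
  offset <- flat_sweep(0, baseline = -5)
  expect_equal(measure_peak(offset, 10)$peak_pa, 0)
  # a genuine inward step is measured relative to baseline
  step <- flat_sweep(-100, baseline = -5)
  expect_equal(measure_peak(step, 10)$peak_pa, -100)
  expect_error(measure_peak(zero, 200), "test epoch")
})

test_that("current density is peak over capacitance", {
  wt <- builtin_params("WT")
  r <- simulate_cell(wt, activation_protocol(), capacitance = 15,
                     noise_sigma = 0)
  iv <- build_iv(r)
  expect_equal(nrow(iv), 14)
  expect_equal(iv$density_pa_pf, iv$peak_pa / 15)
  # -300 pA at 15 pF -> -20 pA/pF
  expect_equal(-300 / 15, -20)
  curves <- list(iv, iv, iv)
  m <- mean_iv(curves)
  expect_equal(m$density_pa_pf, iv$density_pa_pf)
  expect_equal(m$sem_pa_pf, rep(0, nrow(iv)))
  expect_identical(attr(m, "cell_id"), "mean")
})

test_that("activation fit recovers exact Boltzmann points to 1e-6", {
  v <- seq(-110, 20, by = 10)
  y <- (v - 30) * 1 / (1 + exp((-45.5 - v) / 5))
  iv <- data.frame(v_mv = v, density_pa_pf = y)
  fit <- fit_activation(iv)
  expect_true(fit$converged)
  expect_equal(fit$erev, 30, tolerance = 1e-6)
  expect_equal(fit$gmax, 1, tolerance = 1e-6)
  expect_equal(fit$vh, -45.5, tolerance = 1e-6)
  expect_equal(fit$s, 5, tolerance = 1e-6)
  expect_error(fit_activation(iv[1:4, ]), "at least 6")
})

test_that("optimizer RSS beats or matches the lattice-search oracle", {
  set.seed(21)
  spec <- cohort_spec(n_cells = c(WT = 6), seed = 21)
  cells <- simulate_cohort(spec)
  iv <- mean_iv(lapply(cells, build_iv))
  fit <- fit_activation(iv)
  expect_true(fit$converged)
  grid_rss <- grid_fit_rss(iv)
  expect_lte(fit$rss, 1.01 * grid_rss)
})

test_that("normalized activation equals 0.5 at Vh and saturates at 1", {
  v <- seq(-110, 20, by = 10)
  y <- (v - 30) * 2 / (1 + exp((-45.5 - v) / 5))
  iv <- data.frame(v_mv = v, density_pa_pf = y)
  fit <- fit_activation(iv)
  curve <- attr(normalize_activation(iv, fit), "curve")
  expect_equal(curve(fit$vh), 0.5)
  expect_equal(curve(fit$vh + 100), 1, tolerance = 1e-8)
  # analytic value at -50 mV for the WT fixture midpoint and slope
  expect_equal(curve(-50), 1 / (1 + exp((-45.5 + 50) / 5)),
               tolerance = 1e-6)
  norm <- normalize_activation(iv, fit)
  expect_true(all(norm$g_norm > -0.1 & norm$g_norm < 1.1))
})

test_that("inactivation fit recovers exact curve parameters to 1e-6", {
  v <- seq(-120, -60, by = 10)
  y <- 1 / (1 + exp(4 * (v + 78.9) / 25.6))
  fit <- fit_inactivation(data.frame(v_mv = v, i_over_imax = y))
  expect_true(fit$converged)
  expect_equal(fit$vi, -78.9, tolerance = 1e-6)
  expect_equal(fit$z, 4, tolerance = 1e-6)
  expect_equal(fit$thermal_mv, 25.6)
})

test_that("the fully available conditioning sweep defines I/Imax = 1", {
  wt <- builtin_params("WT")
  r <- simulate_cell(wt, inactivation_protocol(), 15, 0)
  ic <- inactivation_curve(r)
  expect_equal(ic$i_over_imax[ic$v_mv == -120], 1)
  expect_true(all(diff(ic$i_over_imax) <= 1e-9))  # monotone availability
})

test_that("kinetics: decay tau matches tau_h in the fast-activation limit", {
  # tau_m << tau_h so the decay is governed by h alone
  p <- channel_params("fastm", gmax_density = 1, erev = 30, vh_act = -45.5,
                      s_act = 5, vi_inact = -78.9, z_inact = 4,
                      tau_m_params = c(0.4, 0, -60, 30),
                      tau_h_params = c(25, 0, -60, 30))
  prot <- activation_protocol(test_from = -40, test_to = -40)
  r <- simulate_cell(p, prot, 15, 0)
  k <- measure_kinetics(r$sweeps, prot$test_onset_ms, prot$test_end_ms)
  expect_true(k$decay_fitted)
  expect_equal(k$tau_decay_ms, 25, tolerance = 0.05)
  # time of peak agrees with the fine-step oracle within one sample
  skip_if_not_installed("deSolve")
  oracle <- ode_peak_oracle(p, -40, 15)
  expect_lt(abs(k$time_to_peak_ms - oracle$t_peak_ms), prot$dt_ms + 1e-9)
})

test_that("a monotonically rising trace yields no decay fit", {
  t <- seq(0, 110, by = 0.2)
  i <- ifelse(t > 10, -(t - 10), 0)  # ramps inward to the very end
  k <- measure_kinetics(data.frame(t_ms = t, i_pa = i), 10, 110)
  expect_false(k$decay_fitted)
  expect_true(is.na(k$tau_decay_ms))
  expect_equal(k$time_to_peak_ms, 100)
})

test_that("charge transfer: rectangle value, monotonicity, additivity", {
  # constant -100 pA from onset with no pre-onset samples: Q(10) = 1 pC
  t <- seq(10, 110, by = 0.2)
  sweep <- data.frame(t_ms = t, i_pa = rep(-100, length(t)))
  q <- charge_transfer(sweep, 10, times_ms = c(2, 10, 100),
                       capacitance_pf = 10)
  expect_equal(q$q_pc[q$t_ms == 10], 1)
  expect_equal(q$q_pc_pf[q$t_ms == 10], 0.1)
  expect_true(all(diff(q$q_pc) >= 0))

  # on a simulated sweep: monotone, additive, and oracle-consistent
  wt <- builtin_params("WT")
  prot <- activation_protocol(test_from = -40, test_to = -40)
  r <- simulate_cell(wt, prot, 15, 0)
  qq <- charge_transfer(r$sweeps, prot$test_onset_ms)
  expect_true(all(diff(qq$q_pc) >= 0))
  seg <- charge_transfer(r$sweeps, prot$test_onset_ms, times_ms = 10)
  mid <- r$sweeps$t_ms >= prot$test_onset_ms + 10 &
    r$sweeps$t_ms <= prot$test_onset_ms + 100
  base_idx <- r$sweeps$t_ms > prot$test_onset_ms - 10 &
    r$sweeps$t_ms < prot$test_onset_ms
  base <- mean(r$sweeps$i_pa[base_idx])
  tail_q <- pracma::trapz(r$sweeps$t_ms[mid],
                          pmax(0, -(r$sweeps$i_pa[mid] - base))) / 1000
  expect_equal(qq$q_pc[qq$t_ms == 100], seg$q_pc + tail_q,
               tolerance = 1e-10)
  skip_if_not_installed("deSolve")
  oracle <- ode_peak_oracle(wt, -40, 15)
  q_oracle <- pracma::trapz(oracle$trace$t_ms,
                            pmax(0, -oracle$trace$i_pa)) / 1000
  expect_equal(qq$q_pc[qq$t_ms == 100], q_oracle, tolerance = 0.01)
})

test_that("conductance density: chord arithmetic and fixture consistency", {
  iv <- data.frame(v_mv = c(-50, -40, -30), density_pa_pf = c(-8, -10, -9))
  expect_equal(conductance_density(iv, erev = 30, mode = "chord_at_-40"),
               10 / 70)
  wt <- builtin_params("WT")
  r <- simulate_cell(wt, activation_protocol(), 15, 0)
  iv_wt <- build_iv(r)
  fit <- fit_activation(iv_wt)
  chord <- conductance_density(iv_wt, fit, mode = "chord_at_-40")
  # chord at -40 equals gmax_density * (m h at the peak), via the oracle
  skip_if_not_installed("deSolve")
  oracle <- ode_peak_oracle(wt, -40, 15)
  mh_peak <- oracle$peak_pa / (15 * wt$gmax_density * (-40 - wt$erev))
  expect_equal(chord, wt$gmax_density * mh_peak, tolerance = 0.02)
  expect_equal(conductance_density(fit = fit, mode = "fitted_gmax"),
               fit$gmax)
})

test_that("constant baseline offsets change no reported quantity", {
  wt <- builtin_params("WT")
  prot <- activation_protocol()
  r <- simulate_cell(wt, prot, 15, noise_sigma = 2, seed = 5)
  r_off <- r
  r_off$sweeps$i_pa <- r$sweeps$i_pa - 7.5
  expect_equal(build_iv(r_off)$peak_pa, build_iv(r)$peak_pa,
               tolerance = 1e-12)
  s40 <- match(-40, prot$step_voltages)
  sw <- r$sweeps[r$sweeps$sweep == s40, ]
  sw_off <- r_off$sweeps[r_off$sweeps$sweep == s40, ]
  expect_equal(
    charge_transfer(sw_off, prot$test_onset_ms)$q_pc,
    charge_transfer(sw, prot$test_onset_ms)$q_pc, tolerance = 1e-9)
  k <- measure_kinetics(sw, prot$test_onset_ms, prot$test_end_ms)
  k_off <- measure_kinetics(sw_off, prot$test_onset_ms, prot$test_end_ms)
  expect_equal(k_off$time_to_peak_ms, k$time_to_peak_ms)
  expect_equal(k_off$tau_decay_ms, k$tau_decay_ms, tolerance = 1e-6)
})

test_that("noise-free round trip recovers all generating midpoints", {
  for (g in c("WT", "Lys785Met", "Pro849Ser", "Pro2124Leu", "Ser2338Phe")) {
    params <- builtin_params(g)
    r_act <- simulate_cell(params, activation_protocol(), 15, 0)
    fit <- fit_activation(build_iv(r_act))
    expect_true(fit$converged, label = paste(g, "activation converged"))
    expect_lt(abs(fit$vh - params$vh_act), 1)
    expect_lt(abs(fit$erev - params$erev), 2)
    r_in <- simulate_cell(params, inactivation_protocol(), 15, 0)
    ifit <- fit_inactivation(r_in)
    expect_true(ifit$converged, label = paste(g, "inactivation converged"))
    expect_lt(abs(ifit$vi - params$vi_inact), 0.5)
    expect_lt(abs(ifit$z - params$z_inact) / params$z_inact, 0.05)
  }
})
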