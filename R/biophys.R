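# Physical constants and the potentiometric probe model.
#
# The model has three compartments: an effectively infinite bath at probe
# activity 1, the cytosol, and the mitochondrial matrix.  Probe movement
# across the plasma membrane follows constant-field (GHK) kinetics
# normalised so that the rate constant at zero potential is k_T (TMRM) or
# k_P (PMPI); the inner membrane equilibrates instantaneously, so the
# matrix activity is Nernstian in psi_M and scaled by 1/a_R'.

R_GAS <- 8.314      # J mol^-1 K^-1
FARADAY <- 96485    # C mol^-1

#' Physical constants for potentiometric calculations
#'
#' @param temperature Absolute temperature in kelvin. Default 310.15 K
#'   (37 degrees C).
#' @return An object of class `physical_constants` with fields
#'   `temperature` (K) and `thermal_voltage` (RT/F, in mV; 26.73 mV at
#'   310.15 K).
#' @export
physical_constants <- function(temperature = 310.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  structure(
    list(temperature = temperature,
         thermal_voltage = 1000 * R_GAS * temperature / FARADAY),
    class = "physical_constants")
}

#' Cell geometry and probe-binding parameters
#'
#' @param vf Mitochondria:cell volume fraction, in (0, 1).
#' @param ar_prime Apparent activity coefficient ratio: nucleoplasmic to
#'   mitochondrial TMRM fluorescence at zero mitochondrial potential.
#'   Lumps membrane binding, matrix activity differences and optical
#'   dilution; in (0, 1].
#' @param vf_se,ar_prime_se Standard errors of the two parameters, used by
#'   error propagation. Default 0.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(vf, ar_prime, vf_se = 0, ar_prime_se = 0) {
  stopifnot(vf > 0, vf < 1, ar_prime > 0, ar_prime <= 1,
            vf_se >= 0, ar_prime_se >= 0)
  structure(list(vf = vf, ar_prime = ar_prime,
                 vf_se = vf_se, ar_prime_se = ar_prime_se),
            class = "cell_params")
}

#' Plasma-membrane probe kinetics
#'
#' @param k_t TMRM plasma-membrane rate constant at zero plasma membrane
#'   potential, s^-1.
#' @param k_p PMPI rate constant, s^-1. Default 0.38.
#' @param p_n Lumped non-potassium permeability term of the Goldman
#'   equation. Only 0 is supported.
#' @return An object of class `probe_kinetics`.
#' @export
probe_kinetics <- function(k_t = 0.015, k_p = 0.38, p_n = 0) {
  stopifnot(k_t > 0, k_p > 0)
  if (p_n != 0)
    stop("only p_n = 0 is supported (potassium-selective Goldman equation)")
  structure(list(k_t = k_t, k_p = k_p, p_n = p_n),
            class = "probe_kinetics")
}

#' Nernst potential from an activity ratio
#'
#' Computes the membrane potential at which a monovalent ion with the
#' given inside:outside activity ratio is at electrochemical equilibrium.
#'
#' @param ratio Inside-to-outside activity ratio (> 0).
#' @param valence Ion valence, +1 or -1.
#' @param constants A [physical_constants()] object.
#' @return Potential in mV (inside minus outside).
#' @seealso [nernst_ratio()] for the inverse.
#' @export
nernst_potential <- function(ratio, valence = 1L,
                             constants = physical_constants()) {
  if (any(ratio <= 0)) stop("activity ratio must be positive")
  if (!all(valence %in% c(-1L, 1L))) stop("valence must be +1 or -1")
  -(constants$thermal_voltage / valence) * log(ratio)
}

#' Equilibrium activity ratio at a given potential
#'
#' Inverse of [nernst_potential()].
#'
#' @param psi Membrane potential in mV.
#' @inheritParams nernst_potential
#' @return Inside-to-outside activity ratio.
#' @export
nernst_ratio <- function(psi, valence = 1L,
                         constants = physical_constants()) {
  if (!all(valence %in% c(-1L, 1L))) stop("valence must be +1 or -1")
  exp(-valence * psi / constants$thermal_voltage)
}

#' Potassium diffusion potential by the Goldman equation
#'
#' With all non-potassium permeabilities set to zero (`p_n = 0`, the only
#' supported configuration) the Goldman equation reduces exactly to the
#' potassium Nernst potential.
#'
#' @param k_ec Extracellular potassium concentration, mM.
#' @param k_ic Intracellular potassium concentration, mM.
#' @param kinetics A [probe_kinetics()] object (carries `p_n`).
#' @param constants A [physical_constants()] object.
#' @return Plasma membrane potential in mV (cell minus bath).
#' @export
goldman_k_potential <- function(k_ec, k_ic, kinetics = probe_kinetics(),
                                constants = physical_constants()) {
  if (any(k_ec <= 0) || any(k_ic <= 0))
    stop("potassium concentrations must be positive")
  if (kinetics$p_n != 0)
    stop("only p_n = 0 is supported (potassium-selective Goldman equation)")
  constants$thermal_voltage * log(k_ec / k_ic)
}

#' GHK rate factor
#'
#' Voltage dependence of the constant-field (Goldman-Hodgkin-Katz) flux,
#' `g(u) = u / (exp(u) - 1)` with the removable singularity `g(0) = 1`
#' handled by a series expansion for `|u| < 1e-4`.  Satisfies the identity
#' `g(-u) = g(u) * exp(u)`.
#'
#' @param u Reduced potential (psi / thermal voltage), dimensionless;
#'   `NA` propagates (samples flagged invalid upstream stay invalid).
#' @return Dimensionless rate factor, vectorised over `u`.
#' @export
ghk_rate_factor <- function(u) {
  out <- u / expm1(u)
  small <- !is.na(u) & abs(u) < 1e-4
  if (any(small)) {
    us <- u[small]
    out[small] <- 1 - us / 2 + us^2 / 12
  }
  out
}

#' Mitochondrial weighting factor D(psi_M)
#'
#' `D(psi_M) = (1 - V_F) + (V_F / a_R') * exp(-u_M)`: the factor relating
#' cytosolic TMRM activity to the fluorescence-equivalent whole-cell
#' activity.  `D(0)` is referred to as `D0` throughout.
#'
#' @param psi_m Mitochondrial membrane potential, mV (matrix minus
#'   cytosol; negative when polarised).
#' @param cell A [cell_params()] object.
#' @param constants A [physical_constants()] object.
#' @return Dimensionless weight, vectorised over `psi_m`.
#' @export
activity_weight <- function(psi_m, cell, constants = physical_constants()) {
  u_m <- psi_m / constants$thermal_voltage
  (1 - cell$vf) + (cell$vf / cell$ar_prime) * exp(-u_m)
}

#' Whole-cell TMRM activity from cytosolic activity
#'
#' `a_cell = a_c * D(psi_M)`: the whole-cell fluorescence-equivalent TMRM
#' activity given the cytosolic activity and the mitochondrial potential,
#' under instantaneous Nernstian equilibration across the inner membrane.
#'
#' @param a_c Cytosolic TMRM activity relative to the bath (>= 0).
#' @inheritParams activity_weight
#' @return Whole-cell activity, dimensionless.
#' @export
cell_activity <- function(a_c, psi_m, cell,
                          constants = physical_constants()) {
  if (any(a_c < 0)) stop("cytosolic activity must be non-negative")
  a_c * activity_weight(psi_m, cell, constants)
}

# Relaxation rate of the whole-cell TMRM activity at constant potentials:
# lambda = k_T * g(u_P) * exp(u_P) / D(psi_M).  Used as the closed-form
# oracle for decay fitting and equilibration times.
tmrm_relaxation_rate <- function(psi_p, psi_m, cell, kinetics,
                                 constants = physical_constants()) {
  u_p <- psi_p / constants$thermal_voltage
  kinetics$k_t * ghk_rate_factor(u_p) * exp(u_p) /
    activity_weight(psi_m, cell, constants)
}

#' Simulate dual-probe fluorescence for a full protocol
#'
#' Forward model of the assay.  Integrates the whole-cell TMRM activity
#' `d a_cell/dt = k_T g(u_P) (1 - a_c exp(u_P))` with
#' `a_c = a_cell / D(psi_M)` (bath activity fixed at 1) and the PMPI
#' activity `db/dt = k_P (exp(u_P) - b)`, then maps activities to
#' fluorescence `f = f_x + scale * activity` on the acquisition grid.
#' The baseline is initialised at distribution equilibrium.
#'
#' @param truth A list with vectorised functions `psi_p(t)` and `psi_m(t)`
#'   (mV) defined on the full protocol span.  After the fixation event both
#'   must be 0 so the traces relax to endpoint plateaus.
#' @param events A [protocol_events()] object; event times are used as
#'   exact discontinuities for the integrator.
#' @param cell A [cell_params()] object.
#' @param kinetics A [probe_kinetics()] object.
#' @param optics Per-channel optical constants:
#'   `list(tmrm = list(f_x, scale), pmpi = list(f_x, scale))` in AU.
#' @param t_end End of the recording, s. Default: last event + 720 s.
#' @param dt Sampling interval of the acquisition grid, s. Default 30.
#' @param noise Optional noise model,
#'   `list(multiplicative = sd, additive = sd)`: Gaussian with SD
#'   proportional to intensity plus an additive Gaussian floor.
#' @param roi_id ROI label for the emitted traces.
#' @param seed Optional integer seed used when `noise` is given.
#' @param constants A [physical_constants()] object.
#' @param rtol,atol Integration tolerances on activities.
#' @return A [trace_set()] with channels `TMRM` and `PMPI`; the noise-free
#'   activities and the truth are attached as attribute `truth`.
#' @export
simulate_protocol <- function(truth, events, cell, kinetics,
                              optics = default_optics(),
                              t_end = NULL, dt = 30, noise = NULL,
                              roi_id = "cell_1", seed = NULL,
                              constants = physical_constants(),
                              rtol = 1e-8, atol = 1e-9) {
  ev <- as.data.frame(events)
  if (is.null(t_end)) t_end <- max(ev$time_s) + 720
  t_grid <- seq(0, t_end, by = dt)
  vt <- constants$thermal_voltage

  deriv <- function(t, y, parms) {
    u_p <- truth$psi_p(t) / vt
    d_m <- activity_weight(truth$psi_m(t), cell, constants)
    a_c <- y[1] / d_m
    da <- kinetics$k_t * ghk_rate_factor(u_p) * (1 - a_c * exp(u_p))
    db <- kinetics$k_p * (exp(u_p) - y[2])
    list(c(da, db))
  }

  a0 <- exp(-truth$psi_p(0) / vt) *
    activity_weight(truth$psi_m(0), cell, constants)
  b0 <- exp(truth$psi_p(0) / vt)

  breaks <- sort(unique(c(0, ev$time_s[ev$time_s > 0 & ev$time_s < t_end],
                          t_end)))
  y <- c(a0, b0)
  sol_t <- numeric(0); sol_a <- numeric(0); sol_b <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    tt <- unique(sort(c(breaks[i], t_grid[t_grid >= breaks[i] &
                                            t_grid <= breaks[i + 1L]],
                        breaks[i + 1L])))
    # integrate from just inside the segment so parameter steps at the
    # boundary are seen as exact discontinuities
    out <- deSolve::lsoda(y, tt, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0)
      stop("integration failed; try a smaller sampling step")
    keep <- out[, 1L] %in% t_grid & !(out[, 1L] %in% sol_t)
    sol_t <- c(sol_t, out[keep, 1L])
    sol_a <- c(sol_a, out[keep, 2L])
    sol_b <- c(sol_b, out[keep, 3L])
    y <- c(out[nrow(out), 2L], out[nrow(out), 3L])
  }
  ord <- order(sol_t)
  sol_t <- sol_t[ord]; sol_a <- sol_a[ord]; sol_b <- sol_b[ord]

  f_t <- optics$tmrm$f_x + optics$tmrm$scale * sol_a
  f_p <- optics$pmpi$f_x + optics$pmpi$scale * sol_b
  if (!is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    nm <- if (is.null(noise$multiplicative)) 0 else noise$multiplicative
    na <- if (is.null(noise$additive)) 0 else noise$additive
    f_t <- f_t * (1 + nm * stats::rnorm(length(f_t))) +
      na * stats::rnorm(length(f_t))
    f_p <- f_p * (1 + nm * stats::rnorm(length(f_p))) +
      na * stats::rnorm(length(f_p))
  }

  df <- rbind(
    data.frame(time_s = sol_t, roi_id = roi_id, channel = "TMRM",
               intensity = f_t, stringsAsFactors = FALSE),
    data.frame(time_s = sol_t, roi_id = roi_id, channel = "PMPI",
               intensity = f_p, stringsAsFactors = FALSE))
  ts <- trace_set(df)
  attr(ts, "truth") <- list(time_s = sol_t, a_cell = sol_a, b = sol_b,
                            psi_p = truth$psi_p(sol_t),
                            psi_m = truth$psi_m(sol_t),
                            optics = optics)
  ts
}

#' Default optical constants for the simulator
#'
#' Backgrounds and scales in AU chosen so that simulated intensities span
#' the range typical of 16-bit camera recordings.
#' @return A list with elements `tmrm` and `pmpi`, each `list(f_x, scale)`.
#' @export
default_optics <- function() {
  list(tmrm = list(f_x = 50, scale = 100),
       pmpi = list(f_x = 100, scale = 280))
}

#' Equilibration time of TMRM across the plasma membrane
#'
#' Integrates the plasma-membrane redistribution ODE at fixed potentials
#' and returns the first time at which the mitochondrial matrix activity
#' reaches the stated fraction of its new equilibrium value.  For
#' `direction = "uptake"` the cell starts probe-free; for
#' `direction = "efflux"` it starts at the distribution equilibrium of
#' `psi_p`/`psi_m_initial` and relaxes after the mitochondrial potential
#' steps to `psi_m` (complete mitochondrial depolarisation corresponds to
#' `psi_m = 0`).
#'
#' @param cell A [cell_params()] object.
#' @param kinetics A [probe_kinetics()] object.
#' @param psi_p Plasma membrane potential, mV, held constant.
#' @param psi_m Mitochondrial membrane potential during the measured
#'   relaxation, mV.
#' @param fraction Fraction of the approach to the new equilibrium, in
#'   (0, 1); 0.9 gives the 90 percent equilibration time.
#' @param direction `"uptake"` or `"efflux"`.
#' @param psi_m_initial Initial mitochondrial potential for efflux, mV.
#' @param horizon Integration horizon, s.
#' @param constants A [physical_constants()] object.
#' @return Time in seconds.
#' @export
equilibration_time <- function(cell, kinetics, psi_p, psi_m,
                               fraction = 0.9,
                               direction = c("uptake", "efflux"),
                               psi_m_initial = psi_m,
                               horizon = 2e5,
                               constants = physical_constants()) {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction < 1)
  vt <- constants$thermal_voltage
  u_p <- psi_p / vt
  d_m <- activity_weight(psi_m, cell, constants)
  a_eq <- exp(-u_p) * d_m
  a0 <- if (direction == "uptake") 0 else
    exp(-u_p) * activity_weight(psi_m_initial, cell, constants)
  if (abs(a_eq - a0) < .Machine$double.eps)
    stop("initial state already at equilibrium; fraction unreachable")

  deriv <- function(t, y, parms) {
    a_c <- y[1] / d_m
    list(kinetics$k_t * ghk_rate_factor(u_p) * (1 - a_c * exp(u_p)))
  }
  tt <- seq(0, horizon, length.out = 4096L)
  out <- deSolve::lsoda(a0, tt, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  frac_path <- (out[, 2L] - a0) / (a_eq - a0)
  if (max(frac_path) < fraction)
    stop(sprintf("fraction %.3g not reached within horizon %.3g s",
                 fraction, horizon))
  fn <- stats::approxfun(out[, 1L], frac_path - fraction)
  i <- which(frac_path >= fraction)[1L]
  stats::uniroot(fn, lower = out[max(1L, i - 1L), 1L],
                 upper = out[i, 1L], tol = 1e-6)$root
}
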