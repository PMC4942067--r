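# Delta-method error propagation through the full calibration map, and a
# Monte-Carlo resampling cross-check.

# parameter vector of the calibration map, with its covariance.
# Regression parameter pairs keep their fitted covariance; all other
# inputs are treated as independent.
error_theta <- function(model, trace_t, trace_p) {
  w <- model$windows
  sig <- model$noise_sd
  sig[!is.finite(sig)] <- 0
  wb <- if (!is.null(w$baseline_eff)) w$baseline_eff else w$baseline
  wd <- if (!is.null(w$decay_eff)) w$decay_eff else w$decay
  base_t <- window_samples(trace_t, wb)
  base_p <- window_samples(trace_p, wb)
  val_p <- window_samples(trace_p, wd)
  th <- c(
    f_x_p   = unname(model$f_x[["PMPI"]]),
    f_end_p = unname(model$f_end[["PMPI"]]),
    icpt_d  = model$fits$decay$intercept,
    slope_d = model$fits$decay$slope,
    f_end_t = unname(model$f_end[["TMRM"]]),
    vf      = model$cell$vf,
    ar      = model$cell$ar_prime,
    fb_t    = mean(base_t$intensity),
    fb_p    = mean(base_p$intensity),
    fv_p    = mean(val_p$intensity))
  cov <- diag(c(
    model$fits$kstep$covariance[1L, 1L],
    sig[["PMPI"]]^2 / model$n_end[["PMPI"]],
    0, 0,
    sig[["TMRM"]]^2 / model$n_end[["TMRM"]],
    model$cell$vf_se^2,
    model$cell$ar_prime_se^2,
    sig[["TMRM"]]^2 / nrow(base_t),
    sig[["PMPI"]]^2 / nrow(base_p),
    sig[["PMPI"]]^2 / nrow(val_p)))
  cov[3:4, 3:4] <- model$fits$decay$covariance
  dimnames(cov) <- list(names(th), names(th))
  list(theta = th, cov = cov)
}

# recompute the calibration outputs for a perturbed parameter vector.
# Moving-fit values/slopes of the raw intensities are precomputed once
# (the activity transforms are affine in intensity).
calibration_map <- function(th, fixed) {
  vt <- fixed$constants$thermal_voltage
  cell <- cell_params(th[["vf"]], th[["ar"]])
  s_p <- th[["f_end_p"]] - th[["f_x_p"]]
  if (s_p <= 0) return(NULL)

  b_v <- (fixed$mf_p$value - th[["f_x_p"]]) / s_p
  b_s <- fixed$mf_p$slope / s_p
  arg_p <- b_v + b_s / fixed$kinetics$k_p
  psi_p <- ifelse(arg_p > 0, vt * log(pmax(arg_p, 1e-300)), NA_real_)
  psi_p_base <- vt * log((th[["fb_p"]] - th[["f_x_p"]]) / s_p)
  psi_val <- vt * log((th[["fv_p"]] - th[["f_x_p"]]) / s_p)

  lambda_raw <- -th[["slope_d"]]
  dt0 <- fixed$dt
  lambda <- if (is.finite(dt0) && lambda_raw * dt0 / 2 < 1 &&
                lambda_raw > 0)
    (2 / dt0) * atanh(lambda_raw * dt0 / 2) else lambda_raw
  f_inf <- -th[["icpt_d"]] / th[["slope_d"]]

  u_val <- psi_val / vt
  e <- exp(-u_val)
  f_x_t <- (f_inf - th[["f_end_t"]] * e) / (1 - e)
  d0 <- activity_weight(0, cell, fixed$constants)
  s_t <- (th[["f_end_t"]] - f_x_t) / d0
  k_t <- lambda * d0 / (ghk_rate_factor(u_val) * exp(u_val))

  a_v <- (fixed$mf_t$value - f_x_t) / s_t
  a_s <- fixed$mf_t$slope / s_t
  u_p <- psi_p / vt
  a_c <- exp(-u_p) * (1 - a_s / (k_t * ghk_rate_factor(u_p)))
  x <- cell$ar_prime * (a_v / a_c - (1 - cell$vf)) / cell$vf
  psi_m <- ifelse(is.finite(x) & x > 0 & is.finite(a_c) & a_c > 0,
                  -vt * log(pmax(x, 1e-300)), NA_real_)

  a_cell_b <- (th[["fb_t"]] - f_x_t) / s_t
  a_c_b <- exp(-psi_p_base / vt)
  xb <- cell$ar_prime * (a_cell_b / a_c_b - (1 - cell$vf)) / cell$vf
  psi_m_base <- if (is.finite(xb) && xb > 0) -vt * log(xb) else NA_real_

  list(psi_p_base = psi_p_base, psi_m_base = psi_m_base,
       psi_p = psi_p, psi_m = psi_m,
       b_v = b_v, b_s = b_s, a_v = a_v, a_s = a_s,
       s_p = s_p, s_t = s_t, k_t = k_t, f_x_t = f_x_t)
}

#' Delta-method standard errors of the calibrated potentials
#'
#' First-order propagation of the errors of all calibration inputs (PMPI
#' background from the potassium-step regression, decay regression
#' parameter pair with its covariance, endpoint and window means, V_F,
#' a_R', and per-sample intensity noise) through the full calibration
#' map, using numerical partial derivatives.  Inputs are treated as
#' independent except the regression parameter pairs.
#'
#' @param model A `calibration_model` from [calibrate_cell()].
#' @param trace_t,trace_p The TMRM and PMPI traces the model was fitted
#'   on.
#' @return A list with per-point `se_p`, `se_m` (mV) and scalar
#'   `baseline_se_p`, `baseline_se_m`.
#' @export
propagate_errors <- function(model, trace_t, trace_p) {
  et <- error_theta(model, trace_t, trace_p)
  th <- et$theta
  constants <- model$constants
  vt <- constants$thermal_voltage
  dtv <- diff(trace_t$time_s)
  dt0 <- stats::median(dtv)
  fixed <- list(
    constants = constants, kinetics = model$kinetics, dt = dt0,
    mf_p = moving_linfit(trace_p$time_s, trace_p$intensity,
                         model$options$window),
    mf_t = moving_linfit(trace_t$time_s, trace_t$intensity,
                         model$options$window))
  f0 <- calibration_map(th, fixed)
  n <- length(f0$psi_p)

  # numerical jacobian of (psi_p_base, psi_m_base, psi_p(t), psi_m(t))
  outputs <- function(f) c(f$psi_p_base, f$psi_m_base, f$psi_p, f$psi_m)
  J <- matrix(0, nrow = 2L + 2L * n, ncol = length(th))
  for (k in seq_along(th)) {
    if (et$cov[k, k] == 0 && all(et$cov[k, -k] == 0)) next
    step <- max(abs(th[k]) * 1e-5, 1e-8)
    thp <- th; thp[k] <- th[k] + step
    thm <- th; thm[k] <- th[k] - step
    fp <- calibration_map(thp, fixed)
    fm <- calibration_map(thm, fixed)
    if (is.null(fp) || is.null(fm)) next
    J[, k] <- (outputs(fp) - outputs(fm)) / (2 * step)
  }
  var_param <- rowSums((J %*% et$cov) * J)

  # per-sample intensity noise through the moving-fit value and slope
  sig <- model$noise_sd
  sig[!is.finite(sig)] <- 0
  vfac <- moving_linfit_varfac(model$options$window, dt0)
  var_bv <- (sig[["PMPI"]] / f0$s_p)^2 * vfac[["value"]]
  var_bs <- (sig[["PMPI"]] / f0$s_p)^2 * vfac[["slope"]]
  var_av <- (sig[["TMRM"]] / f0$s_t)^2 * vfac[["value"]]
  var_as <- (sig[["TMRM"]] / f0$s_t)^2 * vfac[["slope"]]

  arg_p <- f0$b_v + f0$b_s / model$kinetics$k_p
  var_int_p <- (vt / arg_p)^2 *
    (var_bv + var_bs / model$kinetics$k_p^2)
  var_int_p[!is.finite(var_int_p) | arg_p <= 0] <- NA_real_

  # partials of psi_M(t) wrt local TMRM value/slope and psi_P(t)
  pm_of <- function(a_v, a_s, psi_p) {
    u_p <- psi_p / vt
    a_c <- exp(-u_p) * (1 - a_s / (f0$k_t * ghk_rate_factor(u_p)))
    x <- th[["ar"]] * (a_v / a_c - (1 - th[["vf"]])) / th[["vf"]]
    ifelse(is.finite(x) & x > 0, -vt * log(pmax(x, 1e-300)), NA_real_)
  }
  eps_a <- pmax(abs(f0$a_v) * 1e-5, 1e-8)
  d_av <- (pm_of(f0$a_v + eps_a, f0$a_s, f0$psi_p) -
             pm_of(f0$a_v - eps_a, f0$a_s, f0$psi_p)) / (2 * eps_a)
  eps_s <- pmax(abs(f0$a_s) * 1e-5, 1e-10)
  d_as <- (pm_of(f0$a_v, f0$a_s + eps_s, f0$psi_p) -
             pm_of(f0$a_v, f0$a_s - eps_s, f0$psi_p)) / (2 * eps_s)
  eps_p <- 1e-3
  d_pp <- (pm_of(f0$a_v, f0$a_s, f0$psi_p + eps_p) -
             pm_of(f0$a_v, f0$a_s, f0$psi_p - eps_p)) / (2 * eps_p)
  var_int_m <- d_av^2 * var_av + d_as^2 * var_as + d_pp^2 * var_int_p

  se_p <- sqrt(var_param[2L + seq_len(n)] + var_int_p)
  se_m <- sqrt(var_param[2L + n + seq_len(n)] + var_int_m)
  list(se_p = se_p, se_m = se_m,
       baseline_se_p = sqrt(var_param[1L]),
       baseline_se_m = sqrt(var_param[2L]),
       var_int_p = var_int_p, var_int_m = var_int_m)
}

#' Monte-Carlo standard errors of the baseline potentials
#'
#' Independent cross-check of [propagate_errors()]: adds iid Gaussian
#' intensity noise to the supplied traces, redraws V_F and a_R' from
#' their standard errors, reruns the full calibration chain, and returns
#' the empirical SD of the baseline potentials over the draws.
#'
#' @param trace_t,trace_p Noise-free TMRM and PMPI traces.
#' @param events A [protocol_events()] object.
#' @param cell A [cell_params()] object (its `vf_se`/`ar_prime_se` are
#'   the redraw SDs).
#' @param kinetics A [probe_kinetics()] object.
#' @param noise_sd Named vector `c(TMRM =, PMPI =)` of intensity SDs, AU.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param options A [calibration_options()] list.
#' @param constants A [physical_constants()] object.
#' @return A list `sd_psi_p`, `sd_psi_m` (mV), and the draws.
#' @export
mc_baseline_se <- function(trace_t, trace_p, events, cell, kinetics,
                           noise_sd, n_draws = 2000, seed = 1,
                           options = calibration_options(),
                           constants = physical_constants()) {
  set.seed(seed)
  draws_p <- numeric(n_draws)
  draws_m <- numeric(n_draws)
  nt <- nrow(trace_t); np <- nrow(trace_p)
  opts <- options
  opts$noise_sd <- noise_sd
  for (i in seq_len(n_draws)) {
    tt <- trace_t; tp <- trace_p
    tt$intensity <- tt$intensity + noise_sd[["TMRM"]] * stats::rnorm(nt)
    tp$intensity <- tp$intensity + noise_sd[["PMPI"]] * stats::rnorm(np)
    cl <- cell_params(
      max(1e-4, cell$vf + cell$vf_se * stats::rnorm(1L)),
      min(1, max(1e-4, cell$ar_prime +
                   cell$ar_prime_se * stats::rnorm(1L))))
    r <- calibrate_cell(tt, tp, events, cl, kinetics, options = opts,
                        propagate = FALSE, constants = constants)
    b <- attr(r, "baseline")
    draws_p[i] <- b$psi_p
    draws_m[i] <- b$psi_m
  }
  list(sd_psi_p = stats::sd(draws_p, na.rm = TRUE),
       sd_psi_m = stats::sd(draws_m, na.rm = TRUE),
       draws_psi_p = draws_p, draws_psi_m = draws_m)
}
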