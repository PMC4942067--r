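# The inverse problem: millivolt calibration of PMPI and TMRM traces.
#
# The calibration chain per ROI is
#   potassium-step regression  -> f_x_P, s_P, [K+]_ic
#   PMPI back-calculation      -> psi_P(t), baseline psi_P, clamp psi_val
#   TMRM decay regression      -> lambda, f_inf
#   endpoint resolution        -> f_x_T, s_T * D0
#   rate-constant inversion    -> k_T
#   TMRM back-calculation      -> psi_M(t), baseline psi_M
# followed by delta-method error propagation and quality control.

# centred moving linear fit: local value and slope at every sample;
# one-sided at the ends.  Window is in samples (odd recommended).
# Uniformly sampled traces take a vectorised convolution path.
moving_linfit <- function(t, y, window = 5L) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  dtv <- diff(t)
  if (n > window && h > 0L &&
      max(abs(dtv - dtv[1L])) < 1e-9 * abs(dtv[1L])) {
    dt0 <- dtv[1L]
    off <- (-h):h
    value <- as.numeric(stats::filter(y, rep(1 / (2 * h + 1), 2 * h + 1),
                                      sides = 2))
    cs <- off * dt0 / sum((off * dt0)^2)
    # filter applies coefficients to x[i+h], ..., x[i-h] in that order
    slope <- as.numeric(stats::filter(y, rev(cs), sides = 2))
    idx <- c(seq_len(h), (n - h + 1L):n)
  } else {
    value <- numeric(n); slope <- numeric(n)
    idx <- seq_len(n)
  }
  for (i in idx) {
    j <- max(1L, i - h):min(n, i + h)
    tj <- t[j]; yj <- y[j]
    tm <- mean(tj); ym <- mean(yj)
    sxx <- sum((tj - tm)^2)
    b <- if (sxx > 0) sum((tj - tm) * (yj - ym)) / sxx else 0
    slope[i] <- b
    value[i] <- ym + b * (t[i] - tm)
  }
  list(value = value, slope = slope)
}

# variance factors of the moving fit under iid sample noise of unit
# variance: value variance ~ 1/n_w, slope variance ~ 1/sum((t-tbar)^2)
moving_linfit_varfac <- function(window, dt) {
  h <- (window - 1L) %/% 2L
  n <- 2L * h + 1L
  tt <- (seq_len(n) - (h + 1L)) * dt
  c(value = 1 / n, slope = 1 / sum(tt^2))
}

new_regression_fit <- function(slope, intercept, covariance, r2, n_points,
                               sigma = NA_real_, failed = FALSE,
                               reason = NULL) {
  structure(list(slope = slope, intercept = intercept,
                 covariance = covariance, r2 = r2, n_points = n_points,
                 sigma = sigma, failed = failed, reason = reason),
            class = "regression_fit")
}

#' Pre-process a trace set
#'
#' Background subtraction, optional linear spectral unmixing of the
#' channel pair, and an optional, event-gated probe depletion correction
#' that rescales each channel by (background at the reference epoch) /
#' (background at t), piecewise constant between liquid-handling events.
#'
#' @param traces A [trace_set()]; the background trace must be present
#'   when subtraction or depletion correction is requested.
#' @param unmix Optional 2x2 unmixing matrix applied to the
#'   (TMRM, PMPI) channel pair of every ROI (and of the background).
#' @param depletion_correction Logical; apply the background-ratio
#'   rescaling.
#' @param events A [protocol_events()] object (required for depletion
#'   correction: segments are bounded by the event times).
#' @param subtract_background Logical, default TRUE when a background
#'   trace is present.
#' @return A [trace_set()] with corrected intensities (background trace
#'   removed).
#' @export
preprocess <- function(traces, unmix = NULL, depletion_correction = FALSE,
                       events = NULL,
                       subtract_background = !is.null(attr(traces,
                                                           "background"))) {
  bg <- attr(traces, "background")
  if ((subtract_background || depletion_correction) && is.null(bg))
    stop("background trace required for the requested correction")
  df <- as.data.frame(traces)

  scale_fac <- NULL
  if (depletion_correction) {
    if (is.null(events))
      stop("depletion correction requires the protocol events")
    bounds <- sort(unique(c(-Inf, events$time_s, Inf)))
    scale_fac <- lapply(split(bg, bg$channel), function(b) {
      seg <- findInterval(b$time_s, bounds)
      seg_med <- tapply(b$intensity, seg, stats::median)
      ref <- seg_med[[1L]]   # reference epoch: pre-event baseline
      data.frame(time_s = b$time_s,
                 factor = ref / seg_med[as.character(seg)])
    })
  }

  for (ch in unique(df$channel)) {
    i <- df$channel == ch
    if (subtract_background) {
      b <- bg[bg$channel == ch, ]
      df$intensity[i] <- df$intensity[i] -
        stats::approx(b$time_s, b$intensity, df$time_s[i], rule = 2)$y
    }
    if (depletion_correction) {
      sf <- scale_fac[[ch]]
      df$intensity[i] <- df$intensity[i] *
        stats::approx(sf$time_s, sf$factor, df$time_s[i],
                      method = "constant", rule = 2)$y
    }
  }

  if (!is.null(unmix)) {
    if (!all(dim(unmix) == c(2L, 2L)) ||
        abs(det(unmix)) < .Machine$double.eps)
      stop("unmix must be a non-singular 2x2 matrix")
    for (roi in unique(df$roi_id)) {
      it <- df$roi_id == roi & df$channel == "TMRM"
      ip <- df$roi_id == roi & df$channel == "PMPI"
      v <- unmix %*% rbind(df$intensity[it], df$intensity[ip])
      df$intensity[it] <- v[1L, ]
      df$intensity[ip] <- v[2L, ]
    }
  }
  trace_set(df, background = NULL)
}

#' Potassium-step plateau means
#'
#' @param trace_p PMPI trace data.frame (`time_s`, `intensity`).
#' @param windows Segment windows from [segment_windows()].
#' @param tail_frac Fraction of each step window, taken from its end, over
#'   which the plateau mean is computed (default 0.5).
#' @return A data.frame with columns `k_ec`, `f`, `n`.
#' @export
kstep_plateaus <- function(trace_p, windows, tail_frac = 0.5) {
  ks <- windows$ksteps
  if (is.null(ks)) stop("protocol has no k_step events")
  out <- lapply(seq_len(nrow(ks)), function(j) {
    t0 <- ks$end[j] - tail_frac * (ks$end[j] - ks$start[j])
    d <- window_samples(trace_p, c(t0, ks$end[j]))
    data.frame(k_ec = ks$k_ec[j], f = mean(d$intensity), n = nrow(d))
  })
  do.call(rbind, out)
}

#' Potassium-step regression
#'
#' Fits the linear relationship between PMPI plateau fluorescence and
#' extracellular potassium, `f = intercept + m * K_ec`.  Under the probe
#' model the intercept is the PMPI background `f_x_P`, the span to the
#' fixation endpoint is the scale `s_P = f_end_P - intercept`, and the
#' intracellular potassium is `[K+]_ic = s_P / m`.
#'
#' @param plateaus A data.frame with columns `k_ec` (mM) and `f` (AU),
#'   one row per calibration step (at least 3 distinct steps); an
#'   optional column `n` gives the number of samples behind each plateau
#'   mean.
#' @param f_end_p PMPI fluorescence at the fixation endpoint, AU.
#' @param noise_sd Optional per-sample intensity noise SD (AU).  When
#'   given, the parameter covariance is computed from the known
#'   plateau-mean noise (sandwich with variances `noise_sd^2 / n`), which
#'   is far more stable than the 2-residual-df estimate of a 4-point
#'   regression; otherwise the residual-based covariance is used.
#' @return A list with elements `fit` (a `regression_fit`), `f_x_p`,
#'   `s_p`, `k_ic`.  On a non-positive slope or span the fit is flagged
#'   `failed` and the derived values are `NA`.
#' @export
fit_kstep <- function(plateaus, f_end_p, noise_sd = NULL) {
  if (nrow(plateaus) < 3L || length(unique(plateaus$k_ec)) < 3L)
    stop("at least 3 distinct potassium steps required")
  lmfit <- stats::lm(f ~ k_ec, data = plateaus)
  sm <- suppressWarnings(summary(lmfit))  # exact fits are expected
  m <- unname(stats::coef(lmfit)[2L])
  icpt <- unname(stats::coef(lmfit)[1L])
  r2 <- sm$r.squared
  covb <- sm$cov.unscaled * sm$sigma^2
  if (!is.null(noise_sd) && is.finite(noise_sd) && noise_sd > 0 &&
      !is.null(plateaus$n)) {
    X <- cbind(1, plateaus$k_ec)
    xtxi <- solve(crossprod(X))
    W <- diag(noise_sd^2 / plateaus$n, nrow(plateaus))
    covb <- xtxi %*% t(X) %*% W %*% X %*% xtxi
  }
  fit <- new_regression_fit(m, icpt, covb, r2,
                            nrow(plateaus), sigma = sm$sigma)
  s_p <- f_end_p - icpt
  tol <- .Machine$double.eps^0.5 * max(1, abs(f_end_p))
  if (!is.finite(m) || m <= 0 || s_p <= tol) {
    fit$failed <- TRUE
    fit$reason <- "non-positive potassium-step slope or PMPI span"
    return(list(fit = fit, f_x_p = NA_real_, s_p = NA_real_,
                k_ic = NA_real_))
  }
  list(fit = fit, f_x_p = icpt, s_p = s_p, k_ic = s_p / m)
}

#' Back-calculate the plasma membrane potential from a PMPI trace
#'
#' Converts PMPI fluorescence to the reduced probe activity
#' `b = (f - f_x_P) / s_P`, applies the first-order disequilibrium
#' correction `exp(u_P) = b + (1/k_P) db/dt` (derivative by a centred
#' moving linear fit), and maps to millivolts.  Samples where the
#' corrected argument is non-positive are flagged invalid, never
#' interpolated.
#'
#' @param trace_p PMPI trace data.frame (`time_s`, `intensity`).
#' @param f_x_p,s_p PMPI background and scale, AU.
#' @param kinetics A [probe_kinetics()] object (`k_p` is used).
#' @param window Derivative window in samples (default 5).
#' @param constants A [physical_constants()] object.
#' @return A data.frame `time_s`, `psi_p` (mV), `valid`.
#' @export
calibrate_psi_p <- function(trace_p, f_x_p, s_p,
                            kinetics = probe_kinetics(), window = 5L,
                            constants = physical_constants()) {
  b <- (trace_p$intensity - f_x_p) / s_p
  mf <- moving_linfit(trace_p$time_s, b, window)
  arg <- mf$value + mf$slope / kinetics$k_p
  valid <- is.finite(arg) & arg > 0
  psi <- rep(NA_real_, length(arg))
  psi[valid] <- constants$thermal_voltage * log(arg[valid])
  data.frame(time_s = trace_p$time_s, psi_p = psi, valid = valid)
}

#' TMRM decay regression
#'
#' Linearises the post-depolarisation mono-exponential TMRM decay by
#' regressing successive difference quotients against mid-interval
#' fluorescence.  The slope is `-lambda` and the x-intercept is the decay
#' asymptote `f_inf`.  For uniform sampling the discrete-difference bias
#' in the rate is removed analytically
#' (`lambda = (2/dt) atanh(lambda_raw dt / 2)`).
#'
#' @param segment TMRM decay-segment data.frame (`time_s`, `intensity`),
#'   at least 8 samples starting at the depolarisation event and ending
#'   before the first potassium step.
#' @param noise_sd Optional per-sample intensity noise SD (AU); when
#'   given, the sandwich covariance uses the known marginal quotient
#'   noise `2 noise_sd^2 / dt^2` instead of the residual estimate.
#' @return A list with `fit` (a `regression_fit`; its `r2` is the QC
#'   statistic), `lambda_decay` (s^-1) and `f_inf` (AU).  A non-negative
#'   slope (no decay) flags the fit `failed`.
#' @seealso [fit_decay_exp()] for the direct exponential cross-check.
#' @export
fit_decay <- function(segment, noise_sd = NULL) {
  n <- nrow(segment)
  if (n < 8L) stop("decay segment must contain at least 8 samples")
  tt <- segment$time_s; f <- segment$intensity
  dtv <- diff(tt)
  y <- diff(f) / dtv
  x <- (f[-1L] + f[-n]) / 2
  if (stats::var(x) < .Machine$double.eps * max(1, mean(x)^2)) {
    fit <- new_regression_fit(NA_real_, NA_real_, matrix(NA, 2L, 2L),
                              NA_real_, n, failed = TRUE,
                              reason = "constant segment (no decay)")
    return(list(fit = fit, lambda_decay = NA_real_, f_inf = NA_real_))
  }
  lmfit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(lmfit))  # exact fits are expected
  b <- unname(stats::coef(lmfit)[2L])
  a <- unname(stats::coef(lmfit)[1L])
  r2 <- sm$r.squared
  # adjacent difference quotients share one sample: their noise is MA(1)
  # with lag-one correlation -1/2; use the corresponding sandwich
  # covariance instead of the iid formula
  X <- cbind(1, x)
  sig2 <- if (!is.null(noise_sd) && is.finite(noise_sd) && noise_sd > 0)
    2 * noise_sd^2 / stats::median(dtv)^2 else sm$sigma^2
  omega <- diag(sig2, n - 1L)
  if (n > 2L) {
    od <- cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L)
    omega[od] <- -sig2 / 2
    omega[od[, 2:1, drop = FALSE]] <- -sig2 / 2
  }
  xtxi <- solve(crossprod(X))
  covb <- xtxi %*% t(X) %*% omega %*% X %*% xtxi
  dimnames(covb) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  fit <- new_regression_fit(b, a, covb, r2, n, sigma = sm$sigma)
  if (!is.finite(b) || b >= 0) {
    fit$failed <- TRUE
    fit$reason <- "non-negative decay slope (no decay)"
    return(list(fit = fit, lambda_decay = NA_real_, f_inf = NA_real_))
  }
  lambda_raw <- -b
  dt0 <- stats::median(dtv)
  uniform <- max(abs(dtv - dt0)) < 1e-9 * dt0
  lambda <- if (uniform && lambda_raw * dt0 / 2 < 1)
    (2 / dt0) * atanh(lambda_raw * dt0 / 2) else lambda_raw
  list(fit = fit, lambda_decay = lambda, f_inf = -a / b)
}

#' Direct exponential fit of a decay segment
#'
#' Nonlinear least-squares fit of `f(t) = f_inf + A exp(-lambda t)`,
#' provided as an independent cross-check of [fit_decay()].
#'
#' @inheritParams fit_decay
#' @return A list with `lambda_decay`, `f_inf`, `amplitude`.
#' @export
fit_decay_exp <- function(segment) {
  t0 <- segment$time_s - segment$time_s[1L]
  f <- segment$intensity
  f_inf0 <- min(f)
  a0 <- max(f) - f_inf0
  # log-linear starting rate from the upper half of the decay
  up <- f - f_inf0 > 0.2 * a0
  l0 <- if (sum(up) >= 3L)
    max(1e-6, -stats::coef(stats::lm(log(f[up] - f_inf0 + 1e-9) ~
                                       t0[up]))[[2L]])
  else 2 / max(t0[length(t0)], 1)
  # scaleOffset lets the relative-offset test converge on exact data
  fit <- stats::nls(f ~ fi + a * exp(-l * t0),
                    start = list(fi = f_inf0, a = a0, l = l0),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(lambda_decay = unname(cf["l"]), f_inf = unname(cf["fi"]),
       amplitude = unname(cf["a"]))
}

#' Resolve TMRM background and scale from the decay asymptote and endpoint
#'
#' During the decay segment the plasma membrane is clamped at `psi_p_val`
#' and the mitochondria are depolarised, so the decay asymptote is
#' `f_inf = f_x + s_T D0 exp(-u_val)`; at the fixation endpoint both
#' potentials are zero, so `f_end = f_x + s_T D0`.  Solving jointly gives
#' `f_x = (f_inf - f_end exp(-u_val)) / (1 - exp(-u_val))`.
#'
#' @param f_inf Decay asymptote, AU.
#' @param f_end TMRM fixation-endpoint fluorescence, AU.
#' @param psi_p_val Clamped plasma membrane potential during the decay,
#'   mV; `|u_val| >= 0.1` required (the system is ill-conditioned near 0).
#' @param constants A [physical_constants()] object.
#' @return A list with `f_x_t` and `s_t_d0` (the product `s_T * D0`), AU.
#' @export
resolve_background_and_scale <- function(f_inf, f_end, psi_p_val,
                                         constants = physical_constants()) {
  u_val <- psi_p_val / constants$thermal_voltage
  if (abs(u_val) < 0.1)
    stop("clamp potential too close to 0 mV: background/scale separation ",
         "is ill-conditioned")
  e <- exp(-u_val)
  f_x <- (f_inf - f_end * e) / (1 - e)
  list(f_x_t = f_x, s_t_d0 = f_end - f_x)
}

#' TMRM plasma-membrane rate constant from the decay rate
#'
#' Inverts the linearised decay rate: `k_T = lambda D0 / (g(u_val)
#' exp(u_val))`, where `g` is the GHK rate factor and `D0` the
#' mitochondrial weighting factor at zero mitochondrial potential.
#'
#' @param lambda_decay Fitted decay rate, s^-1 (> 0).
#' @param psi_p_val Clamp potential during the decay, mV.
#' @param cell A [cell_params()] object.
#' @param constants A [physical_constants()] object.
#' @return `k_T` in s^-1.
#' @export
derive_k_t <- function(lambda_decay, psi_p_val, cell,
                       constants = physical_constants()) {
  stopifnot(lambda_decay > 0)
  u_val <- psi_p_val / constants$thermal_voltage
  d0 <- activity_weight(0, cell, constants)
  lambda_decay * d0 / (ghk_rate_factor(u_val) * exp(u_val))
}

#' Back-calculate the mitochondrial membrane potential from a TMRM trace
#'
#' Converts TMRM fluorescence to the whole-cell activity
#' `a_cell = (f - f_x_T)/s_T`, removes the plasma-membrane disequilibrium
#' using the flux equation
#' `a_c = exp(-u_P) (1 - (da_cell/dt) / (k_T g(u_P)))`, and inverts the
#' compartment model
#' `exp(-u_M) = a_R' (a_cell/a_c - (1 - V_F)) / V_F` sample by sample.
#' For the baseline the distribution-equilibrium form `a_c = exp(-u_P)`
#' is applied to window means.  Samples with a non-positive cytosolic
#' activity or with `a_cell/a_c <= 1 - V_F` are flagged invalid.
#'
#' @param trace_t TMRM trace data.frame (`time_s`, `intensity`).
#' @param psi_p_trace Output of [calibrate_psi_p()] on the matched PMPI
#'   trace (same time base).
#' @param f_x_t,s_t TMRM background and scale, AU.
#' @param k_t TMRM rate constant, s^-1.
#' @param cell A [cell_params()] object.
#' @param baseline_window `c(start, end)` of the baseline in seconds, used
#'   for the baseline estimate; NULL skips it.
#' @param window Derivative window in samples.
#' @param constants A [physical_constants()] object.
#' @return A data.frame `time_s`, `psi_m`, `valid`; attribute `baseline`
#'   holds `psi_m_base` (mV, NA when undefined).
#' @export
calibrate_psi_m <- function(trace_t, psi_p_trace, f_x_t, s_t, k_t, cell,
                            baseline_window = NULL, window = 5L,
                            constants = physical_constants()) {
  vt <- constants$thermal_voltage
  a_raw <- (trace_t$intensity - f_x_t) / s_t
  mf <- moving_linfit(trace_t$time_s, a_raw, window)
  u_p <- psi_p_trace$psi_p / vt
  g_u <- ghk_rate_factor(u_p)
  a_c <- exp(-u_p) * (1 - mf$slope / (k_t * g_u))
  ratio <- mf$value / a_c
  x <- cell$ar_prime * (ratio - (1 - cell$vf)) / cell$vf
  valid <- psi_p_trace$valid & is.finite(a_c) & a_c > 0 &
    is.finite(x) & x > 0
  psi_m <- rep(NA_real_, length(x))
  psi_m[valid] <- -vt * log(x[valid])

  psi_m_base <- NA_real_
  if (!is.null(baseline_window)) {
    bt <- window_samples(trace_t, baseline_window)
    bp <- psi_p_trace[psi_p_trace$time_s >= baseline_window[1L] &
                        psi_p_trace$time_s < baseline_window[2L], ]
    if (nrow(bt) && mean(bp$valid) >= 0.8) {
      a_cell_b <- (mean(bt$intensity) - f_x_t) / s_t
      a_c_b <- exp(-mean(bp$psi_p[bp$valid]) / vt)
      xb <- cell$ar_prime * (a_cell_b / a_c_b - (1 - cell$vf)) / cell$vf
      if (is.finite(xb) && xb > 0) psi_m_base <- -vt * log(xb)
    }
  }
  out <- data.frame(time_s = trace_t$time_s, psi_m = psi_m, valid = valid)
  attr(out, "baseline") <- psi_m_base
  out
}

#' Calibration options
#'
#' @param window Derivative window (samples) for the moving linear fits.
#' @param kstep_tail_frac Fraction of each potassium-step window used for
#'   the plateau mean.
#' @param endpoint_tail_frac Fraction of the fixation window (from its
#'   end) used for the endpoint means.
#' @param settle Samples dropped at the start of the decay and of each
#'   derived window to avoid liquid-handling transients.
#' @param noise_sd Optional named vector `c(TMRM =, PMPI =)` of intensity
#'   noise SDs (AU); estimated from the detrended baseline when NULL.
#' @return A list of options.
#' @export
calibration_options <- function(window = 5L, kstep_tail_frac = 0.5,
                                endpoint_tail_frac = 0.4, settle = 1L,
                                noise_sd = NULL) {
  list(window = window, kstep_tail_frac = kstep_tail_frac,
       endpoint_tail_frac = endpoint_tail_frac, settle = settle,
       noise_sd = noise_sd)
}

# residual SD of a linearly detrended window (intensity noise estimate)
detrended_sd <- function(trace, window) {
  d <- window_samples(trace, window)
  if (nrow(d) < 4L) return(NA_real_)
  stats::sd(stats::residuals(stats::lm(intensity ~ time_s, data = d)))
}

#' Calibrate a single ROI
#'
#' Runs the complete calibration chain on one ROI's TMRM and PMPI traces
#' and returns calibrated potentials with per-point standard errors and a
#' QC report.
#'
#' @param trace_t,trace_p TMRM and PMPI trace data.frames (`time_s`,
#'   `intensity`), background-corrected.
#' @param events A [protocol_events()] object.
#' @param cell A [cell_params()] object.
#' @param kinetics A [probe_kinetics()] object; `k_t` is re-derived from
#'   the trace, `k_p` is used as given.
#' @param options A [calibration_options()] list.
#' @param criteria A [qc_criteria()] list.
#' @param propagate Logical; run delta-method error propagation
#'   (default TRUE).
#' @param constants A [physical_constants()] object.
#' @return An object of class `potential_trace`: a data.frame `time_s`,
#'   `psi_p`, `psi_m`, `se_p`, `se_m`, `valid` with attributes `baseline`
#'   (baseline potentials and their SEs), `model` (the
#'   `calibration_model`) and `qc` (the `qc_report`).
#' @export
calibrate_cell <- function(trace_t, trace_p, events, cell,
                           kinetics = probe_kinetics(),
                           options = calibration_options(),
                           criteria = qc_criteria(),
                           propagate = TRUE,
                           constants = physical_constants()) {
  vt <- constants$thermal_voltage
  t_end <- max(trace_t$time_s, trace_p$time_s) + 1
  w <- segment_windows(events, t_end)
  flags <- character(0)
  dt0 <- stats::median(diff(sort(unique(trace_t$time_s))))
  # half the derivative window: samples this close to a segment boundary
  # have moving-fit windows straddling the discontinuity
  h_trim <- ((options$window - 1L) %/% 2L) * dt0
  base_eff <- c(w$baseline[1L], w$baseline[2L] - h_trim)
  decay_eff <- c(w$decay[1L] + options$settle * dt0 + h_trim,
                 w$decay[2L] - h_trim)

  # intensity noise
  noise_sd <- options$noise_sd
  if (is.null(noise_sd))
    noise_sd <- c(TMRM = detrended_sd(trace_t, w$baseline),
                  PMPI = detrended_sd(trace_p, w$baseline))

  # endpoint means.  PMPI relaxes within seconds, so a tail mean is
  # always adequate; slow-k_T cells may still be relaxing at the end of
  # the fixation plateau, so the TMRM endpoint falls back to the
  # asymptote of an exponential fit when the fitted residual at the tail
  # is materially above the noise floor.
  ep <- w$endpoint
  ep_tail <- c(ep[2L] - options$endpoint_tail_frac * (ep[2L] - ep[1L]),
               ep[2L])
  end_t <- window_samples(trace_t, ep_tail)
  end_p <- window_samples(trace_p, ep_tail)
  f_end <- c(TMRM = mean(end_t$intensity), PMPI = mean(end_p$intensity))
  n_end <- c(TMRM = nrow(end_t), PMPI = nrow(end_p))
  ep_seg <- window_samples(trace_t, ep, settle = options$settle)
  if (nrow(ep_seg) >= 8L) {
    ef <- tryCatch(fit_decay(ep_seg), error = function(e) NULL)
    if (!is.null(ef) && !ef$fit$failed && is.finite(ef$f_inf)) {
      amp <- ep_seg$intensity[1L] - ef$f_inf
      resid_tail <- amp *
        exp(-ef$lambda_decay * (ep_tail[1L] - ep_seg$time_s[1L]))
      floor_sd <- if (is.finite(noise_sd[["TMRM"]]))
        noise_sd[["TMRM"]] else 0
      if (abs(resid_tail) > max(3 * floor_sd / sqrt(nrow(end_t)),
                                1e-3 * abs(f_end[["TMRM"]])) &&
          ef$fit$r2 > 0.8)
        f_end[["TMRM"]] <- ef$f_inf
    }
  }

  # potassium-step regression
  plateaus <- kstep_plateaus(trace_p, w, options$kstep_tail_frac)
  kf <- fit_kstep(plateaus, f_end[["PMPI"]], noise_sd = noise_sd[["PMPI"]])
  if (kf$fit$failed) flags <- c(flags, "negative_activity")

  # plasma membrane potential
  pp <- calibrate_psi_p(trace_p, kf$f_x_p, kf$s_p, kinetics,
                        options$window, constants)
  base_pp <- pp[pp$time_s >= base_eff[1L] & pp$time_s < base_eff[2L], ]
  psi_p_base <- if (nrow(base_pp) && mean(base_pp$valid) >= 0.8)
    mean(base_pp$psi_p[base_pp$valid]) else NA_real_
  val_pp <- window_samples(pp, decay_eff)
  psi_p_val <- if (nrow(val_pp) && mean(val_pp$valid) >= 0.8)
    mean(val_pp$psi_p[val_pp$valid]) else NA_real_

  # TMRM decay
  decay_seg <- window_samples(trace_t, w$decay, settle = options$settle)
  if (nrow(decay_seg) < 8L) {
    flags <- c(flags, "insufficient_segment")
    df <- list(fit = new_regression_fit(NA, NA, matrix(NA, 2, 2), NA,
                                        nrow(decay_seg), failed = TRUE,
                                        reason = "segment too short"),
               lambda_decay = NA_real_, f_inf = NA_real_)
  } else {
    df <- fit_decay(decay_seg, noise_sd = noise_sd[["TMRM"]])
    if (df$fit$failed) flags <- c(flags, "negative_activity")
  }

  ok <- !kf$fit$failed && !df$fit$failed && is.finite(psi_p_val)
  if (ok) {
    rs <- resolve_background_and_scale(df$f_inf, f_end[["TMRM"]],
                                       psi_p_val, constants)
    d0 <- activity_weight(0, cell, constants)
    s_t <- rs$s_t_d0 / d0
    k_t_fit <- derive_k_t(df$lambda_decay, psi_p_val, cell, constants)
    pm <- calibrate_psi_m(trace_t, pp, rs$f_x_t, s_t, k_t_fit, cell,
                          baseline_window = base_eff,
                          window = options$window, constants = constants)
    psi_m_base <- attr(pm, "baseline")
    if (!is.finite(psi_m_base)) flags <- c(flags, "negative_activity")
  } else {
    rs <- list(f_x_t = NA_real_, s_t_d0 = NA_real_)
    d0 <- activity_weight(0, cell, constants)
    s_t <- NA_real_; k_t_fit <- NA_real_
    pm <- data.frame(time_s = trace_t$time_s, psi_m = NA_real_,
                     valid = FALSE)
    psi_m_base <- NA_real_
  }

  model <- structure(list(
    f_x = c(TMRM = rs$f_x_t, PMPI = kf$f_x_p),
    scale = c(TMRM = s_t, PMPI = kf$s_p),
    s_t_d0 = rs$s_t_d0, d0 = d0,
    lambda_decay = df$lambda_decay, f_inf = df$f_inf,
    f_end = f_end, n_end = n_end,
    k_ic = kf$k_ic, k_t_fit = k_t_fit, psi_p_val = psi_p_val,
    fits = list(kstep = kf$fit, decay = df$fit),
    cell = cell, kinetics = kinetics, constants = constants,
    noise_sd = noise_sd,
    windows = c(w, list(baseline_eff = base_eff, decay_eff = decay_eff)),
    options = options, events = events),
    class = "calibration_model")

  out <- data.frame(time_s = trace_t$time_s,
                    psi_p = pp$psi_p[match(trace_t$time_s, pp$time_s)],
                    psi_m = pm$psi_m,
                    se_p = NA_real_, se_m = NA_real_,
                    valid = pm$valid &
                      pp$valid[match(trace_t$time_s, pp$time_s)])
  baseline <- list(psi_p = psi_p_base, psi_m = psi_m_base,
                   se_p = NA_real_, se_m = NA_real_)

  if (propagate && ok) {
    se <- propagate_errors(model, trace_t, trace_p)
    out$se_p <- se$se_p
    out$se_m <- se$se_m
    baseline$se_p <- se$baseline_se_p
    baseline$se_m <- se$baseline_se_m
  }

  res <- structure(out, baseline = baseline, model = model,
                   flags = unique(flags),
                   traces = list(tmrm = trace_t, pmpi = trace_p),
                   class = c("potential_trace", "data.frame"))
  attr(res, "qc") <- apply_qc(res, criteria)
  res
}

#' @export
print.potential_trace <- function(x, ...) {
  b <- attr(x, "baseline")
  qc <- attr(x, "qc")
  cat(sprintf(
    "<potential_trace> %d samples | baseline psi_P = %.1f mV (SE %.2g), psi_M = %.1f mV (SE %.2g) | QC %s\n",
    nrow(x), b$psi_p, b$se_p, b$psi_m, b$se_m,
    if (is.null(qc)) "not run" else if (qc$passed) "pass" else
      paste("FAIL:", paste(qc$reasons, collapse = ", "))))
  invisible(x)
}

#' Calibrate every ROI of a trace set
#'
#' @param traces A [trace_set()] (already pre-processed, or raw: the
#'   background is subtracted automatically when present).
#' @param events A [protocol_events()] object.
#' @param params A parameter list as returned by [read_params()], or NULL
#'   to pass `cell`/`kinetics`/`constants` explicitly.
#' @param cell,kinetics,constants Used when `params` is NULL.
#' @param depletion_correction Passed to [preprocess()].
#' @param ... Passed to [calibrate_cell()] (`options`, `criteria`,
#'   `propagate`).
#' @return A named list of `potential_trace` objects, one per ROI.
#' @export
calibrate_traces <- function(traces, events, params = NULL,
                             cell = params$cell,
                             kinetics = params$kinetics,
                             constants = params$constants,
                             depletion_correction = FALSE, ...) {
  if (is.null(constants)) constants <- physical_constants()
  if (is.null(kinetics)) kinetics <- probe_kinetics()
  if (!is.null(attr(traces, "background")) || depletion_correction)
    traces <- preprocess(traces, events = events,
                         depletion_correction = depletion_correction)
  rois <- unique(traces$roi_id)
  out <- lapply(rois, function(roi) {
    calibrate_cell(get_trace(traces, roi, "TMRM"),
                   get_trace(traces, roi, "PMPI"),
                   events, cell, kinetics, constants = constants, ...)
  })
  names(out) <- rois
  out
}

#' Write calibrated potentials and model sidecars
#'
#' Emits a long CSV (`time_s, roi_id, psi_p_mV, psi_m_mV, se_p_mV,
#' se_m_mV, valid`) and a JSON sidecar per ROI with the calibration
#' parameters, fit diagnostics and QC report.
#'
#' @param results Named list from [calibrate_traces()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_calibration <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(names(results), function(roi) {
    r <- results[[roi]]
    data.frame(time_s = r$time_s, roi_id = roi, psi_p_mV = r$psi_p,
               psi_m_mV = r$psi_m, se_p_mV = r$se_p, se_m_mV = r$se_m,
               valid = r$valid)
  }))
  utils::write.csv(long, file.path(dir, "calibrated.csv"),
                   row.names = FALSE)
  for (roi in names(results)) {
    r <- results[[roi]]
    m <- attr(r, "model")
    qc <- attr(r, "qc")
    side <- list(
      roi_id = roi,
      baseline = attr(r, "baseline"),
      f_x = as.list(m$f_x), scale = as.list(m$scale),
      lambda_decay = m$lambda_decay, f_inf = m$f_inf,
      f_end = as.list(m$f_end), k_ic = m$k_ic, k_t = m$k_t_fit,
      psi_p_val = m$psi_p_val,
      fits = lapply(m$fits, function(f)
        list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
             n_points = f$n_points, failed = f$failed)),
      qc = list(passed = qc$passed, reasons = as.list(qc$reasons)))
    jsonlite::write_json(side,
                         file.path(dir, paste0(roi, "_model.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
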