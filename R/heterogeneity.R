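# Post-calibration analytics: response windows, mono/biphasic
# classification, joint potential distributions with binning along the
# mitochondrial axis, and sensitivity analyses of the calibration.

#' Response windows
#'
#' @param early `c(start, end)` of the early window relative to the
#'   stimulus, s (default 0-5 min).
#' @param plateau `c(start, end)` of the plateau window relative to the
#'   stimulus, s (default 30-60 min).
#' @param late_center,late_halfwidth Centre and half-width (s) of the
#'   "at 30 min" window used by the biphasic rule.
#' @param early_trim Seconds dropped from the start of the early window
#'   by the phenotype classifier only: back-calculated potentials within
#'   one derivative window of the stimulus event are smeared by the
#'   moving linear fit, which would deflate the early mean and bias the
#'   10 percent rule towards "biphasic".  Default 90 s (one sample
#'   beyond half the default 5-sample window at 30 s cadence).
#' @return A list of window definitions.
#' @export
response_windows <- function(early = c(0, 300), plateau = c(1800, 3600),
                             late_center = 1800, late_halfwidth = 150,
                             early_trim = 90) {
  list(early = early, plateau = plateau,
       late = late_center + c(-1, 1) * late_halfwidth,
       early_trim = early_trim)
}

window_mean <- function(trace, col, window, min_valid = 0.8) {
  d <- trace[trace$time_s >= window[1L] & trace$time_s < window[2L], ]
  if (nrow(d) == 0L || mean(d$valid) < min_valid)
    return(list(value = NA_real_, flagged = TRUE))
  list(value = mean(d[[col]][d$valid]), flagged = FALSE)
}

#' Classify a plasma-membrane response as monophasic or biphasic
#'
#' Depolarisation is measured relative to baseline,
#' `delta(t) = psi_P(t) - baseline`.  The response is biphasic iff the
#' depolarisation around 30 min is at least 10 percent larger than the
#' mean depolarisation over the first 5 min (inclusive at the 10 percent
#' boundary) and the early depolarisation is positive; otherwise
#' monophasic.  The rule is invariant to adding a constant to the whole
#' trace.
#'
#' @param trace A data.frame `time_s`, `psi_p`, `valid`.
#' @param baseline Baseline plasma membrane potential, mV.
#' @param stim_time Stimulus time, s.
#' @param windows A [response_windows()] list.
#' @return A list `phenotype` (`"monophasic"` or `"biphasic"`) and
#'   `flagged` (TRUE when no depolarisation occurred).
#' @export
classify_phenotype <- function(trace, baseline, stim_time,
                               windows = response_windows()) {
  trim <- if (is.null(windows$early_trim)) 0 else windows$early_trim
  d5 <- window_mean(trace, "psi_p",
                    stim_time + windows$early + c(trim, 0))
  d30 <- window_mean(trace, "psi_p", stim_time + windows$late)
  if (is.na(d5$value) || is.na(d30$value))
    return(list(phenotype = "monophasic", flagged = TRUE))
  delta5 <- d5$value - baseline
  delta30 <- d30$value - baseline
  if (delta5 <= 0)
    return(list(phenotype = "monophasic", flagged = TRUE))
  list(phenotype = if (delta30 >= 1.10 * delta5) "biphasic"
       else "monophasic",
       flagged = FALSE)
}

#' Summarise the stimulus response of one calibrated cell
#'
#' Window means of both potentials over the early (0-5 min) and plateau
#' (30-60 min) post-stimulus windows, relative responses as exact
#' differences from baseline, and the mono/biphasic phenotype.
#'
#' @param result A `potential_trace` from [calibrate_cell()].
#' @param stim_time Stimulus time, s.
#' @param windows A [response_windows()] list.
#' @param t_limit Optional recording limit (e.g. the mitochondrial
#'   depolarisation time); a plateau window extending past it flags the
#'   summary.
#' @param roi_id Label carried into the output row.
#' @return A one-row data.frame (class `response_summary`): baseline,
#'   early and plateau potentials, relative responses, `phenotype` and
#'   `flagged`.
#' @export
summarize_response <- function(result, stim_time,
                               windows = response_windows(),
                               t_limit = NULL, roi_id = "cell") {
  b <- attr(result, "baseline")
  early_p <- window_mean(result, "psi_p", stim_time + windows$early)
  early_m <- window_mean(result, "psi_m", stim_time + windows$early)
  plat_p <- window_mean(result, "psi_p", stim_time + windows$plateau)
  plat_m <- window_mean(result, "psi_m", stim_time + windows$plateau)
  flagged <- early_p$flagged || early_m$flagged || plat_p$flagged ||
    plat_m$flagged
  if (!is.null(t_limit) && stim_time + windows$plateau[2L] > t_limit)
    flagged <- TRUE
  ph <- classify_phenotype(result, b$psi_p, stim_time, windows)
  out <- data.frame(
    roi_id = roi_id,
    baseline_psi_p = b$psi_p, baseline_psi_m = b$psi_m,
    early_psi_p = early_p$value, early_psi_m = early_m$value,
    plateau_psi_p = plat_p$value, plateau_psi_m = plat_m$value,
    relative_dp = plat_p$value - b$psi_p,
    relative_dm = plat_m$value - b$psi_m,
    phenotype = ph$phenotype,
    flagged = flagged || ph$flagged,
    stringsAsFactors = FALSE)
  class(out) <- c("response_summary", "data.frame")
  out
}

#' Joint distribution of the two potentials with mitochondrial binning
#'
#' Two-dimensional histogram of (psi_M, psi_P) pairs over cells, plus
#' means of psi_P with SE computed by binning cells along the psi_M axis.
#' SEs and the optional two-group comparison (two-tailed t-test per bin)
#' are computed on replicate-level means, not on pooled cells, to avoid
#' pseudoreplication; bins without enough replicates are marked.
#'
#' @param cells A data.frame of response summaries (rows from
#'   [summarize_response()]), with optional columns `replicate` and
#'   `group`.
#' @param mode `"absolute"` (plateau potentials) or `"relative"`
#'   (differences from baseline).
#' @param m_edges,p_edges Bin edges for the psi_M and psi_P axes, mV;
#'   defaults cover the data.
#' @return A list with `hist` (matrix, psi_M bins x psi_P bins, summing
#'   to the number of cells), `m_edges`, `p_edges`, `binned` (per-psi_M
#'   bin mean psi_P with SE and replicate count) and `comparison`
#'   (per-bin p-values when `group` has two levels; NA where data are
#'   insufficient).
#' @export
joint_distribution <- function(cells, mode = c("absolute", "relative"),
                               m_edges = NULL, p_edges = NULL) {
  mode <- match.arg(mode)
  if (nrow(cells) == 0L) stop("empty input")
  m <- if (mode == "absolute") cells$plateau_psi_m else cells$relative_dm
  p <- if (mode == "absolute") cells$plateau_psi_p else cells$relative_dp
  keep <- is.finite(m) & is.finite(p)
  if (!any(keep))
    stop("empty input: no cells with finite potentials in mode '",
         mode, "'")
  cells <- cells[keep, , drop = FALSE]; m <- m[keep]; p <- p[keep]
  if (is.null(m_edges))
    m_edges <- pretty(range(m), n = 10)
  if (is.null(p_edges))
    p_edges <- pretty(range(p), n = 10)
  mi <- cut(m, m_edges, include.lowest = TRUE, labels = FALSE)
  pi <- cut(p, p_edges, include.lowest = TRUE, labels = FALSE)
  h <- matrix(0L, length(m_edges) - 1L, length(p_edges) - 1L)
  for (i in seq_along(mi))
    if (!is.na(mi[i]) && !is.na(pi[i]))
      h[mi[i], pi[i]] <- h[mi[i], pi[i]] + 1L
  rep_id <- if (!is.null(cells$replicate)) cells$replicate
            else rep("rep1", nrow(cells))
  grp <- if (!is.null(cells$group)) cells$group else NULL

  # replicate-level mean psi_P per psi_M bin
  binned <- do.call(rbind, lapply(seq_len(length(m_edges) - 1L),
                                  function(b) {
    sel <- !is.na(mi) & mi == b
    if (!any(sel))
      return(data.frame(bin = b, mid = mean(m_edges[b + 0:1]),
                        mean_psi_m = NA_real_,
                        mean_psi_p = NA_real_, se = NA_real_,
                        n_cells = 0L, n_replicates = 0L,
                        insufficient = TRUE))
    reps <- tapply(p[sel], rep_id[sel], mean)
    reps_m <- tapply(m[sel], rep_id[sel], mean)
    data.frame(bin = b, mid = mean(m_edges[b + 0:1]),
               mean_psi_m = mean(reps_m),
               mean_psi_p = mean(reps),
               se = if (length(reps) > 1L)
                 stats::sd(reps) / sqrt(length(reps)) else NA_real_,
               n_cells = sum(sel), n_replicates = length(reps),
               insufficient = length(reps) < 2L)
  }))

  comparison <- NULL
  if (!is.null(grp) && length(unique(grp)) == 2L) {
    gl <- unique(grp)
    comparison <- do.call(rbind, lapply(seq_len(length(m_edges) - 1L),
                                        function(b) {
      pvals <- lapply(gl, function(g) {
        sel <- !is.na(mi) & mi == b & grp == g
        if (!any(sel)) return(numeric(0))
        tapply(p[sel], rep_id[sel], mean)
      })
      ok <- all(vapply(pvals, length, integer(1L)) >= 2L)
      data.frame(bin = b, mid = mean(m_edges[b + 0:1]),
                 p_value = if (ok)
                   stats::t.test(pvals[[1L]], pvals[[2L]])$p.value
                 else NA_real_,
                 insufficient = !ok)
    }))
  }
  list(hist = h, m_edges = m_edges, p_edges = p_edges,
       binned = binned, comparison = comparison, n = nrow(cells))
}

# recalibrate the mitochondrial potential of a calibrated cell with a
# perturbed volume fraction, holding the fitted optical constants and
# rate constant at their values (the independent-parameter convention of
# the error propagation)
recalibrate_with_vf <- function(result, vf_new) {
  model <- attr(result, "model")
  tr <- attr(result, "traces")
  cell2 <- cell_params(vf_new, model$cell$ar_prime)
  pp <- data.frame(time_s = result$time_s, psi_p = result$psi_p,
                   valid = is.finite(result$psi_p))
  wb <- if (!is.null(model$windows$baseline_eff))
    model$windows$baseline_eff else model$windows$baseline
  pm <- calibrate_psi_m(tr$tmrm, pp, model$f_x[["TMRM"]],
                        model$scale[["TMRM"]], model$k_t_fit, cell2,
                        baseline_window = wb,
                        window = model$options$window,
                        constants = model$constants)
  pm
}

#' Sensitivity of calibrated potentials to volume-fraction error
#'
#' Recalibrates each cell's mitochondrial potential with the assumed
#' volume fraction perturbed by `vf_error` (e.g. +0.25 for +25 percent),
#' holding the fitted optical constants and rate constant fixed (the
#' independent-parameter convention used by the error propagation), and
#' reports the bias of the absolute potentials and of the
#' relative-to-baseline response.  In the mitochondria-dominated regime
#' the absolute bias approaches `thermal_voltage * log(1 + vf_error)`
#' while the relative bias largely cancels.
#'
#' @param results Named list of `potential_trace` objects from
#'   [calibrate_traces()].
#' @param vf_error Fractional volume-fraction perturbation.
#' @param stim_time Stimulus time, s (for the plateau window).
#' @param windows A [response_windows()] list.
#' @return A list (class `sensitivity_result`) with `scenario`,
#'   `vf_error` and a per-cell data.frame of `bias_abs_baseline`,
#'   `bias_abs_plateau`, `bias_relative` (mV).
#' @export
sensitivity_vf <- function(results, vf_error, stim_time,
                           windows = response_windows()) {
  rows <- lapply(names(results), function(roi) {
    r <- results[[roi]]
    model <- attr(r, "model")
    vf0 <- model$cell$vf
    pm2 <- recalibrate_with_vf(r, vf0 * (1 + vf_error))
    b0 <- attr(r, "baseline")$psi_m
    b2 <- attr(pm2, "baseline")
    r2 <- r; r2$psi_m <- pm2$psi_m; r2$valid <- pm2$valid
    p0 <- window_mean(r, "psi_m", stim_time + windows$plateau)$value
    p2 <- window_mean(r2, "psi_m", stim_time + windows$plateau)$value
    data.frame(roi_id = roi,
               bias_abs_baseline = b2 - b0,
               bias_abs_plateau = p2 - p0,
               bias_relative = (p2 - b2) - (p0 - b0))
  })
  structure(list(scenario = "vf_variation", vf_error = vf_error,
                 applies_to = c("absolute", "relative"),
                 bias = do.call(rbind, rows)),
            class = "sensitivity_result")
}

#' Sensitivity to a fluorescence-collection artifact
#'
#' Multiplies the background-corrected fluorescence of the selected
#' channels by `1 + epsilon` over a time window (by default the glucose
#' stimulation period, leaving the internal calibration untouched),
#' reruns the full calibration, and reports the displacement of the
#' plateau potentials in the (psi_M, psi_P) plane, in absolute and
#' relative-to-baseline coordinates.  The start/end coordinates emitted
#' per cell reproduce the diagonal overlay construction of the
#' distribution plots.
#'
#' @param results Named list of `potential_trace` objects (with traces
#'   and events attached, as produced by [calibrate_traces()]).
#' @param epsilon Fractional fluorescence change (e.g. 0.024).
#' @param window `c(start, end)` in seconds, or `"stimulus_only"` for
#'   stimulus-to-depolarisation.
#' @param channels Channels affected (default both).
#' @param stim_time Stimulus time, s.
#' @param windows A [response_windows()] list.
#' @return A `sensitivity_result` with per-cell displacement vectors
#'   `d_psi_m`, `d_psi_p` (absolute) and `d_rel_m`, `d_rel_p` (relative),
#'   plus start/end coordinates of the overlay segment.
#' @export
sensitivity_artifact <- function(results, epsilon,
                                 window = "stimulus_only",
                                 channels = c("TMRM", "PMPI"),
                                 stim_time, windows = response_windows()) {
  rows <- lapply(names(results), function(roi) {
    r <- results[[roi]]
    model <- attr(r, "model")
    tr <- attr(r, "traces")
    ev <- model$events
    win <- if (identical(window, "stimulus_only"))
      c(model$windows$response[1L], model$windows$response[2L])
    else window
    perturb <- function(trace, ch) {
      if (!(ch %in% channels)) return(trace)
      i <- trace$time_s >= win[1L] & trace$time_s < win[2L]
      fx <- model$f_x[[ch]]
      trace$intensity[i] <- fx +
        (1 + epsilon) * (trace$intensity[i] - fx)
      trace
    }
    r2 <- calibrate_cell(perturb(tr$tmrm, "TMRM"),
                         perturb(tr$pmpi, "PMPI"),
                         ev, model$cell, model$kinetics,
                         options = model$options, propagate = FALSE,
                         constants = model$constants)
    p0m <- window_mean(r, "psi_m", stim_time + windows$plateau)$value
    p0p <- window_mean(r, "psi_p", stim_time + windows$plateau)$value
    p2m <- window_mean(r2, "psi_m", stim_time + windows$plateau)$value
    p2p <- window_mean(r2, "psi_p", stim_time + windows$plateau)$value
    b0 <- attr(r, "baseline"); b2 <- attr(r2, "baseline")
    data.frame(roi_id = roi,
               d_psi_m = p2m - p0m, d_psi_p = p2p - p0p,
               d_rel_m = (p2m - b2$psi_m) - (p0m - b0$psi_m),
               d_rel_p = (p2p - b2$psi_p) - (p0p - b0$psi_p),
               start_m = p0m, start_p = p0p, end_m = p2m, end_p = p2p)
  })
  structure(list(scenario = "collection_artifact", epsilon = epsilon,
                 window = window, channels = channels,
                 applies_to = c("absolute", "relative"),
                 displacement = do.call(rbind, rows)),
            class = "sensitivity_result")
}

#' Predicted-SE Gaussian cloud specification
#'
#' Mean per-cell predicted standard errors of the plateau potentials,
#' in absolute or relative-to-baseline mode, as the SD pair of a
#' two-dimensional Gaussian overlay for the distribution plots.
#'
#' @param results Named list of `potential_trace` objects.
#' @param mode `"absolute"` or `"relative"`.
#' @param stim_time Stimulus time, s.
#' @param windows A [response_windows()] list.
#' @return A `sensitivity_result` with `sd_psi_m`, `sd_psi_p` (mV) and
#'   the per-cell SE table.
#' @export
predicted_se_cloud <- function(results, mode = c("absolute", "relative"),
                               stim_time, windows = response_windows()) {
  mode <- match.arg(mode)
  rows <- lapply(names(results), function(roi) {
    r <- results[[roi]]
    model <- attr(r, "model")
    tr <- attr(r, "traces")
    se <- propagate_window_se(model, tr$tmrm, tr$pmpi,
                              stim_time + windows$plateau,
                              relative = (mode == "relative"))
    data.frame(roi_id = roi, se_psi_p = se$se_p, se_psi_m = se$se_m)
  })
  tab <- do.call(rbind, rows)
  structure(list(scenario = "stochastic_se", applies_to = mode,
                 sd_psi_m = mean(tab$se_psi_m, na.rm = TRUE),
                 sd_psi_p = mean(tab$se_psi_p, na.rm = TRUE),
                 per_cell = tab),
            class = "sensitivity_result")
}

#' Delta-method SE of a window mean (absolute or relative to baseline)
#'
#' @param model A `calibration_model`.
#' @param trace_t,trace_p The fitted traces.
#' @param window `c(start, end)` in seconds.
#' @param relative Logical; SE of (window mean - baseline) instead of the
#'   window mean.
#' @return A list `se_p`, `se_m` (mV).
#' @export
propagate_window_se <- function(model, trace_t, trace_p, window,
                                relative = FALSE) {
  et <- error_theta(model, trace_t, trace_p)
  th <- et$theta
  dt0 <- stats::median(diff(trace_t$time_s))
  fixed <- list(
    constants = model$constants, kinetics = model$kinetics, dt = dt0,
    mf_p = moving_linfit(trace_p$time_s, trace_p$intensity,
                         model$options$window),
    mf_t = moving_linfit(trace_t$time_s, trace_t$intensity,
                         model$options$window))
  idx <- trace_t$time_s >= window[1L] & trace_t$time_s < window[2L]
  outputs <- function(f) {
    wp <- mean(f$psi_p[idx], na.rm = TRUE)
    wm <- mean(f$psi_m[idx], na.rm = TRUE)
    if (relative) c(wp - f$psi_p_base, wm - f$psi_m_base) else c(wp, wm)
  }
  f0 <- calibration_map(th, fixed)
  J <- matrix(0, nrow = 2L, ncol = length(th))
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
  # intensity contribution: window mean of weakly correlated per-point
  # noise; adjacent samples share the moving-fit window
  pe <- propagate_errors(model, trace_t, trace_p)
  n_w <- sum(idx)
  corr_fac <- min(n_w, model$options$window)
  var_int_p <- mean(pe$var_int_p[idx], na.rm = TRUE) * corr_fac / n_w
  var_int_m <- mean(pe$var_int_m[idx], na.rm = TRUE) * corr_fac / n_w
  list(se_p = sqrt(var_param[1L] + var_int_p),
       se_m = sqrt(var_param[2L] + var_int_m))
}
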