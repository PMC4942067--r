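# Containers and I/O for fluorescence trace tables and protocol events.

#' Fluorescence trace set
#'
#' A long-format table of per-ROI, per-channel intensity time series.
#' Rows with `roi_id == "__background__"` are split off into the
#' `background` attribute (one trace per channel).
#'
#' @param df A data.frame with columns `time_s`, `roi_id`, `channel` and
#'   `intensity`. Time must be strictly increasing within each
#'   (roi, channel) pair and intensities non-negative is not enforced
#'   (noise may produce small negatives).
#' @param background Optional data.frame with columns `time_s`, `channel`,
#'   `intensity` holding the background-ROI trace.
#' @return A data.frame of class `trace_set` with attribute `background`.
#' @export
trace_set <- function(df, background = NULL) {
  stopifnot(all(c("time_s", "roi_id", "channel", "intensity") %in%
                  names(df)))
  df$roi_id <- as.character(df$roi_id)
  df$channel <- as.character(df$channel)
  bg_rows <- df$roi_id == "__background__"
  if (any(bg_rows)) {
    background <- df[bg_rows, c("time_s", "channel", "intensity")]
    df <- df[!bg_rows, , drop = FALSE]
  }
  sp <- split(df$time_s, interaction(df$roi_id, df$channel, drop = TRUE))
  if (!all(vapply(sp, function(x) all(diff(x) > 0), logical(1L))))
    stop("time must be strictly increasing within each (roi, channel)")
  rownames(df) <- NULL
  structure(df, background = background,
            class = c("trace_set", "data.frame"))
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d ROIs x %d channels, %d samples%s\n",
              length(unique(x$roi_id)), length(unique(x$channel)),
              nrow(x),
              if (is.null(attr(x, "background"))) "" else
                ", with background trace"))
  invisible(x)
}

#' Extract one ROI/channel trace
#'
#' @param traces A [trace_set()].
#' @param roi ROI identifier.
#' @param channel Channel name (`"TMRM"` or `"PMPI"`).
#' @return A data.frame with columns `time_s`, `intensity`.
#' @export
get_trace <- function(traces, roi, channel) {
  out <- traces[traces$roi_id == roi & traces$channel == channel,
                c("time_s", "intensity")]
  if (nrow(out) == 0L)
    stop(sprintf("no samples for roi '%s' channel '%s'", roi, channel))
  rownames(out) <- NULL
  out
}

#' Read / write trace tables (long CSV)
#'
#' Columns `time_s, roi_id, channel, intensity`; optional rows with
#' `roi_id = "__background__"` carry the background-ROI trace.
#'
#' @param path CSV file path.
#' @return `read_traces` returns a [trace_set()].
#' @export
read_traces <- function(path) {
  trace_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_traces
#' @param traces A [trace_set()].
#' @export
write_traces <- function(traces, path) {
  df <- as.data.frame(traces)
  bg <- attr(traces, "background")
  if (!is.null(bg)) {
    bg$roi_id <- "__background__"
    df <- rbind(df, bg[, c("time_s", "roi_id", "channel", "intensity")])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a trace set to a common uniform grid
#'
#' Linear interpolation of every (roi, channel) trace onto a shared
#' uniform clock, as used for averaging interleaved acquisitions.
#'
#' @param traces A [trace_set()].
#' @param dt Grid interval in seconds (default 30).
#' @return A [trace_set()] on the common grid.
#' @export
resample_traces <- function(traces, dt = 30) {
  t0 <- max(tapply(traces$time_s, interaction(traces$roi_id,
                                              traces$channel, drop = TRUE),
                   min))
  t1 <- min(tapply(traces$time_s, interaction(traces$roi_id,
                                              traces$channel, drop = TRUE),
                   max))
  grid <- seq(ceiling(t0 / dt) * dt, t1, by = dt)
  pieces <- lapply(split(seq_len(nrow(traces)),
                         interaction(traces$roi_id, traces$channel,
                                     drop = TRUE)),
                   function(idx) {
                     d <- traces[idx, ]
                     data.frame(time_s = grid,
                                roi_id = d$roi_id[1L],
                                channel = d$channel[1L],
                                intensity = stats::approx(d$time_s,
                                                          d$intensity,
                                                          grid)$y,
                                stringsAsFactors = FALSE)
                   })
  out <- do.call(rbind, pieces)
  bg <- attr(traces, "background")
  if (!is.null(bg)) {
    bg <- do.call(rbind, lapply(split(bg, bg$channel), function(d)
      data.frame(time_s = grid, channel = d$channel[1L],
                 intensity = stats::approx(d$time_s, d$intensity,
                                           grid)$y)))
  }
  trace_set(out, background = bg)
}

#' Protocol event table
#'
#' Ordered experimental actions that segment a recording: at most one
#' `stimulus`, exactly one `mito_depol` (complete mitochondrial
#' depolarisation cocktail), one or more `k_step` events (each carrying
#' the new extracellular potassium concentration `K_ec_mM`) strictly after
#' the depolarisation, and exactly one final `fixation` event.
#'
#' @param df A data.frame with columns `time_s`,
#'   `kind` in `{stimulus, mito_depol, k_step, fixation}`, `param`, and
#'   `value` (e.g. `k_step / K_ec_mM / 20`).
#' @return A data.frame of class `protocol_events`.
#' @export
protocol_events <- function(df) {
  stopifnot(all(c("time_s", "kind") %in% names(df)))
  if (is.null(df$param)) df$param <- NA_character_
  if (is.null(df$value)) df$value <- NA_real_
  df <- df[order(df$time_s), , drop = FALSE]
  kinds <- c("stimulus", "mito_depol", "k_step", "fixation")
  if (!all(df$kind %in% kinds))
    stop("event kind must be one of ", paste(kinds, collapse = ", "))
  if (sum(df$kind == "mito_depol") != 1L)
    stop("exactly one mito_depol event required")
  if (sum(df$kind == "fixation") != 1L)
    stop("exactly one fixation event required")
  t_depol <- df$time_s[df$kind == "mito_depol"]
  t_fix <- df$time_s[df$kind == "fixation"]
  ks <- df[df$kind == "k_step", , drop = FALSE]
  if (nrow(ks)) {
    if (any(ks$time_s <= t_depol) || any(ks$time_s >= t_fix))
      stop("k_step events must lie strictly between mito_depol and fixation")
    if (any(!is.finite(ks$value)) || any(ks$value <= 0))
      stop("each k_step must carry K_ec_mM > 0 in `value`")
  }
  if (t_fix < max(df$time_s)) stop("fixation must be the last event")
  rownames(df) <- NULL
  structure(df, class = c("protocol_events", "data.frame"))
}

#' @rdname protocol_events
#' @param path CSV file path with columns `time_s, kind, param, value`.
#' @export
read_events <- function(path) {
  protocol_events(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname protocol_events
#' @param events A `protocol_events` object.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Derive segment windows from protocol events
#'
#' @param events A [protocol_events()] object.
#' @param t_end End of the recording, s.
#' @return A list with elements `baseline`, `response` (NULL without a
#'   stimulus), `decay`, `ksteps` (data.frame `start`, `end`, `k_ec`) and
#'   `endpoint`, each a `c(start, end)` window in seconds.
#' @export
segment_windows <- function(events, t_end) {
  ev <- as.data.frame(events)
  t_stim <- ev$time_s[ev$kind == "stimulus"]
  t_depol <- ev$time_s[ev$kind == "mito_depol"]
  t_fix <- ev$time_s[ev$kind == "fixation"]
  ks <- ev[ev$kind == "k_step", , drop = FALSE]
  first_after_baseline <- min(c(t_stim, t_depol))
  k_bounds <- c(ks$time_s, t_fix)
  list(
    baseline = c(0, first_after_baseline),
    response = if (length(t_stim)) c(t_stim, t_depol) else NULL,
    stim_time = if (length(t_stim)) t_stim else NULL,
    decay = c(t_depol, if (nrow(ks)) ks$time_s[1L] else t_fix),
    ksteps = if (nrow(ks))
      data.frame(start = ks$time_s,
                 end = k_bounds[-1L],
                 k_ec = ks$value) else NULL,
    endpoint = c(t_fix, t_end))
}

# samples of a trace falling inside a window [start, end); optionally drop
# the first `settle` samples after the window opens.
window_samples <- function(trace, window, settle = 0L) {
  idx <- which(trace$time_s >= window[1L] & trace$time_s < window[2L])
  if (settle > 0L && length(idx) > settle) idx <- idx[-seq_len(settle)]
  trace[idx, , drop = FALSE]
}

#' Read / write a cell and probe parameter file (YAML)
#'
#' Fields: `temperature_C`, `vf`, `vf_se`, `ar_prime`, `ar_prime_se`,
#' `k_t`, `k_p`, `p_n` (must be 0), and `optics` with per-channel `f_x`
#' and `scale` (used by the simulator only).
#'
#' @param path YAML file path.
#' @return `read_params` returns a list with components `constants`
#'   ([physical_constants()]), `cell` ([cell_params()]), `kinetics`
#'   ([probe_kinetics()]) and `optics`.
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  temp_k <- if (!is.null(p$temperature_C)) p$temperature_C + 273.15
            else 310.15
  list(
    constants = physical_constants(temp_k),
    cell = cell_params(p$vf, p$ar_prime,
                       vf_se = if (is.null(p$vf_se)) 0 else p$vf_se,
                       ar_prime_se = if (is.null(p$ar_prime_se)) 0
                                     else p$ar_prime_se),
    kinetics = probe_kinetics(
      k_t = if (is.null(p$k_t)) 0.015 else p$k_t,
      k_p = if (is.null(p$k_p)) 0.38 else p$k_p,
      p_n = if (is.null(p$p_n)) 0 else p$p_n),
    optics = if (is.null(p$optics)) default_optics() else p$optics)
}

#' @rdname read_params
#' @param params A list as returned by `read_params`.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(list(
    temperature_C = params$constants$temperature - 273.15,
    vf = params$cell$vf, vf_se = params$cell$vf_se,
    ar_prime = params$cell$ar_prime,
    ar_prime_se = params$cell$ar_prime_se,
    k_t = params$kinetics$k_t, k_p = params$kinetics$k_p,
    p_n = params$kinetics$p_n,
    optics = params$optics), path)
  invisible(path)
}
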