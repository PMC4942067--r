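# Synthetic data generator: protocol traces and confocal image fields
# with known ground truth, parameterised by cell-type presets.

#' Cell-type presets
#'
#' Published population parameters for the supported specimens: the
#' mitochondria:cell volume fraction `vf`, the apparent activity
#' coefficient ratio `ar_prime`, the TMRM plasma-membrane rate constant
#' `k_t` and resting / 16 mM glucose mitochondrial potentials.  The
#' resting plasma membrane potential (-65 mV) and the intracellular
#' potassium concentration (140 mM) are assumptions recorded in every
#' truth sidecar; the clonal-line kinetic and potential values reuse the
#' primary-cell determinations where no line-specific value exists.
#'
#' @param name One of `"rat_beta"`, `"human_beta"`, `"ins1_832_13"`,
#'   `"ins1e"`.
#' @return A list of preset parameters.
#' @export
preset <- function(name = c("rat_beta", "human_beta", "ins1_832_13",
                            "ins1e")) {
  name <- match.arg(name)
  base <- list(
    k_t = 0.015, k_t_se = 0.002, k_p = 0.38,
    psi_p_base = -65, psi_p_plateau = -45,
    k_ic = 140, k_ec_base = 5.4,
    psi_m_base_sd = 8, psi_m_glucose_sd = 12, psi_p_base_sd = 3)
  tab <- list(
    rat_beta = list(vf = 0.078, vf_se = 0.0013,
                    ar_prime = 0.296, ar_prime_se = 0.007,
                    psi_m_base = -120, psi_m_glucose = -166),
    human_beta = list(vf = 0.077, vf_se = 0.0006,
                      ar_prime = 0.359, ar_prime_se = 0.005,
                      psi_m_base = -130, psi_m_glucose = -160),
    ins1_832_13 = list(vf = 0.063, vf_se = 0.0049,
                       ar_prime = 0.36, ar_prime_se = 0.05,
                       psi_m_base = -120, psi_m_glucose = -160),
    ins1e = list(vf = 0.0694, vf_se = 0.0008,
                 ar_prime = 0.36, ar_prime_se = 0.05,
                 psi_m_base = -120, psi_m_glucose = -160))
  c(list(name = name), tab[[name]], base)
}

#' Standard protocol event table
#'
#' Builds the canonical recording paradigm: baseline, optional glucose
#' stimulus, complete mitochondrial depolarisation (decay segment),
#' stepwise potassium calibration up to ~80 mM, and a fixation endpoint.
#'
#' @param baseline_s Baseline duration, s.
#' @param stimulus Logical; include a glucose stimulus segment.
#' @param glucose_mM Stimulus glucose concentration.
#' @param stimulus_s Stimulus segment duration, s.
#' @param decay_s Post-depolarisation decay segment duration, s
#'   (20 min default).
#' @param k_steps Extracellular potassium concentrations of the
#'   calibration steps, mM.
#' @param kstep_s Duration of each potassium step, s.
#' @param fixation_s Duration of the fixation endpoint plateau, s.
#' @return A [protocol_events()] object; the recording end time is
#'   attached as attribute `t_end`.
#' @export
standard_protocol <- function(baseline_s = 900, stimulus = TRUE,
                              glucose_mM = 16, stimulus_s = 3900,
                              decay_s = 1200,
                              k_steps = c(10.8, 20, 40, 80),
                              kstep_s = 180, fixation_s = 720) {
  t <- baseline_s
  rows <- list()
  if (stimulus) {
    rows[[length(rows) + 1L]] <-
      data.frame(time_s = t, kind = "stimulus", param = "glucose_mM",
                 value = glucose_mM)
    t <- t + stimulus_s
  }
  rows[[length(rows) + 1L]] <-
    data.frame(time_s = t, kind = "mito_depol", param = NA, value = NA)
  t <- t + decay_s
  for (k in k_steps) {
    rows[[length(rows) + 1L]] <-
      data.frame(time_s = t, kind = "k_step", param = "K_ec_mM", value = k)
    t <- t + kstep_s
  }
  rows[[length(rows) + 1L]] <-
    data.frame(time_s = t, kind = "fixation", param = NA, value = NA)
  ev <- protocol_events(do.call(rbind, rows))
  attr(ev, "t_end") <- t + fixation_s
  ev
}

#' Ground-truth potential time courses for one cell
#'
#' Builds vectorised `psi_p(t)` / `psi_m(t)` functions implementing the
#' protocol: equilibrium baseline; on glucose, a mono-exponential
#' mitochondrial hyperpolarisation (time constant `tau_m`) and a plasma
#' membrane depolarisation that is monophasic or, for biphasic cells,
#' carries a second slow component; on mitochondrial depolarisation the
#' mitochondrial potential collapses to 0 and the plasma membrane is
#' clamped at the potassium diffusion potential; each potassium step
#' shifts the clamp by the Nernst potential of the new bath potassium;
#' after fixation both potentials are 0.
#'
#' @param cell_row One row of a population data.frame from
#'   [make_population()] (or any list with the same fields).
#' @param events A [protocol_events()] object.
#' @param constants A [physical_constants()] object.
#' @param tau_m,tau_p,tau_p2 Time constants (s) of the mitochondrial
#'   response and the fast and slow plasma-membrane response components.
#'   The fast component (20 s) completes well inside the 0-5 min early
#'   window, so an ideal monophasic responder sits below the 10 percent
#'   biphasic threshold; the slow component spans tens of minutes.
#' @return A list with functions `psi_p(t)`, `psi_m(t)` and the derived
#'   clamp potential `psi_val` (mV).
#' @export
truth_functions <- function(cell_row, events,
                            constants = physical_constants(),
                            tau_m = 60, tau_p = 20, tau_p2 = 900) {
  w <- segment_windows(events, Inf)
  vt <- constants$thermal_voltage
  k_ic <- cell_row$k_ic
  psi_val <- vt * log(cell_row$k_ec_base / k_ic)
  t_stim <- w$stim_time
  t_depol <- w$decay[1L]
  t_fix <- w$endpoint[1L]
  ks <- w$ksteps
  has_stim <- !is.null(t_stim)
  biphasic <- isTRUE(cell_row$biphasic > 0)
  d_p1 <- if (has_stim) {
    if (biphasic) 0.6 * (cell_row$psi_p_plateau - cell_row$psi_p_base)
    else cell_row$psi_p_plateau - cell_row$psi_p_base
  } else 0
  d_p2 <- if (has_stim && biphasic)
    0.4 * (cell_row$psi_p_plateau - cell_row$psi_p_base) else 0

  psi_p <- function(t) {
    out <- rep(cell_row$psi_p_base, length(t))
    if (has_stim) {
      i <- t >= t_stim & t < t_depol
      dt <- t[i] - t_stim
      out[i] <- cell_row$psi_p_base + d_p1 * (1 - exp(-dt / tau_p)) +
        d_p2 * (1 - exp(-dt / tau_p2))
    }
    i <- t >= t_depol & t < t_fix
    out[i] <- psi_val
    if (!is.null(ks)) {
      for (j in seq_len(nrow(ks))) {
        i <- t >= ks$start[j] & t < ks$end[j]
        out[i] <- vt * log(ks$k_ec[j] / k_ic)
      }
    }
    out[t >= t_fix] <- 0
    out
  }
  psi_m <- function(t) {
    out <- rep(cell_row$psi_m_base, length(t))
    if (has_stim) {
      i <- t >= t_stim & t < t_depol
      dt <- t[i] - t_stim
      out[i] <- cell_row$psi_m_base +
        (cell_row$psi_m_glucose - cell_row$psi_m_base) *
        (1 - exp(-dt / tau_m))
    }
    out[t >= t_depol] <- 0
    out
  }
  list(psi_p = psi_p, psi_m = psi_m, psi_val = psi_val)
}

#' Draw a synthetic cell population
#'
#' Draws per-cell ground-truth parameters for a preset.  Each cell gets a
#' baseline mitochondrial and plasma membrane potential, a glucose
#' activation scalar producing a continuous spread of stimulated
#' mitochondrial potentials, a plasma-membrane plateau coupled to the
#' mitochondrial hyperpolarisation through a smooth monotone saturating
#' map with additive noise (canonical-pathway emulation), a biphasic flag
#' (biphasic cells draw stronger activation), and a cell-specific volume
#' fraction with coefficient of variation `vf_cell_cv`.  In glibenclamide
#' mode the plasma membrane is depolarised while the mitochondrial
#' potential stays near baseline (K_ATP bypass).
#'
#' @param n_cells Number of cells.
#' @param preset_name Preset passed to [preset()].
#' @param glucose_mM Stimulus concentration (scales mean activation
#'   linearly between 3 mM, no response, and 16 mM, full response).
#' @param secretagogue `"glucose"` or `"glibenclamide"`.
#' @param fraction_biphasic Fraction of biphasic responders.
#' @param vf_cell_cv Cell-to-cell coefficient of variation of the volume
#'   fraction (default 0.25).
#' @param seed Integer seed; the draw is reproducible from
#'   (arguments, seed).
#' @param constants A [physical_constants()] object.
#' @return A data.frame (one row per cell) carrying every generator
#'   parameter; the preset is attached as attribute `preset`.
#' @export
make_population <- function(n_cells, preset_name = "rat_beta",
                            glucose_mM = 16,
                            secretagogue = c("glucose", "glibenclamide"),
                            fraction_biphasic = 0.4, vf_cell_cv = 0.25,
                            seed = 1,
                            constants = physical_constants()) {
  secretagogue <- match.arg(secretagogue)
  pr <- preset(preset_name)
  set.seed(seed)
  psi_m_base <- stats::rnorm(n_cells, pr$psi_m_base, pr$psi_m_base_sd)
  psi_p_base <- stats::rnorm(n_cells, pr$psi_p_base, pr$psi_p_base_sd)
  biphasic <- as.integer(stats::runif(n_cells) < fraction_biphasic)
  # activation scalar in [0, 1]: how strongly glucose mobilises energy
  # metabolism in this cell; biphasic responders draw from the upper range
  act_mean <- max(0, min(1, (glucose_mM - 3) / (16 - 3)))
  act <- stats::rbeta(n_cells, 2 + 4 * act_mean + 2 * biphasic,
                      2 + 4 * (1 - act_mean))
  full_dm <- (pr$psi_m_glucose - pr$psi_m_base) +
    stats::rnorm(n_cells, 0, pr$psi_m_glucose_sd)
  if (secretagogue == "glucose") {
    psi_m_glucose <- psi_m_base + act * full_dm
    dm <- pmax(0, psi_m_base - psi_m_glucose)   # hyperpolarisation, mV > 0
    dp_max <- 28
    psi_p_plateau <- psi_p_base +
      dp_max * (1 - exp(-dm / 25)) + stats::rnorm(n_cells, 0, 1.5)
  } else {
    # K_ATP closed pharmacologically: full plasma-membrane depolarisation,
    # mitochondria near baseline (slight hyperpolarisation from reduced
    # demand), tighter spread
    psi_m_glucose <- psi_m_base + stats::rnorm(n_cells, -4, 2)
    psi_p_plateau <- psi_p_base + 26 + stats::rnorm(n_cells, 0, 1.5)
  }
  vf_cell <- pr$vf * pmax(0.2, stats::rnorm(n_cells, 1, vf_cell_cv))
  pop <- data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n_cells)),
    psi_m_base = psi_m_base, psi_p_base = psi_p_base,
    psi_m_glucose = psi_m_glucose, psi_p_plateau = psi_p_plateau,
    biphasic = biphasic, activation = act, vf_cell = vf_cell,
    k_t = pr$k_t, k_ic = pr$k_ic, k_ec_base = pr$k_ec_base,
    stringsAsFactors = FALSE)
  attr(pop, "preset") <- pr
  attr(pop, "seed") <- seed
  pop
}

#' Render protocol fluorescence traces for a population
#'
#' Runs the forward simulator ([simulate_protocol()]) for every cell of a
#' population and assembles a single [trace_set()] with a shared
#' background trace, optional probe depletion steps at liquid-handling
#' events, optional channel crosstalk and optional noise.  Probe
#' depletion multiplies all probe-derived fluorescence (including the
#' background ROI) by a cumulative factor that drops by `depletion` at
#' each liquid-handling event.
#'
#' @param population A data.frame from [make_population()].
#' @param events A [protocol_events()] object (see [standard_protocol()]).
#' @param noise Optional noise model as in [simulate_protocol()].
#' @param depletion Optional per-event fractional probe loss (e.g. 0.15).
#' @param crosstalk Optional fraction of TMRM fluorescence leaking into
#'   the PMPI channel.
#' @param use_cell_vf Logical; render each cell with its own `vf_cell`
#'   (TRUE) or with the preset population value (FALSE, default) -- the
#'   latter makes noise-free round trips exact.
#' @param seed Integer seed for the noise draws.
#' @param optics Optical constants as in [simulate_protocol()].
#' @param dt Sampling interval, s.
#' @param constants A [physical_constants()] object.
#' @return A [trace_set()] with attribute `truth`: per-cell truth
#'   parameters, exact potential time courses, the seed and preset name.
#' @export
make_protocol_traces <- function(population, events, noise = NULL,
                                 depletion = NULL, crosstalk = NULL,
                                 use_cell_vf = FALSE, seed = 1,
                                 optics = default_optics(), dt = 30,
                                 constants = physical_constants()) {
  pr <- attr(population, "preset")
  t_end <- attr(events, "t_end")
  if (is.null(t_end)) t_end <- max(events$time_s) + 720
  kin <- probe_kinetics(k_t = pr$k_t, k_p = pr$k_p)
  t_grid <- seq(0, t_end, by = dt)

  # cumulative depletion factor, piecewise constant between events
  dep_fac <- rep(1, length(t_grid))
  if (!is.null(depletion) && depletion > 0) {
    for (te in events$time_s)
      dep_fac[t_grid >= te] <- dep_fac[t_grid >= te] * (1 - depletion)
  }

  set.seed(seed)
  cell_seeds <- sample.int(2^31 - 1L, nrow(population) + 1L)
  rows <- vector("list", nrow(population))
  truths <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    cr <- population[i, ]
    cell <- cell_params(if (use_cell_vf) cr$vf_cell else pr$vf,
                        pr$ar_prime)
    kin_i <- probe_kinetics(k_t = cr$k_t, k_p = pr$k_p)
    tf <- truth_functions(cr, events, constants)
    ts <- simulate_protocol(tf, events, cell, kin_i, optics = optics,
                            t_end = t_end, dt = dt, noise = NULL,
                            roi_id = cr$cell_id, constants = constants)
    tr <- attr(ts, "truth")
    df <- as.data.frame(ts)
    # depletion scales all probe-derived fluorescence
    df$intensity <- df$intensity * dep_fac[match(df$time_s, t_grid)]
    if (!is.null(crosstalk) && crosstalk > 0) {
      it <- df$channel == "TMRM"
      ip <- df$channel == "PMPI"
      df$intensity[ip] <- df$intensity[ip] +
        crosstalk * df$intensity[it]
    }
    if (!is.null(noise)) {
      set.seed(cell_seeds[i])
      nm <- if (is.null(noise$multiplicative)) 0 else noise$multiplicative
      na <- if (is.null(noise$additive)) 0 else noise$additive
      df$intensity <- df$intensity *
        (1 + nm * stats::rnorm(nrow(df))) + na * stats::rnorm(nrow(df))
    }
    rows[[i]] <- df
    truths[[i]] <- c(as.list(cr), list(psi_val = tf$psi_val,
                                       psi_p_t = tr$psi_p,
                                       psi_m_t = tr$psi_m,
                                       time_s = tr$time_s))
  }

  # background ROI: medium probe fluorescence, proportional to loading;
  # channel crosstalk is optical and affects the background ROI as well
  bg_level <- c(TMRM = 20, PMPI = 40)
  if (!is.null(crosstalk) && crosstalk > 0)
    bg_level[["PMPI"]] <- bg_level[["PMPI"]] +
      crosstalk * bg_level[["TMRM"]]
  bg <- do.call(rbind, lapply(names(bg_level), function(ch) {
    b <- bg_level[[ch]] * dep_fac
    if (!is.null(noise)) {
      set.seed(cell_seeds[nrow(population) + 1L] + match(ch, names(bg_level)))
      nm <- if (is.null(noise$multiplicative)) 0 else noise$multiplicative
      na <- if (is.null(noise$additive)) 0 else noise$additive
      b <- b * (1 + nm * stats::rnorm(length(b))) +
        na * stats::rnorm(length(b))
    }
    data.frame(time_s = t_grid, channel = ch, intensity = b)
  }))

  out <- trace_set(do.call(rbind, rows), background = bg)
  names(truths) <- population$cell_id
  attr(out, "truth") <- list(cells = truths, seed = seed,
                             preset = pr$name,
                             depletion = depletion, crosstalk = crosstalk,
                             optics = optics, events = events,
                             probe_loading = list(tmrm_nM = 7.5,
                                                  pmpi_dilution = "1:200",
                                                  tpb_uM = 1))
  out
}
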