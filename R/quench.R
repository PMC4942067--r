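# Quench-mode rhodamine 123: forward simulator and internal-consistency
# analyzer reproducing the whole-cell vs mitochondrial vs nucleosol
# contrast.

#' Quench-mode fluorescence model
#'
#' @param c_q Apparent quench limit, in units of the loading activity.
#' @param hill Quench steepness (>= 1).  The default 1 gives a purely
#'   saturating law whose plateau is the quench limit, so deep-quench
#'   mitochondrial fluorescence is set by `c_q` alone; larger values make
#'   fluorescence decline above `c_q`.
#' @param cell A [cell_params()] object (compartment volumes).
#' @param closed_cell Logical; the bath is dye-free after loading and
#'   total intracellular probe is conserved.
#' @return An object of class `quench_model`.
#' @export
quench_model <- function(c_q, hill = 1, cell = cell_params(0.078, 0.296),
                         closed_cell = TRUE) {
  stopifnot(c_q > 0, hill >= 1)
  structure(list(c_q = c_q, hill = hill, cell = cell,
                 closed_cell = closed_cell),
            class = "quench_model")
}

#' Quench-mode fluorescence of a probe concentration
#'
#' `F(c) = c / (1 + (c / c_q)^hill)`: linear for `c << c_q`,
#' saturating (hill = 1) or declining (hill > 1) above the quench limit.
#'
#' @param c Probe concentration (activity units, >= 0), vectorised.
#' @param model A [quench_model()] object.
#' @return Fluorescence, AU per unit volume.
#' @export
quench_fluorescence <- function(c, model) {
  if (any(c < 0)) stop("concentration must be non-negative")
  c / (1 + (c / model$c_q)^model$hill)
}

#' Simulate quench-mode rhodamine 123 traces
#'
#' Closed-cell redistribution: the total intracellular dye is conserved
#' while the matrix concentration follows the cytosolic one by the Nernst
#' relation `c_m = c_c exp(-u_M)`.  Treatments move the mitochondrial
#' potential (glucose hyperpolarises, FCCP collapses it to 0); oligomycin
#' is modelled as a fractional drop of the apparent quench limit at held
#' potential (an ultrastructural effect, with no mechanistic claim).
#' Readouts: `nucleosol` = F(c_cyto), `mito` = F(c_matrix), and
#' `whole_cell` = volume-weighted sum of the two.
#'
#' @param psi_m_trace Data.frame `time_s`, `psi_m` (mV): the true
#'   mitochondrial potential time course.
#' @param loading Initial cytosolic dye concentration (activity units) at
#'   the first sample's potential.
#' @param model A [quench_model()] object.
#' @param oligomycin_time Optional time (s) after which the quench limit
#'   is reduced.
#' @param oligomycin_cq_drop Fractional quench-limit reduction (e.g. 0.2).
#' @param noise_sd Optional relative Gaussian noise SD.
#' @param seed Integer seed used when noise is enabled.
#' @param constants A [physical_constants()] object.
#' @return A data.frame `time_s`, `whole_cell`, `mito`, `nucleosol`,
#'   `c_cyto`, `c_mito`; the conserved total and model are attached as
#'   attributes.
#' @export
simulate_quench_traces <- function(psi_m_trace, loading = 5,
                                   model = quench_model(c_q = 30),
                                   oligomycin_time = NULL,
                                   oligomycin_cq_drop = 0.2,
                                   noise_sd = NULL, seed = 1,
                                   constants = physical_constants()) {
  vf <- model$cell$vf
  u_m <- psi_m_trace$psi_m / constants$thermal_voltage
  if (model$closed_cell) {
    w <- (1 - vf) + vf * exp(-u_m)
    total <- loading * w[1L]         # conserved intracellular dye
    c_c <- total / w
    c_m <- c_c * exp(-u_m)
    # conservation audit
    err <- max(abs((1 - vf) * c_c + vf * c_m - total)) / total
    if (err > 1e-9)
      stop("internal error: dye conservation violated beyond 1e-9")
  } else {
    # open cell: the bath keeps the cytosol at the loading activity
    c_c <- rep(loading, length(u_m))
    c_m <- c_c * exp(-u_m)
    total <- NA_real_
  }
  cq <- rep(model$c_q, length(u_m))
  if (!is.null(oligomycin_time))
    cq[psi_m_trace$time_s >= oligomycin_time] <-
      model$c_q * (1 - oligomycin_cq_drop)
  fl <- function(c, q) c / (1 + (c / q)^model$hill)
  nucleosol <- fl(c_c, cq)
  mito <- fl(c_m, cq)
  whole <- (1 - vf) * nucleosol + vf * mito
  if (!is.null(noise_sd)) {
    set.seed(seed)
    n <- length(whole)
    whole <- whole * (1 + noise_sd * stats::rnorm(n))
    mito <- mito * (1 + noise_sd * stats::rnorm(n))
    nucleosol <- nucleosol * (1 + noise_sd * stats::rnorm(n))
  }
  out <- data.frame(time_s = psi_m_trace$time_s, whole_cell = whole,
                    mito = mito, nucleosol = nucleosol,
                    c_cyto = c_c, c_mito = c_m)
  attr(out, "total_dye") <- total
  attr(out, "model") <- model
  out
}

#' Analyze quench-mode traces for internal consistency
#'
#' The quench-mode interpretation of whole-cell rhodamine 123
#' fluorescence requires the mitochondrial (high-pass) signal to stay
#' constant across a treatment.  This analyzer compares the mitochondrial
#' trace before and after each treatment and returns a verdict.
#'
#' @param traces A data.frame with columns `time_s`, `whole_cell`,
#'   `mito`, `nucleosol` (e.g. from [simulate_quench_traces()] or ROI
#'   extraction of a high-pass filtered stack).
#' @param treatments Named numeric vector of treatment times, s.
#' @param tolerance Maximum admissible relative change of the
#'   mitochondrial trace across a treatment (default 0.05).
#' @param quench_check Optional list `list(loading, c_q)`; when the
#'   loading is below the quench limit the quench-mode assumptions do not
#'   apply and the verdict says so.
#' @param nuclear_contamination Optional relative high-pass signal level
#'   inside the nuclear ROI; above `tolerance` the verdict is refused.
#' @param window_s Averaging window on each side of a treatment, s.
#' @return A list with `verdict` (one of `"consistent"`,
#'   `"assumption violated"`, `"quench-mode assumptions inapplicable"`),
#'   per-treatment relative changes of the three readouts, and the input
#'   traces.
#' @export
analyze_quench <- function(traces, treatments, tolerance = 0.05,
                           quench_check = NULL,
                           nuclear_contamination = NULL,
                           window_s = 120) {
  if (!is.null(nuclear_contamination) &&
      nuclear_contamination > tolerance)
    stop("nuclear ROI contaminated by high-pass mitochondrial signal: ",
         "verdict refused")
  if (!is.null(quench_check) &&
      quench_check$loading < quench_check$c_q) {
    return(list(verdict = "quench-mode assumptions inapplicable",
                changes = NULL, traces = traces))
  }
  changes <- lapply(treatments, function(tt) {
    pre <- traces$time_s >= tt - window_s & traces$time_s < tt
    post <- traces$time_s > tt & traces$time_s <= tt + window_s
    vapply(c("whole_cell", "mito", "nucleosol"), function(ch) {
      m0 <- mean(traces[[ch]][pre]); m1 <- mean(traces[[ch]][post])
      (m1 - m0) / m0
    }, numeric(1L))
  })
  names(changes) <- names(treatments)
  mito_change <- vapply(changes, function(x) abs(x[["mito"]]),
                        numeric(1L))
  verdict <- if (any(mito_change > tolerance)) "assumption violated"
             else "consistent"
  list(verdict = verdict, changes = changes, traces = traces)
}
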