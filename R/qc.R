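# Quality control of calibrated single-cell traces.

#' Quality-control thresholds
#'
#' Defaults follow the assay's standard criteria: both calibration
#' regressions must have r^2 > 0.2, baseline standard errors of either
#' potential must not exceed 25 mV, and the baseline plasma membrane
#' potential must not be more depolarised than -40 mV.
#'
#' @param r2_min Minimum regression r^2 (exclusive; r^2 <= r2_min fails).
#' @param se_max Maximum baseline SE, mV.
#' @param psi_p_base_max Most depolarised admissible baseline plasma
#'   membrane potential, mV.
#' @return A list of thresholds.
#' @export
qc_criteria <- function(r2_min = 0.2, se_max = 25, psi_p_base_max = -40) {
  list(r2_min = r2_min, se_max = se_max,
       psi_p_base_max = psi_p_base_max)
}

#' Apply quality control to a calibrated trace
#'
#' @param result A `potential_trace` from [calibrate_cell()].
#' @param criteria A [qc_criteria()] list.
#' @return An object of class `qc_report`: `list(passed, reasons)` with
#'   `passed` true iff `reasons` is empty.  Possible reasons: `low_r2`,
#'   `high_se`, `depolarized_baseline`, `negative_activity`,
#'   `insufficient_segment`.
#' @export
apply_qc <- function(result, criteria = qc_criteria()) {
  model <- attr(result, "model")
  baseline <- attr(result, "baseline")
  reasons <- character(0)
  reasons <- c(reasons, attr(result, "flags"))
  r2s <- c(model$fits$kstep$r2, model$fits$decay$r2)
  if (any(is.finite(r2s) & r2s <= criteria$r2_min))
    reasons <- c(reasons, "low_r2")
  ses <- c(baseline$se_p, baseline$se_m)
  if (any(is.finite(ses) & ses > criteria$se_max))
    reasons <- c(reasons, "high_se")
  if (is.finite(baseline$psi_p) &&
      baseline$psi_p > criteria$psi_p_base_max)
    reasons <- c(reasons, "depolarized_baseline")
  if (!is.finite(baseline$psi_p) || !is.finite(baseline$psi_m))
    reasons <- c(reasons, "negative_activity")
  reasons <- unique(reasons)
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(if (x$passed) "QC: pass\n"
      else paste0("QC: FAIL (", paste(x$reasons, collapse = ", "), ")\n"))
  invisible(x)
}
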