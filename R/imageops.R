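# Confocal-image estimators: mitochondria:cell volume fraction by
# stereology, apparent activity coefficient ratio by decay-slope
# regression, and ROI trace extraction from time-lapse stacks.

#' High-pass filter a mitochondrial-channel image
#'
#' Difference-of-Gaussians band-pass isolating mitochondrial spatial
#' frequencies; negative responses are clipped to zero.  Sigmas are in
#' micrometres and converted to pixels with the supplied pixel size.
#'
#' @param image 2D numeric matrix (mitochondrial channel).
#' @param pixel_size_um Pixel size, micrometres.
#' @param small_sigma,large_sigma Gaussian sigmas in micrometres
#'   (`large_sigma > small_sigma > 0`); defaults 0.1 and 1.0.
#' @return Filtered matrix, same shape, non-negative.
#' @export
highpass_mito <- function(image, pixel_size_um, small_sigma = 0.1,
                          large_sigma = 1.0) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  if (!(large_sigma > small_sigma && small_sigma > 0))
    stop("require large_sigma > small_sigma > 0")
  s1 <- small_sigma / pixel_size_um
  s2 <- large_sigma / pixel_size_um
  img <- EBImage::Image(image)
  lo1 <- if (s1 >= 0.3) EBImage::gblur(img, sigma = s1) else img
  lo2 <- EBImage::gblur(img, sigma = s2)
  out <- EBImage::imageData(lo1) - EBImage::imageData(lo2)
  out[out < 0] <- 0
  out
}

# Otsu threshold on a numeric matrix (EBImage expects [0, 1])
otsu_threshold <- function(x, mask = NULL) {
  v <- if (is.null(mask)) x else x[mask > 0]
  rng <- range(v, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1L])
  scaled <- (x - rng[1L]) / diff(rng)
  scaled[scaled < 0] <- 0; scaled[scaled > 1] <- 1
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1L] + th * diff(rng)
}

#' Estimate the mitochondria:cell volume fraction by stereology
#'
#' Binarises the whole-cell channel and the high-pass filtered
#' mitochondrial channel of every plane, pools the pixel counts over all
#' cells and planes, and applies the stereological correction:
#' `V_F = (2/3) * sum(mito pixels) / sum(cell pixels)`.  Counts are
#' pooled before division, not averaged per cell.  Cells should be
#' distributed across the 10 serial z-planes for balanced sampling; when
#' an immunopositivity mask is present only pixels inside it are counted.
#'
#' @param images A list of plane records, each a list with matrices
#'   `cell` (whole-cell channel) and `mito` (mitochondrial channel),
#'   `pixel_size_um`, optional binary `mask_cell` (analysis region,
#'   e.g. manually outlined cells) and optional `mask_immuno`.
#' @param threshold_method `"otsu"` (per image) or `"fixed"`.
#' @param fixed_thresholds Named list `list(cell =, mito =)` used when
#'   `threshold_method = "fixed"`.
#' @param correction Stereological correction factor (default 2/3).
#' @param highpass Logical; apply [highpass_mito()] to the mitochondrial
#'   channel first (default TRUE).
#' @param n_cells Number of cells represented (for the warning and
#'   record); default `length(images)`.
#' @return An object of class `stereology_result`:
#'   `list(vf, mito_pixels, cell_pixels, n_cells, se)` where `se` is the
#'   between-plane SE of the per-plane ratios (widened by a factor
#'   sqrt(10/n) and flagged when fewer than 10 cells are supplied).
#' @export
estimate_vf <- function(images, threshold_method = c("otsu", "fixed"),
                        fixed_thresholds = NULL, correction = 2 / 3,
                        highpass = TRUE, n_cells = length(images)) {
  threshold_method <- match.arg(threshold_method)
  mito_tot <- 0; cell_tot <- 0
  per_plane <- numeric(0)
  for (rec in images) {
    mask <- if (!is.null(rec$mask_cell)) rec$mask_cell > 0
            else matrix(TRUE, nrow(rec$cell), ncol(rec$cell))
    if (!is.null(rec$mask_immuno)) mask <- mask & rec$mask_immuno > 0
    if (!any(mask)) stop("empty cell mask in an image record")
    mito_img <- if (highpass)
      highpass_mito(rec$mito, rec$pixel_size_um) else rec$mito
    if (threshold_method == "otsu") {
      # cell channel: foreground vs background over the full field;
      # mitochondrial channel: rods vs cell interior, computed inside the
      # cell mask where the two classes are balanced (over the full field
      # the dominant empty background biases Otsu far below half-maximum
      # and inflates the rod area)
      th_c <- otsu_threshold(rec$cell)
      th_m <- otsu_threshold(mito_img, mask)
    } else {
      th_c <- fixed_thresholds$cell
      th_m <- fixed_thresholds$mito
    }
    cell_px <- (rec$cell > th_c) & mask
    mito_px <- (mito_img > th_m) & cell_px
    mito_tot <- mito_tot + sum(mito_px)
    cell_tot <- cell_tot + sum(cell_px)
    per_plane <- c(per_plane,
                   if (sum(cell_px)) sum(mito_px) / sum(cell_px) else NA)
  }
  if (cell_tot == 0) stop("no cell pixels detected")
  vf <- correction * mito_tot / cell_tot
  se <- correction * stats::sd(per_plane, na.rm = TRUE) /
    sqrt(sum(is.finite(per_plane)))
  low_n <- n_cells < 10L
  if (low_n) {
    warning("fewer than 10 cells: volume-fraction SE widened")
    se <- se * sqrt(10 / max(1L, n_cells))
  }
  structure(list(vf = vf, mito_pixels = mito_tot, cell_pixels = cell_tot,
                 n_cells = n_cells, se = se, low_n = low_n),
            class = "stereology_result")
}

#' @export
print.stereology_result <- function(x, ...) {
  cat(sprintf("<stereology_result> V_F = %.4f (SE %.4f), %d/%d px, %d cells\n",
              x$vf, x$se, x$mito_pixels, x$cell_pixels, x$n_cells))
  invisible(x)
}

#' Estimate the apparent activity coefficient ratio a_R'
#'
#' Ordinary least squares of nuclear TMRM fluorescence on mitochondrial
#' TMRM fluorescence recorded while the probe leaks out of the cell after
#' pharmacological collapse of the mitochondrial potential.  The slope is
#' a_R'; the intercept absorbs autofluorescence and high-affinity binding
#' (which are constant in time and therefore do not bias the slope).
#'
#' @param nuclear_trace,mito_trace Numeric vectors of fluorescence (AU)
#'   over the decay, at least 8 time points; the mitochondrial trace must
#'   span at least a 2-fold intensity range.
#' @return A list with `slope` (a_R'), `intercept` (AU), `r2` and the
#'   `fit` (a `regression_fit`).
#' @export
estimate_ar_prime <- function(nuclear_trace, mito_trace) {
  stopifnot(length(nuclear_trace) == length(mito_trace))
  if (length(mito_trace) < 8L)
    stop("at least 8 time points required")
  rng <- range(mito_trace)
  if (!(rng[2L] > 0) || rng[2L] / max(rng[1L], .Machine$double.eps) < 2)
    stop("mitochondrial trace spans less than 2-fold: fit unreliable")
  lmfit <- stats::lm(nuclear_trace ~ mito_trace)
  sm <- suppressWarnings(summary(lmfit))  # exact fits are expected
  cf <- stats::coef(lmfit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r2 = sm$r.squared,
       fit = new_regression_fit(unname(cf[2L]), unname(cf[1L]),
                                sm$cov.unscaled * sm$sigma^2,
                                sm$r.squared,
                                length(mito_trace), sigma = sm$sigma))
}

#' Mean ROI traces from a time-lapse stack
#'
#' @param stack A named list of 3D arrays (`x` by `y` by `t`), one per
#'   channel.
#' @param rois Integer label matrix (same x/y shape); label 0 is treated
#'   as the background ROI and emitted as the background trace.
#' @param times Optional vector of frame times, s (default frame index
#'   minus one).
#' @return A [trace_set()] with one trace per (label, channel); labels
#'   become `roi_<label>`.
#' @export
roi_mean_traces <- function(stack, rois, times = NULL) {
  frames <- dim(stack[[1L]])[3L]
  if (is.null(times)) times <- seq_len(frames) - 1
  if (!all(dim(rois) == dim(stack[[1L]])[1:2]))
    stop("ROI labels must match the image shape")
  labels <- sort(unique(as.vector(rois)))
  rows <- list(); bg <- list()
  for (ch in names(stack)) {
    arr <- stack[[ch]]
    for (lb in labels) {
      idx <- rois == lb
      vals <- vapply(seq_len(frames),
                     function(k) mean(arr[, , k][idx]), numeric(1L))
      if (lb == 0) {
        bg[[ch]] <- data.frame(time_s = times, channel = ch,
                               intensity = vals)
      } else {
        rows[[paste(ch, lb)]] <- data.frame(
          time_s = times, roi_id = sprintf("roi_%d", lb), channel = ch,
          intensity = vals, stringsAsFactors = FALSE)
      }
    }
  }
  trace_set(do.call(rbind, rows),
            background = if (length(bg)) do.call(rbind, bg) else NULL)
}
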