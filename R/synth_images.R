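# Synthetic two-channel confocal fields for the stereology estimators.

# pixels of a thick line segment (rod) inside an n x n field
rod_pixels <- function(n, cx, cy, angle, length_px, width_px) {
  hx <- cos(angle) * length_px / 2
  hy <- sin(angle) * length_px / 2
  x0 <- cx - hx; y0 <- cy - hy; x1 <- cx + hx; y1 <- cy + hy
  pad <- width_px / 2 + 1
  xr <- max(1L, floor(min(x0, x1) - pad)):min(n, ceiling(max(x0, x1) + pad))
  yr <- max(1L, floor(min(y0, y1) - pad)):min(n, ceiling(max(y0, y1) + pad))
  if (!length(xr) || !length(yr)) return(NULL)
  gx <- rep(xr, times = length(yr))
  gy <- rep(yr, each = length(xr))
  dx <- x1 - x0; dy <- y1 - y0
  ll <- dx * dx + dy * dy
  tpar <- pmin(1, pmax(0, ((gx - x0) * dx + (gy - y0) * dy) / ll))
  d2 <- (gx - (x0 + tpar * dx))^2 + (gy - (y0 + tpar * dy))^2
  keep <- d2 <= (width_px / 2)^2
  cbind(gx[keep], gy[keep])
}

#' Generate synthetic two-channel confocal image fields
#'
#' Renders one cell per field: an elliptical cytoplasm in the whole-cell
#' channel, a nucleus, and rod-shaped mitochondria in the mitochondrial
#' channel.  The rendered 2D mitochondrial footprint is
#' `overprojection` (default 3/2) times the preset's true 3D volume
#' fraction, emulating axial overprojection of mitochondria through the
#' confocal slice, so that the 2/3 stereological factor of
#' [estimate_vf()] is exercised; the last rod is trimmed so the drawn
#' pixel count matches the target exactly.  Cells are assigned
#' round-robin to 10 serial z-planes, with the cross-section shrinking
#' away from the midplane.  A small Gaussian blur and mixed
#' multiplicative/additive noise emulate optics and detection.
#'
#' @param preset_name Passed to [preset()]; sets the true volume
#'   fraction.
#' @param n_cells Number of fields (one cell each); at least 10
#'   recommended.
#' @param seed Integer seed; fields are reproducible from
#'   (arguments, seed).
#' @param field_px Field edge, pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param overprojection Footprint inflation factor (default 1.5).
#' @param rod_length_um,rod_width_um Mitochondrial rod geometry.
#' @param blur_sigma_px Gaussian optical blur, pixels (0 disables).
#' @param noise_mult,noise_add Noise model parameters.
#' @param vf_true Override of the preset's true volume fraction.
#' @return A list of per-field records (`cell`, `mito`, `pixel_size_um`,
#'   `z_plane`, `mask_cell`, `mask_nucleus`, `mask_rods`) suitable for
#'   [estimate_vf()]; ground truth is attached as attribute `truth`.
#' @export
make_images <- function(preset_name = "rat_beta", n_cells = 50, seed = 1,
                        field_px = 160, pixel_size_um = 0.1,
                        overprojection = 1.5, rod_length_um = 1.5,
                        rod_width_um = 0.4, blur_sigma_px = 0.4,
                        noise_mult = 0.03, noise_add = 0.01,
                        vf_true = NULL) {
  pr <- preset(preset_name)
  if (is.null(vf_true)) vf_true <- pr$vf
  set.seed(seed)
  n <- field_px
  xs <- matrix(rep(seq_len(n), times = n), n, n)
  ys <- matrix(rep(seq_len(n), each = n), n, n)
  fields <- vector("list", n_cells)
  truth_rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    z <- ((i - 1L) %% 10L) + 1L
    zfac <- sqrt(pmax(0.2, 1 - ((z - 5.5) / 6.5)^2))
    a <- stats::runif(1, 0.32, 0.42) * n * zfac
    b <- stats::runif(1, 0.32, 0.42) * n * zfac
    cx <- n / 2 + stats::runif(1, -4, 4)
    cy <- n / 2 + stats::runif(1, -4, 4)
    cell_mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    nuc_mask <- ((xs - cx) / (0.45 * a))^2 +
      ((ys - cy) / (0.45 * b))^2 <= 1
    cyto <- cell_mask & !nuc_mask

    target <- round(overprojection * vf_true * sum(cell_mask))
    if (target > 0.6 * sum(cyto))
      stop("target volume fraction geometrically unreachable with the ",
           "rod parameters")
    rods <- matrix(FALSE, n, n)
    drawn <- 0L
    guard <- 0L
    while (drawn < target && guard < 5000L) {
      guard <- guard + 1L
      ang <- stats::runif(1, 0, pi)
      r <- sqrt(stats::runif(1)) # denser towards the periphery is fine
      th <- stats::runif(1, 0, 2 * pi)
      px <- cx + r * a * 0.92 * cos(th)
      py <- cy + r * b * 0.92 * sin(th)
      if (!cyto[round(px), round(py)]) next
      pix <- rod_pixels(n, px, py, ang, rod_length_um / pixel_size_um,
                        rod_width_um / pixel_size_um)
      if (is.null(pix) || !nrow(pix)) next
      inside <- cyto[pix]
      pix <- pix[inside, , drop = FALSE]
      new <- !rods[pix]
      pix <- pix[new, , drop = FALSE]
      if (!nrow(pix)) next
      if (drawn + nrow(pix) > target)
        pix <- pix[seq_len(target - drawn), , drop = FALSE]
      rods[pix] <- TRUE
      drawn <- drawn + nrow(pix)
    }

    cell_img <- 0.55 * cell_mask + 0.08 * nuc_mask
    mito_img <- 0.05 * cell_mask + 0.95 * rods
    if (blur_sigma_px > 0) {
      cell_img <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(cell_img), sigma = blur_sigma_px))
      mito_img <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(mito_img), sigma = blur_sigma_px))
    }
    cell_img <- cell_img * (1 + noise_mult * stats::rnorm(n * n)) +
      noise_add * abs(stats::rnorm(n * n))
    mito_img <- mito_img * (1 + noise_mult * stats::rnorm(n * n)) +
      noise_add * abs(stats::rnorm(n * n))
    dim(cell_img) <- c(n, n); dim(mito_img) <- c(n, n)

    fields[[i]] <- list(cell = cell_img, mito = mito_img,
                        pixel_size_um = pixel_size_um, z_plane = z,
                        mask_cell = cell_mask, mask_nucleus = nuc_mask,
                        mask_rods = rods)
    truth_rows[[i]] <- data.frame(field = i, z_plane = z,
                                  cell_px = sum(cell_mask),
                                  mito_px = drawn)
  }
  tr <- do.call(rbind, truth_rows)
  attr(fields, "truth") <- list(
    vf_true = vf_true, overprojection = overprojection,
    per_field = tr, seed = seed, preset = pr$name,
    planar_fraction = sum(tr$mito_px) / sum(tr$cell_px))
  fields
}
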