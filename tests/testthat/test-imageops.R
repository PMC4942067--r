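# Stereology, binding-slope estimation and ROI extraction.

test_that("high-pass filter removes flat and low-frequency structure", {
  flat <- matrix(5, 64, 64)
  expect_equal(max(abs(highpass_mito(flat, 0.1))), 0, tolerance = 1e-8)
  # pure low-frequency blob: the closed-form 2D kernel response is
  # s^2/(s^2+s1^2) - s^2/(s^2+s2^2) of the amplitude (s = 5 um blob,
  # s1/s2 the filter sigmas) -- about 3.8 percent here, vanishing as the
  # blob grows
  xs <- row(matrix(0, 128, 128)); ys <- col(matrix(0, 128, 128))
  blob <- exp(-((xs - 64)^2 + (ys - 64)^2) / (2 * 50^2))
  pred <- 50^2 / (50^2 + 1^2) - 50^2 / (50^2 + 10^2)
  expect_equal(max(highpass_mito(blob, 0.1)), pred, tolerance = 0.05)
  expect_lt(max(highpass_mito(blob, 0.1)), 0.05)
  expect_error(highpass_mito(flat, 0.1, small_sigma = 2, large_sigma = 1),
               "large_sigma")
})

test_that("high-pass filter retains thin rods on a smooth gradient", {
  n <- 128
  xs <- row(matrix(0, n, n)); ys <- col(matrix(0, n, n))
  bg <- 0.8 * exp(-((xs - 40)^2 + (ys - 90)^2) / (2 * 50^2))
  rods <- matrix(FALSE, n, n)
  for (cx in c(30, 64, 100)) rods[cx + 0:2, 20:110] <- TRUE
  img <- bg + 1.0 * rods
  hp <- highpass_mito(img, pixel_size_um = 0.1)
  th <- 0.25
  expect_gt(mean(hp[rods] > th), 0.95)
  expect_gt(mean(hp[!rods] <= th), 0.99)
})

test_that("volume fraction applies the 2/3 factor to pooled pixel counts", {
  n <- 400
  cell <- matrix(0, n, n); cell[1:400, 1:250] <- 1     # 100000 px
  mito <- matrix(0, n, n); mito[1:150, 1:100] <- 1     # 15000 px
  rec <- list(cell = cell, mito = mito, pixel_size_um = 0.1)
  sv <- estimate_vf(list(rec), threshold_method = "fixed",
                    fixed_thresholds = list(cell = 0.5, mito = 0.5),
                    highpass = FALSE, n_cells = 10)
  expect_equal(sv$vf, 0.100, tolerance = 1e-9)
  expect_equal(sv$cell_pixels, 100000)
  expect_equal(sv$mito_pixels, 15000)
  # no mitochondrial signal
  rec0 <- rec; rec0$mito <- matrix(0, n, n)
  expect_equal(estimate_vf(list(rec0), threshold_method = "fixed",
                           fixed_thresholds = list(cell = 0.5, mito = 0.5),
                           highpass = FALSE, n_cells = 10)$vf, 0)
  # pooling convention: counts are summed before the division, which
  # differs from the mean of per-cell ratios when cells differ in size
  cell_small <- matrix(0, n, n); cell_small[1:200, 1:250] <- 1  # 50000 px
  recs <- list(
    list(cell = cell, mito = mito, pixel_size_um = 0.1),
    list(cell = cell_small, mito = matrix(0, n, n),
         pixel_size_um = 0.1))
  sv2 <- estimate_vf(recs, threshold_method = "fixed",
                     fixed_thresholds = list(cell = 0.5, mito = 0.5),
                     highpass = FALSE, n_cells = 20)
  expect_equal(sv2$vf, (2 / 3) * 15000 / 150000, tolerance = 1e-9)
  per_cell_mean <- mean(c((2 / 3) * 0.15, 0))
  expect_false(isTRUE(all.equal(sv2$vf, per_cell_mean)))
})

test_that("volume fraction estimate is invariant to intensity rescaling", {
  imgs <- make_images("rat_beta", n_cells = 10, seed = 3)
  scaled <- lapply(imgs, function(rec) {
    rec$cell <- rec$cell * 2; rec$mito <- rec$mito * 2; rec
  })
  a <- estimate_vf(imgs)
  b <- estimate_vf(scaled)
  expect_equal(a$mito_pixels, b$mito_pixels)
  expect_equal(a$cell_pixels, b$cell_pixels)
})

test_that("generator round trip recovers the preset volume fraction", {
  imgs <- make_images("rat_beta", n_cells = 50, seed = 1)
  sv <- estimate_vf(imgs)
  expect_lt(abs(sv$vf / 0.078 - 1), 0.10)
  # the rendered planar fraction honours the 3/2 overprojection
  tr <- attr(imgs, "truth")
  expect_equal(tr$planar_fraction, 1.5 * 0.078, tolerance = 0.02)
})

test_that("balanced 10-plane sampling is unbiased across seeds", {
  est <- vapply(1:10, function(s)
    estimate_vf(make_images("rat_beta", n_cells = 20, seed = s))$vf,
    numeric(1))
  expect_lt(abs(mean(est) - 0.078), sd(est))
})

test_that("fewer than 10 cells widens the SE with a warning", {
  imgs <- make_images("rat_beta", n_cells = 12, seed = 2)
  expect_warning(sv <- estimate_vf(imgs[1:5], n_cells = 5),
                 "fewer than 10")
  sv10 <- estimate_vf(imgs[1:10], n_cells = 10)
  expect_true(sv$low_n)
  expect_false(sv10$low_n)
})

test_that("binding-ratio slope estimation matches constructed lines", {
  mito <- seq(1000, 100, length.out = 20)
  nuc <- 0.296 * mito + 20
  ar <- estimate_ar_prime(nuc, mito)
  expect_equal(ar$slope, 0.296, tolerance = 1e-12)
  expect_equal(ar$intercept, 20, tolerance = 1e-9)
  expect_equal(ar$r2, 1)
  ident <- estimate_ar_prime(mito, mito)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-9)
  expect_error(estimate_ar_prime(rep(5, 20), rep(7, 20)), "2-fold")
  expect_error(estimate_ar_prime(nuc[1:5], mito[1:5]), "8 time points")
})

test_that("binding-ratio slope is invariant to nuclear offsets", {
  set.seed(5)
  for (i in 1:5) {
    mito <- exp(seq(log(900), log(80), length.out = 15)) +
      stats::rnorm(15, 0, 5)
    nuc <- 0.35 * mito + stats::rnorm(15, 0, 3)
    off <- stats::runif(1, -50, 200)
    a <- estimate_ar_prime(nuc, mito)
    b <- estimate_ar_prime(nuc + off, mito)
    expect_equal(a$slope, b$slope, tolerance = 1e-10)
    expect_equal(b$intercept - a$intercept, off, tolerance = 1e-8)
  }
})

test_that("ROI trace extraction recovers rendered intensities", {
  n <- 32; frames <- 6
  labels <- matrix(0L, n, n)
  labels[4:12, 4:12] <- 1L
  labels[20:28, 20:28] <- 2L
  truth1 <- seq(100, 150, length.out = frames)
  truth2 <- seq(80, 30, length.out = frames)
  arr <- array(5, dim = c(n, n, frames))   # background level 5
  for (k in seq_len(frames)) {
    arr[, , k][labels == 1L] <- truth1[k]
    arr[, , k][labels == 2L] <- truth2[k]
  }
  ts <- roi_mean_traces(list(TMRM = arr), labels,
                        times = (seq_len(frames) - 1) * 30)
  expect_equal(get_trace(ts, "roi_1", "TMRM")$intensity, truth1)
  expect_equal(get_trace(ts, "roi_2", "TMRM")$intensity, truth2)
  bg <- attr(ts, "background")
  expect_equal(bg$intensity, rep(5, frames))
  # single-pixel ROI equals that pixel's series
  lab1 <- matrix(0L, n, n); lab1[7, 9] <- 3L
  ts1 <- roi_mean_traces(list(TMRM = arr), lab1)
  expect_equal(get_trace(ts1, "roi_3", "TMRM")$intensity,
               arr[7, 9, ])
  expect_error(roi_mean_traces(list(TMRM = arr), matrix(0L, 5, 5)),
               "shape")
})
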