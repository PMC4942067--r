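# The inverse calibration chain: regressions, background/scale
# resolution, rate-constant inversion and potential back-calculation.

test_that("potassium-step regression recovers a constructed linear system", {
  pl <- data.frame(k_ec = c(10.8, 20, 40, 80))
  pl$f <- 100 + 2 * pl$k_ec
  kf <- fit_kstep(pl, f_end_p = 380)
  expect_equal(kf$f_x_p, 100, tolerance = 1e-9)
  expect_equal(kf$s_p, 280, tolerance = 1e-9)
  expect_equal(kf$k_ic, 140, tolerance = 1e-9)
  expect_false(kf$fit$failed)
  # degenerate: endpoint equal to the intercept leaves no PMPI span
  expect_true(fit_kstep(pl, f_end_p = 100)$fit$failed)
  expect_error(fit_kstep(pl[1:2, ], 380), "3 distinct")
})

test_that("PMPI back-calculation maps steady activities to millivolts", {
  tt <- seq(0, 300, 30)
  tr <- data.frame(time_s = tt, intensity = 100 + 280 * 0.0728)
  pp <- calibrate_psi_p(tr, 100, 280)
  expect_equal(pp$psi_p, rep(vt0 * log(0.0728), 11), tolerance = 1e-9)
  expect_equal(mean(pp$psi_p), -70.0, tolerance = 1e-3)
  tr1 <- data.frame(time_s = tt, intensity = 100 + 280 * 1)
  expect_equal(calibrate_psi_p(tr1, 100, 280)$psi_p, rep(0, 11))
  # below-background samples are flagged invalid, not interpolated
  tr2 <- tr; tr2$intensity[5] <- 0
  pp2 <- calibrate_psi_p(tr2, 100, 280)
  expect_false(all(pp2$valid))
  expect_true(anyNA(pp2$psi_p))
})

test_that("disequilibrium correction tracks a potential step much faster than Nernst-of-b", {
  # a slowly redistributing probe makes the lag observable on the grid
  k_p <- 0.01
  kin <- probe_kinetics(k_p = k_p)
  tt <- seq(0, 1500, 30)
  t_step <- 600
  u0 <- -70 / vt0; u1 <- -40 / vt0
  b <- ifelse(tt < t_step, exp(u0),
              exp(u1) + (exp(u0) - exp(u1)) * exp(-k_p * (tt - t_step)))
  tr <- data.frame(time_s = tt, intensity = 100 + 280 * b)
  pp <- calibrate_psi_p(tr, 100, 280, kinetics = kin)
  naive <- vt0 * log(b)
  settle_time <- function(psi) {
    ok <- abs(psi + 40) < 1 & tt > t_step
    ok[is.na(ok)] <- FALSE
    settled <- rev(cumprod(rev(ok | tt <= t_step))) > 0 & tt > t_step
    if (!any(settled)) Inf else min(tt[settled]) - t_step
  }
  t_corr <- settle_time(pp$psi_p)
  t_naive <- settle_time(naive)
  expect_lte(t_corr, 150)  # a couple of samples plus the fit window
  expect_gte(t_naive / t_corr, 5)
})

test_that("decay regression recovers rate and asymptote of an exact exponential", {
  tt <- seq(0, 1200, 30)
  seg <- data.frame(time_s = tt, intensity = 200 + 800 * exp(-0.004 * tt))
  fd <- fit_decay(seg)
  expect_equal(fd$lambda_decay, 0.004, tolerance = 1e-6)
  expect_equal(fd$f_inf, 200, tolerance = 0.02)
  expect_gt(fd$fit$r2, 0.999)
  # agreement with the direct nonlinear exponential fit (oracle route)
  fe <- fit_decay_exp(seg)
  expect_equal(fd$lambda_decay, fe$lambda_decay, tolerance = 1e-4)
  expect_equal(fd$f_inf, fe$f_inf, tolerance = 1e-3)
  # constant segment: no decay
  flat <- data.frame(time_s = tt, intensity = rep(300, length(tt)))
  expect_true(fit_decay(flat)$fit$failed)
  expect_error(fit_decay(seg[1:5, ]), "8 samples")
})

test_that("background/scale resolution inverts its forward relation", {
  psi_val <- vt0 * log(1 / 20.09)  # about -80.2 mV
  f_inf <- 50 + 150 * 20.09
  expect_equal(f_inf, 3063.5, tolerance = 1e-3)
  rs <- resolve_background_and_scale(f_inf, f_end = 200,
                                     psi_p_val = psi_val)
  expect_equal(rs$f_x_t, 50, tolerance = 1e-9)
  expect_equal(rs$s_t_d0, 150, tolerance = 1e-9)
  expect_error(resolve_background_and_scale(3063.5, 200, 0),
               "ill-conditioned")
})

test_that("rate-constant inversion matches the simulator's closed form", {
  cell <- rat_cell()
  expect_equal(derive_k_t(3.9625e-3, -2 * vt0, cell), 0.0150,
               tolerance = 2e-3)
  # V_F -> 0: k_T = lambda / (g(u) exp(u))
  small <- cell_params(1e-9, 0.5)
  u <- -1.5
  expect_equal(derive_k_t(0.002, u * vt0, small),
               0.002 / (ghk_rate_factor(u) * exp(u)), tolerance = 1e-6)
})

test_that("mitochondrial back-calculation matches the worked example", {
  tt <- seq(0, 300, 30)
  tr <- data.frame(time_s = tt, intensity = rep(7857, 11))
  pp <- data.frame(time_s = tt, psi_p = rep(-50, 11), valid = TRUE)
  pm <- calibrate_psi_m(tr, pp, f_x_t = 50, s_t = 100, k_t = 0.015,
                        cell = rat_cell(), baseline_window = c(0, 310))
  expect_equal(attr(pm, "baseline"), -100.0, tolerance = 1e-3)
  expect_equal(pm$psi_m, rep(attr(pm, "baseline"), 11), tolerance = 1e-6)
  # fully depolarised mitochondria: a_cell / a_c = D0 gives 0 mV
  d0 <- activity_weight(0, rat_cell())
  tr0 <- data.frame(time_s = tt,
                    intensity = 50 + 100 * d0 * exp(50 / vt0))
  pm0 <- calibrate_psi_m(tr0, pp, 50, 100, 0.015, rat_cell(),
                         baseline_window = c(0, 310))
  expect_equal(attr(pm0, "baseline"), 0, tolerance = 1e-6)
})

test_that("noise-free protocol round trip recovers the rat preset truth", {
  fx <- rat_fixture()
  b <- attr(fx$r, "baseline")
  m <- attr(fx$r, "model")
  expect_equal(b$psi_p, -65, tolerance = 0.01)
  expect_equal(b$psi_m, -120, tolerance = 0.01)
  expect_equal(m$k_t_fit, 0.015, tolerance = 2e-4)
  expect_equal(m$k_ic, 140, tolerance = 0.1)
  expect_equal(m$psi_p_val, goldman_k_potential(5.4, 140),
               tolerance = 0.01)
  s <- summarize_response(fx$r, stim_time = 900)
  expect_equal(s$plateau_psi_m, -166, tolerance = 0.01)
  expect_true(attr(fx$r, "qc")$passed)
})

test_that("round trip holds across a grid of admissible truths", {
  ev <- standard_protocol(stimulus = FALSE)
  grid <- expand.grid(psi_p = c(-90, -65, -45),
                      psi_m = c(-160, -120, -80),
                      k_t = c(0.005, 0.05))
  for (i in seq_len(nrow(grid))) {
    pop <- rat_population()
    pop$psi_p_base <- grid$psi_p[i]
    pop$psi_m_base <- grid$psi_m[i]
    pop$k_t <- grid$k_t[i]
    ts <- make_protocol_traces(pop, ev, seed = 1)
    r <- calibrate_traces(ts, ev, rat_params(), propagate = FALSE)[[1]]
    b <- attr(r, "baseline"); m <- attr(r, "model")
    expect_equal(b$psi_p, grid$psi_p[i], tolerance = 0.5 / 90)
    expect_lt(abs(b$psi_m - grid$psi_m[i]), 0.5)
    expect_lt(abs(m$k_t_fit / grid$k_t[i] - 1), 0.02)
  }
})

test_that("recovered baseline is invariant to the valinomycin clamp potential", {
  # clamp set by the baseline bath potassium: -87, -75 and -60 mV
  k_ic <- 140
  clamps <- k_ic * exp(c(-87, -75, -60) / vt0)
  base <- k_t <- numeric(length(clamps))
  for (j in seq_along(clamps)) {
    pop <- rat_population()
    pop$k_ec_base <- clamps[j]
    ev <- standard_protocol(stimulus = FALSE)
    ts <- make_protocol_traces(pop, ev, seed = 1)
    r <- calibrate_traces(ts, ev, rat_params(), propagate = FALSE)[[1]]
    base[j] <- attr(r, "baseline")$psi_m
    k_t[j] <- attr(r, "model")$k_t_fit
  }
  expect_lt(diff(range(base)), 0.5)
  expect_lt(diff(range(k_t)) / 0.015, 0.01)
})

test_that("preprocess: identity unmixing and background subtraction leave net traces intact", {
  fx <- rat_fixture_short()
  ts <- fx$ts
  pre <- preprocess(ts, unmix = diag(2))
  f_raw <- get_trace(ts, "cell_001", "TMRM")$intensity
  f_cor <- get_trace(pre, "cell_001", "TMRM")$intensity
  expect_equal(f_cor, f_raw - 20, tolerance = 1e-9)  # background level
  expect_error(preprocess(ts, unmix = matrix(1, 2, 2)), "non-singular")
})

test_that("preprocess undoes probe depletion and channel crosstalk", {
  pop <- rat_population()
  ev <- standard_protocol(stimulus = FALSE)
  clean <- make_protocol_traces(pop, ev, seed = 1)
  depl <- make_protocol_traces(pop, ev, seed = 1, depletion = 0.15)
  cor <- preprocess(depl, depletion_correction = TRUE, events = ev)
  ref <- preprocess(clean, events = ev)
  expect_equal(get_trace(cor, "cell_001", "TMRM")$intensity,
               get_trace(ref, "cell_001", "TMRM")$intensity,
               tolerance = 1e-6)
  # post-event intensities were scaled back up by 1/0.85 per event
  raw_t <- get_trace(depl, "cell_001", "TMRM")
  post <- raw_t$time_s > ev$time_s[1] & raw_t$time_s < ev$time_s[2]
  fac <- get_trace(cor, "cell_001", "TMRM")$intensity[post] /
    (raw_t$intensity[post] - 20 * 0.85)
  expect_equal(fac, rep(1 / 0.85, sum(post)), tolerance = 1e-6)

  kappa <- 0.1
  xtalk <- make_protocol_traces(pop, ev, seed = 1, crosstalk = kappa)
  unm <- preprocess(xtalk, unmix = matrix(c(1, -kappa, 0, 1), 2, 2))
  expect_equal(get_trace(unm, "cell_001", "PMPI")$intensity,
               get_trace(ref, "cell_001", "PMPI")$intensity,
               tolerance = 1e-6)
})

test_that("depletion correction improves calibration on depleted traces", {
  pop <- rat_population()
  ev <- standard_protocol(stimulus = FALSE)
  depl <- make_protocol_traces(pop, ev, seed = 1, depletion = 0.15)
  r_cor <- calibrate_traces(depl, ev, rat_params(),
                            depletion_correction = TRUE,
                            propagate = FALSE)[[1]]
  r_unc <- calibrate_traces(depl, ev, rat_params(),
                            propagate = FALSE)[[1]]
  err_cor <- abs(attr(r_cor, "baseline")$psi_m + 120)
  err_unc <- abs(attr(r_unc, "baseline")$psi_m + 120)
  expect_lt(err_cor, err_unc)
  expect_lt(err_cor, 0.5)
})

test_that("noisy round trip stays near truth with high QC pass rate", {
  pop <- rat_population(6, seed = 42)
  ev <- standard_protocol(stimulus = FALSE)
  ts <- make_protocol_traces(pop, ev, seed = 7,
                             noise = list(multiplicative = 0.01,
                                          additive = 1))
  res <- calibrate_traces(ts, ev, rat_params())
  passed <- vapply(res, function(r) attr(r, "qc")$passed, logical(1))
  expect_gt(mean(passed), 0.9)
  err_m <- vapply(seq_along(res), function(i)
    attr(res[[i]], "baseline")$psi_m - pop$psi_m_base[i], numeric(1))
  err_kic <- vapply(res, function(r)
    attr(r, "model")$k_ic / 140 - 1, numeric(1))
  expect_lt(stats::median(abs(err_m)), 5)
  expect_lt(max(abs(err_kic)), 0.05)
})
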