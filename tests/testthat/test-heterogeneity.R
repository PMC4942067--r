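# Response summaries, phenotype classification, joint distributions and
# the sensitivity analyses.

make_psi_trace <- function(tt, psi_p, psi_m = rep(-120, length(tt))) {
  structure(data.frame(time_s = tt, psi_p = psi_p, psi_m = psi_m,
                       se_p = 0, se_m = 0, valid = TRUE),
            baseline = list(psi_p = psi_p[1], psi_m = psi_m[1],
                            se_p = 0, se_m = 0),
            class = c("potential_trace", "data.frame"))
}

test_that("response summaries are exact window arithmetic", {
  tt <- seq(0, 5400, 30)
  r <- make_psi_trace(tt, rep(-70, length(tt)))
  s <- summarize_response(r, stim_time = 0)
  expect_equal(s$relative_dp, 0)
  expect_equal(s$relative_dm, 0)
  # a flat trace shows no depolarisation: monophasic with a flag
  expect_equal(s$phenotype, "monophasic")
  expect_true(s$flagged)
  # plateau window beyond the recording limit is flagged
  s2 <- summarize_response(r, stim_time = 3000, t_limit = 5400)
  expect_true(s2$flagged)
  # relative response is plateau minus baseline exactly
  psi <- ifelse(tt < 600, -70, -50)
  r3 <- make_psi_trace(tt, psi, ifelse(tt < 600, -120, -160))
  s3 <- summarize_response(r3, stim_time = 600,
                           windows = response_windows(plateau = c(1800,
                                                                  4500)))
  expect_equal(s3$relative_dp, -50 - (-70))
  expect_equal(s3$relative_dm, -160 - (-120))
})

test_that("biphasic rule compares late to early depolarisation with inclusive boundary", {
  tt <- seq(0, 3600, 30)
  mk <- function(d5, d30) {
    ramp <- ifelse(tt < 300, d5, ifelse(tt < 1500, d5, d30))
    make_psi_trace(tt, -70 + ramp)
  }
  # 25 >= 1.10 * 20: biphasic
  expect_equal(classify_phenotype(mk(20, 25), -70, 0)$phenotype,
               "biphasic")
  # equal phases: monophasic
  expect_equal(classify_phenotype(mk(20, 20), -70, 0)$phenotype,
               "monophasic")
  # exactly 10 percent more depolarised: inclusive, biphasic
  expect_equal(classify_phenotype(mk(20, 22), -70, 0)$phenotype,
               "biphasic")
  # no depolarisation: monophasic with a flag
  res <- classify_phenotype(mk(-5, -5), -70, 0)
  expect_equal(res$phenotype, "monophasic")
  expect_true(res$flagged)
  # invariant to a constant added to the whole trace
  tr <- mk(20, 25)
  tr$psi_p <- tr$psi_p + 13
  expect_equal(classify_phenotype(tr, -70 + 13, 0)$phenotype, "biphasic")
})

test_that("joint distribution conserves counts and recovers a monotone coupling", {
  # enough replicates that the replicate-level SE estimate is stable
  # (with few replicates the 2-SE band has well under 90 percent
  # coverage simply because the SE itself is noisy)
  set.seed(3)
  n <- 960
  dm <- runif(n, -60, -5)
  dp <- 28 * (1 - exp(dm / 25)) + rnorm(n, 0, 1.2)
  cells <- data.frame(plateau_psi_m = -120 + dm, plateau_psi_p = -65 + dp,
                      relative_dm = dm, relative_dp = dp,
                      replicate = rep(paste0("rep", 1:16), length.out = n))
  jd <- joint_distribution(cells, mode = "relative")
  expect_equal(sum(jd$hist), n)
  good <- !jd$binned$insufficient & jd$binned$n_cells >= 8
  pred <- 28 * (1 - exp(jd$binned$mean_psi_m[good] / 25))
  within <- abs(jd$binned$mean_psi_p[good] - pred) <=
    2 * jd$binned$se[good]
  expect_gte(mean(within), 0.9)
  # single cell: occupied bin count 1 and SE marked undefined
  jd1 <- joint_distribution(cells[1, ], mode = "relative")
  expect_equal(sum(jd1$hist), 1)
  expect_true(all(jd1$binned$insufficient |
                    jd1$binned$n_cells == 0))
  expect_error(joint_distribution(cells[0, ]), "empty")
})

test_that("glibenclamide populations occupy a tighter mitochondrial range", {
  glc <- make_population(120, "rat_beta", seed = 5,
                         secretagogue = "glucose")
  glb <- make_population(120, "rat_beta", seed = 5,
                         secretagogue = "glibenclamide")
  # absolute plateau spread is tighter, and the evoked change much so
  expect_lt(sd(glb$psi_m_glucose), sd(glc$psi_m_glucose))
  expect_lt(sd(glb$psi_m_glucose - glb$psi_m_base),
            0.5 * sd(glc$psi_m_glucose - glc$psi_m_base))
  # plasma membrane still depolarises under glibenclamide
  expect_gt(mean(glb$psi_p_plateau - glb$psi_p_base), 15)
})

test_that("volume-fraction misspecification biases absolute but not relative potentials", {
  fx <- rat_fixture()
  sv <- sensitivity_vf(fx$res, vf_error = 0.25, stim_time = 900)
  bias <- sv$bias
  closed_form <- vt0 * log(1.25)
  expect_equal(bias$bias_abs_baseline, closed_form, tolerance = 0.1 / 6)
  expect_equal(bias$bias_abs_plateau, closed_form, tolerance = 0.1 / 6)
  expect_true(all(abs(bias$bias_relative) < 1))
  expect_true(all(abs(bias$bias_relative) <
                    abs(bias$bias_abs_baseline)))
  # the negative perturbation mirrors the sign
  sv2 <- sensitivity_vf(fx$res, vf_error = -0.25, stim_time = 900)
  expect_equal(sv2$bias$bias_abs_baseline, vt0 * log(0.75),
               tolerance = 0.1 / 6)
  # zero error, zero bias
  sv0 <- sensitivity_vf(fx$res, vf_error = 0, stim_time = 900)
  expect_equal(sv0$bias$bias_abs_baseline, 0, tolerance = 1e-9)
})

test_that("collection artifacts displace potentials by the logarithmic closed form", {
  fx <- rat_fixture()
  # PMPI-only +2.4 percent at the plateau shifts psi_P by Vt ln(1.024)
  sa <- sensitivity_artifact(fx$res, epsilon = 0.024,
                             channels = "PMPI", stim_time = 900)
  expect_equal(sa$displacement$d_psi_p, vt0 * log(1.024),
               tolerance = 0.02)
  # zero artifact, zero displacement
  s0 <- sensitivity_artifact(fx$res, epsilon = 0, stim_time = 900)
  expect_equal(s0$displacement$d_psi_p, 0, tolerance = 1e-9)
  expect_equal(s0$displacement$d_psi_m, 0, tolerance = 1e-9)
  # +20 percent vs +2.4 percent: ordered, scaling with log(1 + eps)
  s_small <- sensitivity_artifact(fx$res, epsilon = 0.024,
                                  stim_time = 900)
  s_big <- sensitivity_artifact(fx$res, epsilon = 0.20, stim_time = 900)
  mag <- function(s) sqrt(s$displacement$d_psi_m^2 +
                            s$displacement$d_psi_p^2)
  expect_gt(mag(s_big), mag(s_small))
  # magnitudes track the logarithmic, not linear, scaling in epsilon
  expect_equal(mag(s_big) / mag(s_small),
               log(1.20) / log(1.024), tolerance = 0.25)
  # both channels rising mimics depolarisation plus hyperpolarisation
  expect_gt(s_big$displacement$d_psi_p, 0)
  expect_lt(s_big$displacement$d_psi_m, 0)
})

test_that("predicted SE clouds: absolute exceeds relative and scales with noise", {
  fx <- rat_fixture_short()
  tr <- attr(fx$r, "traces")
  cellp <- cell_params(0.078, 0.296, vf_se = 0.25 * 0.078 / 2)
  run <- function(sig) {
    opts <- calibration_options(noise_sd = c(TMRM = sig,
                                             PMPI = sig / 100))
    res <- list(cell_001 = calibrate_cell(tr$tmrm, tr$pmpi, fx$ev, cellp,
                                          probe_kinetics(),
                                          options = opts))
    list(abs = predicted_se_cloud(res, "absolute", stim_time = 900,
                                  windows = response_windows(
                                    plateau = c(-600, 0))),
         rel = predicted_se_cloud(res, "relative", stim_time = 900,
                                  windows = response_windows(
                                    plateau = c(-600, 0))))
  }
  se1 <- run(100)
  expect_gt(se1$abs$sd_psi_m, se1$rel$sd_psi_m)
  # all-zero input variance collapses the cloud
  res0 <- list(cell_001 = fx$r)
  s0 <- predicted_se_cloud(res0, "absolute", stim_time = 900,
                           windows = response_windows(
                             plateau = c(-600, 0)))
  expect_lt(s0$sd_psi_m, 1e-2)
})
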