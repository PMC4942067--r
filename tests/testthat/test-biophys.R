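# Potential formulas, the GHK rate factor, the compartment model and the
# forward simulator.

test_that("Nernst potential matches closed-form values and inverts", {
  expect_equal(nernst_potential(1), 0)
  expect_equal(nernst_potential(10), -vt0 * log(10), tolerance = 1e-12)
  # cation accumulation at the rat resting mitochondrial potential
  expect_equal(nernst_potential(89.1), -120.0, tolerance = 1e-4)
  expect_equal(nernst_potential(10, valence = -1L),
               -nernst_potential(10))
  expect_equal(nernst_ratio(nernst_potential(89.1)), 89.1,
               tolerance = 1e-12)
  expect_error(nernst_potential(0), "positive")
  expect_error(nernst_potential(2, valence = 2L), "valence")
})

test_that("Goldman potential with P_N = 0 reduces exactly to Nernst", {
  expect_equal(goldman_k_potential(140, 140), 0)
  expect_equal(goldman_k_potential(5.4, 140), -87.0, tolerance = 1e-4)
  expect_equal(goldman_k_potential(80, 140), -14.96, tolerance = 1e-3)
  for (k in c(2, 20, 75))
    expect_equal(goldman_k_potential(k, 140),
                 -nernst_potential(k / 140))
  expect_error(probe_kinetics(p_n = 0.1), "p_n = 0")
  expect_error(goldman_k_potential(0, 140), "positive")
})

test_that("GHK rate factor handles the singularity and its identity", {
  expect_equal(ghk_rate_factor(0), 1)
  expect_equal(ghk_rate_factor(-2), 2.3130, tolerance = 1e-4)
  u <- seq(-10, 10, length.out = 401)
  expect_equal(ghk_rate_factor(-u), ghk_rate_factor(u) * exp(u),
               tolerance = 1e-12)
  # series expansion joins the exact branch smoothly
  expect_equal(ghk_rate_factor(9.999e-5), ghk_rate_factor(1.0001e-4),
               tolerance = 1e-7)
})

test_that("cell activity weight matches the worked compartment example", {
  cell <- rat_cell()
  expect_equal(cell_activity(3.7, 0, cell_params(1e-9, 0.5)), 3.7,
               tolerance = 1e-6)   # vanishing mitochondria
  expect_equal(activity_weight(0, cell), 1.1855, tolerance = 1e-4)
  expect_equal(cell_activity(6.492, -100, cell), 78.07, tolerance = 1e-3)
  expect_error(cell_activity(-1, 0, cell), "non-negative")
})

test_that("simulated traces sit at the fixed point under constant potentials", {
  cell <- rat_cell(); kin <- probe_kinetics()
  ev <- protocol_events(data.frame(
    time_s = c(600, 900, 1200),
    kind = c("mito_depol", "k_step", "fixation"),
    param = c(NA, "K_ec_mM", NA), value = c(NA, 80, NA)))
  truth <- list(psi_p = function(t) rep(-65, length(t)),
                psi_m = function(t) rep(-120, length(t)))
  ts <- simulate_protocol(truth, ev, cell, kin, t_end = 570, dt = 30)
  tr <- attr(ts, "truth")
  a_eq <- exp(65 / vt0) * activity_weight(-120, cell)
  b_eq <- exp(-65 / vt0)
  expect_equal(tr$a_cell, rep(a_eq, length(tr$a_cell)), tolerance = 1e-6)
  expect_equal(tr$b, rep(b_eq, length(tr$b)), tolerance = 1e-6)
  f <- get_trace(ts, "cell_1", "TMRM")
  expect_equal(f$intensity, rep(50 + 100 * a_eq, nrow(f)),
               tolerance = 1e-6)
})

test_that("TMRM is independent of the mitochondrial potential as V_F -> 0", {
  kin <- probe_kinetics()
  ev <- protocol_events(data.frame(
    time_s = c(300, 600, 900), kind = c("mito_depol", "k_step", "fixation"),
    param = NA, value = c(NA, 80, NA)))
  run <- function(psi_m_val) {
    truth <- list(psi_p = function(t) ifelse(t < 150, -65, -40),
                  psi_m = function(t) rep(psi_m_val, length(t)))
    attr(simulate_protocol(truth, ev, cell_params(1e-8, 0.3), kin,
                           t_end = 280, dt = 10), "truth")$a_cell
  }
  expect_equal(run(-150), run(0), tolerance = 1e-5)
})

test_that("post-depolarisation decay follows the linearised rate", {
  cell <- rat_cell()
  kin <- probe_kinetics(k_t = 0.015)
  psi_p <- -2 * vt0
  lam <- kin$k_t * ghk_rate_factor(-2) * exp(-2) /
    activity_weight(0, cell)
  expect_equal(lam, 3.96e-3, tolerance = 1e-3)
  expect_equal(log(10) / lam, 581, tolerance = 1e-3)
  # numerical integration agrees with the closed form within 1 percent
  ev <- protocol_events(data.frame(
    time_s = c(60, 1800, 2100), kind = c("mito_depol", "k_step", "fixation"),
    param = NA, value = c(NA, 80, NA)))
  truth <- list(psi_p = function(t) rep(psi_p, length(t)),
                psi_m = function(t) ifelse(t < 60, -120, 0))
  tr <- attr(simulate_protocol(truth, ev, cell, kin, t_end = 1790,
                               dt = 30), "truth")
  sel <- tr$time_s >= 90 & tr$time_s <= 1500
  a_eq <- exp(2) * activity_weight(0, cell)
  lam_num <- -coef(lm(log(tr$a_cell[sel] - a_eq) ~ tr$time_s[sel]))[[2]]
  expect_equal(lam_num, lam, tolerance = 0.01)
})

test_that("equilibration times follow first-order kinetics", {
  cell <- rat_cell(); kin <- probe_kinetics(0.015)
  # efflux after complete depolarisation at u_P = -2: t90 = 581 s
  t90 <- equilibration_time(cell, kin, psi_p = -2 * vt0, psi_m = 0,
                            direction = "efflux", psi_m_initial = -120)
  expect_equal(t90, 581.35, tolerance = 0.005)
  t99 <- equilibration_time(cell, kin, psi_p = -2 * vt0, psi_m = 0,
                            fraction = 0.99, direction = "efflux",
                            psi_m_initial = -120)
  expect_equal(t99 / t90, 2, tolerance = 0.01)
  # uptake is D(psi_M)-fold slower into polarised mitochondria
  r0 <- equilibration_time(cell, kin, -65, 0, direction = "uptake")
  r1 <- equilibration_time(cell, kin, -65, -120, direction = "uptake")
  expect_equal(r1 / r0, 20.6, tolerance = 0.005)
  # polarised uptake takes tens of minutes (the frame-rate rationale)
  expect_gt(r1, 1000)
  expect_error(
    equilibration_time(cell, kin, -65, -120, direction = "uptake",
                       horizon = 60),
    "horizon")
})

test_that("protocol event tables are validated", {
  expect_error(protocol_events(data.frame(time_s = 1, kind = "fixation")),
               "mito_depol")
  expect_error(protocol_events(data.frame(
    time_s = c(100, 50, 200), kind = c("mito_depol", "k_step", "fixation"),
    param = NA, value = c(NA, 20, NA))), "strictly between")
  expect_error(protocol_events(data.frame(
    time_s = c(100, 150, 200), kind = c("mito_depol", "k_step", "fixation"),
    param = NA, value = c(NA, -5, NA))), "K_ec_mM > 0")
})
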