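# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

vt0 <- physical_constants()$thermal_voltage

rat_cell <- function() cell_params(0.078, 0.296)

# a single deterministic rat cell at the preset resting/stimulated truth
rat_population <- function(n = 1, seed = 1, ...) {
  pop <- make_population(n, "rat_beta", seed = seed, ...)
  if (n == 1) {
    pop$psi_m_base <- -120; pop$psi_p_base <- -65
    pop$psi_m_glucose <- -166; pop$biphasic <- 0
  }
  pop
}

rat_params <- function() list(cell = rat_cell(),
                              kinetics = probe_kinetics(),
                              constants = physical_constants())

# noise-free full-protocol rat fixture with its calibration
rat_fixture <- function() cached("rat_fixture", {
  pop <- rat_population()
  ev <- standard_protocol()
  ts <- make_protocol_traces(pop, ev, seed = 1)
  res <- calibrate_traces(ts, ev, rat_params())
  list(pop = pop, ev = ev, ts = ts, res = res, r = res[[1]])
})

# short calibration-only protocol (no stimulus), noise-free
rat_fixture_short <- function() cached("rat_fixture_short", {
  pop <- rat_population()
  ev <- standard_protocol(stimulus = FALSE)
  ts <- make_protocol_traces(pop, ev, seed = 1)
  res <- calibrate_traces(ts, ev, rat_params())
  list(pop = pop, ev = ev, ts = ts, res = res, r = res[[1]])
})
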