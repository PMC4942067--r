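# mitovolt

Absolute, millivolt-calibrated measurement of the mitochondrial
membrane potential (ΔψM) and the plasma membrane potential (ΔψP) in
single intact cells, from dual-probe fluorescence time-lapse
recordings: non-quench-mode TMRM (cationic, reports both potentials)
plus an anionic bis-oxonol ΔψP indicator (PMPI).  The package is aimed
at cell biologists and bioenergeticists who need ΔψM as an absolute
number — for example to compare β-cell specimens that differ in
mitochondrial content or resting ΔψP, where conventional
fluorescence-ratio readouts are uninterpretable.

## The model in brief

Bath (activity 1), cytosol and mitochondrial matrix are linked by a
constant-field (GHK) plasma-membrane flux and an instantaneously
Nernstian inner membrane.  With reduced potentials u = ψ/(RT/F) and
g(u) = u/(e^u − 1):

    d a_cell/dt = k_T g(u_P) (1 − a_c e^{u_P}),   a_c = a_cell / D(ψ_M)
    d b/dt      = k_P (e^{u_P} − b)
    D(ψ_M)      = (1 − V_F) + (V_F / a_R') e^{−u_M}
    f           = f_x + s · activity          (per channel)

V_F is the mitochondria:cell volume fraction (confocal stereology with
the 2/3 correction factor, `estimate_vf()`), a_R' the apparent activity
coefficient ratio (nuclear-on-mitochondrial decay slope,
`estimate_ar_prime()`).  An internal calibration at the end of every
recording — complete mitochondrial depolarisation (mono-exponential
TMRM decay), stepwise bath-K⁺ elevations, and a fixation endpoint that
zeroes both potentials — determines all per-cell constants
(f_x, s, k_T, [K⁺]_ic) by two linear regressions and an endpoint
resolution, after which both potential time courses are back-calculated
in mV with delta-method standard errors and quality control
(r² > 0.2, baseline SE ≤ 25 mV, baseline ψP ≤ −40 mV).

Also included: a quench-mode rhodamine 123 simulator/analyzer that
reproduces the internal inconsistency of whole-cell quench-mode
readouts (mitochondrial fluorescence is not constant across an
oligomycin treatment), post-calibration heterogeneity analytics
(mono/biphasic classification, ΔψM-binned joint distributions,
sensitivity analyses), and a synthetic-data generator producing
protocol traces and two-channel confocal fields with exact ground
truth.

## Worked example

Simulate three rat β-cells through the full protocol (15 min baseline,
16 mM glucose, depolarisation cocktail, K⁺ steps to 80 mM, fixation)
with realistic camera noise, then calibrate:

```r
library(mitovolt)

pop <- make_population(3, "rat_beta", seed = 42)
ev  <- standard_protocol()
ts  <- make_protocol_traces(pop, ev, seed = 42,
                            noise = list(multiplicative = 0.0025,
                                         additive = 1))
params <- list(cell = cell_params(0.078, 0.296,
                                  vf_se = 0.0013, ar_prime_se = 0.007),
               kinetics = probe_kinetics(),
               constants = physical_constants())
res <- calibrate_traces(ts, ev, params)

res[["cell_001"]]
#> <potential_trace> 249 samples | baseline psi_P = -64.1 mV (SE 0.62),
#>   psi_M = -110.4 mV (SE 1.9) | QC pass

m <- attr(res[["cell_001"]], "model")
sprintf("k_T = %.4f 1/s, [K+]_ic = %.0f mM", m$k_t_fit, m$k_ic)
#> "k_T = 0.0155 1/s, [K+]_ic = 141 mM"

summarize_response(res[["cell_001"]], stim_time = 900)[
  , c("plateau_psi_m", "plateau_psi_p", "phenotype")]
#>   plateau_psi_m plateau_psi_p  phenotype
#> 1     -155.8         -39.3    monophasic
```

This cell's generated ground truth was ψM = −109 mV at baseline and
−151 mV at the glucose plateau: the baseline is recovered within its
predicted SE, k_T (truth 0.015 s⁻¹) within 4 %, and [K⁺]_ic (truth
140 mM) within 1 %.  The plateau reads a few mV more polarised than
truth — single-sample back-calculation far from probe equilibrium
amplifies noise convexly, which the per-point SEs report (see the
vignette's limitations section).  Noise-free recordings are recovered
to better than 0.05 mV.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mitovolt", package="mitovolt"))')" \
    simulate --preset rat_beta --n-cells 6 --seed 1 --out sim/
# then: calibrate, hetero, simulate-images, quench-demo
```

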