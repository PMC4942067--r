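---
title: "Absolute calibration of mitochondrial and plasma membrane potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute calibration of mitochondrial and plasma membrane potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovolt)
```

## The measurement problem

Redistribution-type potentiometric dyes report membrane potentials only
indirectly: their fluorescence follows probe content, which lags the
potential because permeation across the plasma membrane is slow and
voltage dependent, and which confounds the mitochondrial potential
(&Delta;&psi;~M~) with the plasma membrane potential (&Delta;&psi;~P~),
the amount of mitochondria per cell, and probe binding.  `mitovolt`
implements a dual-probe assay that removes these confounds and returns
both potentials in absolute millivolts for every cell in a time-lapse
recording: a cationic probe (TMRM, non-quench mode) reports the product
of both potential-driven accumulations, while an anionic indicator
(PMPI) reports &Delta;&psi;~P~ alone; an internal calibration performed
at the end of each recording (complete mitochondrial depolarisation,
stepwise potassium elevations, and a fixation endpoint that zeroes both
potentials) supplies every remaining per-cell constant.

## The probe model

The package models three compartments: the bath (an effectively
infinite reservoir, extracellular probe activity defined as 1), the
cytosol, and the mitochondrial matrix.  Two assumptions reduce the
system to one ordinary differential equation per probe:

1. **GHK plasma-membrane flux.** Probe crossing the plasma membrane
   follows a constant-field (Goldman-Hodgkin-Katz) law, normalised so
   that the rate constant at zero potential is `k_t` (TMRM) or `k_p`
   (PMPI).  With the reduced potential $u_P = \psi_P/(RT/F)$ and the
   rate factor $g(u) = u/(e^u - 1)$, the whole-cell TMRM activity
   $a_\mathrm{cell}$ obeys
   $$\frac{da_\mathrm{cell}}{dt} = k_T\, g(u_P)\,(1 - a_c e^{u_P}),
   \qquad a_c = \frac{a_\mathrm{cell}}{D(\psi_M)},$$
   and the PMPI activity $b$ obeys $db/dt = k_P(e^{u_P} - b)$.
2. **Instantaneous inner-membrane equilibrium.** The inner membrane is
   fast and Nernstian, so the matrix activity is
   $a_m = a_c e^{-u_M}$, scaled in fluorescence terms by the apparent
   activity coefficient ratio $a_R'$ (binding, matrix activity
   differences, optical dilution).  Fluorescence-equivalent whole-cell
   activity is then $a_\mathrm{cell} = a_c\, D(\psi_M)$ with
   $$D(\psi_M) = (1 - V_F) + \frac{V_F}{a_R'} e^{-u_M},$$
   where $V_F$ is the mitochondria:cell volume fraction.  $D(0)$ is
   written $D_0$.

Fluorescence is affine in activity, $f = f_x + s\,a$, with a per-trace
residual background $f_x$ (autofluorescence plus potential-independent
high-affinity binding) and scale $s$.

Two closed forms anchor everything.  At constant potentials the TMRM
activity relaxes mono-exponentially with rate
$\lambda = k_T g(u_P) e^{u_P} / D(\psi_M)$; and at distribution
equilibrium $a_\mathrm{cell} = e^{-u_P} D(\psi_M)$, $b = e^{u_P}$.

## The inverse calibration

Each ROI is calibrated independently by `calibrate_cell()`:

1. **Potassium steps** (`fit_kstep`).  With valinomycin rendering the
   membrane potassium selective, each bath potassium concentration
   $K_{ec}$ clamps $\psi_P$ at the potassium Nernst potential, so the
   PMPI plateau fluorescence is linear in $K_{ec}$:
   $f = f_{x,P} + (s_P/K_{ic}) K_{ec}$.  The regression intercept is
   the PMPI background, the span to the fixation endpoint is the scale,
   and their ratio with the slope yields $[K^+]_{ic}$ with no prior
   assumption about its value.
2. **&Delta;&psi;~P~ back-calculation** (`calibrate_psi_p`).  The
   first-order disequilibrium correction
   $e^{u_P} = b + \dot b / k_P$ (derivative from a centred moving
   linear fit) undistorts the PMPI kinetics; $k_P$ is fixed at the
   known value 0.38 s^-1^ because PMPI redistribution is fast relative
   to the 30 s sampling.
3. **TMRM decay** (`fit_decay`).  Collapsing &Delta;&psi;~M~ while
   clamping &Delta;&psi;~P~ turns the TMRM trace into an exact
   exponential whose rate and asymptote are estimated by regressing
   successive difference quotients on mid-interval fluorescence.  The
   regression's $r^2$ doubles as the quality-control statistic, and a
   direct nonlinear exponential fit (`fit_decay_exp`) is kept as an
   independent cross-check.
4. **Background/scale resolution and k~T~**
   (`resolve_background_and_scale`, `derive_k_t`).  The decay asymptote
   ($f_\infty = f_x + s_T D_0 e^{-u_{val}}$) and the fixation endpoint
   ($f_\mathrm{end} = f_x + s_T D_0$) are solved jointly for $f_{x,T}$
   and $s_T D_0$; the decay rate is inverted to the cell-specific rate
   constant $k_T = \lambda D_0 / (g(u_{val}) e^{u_{val}})$.
5. **&Delta;&psi;~M~ back-calculation** (`calibrate_psi_m`).  The flux
   equation gives the cytosolic activity even out of equilibrium,
   $a_c = e^{-u_P}(1 - \dot a_\mathrm{cell}/(k_T g(u_P)))$, and the
   compartment model is inverted per sample:
   $e^{-u_M} = a_R'(a_\mathrm{cell}/a_c - (1 - V_F))/V_F$.  The
   baseline uses the equilibrium form $a_c = e^{-u_P}$ on window means,
   which is legitimate because recordings start after the probes have
   equilibrated.

Standard errors come from first-order (delta-method) propagation of all
calibration inputs through this exact chain (`propagate_errors`), with
numerical partial derivatives; regression parameter pairs keep their
fitted covariance and everything else is treated as independent.  A
Monte-Carlo resampling cross-check (`mc_baseline_se`) validates the
approximation (the test suite requires agreement within 20 percent at
up to 2 percent relative intensity noise).

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `temperature` | K | 310.15 | sets RT/F = 26.73 mV |
| `vf` (V~F~) | - | preset (rat 0.078) | specimen specific, from stereology |
| `ar_prime` (a~R~') | - | preset (rat 0.296) | specimen specific, from the binding slope |
| `k_t` | s^-1^ | fitted per trace | population value 0.015 for primary beta-cells |
| `k_p` | s^-1^ | 0.38 | fixed; readout insensitive to its exact value |
| `p_n` | - | 0 | potassium-selective Goldman equation only |
| `window` | samples | 5 | derivative window at 30 s cadence |
| QC `r2_min` | - | 0.2 | either regression at or below fails |
| QC `se_max` | mV | 25 | on either baseline SE |
| QC `psi_p_base_max` | mV | -40 | depolarised baselines excluded |

## The synthetic-data generator

No single-cell recordings are distributed with the assay, so validation
rests on `make_population()` / `make_protocol_traces()` /
`make_images()`, which generate protocol traces and two-channel
confocal fields with exact ground truth.  The trace generator renders
the full paradigm - equilibrium baseline, glucose step, complete
mitochondrial depolarisation with its 20 min decay, four potassium
steps to 80 mM, and a 12 min fixation plateau at 30 s sampling - with
per-cell heterogeneity (baseline potentials, a glucose activation
scalar giving a continuous spread of stimulated &Delta;&psi;~M~, a
saturating monotone &Delta;&psi;~M~ to &Delta;&psi;~P~ coupling with
noise emulating the K~ATP~ pathway, biphasic responders with a slow
second depolarisation component), optional probe depletion at
liquid-handling events (the 10-20 percent range seen with untreated
plasticware), optional channel crosstalk, and seeded
multiplicative-plus-additive noise.  Defaults pin the published rat
beta-cell population values (V~F~ 7.8 percent, a~R~' 0.296, k~T~
0.015 s^-1^, resting &Delta;&psi;~M~ -120 mV, -166 mV in 16 mM
glucose); the resting &Delta;&psi;~P~ (-65 mV) and $[K^+]_{ic}$
(140 mM) are assumptions recorded in every truth sidecar, as no
measured values are available.  The cell-to-cell V~F~ coefficient of
variation defaults to 0.25, mirroring the plus/minus 25 percent
sensitivity scenario rather than a measured number.

Response kinetics: the mitochondrial response and the slow biphasic
plasma-membrane component use 60 s and 900 s time constants; the fast
depolarisation uses 20 s so that an ideal monophasic responder
completes well inside the 0-5 min early window and sits below the
10 percent biphasic threshold.  The stimulus segment lasts 65 min so
the 30-60 min plateau window clears the depolarisation event by more
than one derivative window.

The image generator renders one cell per field (0.1 um pixels, 16 um
fields, elliptical cytoplasm and nucleus, 0.4 x 1.5 um rods) with the
2D mitochondrial footprint inflated 3/2-fold over the true volume
fraction, so the 2/3 stereological factor of `estimate_vf()` is
genuinely exercised rather than cancelled; cells rotate round-robin
through 10 z-planes with midplane-dependent cross sections.  The
default point-spread blur is deliberately mild (sigma 0.4 px): at a
realistic confocal PSF (sigma about 1 px) Otsu binarisation dilates the
blurred rods and inflates V~F~ by 2-3 percent, a limitation users
should expect with real images too.

What passing tests therefore show: the inverse calibration exactly
inverts the stated forward model, the estimators are unbiased on data
that satisfy the model's assumptions, and the error propagation is
first-order correct.  What they do not show: robustness to motion,
focus drift, photobleaching, probe efflux-pump activity, segmentation
error, or any deviation of real probe photophysics from the
GHK/Nernst/affine-fluorescence model.

## Numerical choices

* Integration by `deSolve::lsoda` with absolute tolerance 1e-9 on
  activities; protocol events are exact parameter discontinuities
  (integration restarts at each event).
* The decay regression removes the discrete-difference bias in the rate
  analytically for uniform sampling
  ($\lambda = (2/\Delta t)\,\mathrm{atanh}(\lambda_\mathrm{raw}\Delta t/2)$),
  and its parameter covariance uses an MA(1) sandwich because adjacent
  difference quotients share a sample.  When an intensity noise SD is
  available, regression covariances are computed from it rather than
  from residuals (a 4-point potassium regression has 2 residual
  degrees of freedom).
* Window means of back-calculated potentials exclude half a derivative
  window at segment boundaries, where the moving fit straddles the
  discontinuity; the phenotype classifier similarly trims the first
  90 s after the stimulus.
* The TMRM fixation endpoint falls back to the asymptote of an
  exponential fit of the plateau whenever the fitted residual at the
  tail exceeds the noise floor (slow-k~T~ cells have not settled within
  the plateau); PMPI always uses the tail mean.
* Samples where a back-calculated activity is non-positive are flagged
  invalid and never interpolated; baseline and summary windows require
  at least 80 percent valid samples.
* The biphasic boundary is inclusive: a 30 min depolarisation exactly
  10 percent above the early mean classifies as biphasic.  The
  10 percent rule is interpreted on depolarisation relative to
  baseline, not on raw millivolts, because raw-mV ratios would depend
  on the arbitrary zero.
* `fit_kstep` plateau statistic: mean of the last 50 percent of each
  step window (PMPI relaxes within seconds of a step).

## Design decisions in the open

* **"Normalised fluorescence" regressions.**  The two calibration
  regressions operate on the plain linearisations of the model
  ($f$ vs $K_{ec}$; $\Delta f/\Delta t$ vs $f$), which are exactly
  linear under the model.  Slope and intercept units may differ from
  other implementations of the assay, but the regression structure that
  quality control and error propagation rely on is preserved.
* **V~F~ sensitivity convention.**  `sensitivity_vf()` perturbs V~F~ in
  the compartment inversion while holding the fitted optical constants
  and k~T~ fixed - the independent-parameter convention of the error
  propagation.  In the mitochondria-dominated regime the absolute bias
  then approaches $RT/F \cdot \ln(1 + \varepsilon)$ (+5.96 mV at +25
  percent) while the relative-to-baseline response is nearly immune;
  propagating the perturbation through the endpoint-based scale
  resolution as well would partially self-correct the absolute bias
  (to about 4.9 mV) without changing the qualitative conclusion.
* **Collection-artifact convention.**  `sensitivity_artifact()` scales
  the background-corrected (net) fluorescence,
  $f' = f_x + (1+\varepsilon)(f - f_x)$, so a PMPI-only artifact at an
  equilibrium plateau displaces &Delta;&psi;~P~ by exactly
  $RT/F\cdot\ln(1+\varepsilon)$ (0.63 mV at +2.4 percent).
* **Quench law.**  The quench-mode rhodamine 123 module uses a
  Hill-type saturable law $F(c) = c/(1 + (c/c_q)^h)$ with default
  $h = 1$, which makes deep-quench mitochondrial fluorescence a pure
  function of the apparent quench limit $c_q$ - the regime in which the
  whole-cell signal inverts sign and in which an oligomycin-evoked
  quench-limit change masquerades as hyperpolarisation.  The law and
  the representation of oligomycin as a parameterised $c_q$ drop are
  modelling choices, not mechanistic claims, and are swappable.

## Known limitations

* Single-sample &Delta;&psi;~M~ back-calculation amplifies intensity
  noise severely wherever the probe is far from equilibrium (deeply
  hyperpolarised plateaus): the correction divides by
  $k_T g(u_P) a_c e^{u_P}$, which is small exactly there.  Predicted
  SEs report this honestly; population averaging or longer derivative
  windows are the practical mitigations.
* Equilibration-time predictions (`equilibration_time`) reproduce the
  first-order structure (t~99~ = 2 t~90~; polarised uptake
  $D(\psi_M)/D_0$-fold slower than depolarised) and the order of
  magnitude of published times; exact times depend on potentials that
  are not published numerically.
* The stereology estimator inherits the bias of threshold-based
  binarisation under optical blur (see above), and assumes the masks
  provided to it are correct; no segmentation is performed.
* `p_n` other than 0 (non-potassium leak in the Goldman equation) is
  not supported and raises an error rather than silently approximating.

## Problem sizes used in the validation suite

The bundled tests run the full chain on single cells and small
populations (6-10 cells), a 50-field image set, a 2000-draw Monte-Carlo
SE cross-check, and an 8-point truth grid for round-trip recovery;
`scripts/acceptance.R` regenerates the headline preset recoveries from
scratch at those sizes.
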