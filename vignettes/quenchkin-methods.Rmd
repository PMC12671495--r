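---
title: "Models and methods in quenchkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quenchkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchkin)
```

quenchkin analyzes the standard chlorophyll-fluorescence readouts used to
map light harvesting and photoprotection across PSII antenna genotypes.
This vignette explains each model, its assumptions and tunable parameters,
the numerical choices underneath, what the synthetic generator does and does
not emulate, and known limitations.

## Connected-units induction model

When leaves are infiltrated with DCMU, the reduced quinone acceptor of PSII
cannot be reoxidized, so under continuous light every reaction center closes
exactly once and the fluorescence rise from F0 to Fm reflects the optical
cross section and the excitonic connectivity of the antenna bed. We use the
classical connected-units (Joliot-type) formulation: with inter-unit
transfer probability $p$, the relative variable fluorescence is

$$V(C) = \frac{(1-p)\,C}{1 - p\,C}, \qquad p = \frac{J}{1+J},$$

and closure proceeds as

$$\frac{dC}{dt} = k_\mathrm{ph}\,\frac{1-C}{1-pC}, \qquad C(0)=0 .$$

$J \ge 0$ is the connectivity that sets the curvature of the sigmoid
(reported values near 2 in connected wild-type antennae); both the $J$ and
$p$ parameterizations of the same hyperbola are exposed (`p_from_J`,
`J_from_p`) because the literature uses either. $k_\mathrm{ph}$ (s⁻¹) is the
photochemical closure rate at open centers, proportional to the optical
cross section times irradiance. $J = 0$ collapses to the unconnected
exponential limit $V = 1 - e^{-k_\mathrm{ph} t}$, which the tests assert
exactly.

Separating the variables gives the implicit closed form
$k_\mathrm{ph} t = -(1-p)\ln(1-C) + pC$, which we invert per time point by
guarded bisection (90 halvings on $C \in [0, 1)$; the left side is strictly
increasing in $C$, so convergence is unconditional and accurate to well
below 1e-12). A property test checks this path against brute-force `lsoda`
integration of the ODE to better than 1e-6 on every shipped preset.

Fitting estimates $(J, k_\mathrm{ph}, F_0, F_v)$ by Levenberg–Marquardt.
Initialization matters little for these well-conditioned curves; we take a
coarse grid over $J$ with $k_\mathrm{ph}$ matched to the observed two-thirds
rise time, then refine, with bounds $J \in [0, 10]$ and positive rates. Some
instrument fit conventions carry a baseline parameter and an effective PSII
yield as separate arguments; these are absorbed here into $F_0$ and
$k_\mathrm{ph}$ respectively, since neither is separately identifiable from
a single induction curve.

**Antenna size.** The conventional functional antenna size is the
reciprocal two-thirds rise time $1/t_{2/3}$ of the double-normalized curve
$(F-F_0)/(F_m-F_0)$. $t_{2/3}$ is the earliest crossing of 2/3, linearly
interpolated between bracketing samples. Because an Fm that is not actually
reached within the record would silently corrupt the normalization, the
accessor first checks that the final 20% of the record has flattened
(medians of the last two 10%-of-span windows within 0.02 of each other) and
errors otherwise.

**Relative optical cross sections.** For this model the complementary area
of the normalized curve is exactly
$\int_0^\infty (1-V)\,dt = 1/k_\mathrm{ph}$, independent of $J$ (substitute
$dt = (1-pC)/[k(1-C)]\,dC$ and the integrand collapses to $dC$). The
time-axis factor that equalizes the complementary areas of two genotypes is
therefore exactly their ratio of closure rates, i.e. the relative optical
cross section at equal irradiance. The implementation normalizes each trace
with the *fitted* $F_0$ and $F_v$ (not the observed extremes) and completes
the area beyond the recorded span with the fitted model's analytic tail
$(1-C_\mathrm{end})/k_\mathrm{ph}$; this keeps the estimator unbiased for
slow genotypes whose sweep does not fully saturate. The crossing-time ratio
at $V = 0.6$ is reported as a diagnostic only — when two genotypes differ in
$J$, the equal-area and equal-crossing criteria disagree slightly, and the
area criterion is the primary one. A shape-discrepancy score (RMS distance
of the rescaled curves) above 0.02 flags differing connectivity.

**Untreated rises and the PQ pool.** Without DCMU the rise is governed by
filling of the plastoquinone (PQ) pool. We use a deliberately minimal
two-pool model: closure as above, reopening by transfer to the oxidized
pool fraction $q$,

$$\frac{dC}{dt} = k_\mathrm{ph}\frac{1-C}{1-pC} - k_\mathrm{ox} C q,
\qquad \frac{dq}{dt} = -\frac{k_\mathrm{ox} C q}{n_\mathrm{PQ}},$$

integrated with `lsoda`. No PSI reoxidation, no thylakoid-domain
heterogeneity, no ms-scale flash photophysics: the model is sufficient for
slowdown-ratio logic, not for mechanistic PQ kinetics. Defaults:
$n_\mathrm{PQ} = 14$ oxidized electron equivalents per reaction center
(about 7 PQ molecules, the textbook pool size) and
$k_\mathrm{ox} = 300\ \mathrm{s^{-1}}$ (ms-scale reoxidation), placing the
weak-light rise firmly in the pool-limited regime where the time to any
fixed normalized level scales as $n_\mathrm{PQ}/k_\mathrm{ph}$. The
slowdown of a test genotype relative to a reference is measured at the
$V = 0.6$ crossing of the min/max-normalized rise; its product with the
relative cross section estimates the fold difference in PQ pool per active
reaction center. Following common reporting practice the slowdown is also
rounded (half-to-even) before multiplication and the product rounded to the
nearest integer as a "nominal" value.

## PAM quenching analysis

Level extraction from a pulse protocol is windowed and rank-based for jitter
robustness: F0 is the median of the pre-actinic baseline outside pulse
windows, Fm the maximum in the first (dark-adapted) pulse window, per-pulse
Fm′ the maximum within the pulse window and Fs the median of the second
preceding it. Small Fm′ > Fm excursions (≤ 2%) warn rather than fail, since
they are indistinguishable from noise.

NPQ uses the Stern–Volmer convention $(F_m - F_m')/F_m'$. Yields use the
simple complementary partition $\Phi_{II} = (F_m'-F_s)/F_m'$,
$\Phi_{NO} = F_s/F_m$, $\Phi_{NPQ} = F_s/F_m' - F_s/F_m$, which sums to 1
identically — the conservation is asserted at machine precision in the
tests. The fuller lake-model partition
($\Phi_{NO} = 1/(NPQ + 1 + q_L(F_m/F_0 - 1))$) is available behind
`lake = TRUE` but is not the default, matching prevailing usage. When F0′
is not measured it is estimated by the standard approximation
$F_0/(F_v/F_m + F_0/F_m')$.

qE/qI decomposition is operational, not mechanistic: maximal NPQ is read at
the last pulse of the light period, qI at the final pulse of the recorded
dark window (8 min in the default protocol), and qE is their difference.
This matches how rapidly relaxing versus sustained quenching is usually
quoted from two-period induction/relaxation protocols. An exponential
unmixing of the dark-phase relaxation is available as a secondary method
(`method = "exponential"`).

NPQ definite integrals (default window 0–480 s) use the trapezoid rule with
interpolation to the window edges, which makes the integral exactly additive
over subwindows. No baseline subtraction is applied by default; whether a
baseline should be removed before integrating is protocol-dependent and the
choice is surfaced as `subtract_baseline`. The NPQ-integral versus
antenna-content relation is fitted with a four-parameter logistic
constrained to be increasing.

## Xanthophyll cycle

The violaxanthin → antheraxanthin → zeaxanthin chain is modelled as linear
first-order kinetics with light-gated rates: forward de-epoxidation rates
$k_{VD}, k_{AZ}$ act during actinic segments, a single reverse epoxidation
rate $k_{EP}$ acts in darkness. Within each constant-light segment the
exact solution is the matrix exponential of the generator matrix, whose
columns sum to zero — pool conservation therefore holds to machine
precision, which the tests assert at 1e-12. The de-epoxidation index is
$DI = (Z + 0.5A)/(V+A+Z)$, the standard de-epoxidation state with
antheraxanthin counted half-converted; a `z_only` variant is provided since
some reports omit the 0.5 weighting. Rate fitting runs
Levenberg–Marquardt on log-rates (positivity by construction) against the
stacked V/A/Z residuals and refuses all-dark data as under-determined.

## Photoinhibition

Fv/Fm decline under photoinhibitory treatment is fitted as a single
exponential toward a plateau, $y(t) = y_p + (y_0 - y_p)e^{-kt}$; half-time
$t_{1/2} = \ln 2 / k$ is defined on the initial-to-plateau span, which makes
it invariant to the plateau estimate (the halfway-to-zero alternative is
computable from the returned parameters). Biphasic damage/repair kinetics
are out of scope. A nonparametric cross-check — the interpolated time at
which the data cross halfway between fitted initial and plateau — is
reported and agrees with $\ln 2/k$ within one sampling interval on clean
data.

## pmf light saturation

ECS-derived pmf amplitudes versus irradiance are fitted with the rectangular
hyperbola $a_\mathrm{max} I/(I + I_{1/2})$; only a half-saturation point is
usually quoted for such curves, and the hyperbola is the minimal form with
that parameter. An exponential-saturation alternative is available via
`form = "exponential"`. The fit is scale-equivariant in amplitude, so
relative $a_\mathrm{max}$ between genotypes is meaningful regardless of
instrument units.

## Genotype presets and the synthetic generator

Presets bundle published phenotypes per genotype: connectivity $J$, Fv/Fm,
relative F0, relative cross section, qE amplitude, Φ_NO plateau,
de-epoxidation endpoint, photoinhibition half-time (or 6-h endpoint for the
wild type), pmf amplitude and half-saturation, xanthophyll pool size, PsbS
level, and chlorophyll a/b ratio. Every numeric field carries a provenance
tag (`measured` / `derived` / `assumed`), and a test asserts the annotation
is complete. Derived fields are computed at build time rather than stored:

* `k_ph` anchors to the wild-type antenna size (1/t_2/3 = 5.76 s⁻¹) and
  scales by the relative cross section. Published per-genotype antenna-size
  and cross-section factors come from different instruments and light
  qualities and are not mutually consistent under a single $k_\mathrm{ph}$;
  we treat the cross-section factors as the generative truth and keep the
  per-genotype antenna-size table values as metadata.
* the koLhcb quenching amplitudes honour its published maximal NPQ of 22%
  of wild type: the fast amplitude is an assumed split and the sustained
  amplitude is solved from the constraint.
* xanthophyll forward rates are solved (1-D root find) so the simulated
  end-of-light DI equals the published endpoint, with an assumed
  $k_{AZ}/k_{VD} = 0.5$ and dark epoxidation time constant of 10 min.
* the wild-type photoinhibition rate is solved from its published 6-h
  endpoint (80% of the initial 0.82) with plateau 0; mutants use published
  half-times with an assumed plateau of 0.1.

NPQ trace synthesis uses two first-order components relaxing toward their
phase targets: the fast component toward qE in light (τ = 30 s) and toward
0 in darkness (τ = 60 s), the sustained component toward qI in light
(τ = 180 s) and frozen in darkness. These time constants are assumed — the
published kinetics are shown only graphically — and are excluded from any
recovery claim. Fm′ is back-computed as $F_m/(1+NPQ)$ and Fs from an
assumed steady-state Φ_II of 0.3 under 1000 µmol photons m⁻² s⁻¹, so the
full pulse pipeline sees realistic levels. During a synthetic pulse the
signal is frozen at the level implied by NPQ at pulse onset (quenching does
not relax within a sub-second pulse).

Two distinct PAM session kinds are generated because the published plateau
yields and the 1000-µmol NPQ kinetics belong to different protocols: a
`pam_session` light-response staircase (25–1000 µmol, 60-s steps, pulse at
each step's end) for Fv/Fm and yield partitioning, and an `npq_protocol`
(two 8-min illumination periods at 1000 µmol with 8-min dark windows,
pulses every 30 s) for NPQ kinetics and qE/qI. At high NPQ a Φ_NO of 0.28
cannot coexist with the transient NPQ maximum in one protocol (it would
force Fs > Fm′), which is why the staircase, not the NPQ protocol, carries
the yield targets.

Noise is multiplicative Gaussian (fluorescence noise scales with signal),
clipped at zero, seeded, and applied without touching the global RNG state.
Default problem sizes are small by design — induction 0–2 s at 1 ms,
untreated rises 0–10 s at 5 ms, PAM sessions ≈16–33 min at 0.5 s, pigment
courses every 30 s, decay courses every 15 min — which keeps full recovery
suites at desk scale (seconds) while leaving every estimator deeply
over-determined.

What the generator does **not** emulate: detector shot/readout structure,
instrument-specific pulse shapes, the O–J–I–P intermediate steps of real
induction curves, state transitions (qT), PSI spillover, and drift. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated models, not robustness to every artifact of real traces.

## Numerical choices and degenerate inputs

* Implicit-model inversion: fixed-count bisection (no derivative, no
  failure mode); fits: `minpack.lm` Levenberg–Marquardt with tight
  (1e-14) convergence tolerances.
* Crossing times: earliest crossing with linear interpolation; ties broken
  toward the earliest sample.
* Traces must have strictly increasing time and at least 4 samples; time is
  always seconds internally (readers convert `ms`/`min` via a `time_unit`
  metadata tag) to preclude 1000-fold unit errors.
* Degenerate inputs fail loudly and specifically: non-monotone time names
  the offending row, truncated inductions warn, non-declining decay courses
  and all-dark pigment courses error, zero xanthophyll pools error.

## Limitations

The connected-units model carries one connectivity parameter; heterogeneous
antenna domains (e.g. mixed populations of connected and isolated centers)
are not modelled and show up as shape-discrepancy flags instead. The PQ-pool
model is a ratio instrument, not a mechanism. The qE/qI split inherits the
protocol's dark-window length. All published-value recovery is
preset-mediated: it validates the estimators against encoded truth, not the
original instrument records, which are not publicly deposited.
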