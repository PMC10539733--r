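---
title: "Methods: 19F relaxation, binding and kinetics of fluoroproline peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 19F relaxation, binding and kinetics of fluoroproline peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpronmr)
```

This vignette is the package's own account of the models it implements,
the choices made where the methodology was genuinely open, and what its
synthetic-data tests do and do not establish.

## The spin system and the relaxation model

A Cγ-fluorinated proline carries the ¹⁹F in the middle of a rigid
five-membered ring, 2.0 Å from its geminal Hγ and 2.4–3.3 Å from the
two Hβ and two Hδ protons, with the exact distances set by the ring
pucker. Fluorination stereochemistry locks that pucker — Cγ-*exo* for
(4R)-FPro, Cγ-*endo* for (4S)-FPro, with computed major-conformer
populations above 90 % — so the package treats each site as a single
rigid conformer undergoing isotropic rotational diffusion with one
correlation time τc. The packaged `fpro_geometries()` table carries the
DFT-derived distances and ¹⁹F CSA tensors (Δσ ≈ −74 to −85 ppm for the
major puckers, −26 to −33 ppm for the minor ones, asymmetry η, and the
antisymmetric components, which are stored but unused).

Rates are computed as **pairwise-additive dipole–dipole plus symmetric
CSA**, with the normalisation J(ω) = (2/5)·τc/(1+ω²τc²) paired to the
prefactors shown on `r1_longitudinal()` and `r2_transverse()`. What is
deliberately left out:

* dipole–dipole/CSA and dipole–dipole/dipole–dipole cross-correlations,
* H–H couplings among the ring protons,
* antisymmetric CSA contributions,
* protons beyond the five ring protons of the table,
* internal motion (no order parameters, no pucker-exchange model).

The reference treatment for this system is a full Bloch–Redfield
calculation on the complete spin system; the additive model is the
standard analytical approximation. Its observable costs, measured by
this package's own tests:

* The R₁(τc) "camel hump" maxima land at 0.299 ns and 4.06 ns at
  14.1 T for the (4R)-*exo* major conformer, i.e. the upper maximum
  sits ~8 % below the full-treatment position (≈4.4 ns). The hump
  positions are controlled by 1/ωF and 1/(ωH−ωF); the additive
  approximation shifts the weights, not the mechanism.
* |NOE| is slightly overestimated (remote protons would add leakage to
  ρ), so τc estimates inverted from measured NOEs are quoted against
  interval targets (position 4 ≈ 0.35–0.65 ns, position 8 ≈
  0.6–1.0 ns) rather than point values.
* R₁ in the 0.4–0.9 ns window reproduces the measured 2.1–2.3 s⁻¹
  band for the (4R)-*exo* conformer but overestimates it (up to
  ~3.1 s⁻¹) for the (4S)-*endo* major conformer, whose larger CSA and
  shorter Hβ2/Hδ2 distances make the neglected cross-correlations more
  consequential. This is the main known accuracy limit of the additive
  model here.

### Limits worth knowing exactly

Two closed-form limits anchor the implementation. In extreme narrowing
all spectral densities are equal and the two-spin NOE is
+(γH/γF)/2 = +53.1 %. For slow tumbling every J scales as 1/(ω²τc), so
the *ratios* of spectral densities freeze at values set by the
frequencies alone:

σ/ρ → (6·rS − 1)/(1 + 3·rF + 6·rS)

with rF = (Δω/ωF)² ≈ 0.0039 and rS = (Δω/(ωH+ωF))² ≈ 0.0009, where
Δω = ωH−ωF. Numerically σ/ρ → −0.978 and the NOE → −103.9 %, not
the textbook −γH/γF = −106.2 %: the textbook value is a strict bound
approached only when J(ωF) and J(ωH+ωF) are neglected entirely, which
the Lorentzian spectral density never permits at finite field. The test
suite asserts the analytically derived −103.9 % and the strict bound.

### Inversions

`invert_tauc_from_noe()` bisects on log τc over [10 ps, 5 ns], the
branch on which the NOE is strictly monotonic (asserted numerically for
all four conformers); outside the attainable NOE range it errors,
naming the interval. `invert_tauc_from_r1()` returns *all* crossings on
[10 ps, 100 ns] — up to four for camel-hump curves — leaving the choice
of the physically plausible root to the caller, because a measured R₁
alone cannot distinguish them. Maxima are located discretely on a
≥50-points-per-decade grid and refined by golden-section search on
log τc (`stats::optimize`, tolerance 1e−4 in log₁₀ units).

## Relaxation fitting

All fits in the package go through one Levenberg–Marquardt least-squares
core with forward-difference Jacobians; parameter covariance is
s²(JᵀWJ)⁻¹ with s² the reduced weighted residual sum of squares. Rates
are parameterised on the log scale, which enforces positivity without
constrained optimisation; standard errors are mapped back by the delta
method. Starting values come from log-linear regression on the tail of
the decay. A constant intensity series is rejected (the rate is
unidentifiable), as are series with fewer than four distinct times.
Replicated time points — both acquisition schedules repeat one delay —
enter as independent observations.

The NOE build-up is fitted with the three-parameter model
I(t) = I₀ + (σ/ρ)(γH/γF)I₀(1−e^(−ρt)); the steady-state NOE is the
fitted plateau (γH/γF)σ/ρ, never the last measured point, and its
uncertainty includes the ρ–σ covariance.

## Binding equilibria and the titration fit

Speciation for the 1:1 model is the closed-form quadratic; for the 1:2
model (two sequential macroscopic constants, no statistical factors, no
cooperativity — the stoichiometry is all the data support) it is a
monotone one-dimensional root solve on free SH3.
`solve_equilibrium_ode()` reaches the same state by integrating the
mass-action equations from the all-free state until max|dX/dt| drops
below 1e−10 of the concentration scale. The stepper is backward Euler
with Newton iterations on the two-dimensional state rather than an
explicit scheme: switching the second binding step off by sending Kd₂
to infinity makes the system arbitrarily stiff, and only an
unconditionally stable stepper reaches steady state in a bounded step
budget. Detailed balance and mass conservation at the returned state
are asserted in the tests against the closed form and against an
independent bisection oracle.

`fit_titration()` fits, jointly to both observable blocks:

* per ¹⁹F signal, the bound-minus-free shift difference Δν (Hz),
  predicting the observed perturbation as p_b·Δν with p_b the *peptide*
  bound fraction;
* for the amide block, a saturating composite CSP, predicting
  f_b·CSP_max with f_b the *protein* bound fraction;
* Kd (log-parameterised; clamped in the objective against exp
  under/overflow).

Blocks are weighted by 1/noise² with defaults 1.6 Hz (¹⁹F) and
0.005 ppm (composite CSP). The 1.6 Hz figure is the back-calculation
residual the ¹⁹F titrations support; 0.005 ppm is a plumbing default
for the amide composite, configurable. The reduced χ² reported is the
weighted residual sum over N−NP. A warning is raised when the bound
fraction never crosses the 10–90 % range (Kd weakly identified), and
the fit is invariant to expressing ¹⁹F shifts in ppm given the
spectrometer frequency (tested).

The composite CSP is √(ΔδN² + w·ΔδH²) with w = 5 by default, read
literally from the formula as printed. The commoner conventions scale
the *proton* term by 25 or the nitrogen term down; since the source is
ambiguous the weight is an argument, and nothing downstream depends on
its absolute value — it only rescales CSP_max.

### Model comparison and its one caveat

Fitting the 1:2 model to 1:1-generated data should show no reduced-χ²
improvement, and does — *under measurement noise*. The comparison is
run warm-started from the 1:1 solution (Kd₂ large, second-state shifts
equal to the first) so the models are properly nested. With the 15 %
systematic stock-concentration bias switched on, however, the extra 1:2
parameters genuinely absorb part of the systematic misfit and produce
an apparent ~20 % median improvement. The lesson is methodological:
stoichiometry discrimination by χ² is only meaningful when the
concentrations are accurate, so the model-comparison test runs at
measurement noise only.

## Exchange kinetics

Apparent transverse rates come from Lorentzian line fits
(R₂‡ = π·FWHM; sum of Lorentzians plus constant baseline; overlapping
centres closer than a quarter of the broader width trigger a
covariance warning). The fast-exchange model
R₂‡ = p_f R₂f + p_b R₂b + p_f p_b Δω²/k_exc with
k_exc = k_on([SH3]free + Kd) is fitted for (k_on, R₂f, R₂b) per signal
— the optimisation is intentionally per signal, so anomalous behaviour
(such as opposite-sign width trends of the two signals of one peptide,
observed experimentally for MpRS) surfaces as a poor per-signal fit
rather than being averaged away. Δω, p_b, p_f, [SH3]free and Kd are
taken from the CSP fit and held fixed. k_on is fitted on the log scale
with a multi-start over 10⁶–10¹⁰ M⁻¹s⁻¹; if the exchange term
contributes less than 10 % of every R₂‡ the result is flagged
unidentifiable. The closed form assumes k_exc ≫ Δω; a validity flag
trips below k_exc = 5|Δω| (the qualitative condition made concrete).

The 8 Hz exponential broadening applied during processing is added by
the spectrum generator and can be subtracted by the caller as a
constant before converting widths to rates; it is not subtracted by
default, since whether the experimental analysis did so is not
recorded.

## Conformation reporters

The Cβ−Cγ difference calls trans at ≤5 ppm (the established criterion)
and cis at ≥8 ppm — conservative relative to the ~9–10 ppm typical of
cis prolines — with an explicit *ambiguous* zone between, so borderline
cases are visible rather than silently binned; a fluorinated Cγ
(≈95 ppm) voids the indicator. Pucker classification is
nearest-reference by RMS over shared couplings, ties reported rather
than broken, with (4R) ↦ Cγ-*exo* and (4S) ↦ Cγ-*endo*. The measured
(4S) sites deviate from the free amino acid by ≈5 Hz in ³J(F–Hδ2) —
an unexplained but reproducible offset — and the classifier flags any
residual above 4 Hz rather than interpreting it. Hδ2/Hδ3 follow the
table order of the transcribed assignments; the tables carry no
stereo-assignment, so only magnitude comparisons are meaningful.

## The synthetic world

`generator_config()` states the simulated experiment once:

| parameter | default | origin |
|---|---|---|
| ¹⁹F shift noise | 1.6 Hz | back-calculation residual of the titration fits |
| composite CSP noise | 0.005 ppm | plumbing default, configurable |
| line-width noise | 5 % relative | typical width-fit scatter |
| stock concentration bias | 15 %, one draw per stock | stated concentration uncertainty |
| exponential broadening | 8 Hz | processing apodisation |
| titration schedule | SH3 314 µM start, peptide 0→2000 µM in 12 points | reconstructed protocol |

The exact aliquot list of the experiment was not tabulated. The default
schedule starts the protein at 314 µM in 170 µL, takes the first
peptide point at 50 µM, climbs a roughly geometric ladder to 2 mM, and
dilutes the protein according to the aliquot volumes implied by the
millimolar stock (5.1/5.7 mM for the two peptides) — reproducing the
features that matter for identifiability: a mostly bound first point
(p_b ≈ 0.74) and >10-fold saturation span. Concentration error is a
single multiplicative draw per stock, not per point, because all
aliquots of a titration come from the same stock; modelling it per
point would understate the Kd uncertainty, which is dominated by
exactly this systematic term. With measurement noise only, the median
relative error on the recovered Kd is a few per cent; switching the
stock bias on widens it to roughly the ±30 µM the real titrations
quote. Amide bound-state shifts are not tabulated anywhere, so the
generator invents a saturating composite CSP (default 0.1 ppm); only
Kd/Δν recovery is therefore testable, not absolute protein CSPs.

What a green test does *not* establish: the generator shares its
forward model (fast-exchange averaging, Eq.-style line widths,
monoexponential decays) with the fitters, so recovery tests validate
estimator correctness and calibration, not the physical adequacy of
those models; there is no impurity species, no minor cis conformers
(beyond optional static peaks), no baseline or phase distortions, and
no intermediate-exchange line shapes.

## Numerical conventions

* ppm→rad s⁻¹ for Δσ uses ωF at the configured B₀ (14.1 T default);
  ¹⁹F ppm↔Hz conversion uses the spectrometer frequency implied by B₀
  unless given explicitly, and the titration reader refuses ppm input
  without one.
* NOE inversion: bisection to 1e−7 on log₁₀ τc (≈2e−7 relative).
* R₁ inversion: 80 points per decade for crossing detection, each root
  polished by bisection to 1e−8 in log₁₀ units.
* Steady state: max|dX/dt| < 1e−10·max(totals, 1 µM); Newton inner
  tolerance 1e−13 of the concentration scale.
* Seeds: every generator call reseeds from its config, so identical
  configs give bit-identical data; Monte-Carlo loops in the tests and
  the acceptance script derive sub-seeds below 2³¹ from one master
  seed.
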