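---
title: "Growth kinetics of elongating plant organs: models and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinetics of elongating plant organs: models and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitexex)
```

## The growth law and its kinetic reading

The package models dimensionless relative elongation `(V(t) − V0)/V0` of
an elongating organ (time in seconds throughout; minute- and hour-stamped
inputs are converted at the I/O boundary) as

$$y(t) = A t + B + C e^{-e^{-D (t - t_e)}}.$$

The law follows from the Lockhart/Ortega description of cell expansion —
relative volumetric growth rate equal to a viscoplastic extensibility
times the turgor in excess of the yield threshold — combined with
first-order kinetics of a wall-loosening factor, $dn/dt = k_1 - k_2 n$,
under the assumption that the biosynthesis time constant $T_1 = 1/k_1$
far exceeds the reduction one $T_2 = 1/k_2$. Early on, biosynthesis
limits growth and the solution linearises to
$\bar\Phi_0 t + \bar\Phi_0 t^2/(2T_1)$ with
$\bar\Phi_0 = \Phi_0 (P - Y) n_0$ (`epoch1_approx()`); once the
diffusion/reduction mechanism dominates, the dominant term is a Gompertz
sigmoid (`epoch2_approx()`). The derivation's constant prefactor and the
nested `exp(D t_e)`-type factor are absorbed into the fitted `C` and
`t_e`, and the two epochs' additive constants into the single fitted `B`
— which is why the package exposes exactly five coefficients.

Interpretation of the coefficients:

* `A` (s⁻¹): slope of the linear start-up. Since
  $A \approx \Phi_0 (P-Y) n_0$ with the Lockhart constant fixed at
  $\Phi_0 = 10^{-6}\,\mathrm{MPa^{-1} s^{-1}}$, `derive_kinetics()`
  reports `A/Φ₀` as a *turgor proxy* on a proportional MPa scale.
  The growth-factor concentration scale $n_0$ is not observable — no
  units for it are ever stated in this literature — so it is normalised
  to 1 and every derived quantity is proportional in it.
* `C`: growth amplitude. A rough association $C \sim \exp(1/k_2)$ holds
  only in the diffusion-dominated epoch; the package treats it as a
  diagnostic and never enforces it.
* `D` (s⁻¹): identified with the reduction rate $k_2$; `T2 = 1/D`.
* `t_e` (s): the effective moment at which a supplied growth factor
  starts to dominate — the sigmoid inflection. The analytic rate
  (`growth_rate()`) peaks exactly there with value $CD/e$.
* `B`: collects constants and slowly varying expansion orders; it has no
  established biological reading.

Standard errors of derived quantities propagate by first-order total
derivatives (e.g. $\mathrm{se}(T_2) = \mathrm{se}(D)/D^2$). Replicate
aggregation (`aggregate_fits()`) reports three distinct uncertainties —
the per-fit asymptotic SE, the across-replicate sample SD, and the
total-derivative propagation of per-fit SEs into the mean — because the
three answer different questions and collapsing them is a common source
of confusion in growth tables.

## Fitting

`fit_growth()` minimises the unweighted residual sum of squares with
bounded Levenberg–Marquardt (`minpack.lm`), bounds `A ≥ 0`, `C ≥ 0`,
`D > 0`, and `t_e` within the record span extended by one span on either
side. Weighting is deliberately not offered: elongation records have
approximately homoscedastic digitisation/sensor noise.

Starting values are data-driven (`initialize_growth_fit()`): the onset
`t_e0` is placed at the earliest maximum of the moving-average-smoothed
finite-difference rate (earliest, so plateaus resolve toward growth
onset; the window grows with the sample count so dense noisy records
still give a stable estimate); the start-up line is fitted only to
samples before half the onset time, because a fixed head fraction
swallows the sigmoid whenever `t_e` sits early in the record; `D0` uses
the exact Gompertz 10–90% rise factor $\ln(\ln 10 / \ln(10/9)) = 3.084$
divided by the observed rise duration; `C0` is the detrended amplitude.
A series whose detrended amplitude does not exceed ten times the noise
floor (median absolute first difference) is refused as signal-free
rather than fitted.

On a failed attempt the start is jittered (up to 5 restarts, driven by a
small private linear-congruential stream so the user's RNG state is
untouched) and a solution with `C` collapsed onto zero — a degenerate
basin, not a fit — is treated as a failure. A solution with `D` on a
bound is refused outright: the sigmoid time scale was not identified.
Standard errors come from the residual-variance-scaled inverse curvature;
because the five coefficients span ~10 orders of magnitude the curvature
matrix is equilibrated by its diagonal before inversion.

Design of the recovery study (`parameter_recovery_study()`): coefficients
are drawn uniformly over the ranges spanned by published coleoptile fits
(`A` ∈ [0, 3e-6] s⁻¹, `B` ∈ [−0.006, 0.01], `C` ∈ [0.03, 0.33], `D` ∈
[9e-5, 5.5e-4] s⁻¹, `t_e` ∈ [9800, 24700] s), each record spans
`[0, t_e + 6/D]` at 600 samples — long enough for the sigmoid to
saturate, as an experimenter would run it — with Gaussian noise of 0.5%
of the amplitude `C`. Under these conditions ≥ 90% of 200 seeded
replicates recover `C` and `D` within 5% and `t_e` within 2%.

## Rate–elongation calculus and peak summaries

Growth-rate records integrate to elongation by the trapezoidal rule
(`cumulative_elongation()`; the rule is fixed, documented, and exact for
constant rates) and elongation differentiates back by central differences
with second-order one-sided stencils at the record ends
(`differentiate()`), so the round trip is the identity to ~1e-8 relative
at 1 s sampling. `peak_stats()` smooths with an odd centred moving
average (default 5 samples, configurable and logged) before locating the
global maximum; the full width at half maximum interpolates the crossings
linearly; a maximum on the record boundary is flagged (`has_peak =
FALSE`) instead of given a spurious width. Because published summary
tables do not state whether "total growth rate" is a mean rate or an
integral per duration, both variants are computed and labelled.

## Growth-rate spectra

For several non-interacting wall-loosening factors the Ortega balance
(elastic term neglected, constant turgor excess) makes the growth rate a
positively weighted sum of exponential decays; each component contributes
a Lorentzian $P(f) \propto 1/(k^2 + 4\pi^2 f^2)$ to the one-sided power
spectral density, maximal at $f = 0$ with value $1/k^2$. The package uses
the plain periodogram with a rectangular window and a one-sided density
normalisation (`p = |X|² dt/n`, interior bins doubled) under which
Parseval's identity `sum(p)·df = mean(x²)` holds exactly — the
convention is config-exposed in the sense that the detrend mode is, and
is stated in the object.

Detrending defaults matter: mean or model detrending zeroes the $f = 0$
bin by construction, so *intensity readings at zero frequency must use
`detrend = "none"`*; detrended spectra are for examining the oscillatory
remainder. `fit_lorentzian()` inverts the Lorentzian over a configurable
low-frequency window, excluding the $f=0$ bin (it is not doubled by the
one-sided folding and is structurally off the model); with two
well-separated components the low band is dominated by the slower rate,
which is recovered within ~10% when the rates differ by a factor of ~20
or more. Absolute intensities are comparable only within one run's
convention; between treatments only ratios (which follow $1/k^2$) are
interpretable.

## Cross-correlation and the zero-lag derivative jump

The discrete cross-correlation $(f\star g)[n] = \sum_m f[m] g[m+n]$ is
taken over the valid overlap of the two records; `raw` is the default
normalisation because the published curves are unnormalised, with
`biased`, `unbiased` and `coeff` (bounded by 1 in magnitude) exposed.
pH enters as-is — the negative logarithm is already applied — and the
elongation record is the second argument, so a positive lag means the
growth response trails the pH record. Resampling to a common grid is by
linear interpolation; the default maximum lag is a quarter of the record.

Differentiating with respect to the lag (`ccf_derivative()`, central
differences on the interior of the lag grid) is discretely identical to
correlating pH with $du/dt$ — the identity holds to near machine
precision for signals that vanish at the record edges, which is the
faithful discretisation of the infinite-record integral the identity is
derived from. Its dimensional content is H⁺ activity per micrometre of
growth, so a discontinuity of the derivative at zero lag
(`jump_at_zero()`: right minus left one-sided least-squares slopes over a
5-lag window by default, window logged, bootstrap SE from residual
resampling with a fixed seed) quantifies acid secretion per unit growth.

Two numerical facts shape how the jump should be read. First, for a
finite record the overlap boundary itself contributes a kink at zero lag
of order `f(T)·g(T)` — it is part of the estimator's convention, scales
bilinearly with the signals exactly as the genuine effect does, and
cancels in treatment ratios computed under a common protocol (equal
record lengths, sampling and windows), which is how `activity_profile()`
presents results. Second, a genuinely smooth pair yields only curvature
leakage that vanishes proportionally with the sampling interval, whereas
a real coincident discontinuity gives a refinement-stable jump — the
package's tests discriminate the two exactly this way. Absolute jump
values are reported in pH·μm/s with the explicit caveat that only
between-treatment ratios are interpretable.

The synthetic pair generator (`make_ph_pair()`) offers two acidification
profiles: the onset-anchored saturating exponential
`pH0 − ΔpH(1 − e^{−r(t−onset)})`, and a `mirror` profile in which
acidification tracks the growth sigmoid itself — under acid-growth
coupling the two rate pulses are then exact shifted copies, so
correlating the rates recovers a constructed lag at sample resolution.
The mirror profile exists because cross-correlating two *monotone*
saturating traces is a degenerate lag problem (the objective is flat in
the lag); rate pulses are the well-posed carrier of delay information.

## The E_H+ membrane constant

The empirical relation $E_m = E_{H+} \cdot (\mathrm{pH} \cdot \mu m)$
links membrane potential to the product of pH and elongation;
`aggregate_ehplus()` reproduces the published table layout (row means
over time points, column means over treatments, grand mean as the mean
of row means — equal, for a complete table, to the mean of all cells).
Sign convention: cells keep the sign of $E_m$ (negative), while the
headline constant is quoted as a magnitude (0.157 V/mm in maize);
mV/μm and V/mm are the same unit. Because the literature quotes the
grand-mean uncertainty without defining it — and no single definition
reproduces the printed ±0.009 — three labelled spreads are reported (SD
of row means, SD of column means, mean of row SDs). Whether the
elongation entering the ratio is cumulative or a per-interval increment
is a convention of the data set; the functions compute the ratio for
whatever μm value is supplied and the ambiguity is documented rather
than resolved.

## Synthetic data: what it emulates and what it does not

The generators produce: growth curves obeying the growth law with iid
Gaussian noise (default 0.5% of `C`, matching the visual scatter of
published digitised records); multi-factor growth rates as weighted
exponential decays with the completeness constraint $\sum w_i = 1$
enforced to 1e-9; and pH/elongation pairs with designed onset, lag and
slope break. All are bit-reproducible under a fixed seed, and changing
only the seed changes only the noise.

They do *not* emulate: heteroscedastic or autocorrelated sensor noise,
digitisation quantisation, drift or step artefacts, turgor fluctuations,
or abraded-tissue effects on pH coupling. Passing tests therefore
demonstrate estimator correctness under the model's own assumptions, not
robustness to every artefact of real records.

## Problem sizes and numerical choices

The test suite and the acceptance script use records of 600–36 001
samples, 200-replicate recovery studies, and 1024-point spectra — sizes
chosen so the whole suite runs in well under a minute while every
asymptotic claim (Parseval to 1e-6, round-trip calculus to 1e-6 relative,
log-log slope −2 ± 0.05 across a decade of `k`) is already in its
converged regime. Tolerances in the tests are derived from oracle
computations (fourth-order finite differences, Runge–Kutta integration,
high-precision arithmetic frozen into the suite), never tuned to outputs.
Degenerate inputs fail loudly and early: non-monotone time stamps,
missing values, signal-free series, non-uniform sampling beyond 1%
jitter for spectra, ragged ratio matrices.

## Known limitations

* The elastic term $(1/\varepsilon) dP/dt$ of the full Ortega equation is
  outside scope; all spectra assume the viscoplastic regime.
* Absolute turgor is not recoverable — only the proxy `A/Φ₀`
  (proportional in the unobservable $n_0$).
* Spectral peak hunting / oscillation significance testing is not
  provided; the spectral module is built around the $f = 0$ reading.
* Cross-correlation jump values are convention-bound (record length,
  normalisation, window); treat absolute values as arbitrary units.
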