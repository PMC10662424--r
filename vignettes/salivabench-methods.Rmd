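---
title: "Methods: in vitro benchmarking of saliva-substitute lubricants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vitro benchmarking of saliva-substitute lubricants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivabench)
```

Saliva substitutes for xerostomia (dry mouth) are routinely compared with
four in vitro assays: rotational shear rheology, capillary-breakup
extensional rheometry (CaBER), soft tribology on dry-mouth-mimicking
elastomer surfaces, and quartz-crystal-microbalance (QCM-D) adsorption and
desorption. `salivabench` implements the analysis side of all four assays
as a reusable pipeline, together with a synthetic-data module that
emulates the instruments with known ground truth, so every stage is
testable without instrument access.

## Shear rheology and format classification

Flow curves (apparent viscosity $\eta_{shear}$ versus shear rate
$\dot\gamma$, typically 0.1–1000 s$^{-1}$ at 37 °C) are summarised by the
apparent viscosity at the orally relevant shear rate of 50 s$^{-1}$,
obtained by log–log linear interpolation between the bracketing measured
points (`viscosity_at()`). Flow curves span decades on both axes and are
locally near power-law, so interpolating linearly in log–log space is the
natural choice; queries outside the measured range raise an error rather
than extrapolate silently.

Products are binned into three format categories by the 50 s$^{-1}$
viscosity (`classify_viscosity()`): *liquids* below 0.10 Pa s, *viscous
liquids* between 0.10 and 1.0 Pa s, and *gels* above 1.0 Pa s. The
interval is taken closed on the viscous-liquid side, so the outer classes
are defined by strict inequalities; the 1.0 Pa s gel threshold is the one
consistent with typical measured gel viscosities of 5–8 Pa s.

For downstream use (the Trouton ratio below) the full rate dependence is
fitted with a four-parameter Cross model in log-viscosity space
(`fit_shear_model()`),

$$\eta(\dot\gamma) = \eta_\infty +
  \frac{\eta_0 - \eta_\infty}{1 + (\lambda\dot\gamma)^m},$$

which captures in one family both near-Newtonian sprays with a low-rate
plateau and gels whose viscosity falls three decades over the sweep. The
fit is deterministic: $\eta_0$ starts at the largest measured viscosity,
$\eta_\infty$ at the smallest, $\lambda$ at the reciprocal of the rate
where the curve passes its geometric-mean viscosity, and $m$ at 1;
optimisation is Levenberg–Marquardt (`minpack.lm`) on log-transformed
positive parameters. An exactly constant curve short-circuits to the
Newtonian fit.

## Extensional rheology (CaBER)

A CaBER run tracks the minimum diameter $D_{min}(t)$ of the liquid bridge
left between two plates (diameter $D_0$ = 6 mm, initial gap 3 mm — aspect
ratio 0.5 — stretched to 10 mm) with a laser micrometer of 20 µm
resolution. Two thinning models are fitted:

* **Elastocapillary (elastic) model.** For a dilute elastic fluid the
  force balance predicts exponential thinning,
  $D_{min}(t) \sim e^{-t/3\lambda_c}$, with relaxation time $\lambda_c$.
  `fit_elastic()` regresses $\ln D$ on $t$ and reports
  $\lambda_c = -1/(3\,\mathrm{slope})$.
* **Power-law model.** For inelastic shear-thinning fluids,
  $D_{min}(t) = 2\phi_0 (\sigma/K)(t_b - t)^n$ with prefactor
  $\phi_0 = 0.142$, surface tension $\sigma$ (a required per-sample
  scalar, measured separately), consistency $K$, exponent $n$ and breakup
  time $t_b$. `fit_power_law()` solves the nonlinear least-squares
  problem in log-diameter space, initialising $t_b$ from the observed
  breakup and $(K, n)$ from a linear regression at that $t_b$, and
  constrains the fitted $t_b$ to lie beyond the last usable sample.

`select_thinning_model()` fits both and keeps the lower rms log-residual,
with ties going to the power law (the model describing most substitutes);
liquids with dominant elasticity select the elastic model on residuals
alone.

**Window selection.** The instrument trace includes an initial plateau
(before thinning sets in) and a censored tail at the resolution floor.
Fits discard the longest initial run of diameters above 95% of the
starting value, all samples at or below the resolution floor, and
beads-on-a-string artifacts — samples where the diameter locally rises by
more than 5% between neighbours, an instability seen with elastic
filaments. Among what remains, the elastic fit uses the longest
contiguous window whose log-linear rms residual is below 0.05 (trimmed
from the worse-fitting end if necessary). These windowing rules are
package decisions; instrument software typically leaves them unstated.

**Breakup detection.** `detect_breakup()` returns the earliest time at
which the diameter reaches the resolution floor and never rises above it
again; an isolated noise dip is therefore ignored, and a trace that ends
above the floor yields `NA` rather than an error.

**Derived profile.** `extensional_profile()` computes the Hencky strain
$\varepsilon = -2\ln(D_{min}/D_0)$, the instantaneous strain rate
$\dot\varepsilon = -(2/D_{min})\,dD_{min}/dt$, the apparent extensional
viscosity $\eta_{ext} = (2\sigma/D_{min})/\dot\varepsilon$, and the
strain-rate-matched Trouton ratio
$T_r(\dot\varepsilon) = \eta_{ext}(\dot\varepsilon) /
\eta_{shear}(\dot\varepsilon)$, where the denominator is the fitted Cross
model evaluated at a shear rate numerically equal to the strain rate.
Matching rates pointwise avoids the large bias a single reference shear
viscosity would introduce for samples spanning five decades of viscosity;
the conventional $\sqrt{3}$ kinematic conversion between extension and
shear rates is deliberately not applied, so $T_r$ here is defined exactly
as the ratio at equal numerical rates. The maxima of $\eta_{ext}$ and
$T_r$ are extracted independently — they need not occur at the same
strain.

**Numerical differentiation.** $dD/dt$ comes from local quadratic
least-squares fits over a centred window (5% of the segment length,
minimum 5 points); raw finite differences would amplify the micrometer's
quantisation noise. Smoothing is confined to the post-plateau,
above-floor segment so windows never straddle the plateau kink or the
censored tail; masked artifact points are excluded from each window.
Maxima are taken over a valid window that additionally requires the
diameter below 95% of the post-plateau start and the strain rate above a
floor (default $10^{-3}$ s$^{-1}$), since $\eta_{ext}$ is singular as
$\dot\varepsilon \to 0$. On noiseless exponential traces the pipeline
reproduces the symbolic results ($\dot\varepsilon = 2/3\lambda_c$,
$\eta_{ext} = 3\lambda_c\sigma/D$) to better than 0.5% away from window
edges, which is the accuracy bound enforced in the test suite.

## Soft tribology

`hertz_sphere_contact()` implements the classical sphere-on-flat Hertz
solution with both bodies of the same modulus:
$E^* = E/(2(1-\nu^2))$, $a = (3FR/4E^*)^{1/3}$, mean pressure
$F/\pi a^2$, peak pressure $1.5\times$ the mean. A Poisson ratio of 0.5
(incompressible elastomer) is the default, which reproduces the nominal
~200 kPa contact pressure of a 19 mm PDMS ball loaded at 2.0 N.
`friction_from_torque()` converts plate-on-plate torque sweeps via
$\mu = M/(R F_N)$ and `entrainment_from_angular()` applies
$U = \Omega R$.

`segment_regimes()` classifies a Stribeck curve into boundary, mixed and
hydrodynamic regimes from the slope of the smoothed log–log curve: the
boundary plateau is the initial run with $|d\log\mu / d\log U| < 0.1$,
the mixed regime ends at the curve minimum (searched from the plateau end
onward, so the regime ordering is preserved even for curves that rise
monotonically out of the plateau), and the hydrodynamic branch starts
where the slope exceeds $+0.1$ after the minimum. Slopes use degree-1
local fits over 5-point windows: in the one-sided windows at the curve
ends a quadratic term is poorly determined and would inflate the slope
variance severalfold. The boundary friction coefficient is reported as
the median measured $\mu$ over the plateau (a plateau median and a
point reading at a reference speed are both exposed, since published
"boundary" values may be either). `percent_reduction()` expresses
pairwise lubricant comparisons as $100(1 - \mu_a/\mu_b)$.

## QCM-D adsorption and desorption

Adsorption of a lubricant onto a PDMS-coated sensor lowers the resonance
frequency; rinsing with buffer removes part of the layer and raises it
again. `summarize_qcmd()` reports three quantities. The pre- and
post-rinse plateaus are medians over trailing 10% windows of the
adsorption phase and of the whole trace respectively — medians resist
drift and spikes. The saturation time is the first time after injection
at which $|\Delta f|$ exceeds 98% of the pre-rinse plateau and stays
above it until the rinse; the trace is lightly median-smoothed (31
samples) before thresholding because the 2% headroom of the criterion is
comparable to raw counter noise, and for noiseless exponential kinetics
with time constant $\tau$ the detected time is $\tau\ln(1/0.02) \approx
3.91\tau$. The desorption extent — the "in vitro coating index" — is the
relative plateau drop
$100(|\Delta f|_{before} - |\Delta f|_{after})/|\Delta f|_{before}$. The
index counts material *removed*, so larger values mean a poorer coating;
the summary carries a textual note rather than inverting the scale. A
negative extent (continued adsorption after rinsing) is reported as is.

## Synthetic instrument data

`generate_flow_curve()`, `generate_thinning_trace()`,
`generate_friction_curve()` and `generate_qcmd_trace()` emulate the four
instruments from explicit parameter objects; every generator takes an
explicit seed, leaves the caller's RNG state untouched, and is
bit-reproducible. Noise is multiplicative lognormal (CV 2% by default)
for viscosity, diameter and friction — instrument scatter on these
channels is scale-proportional — and additive Gaussian (sd 0.5 Hz) for
the frequency counter. Thinning traces are censored at the 20 µm
resolution floor rather than truncated, exactly as a laser micrometer
reports them, which exercises breakup detection. The Stribeck generator
blends a boundary plateau into a rising branch $c(\eta U)^p$ with a
logistic weight in $\log U$; the QCM-D generator uses exponential
adsorption and desorption kinetics. The Cross flow-curve law, the
Stribeck blend and the exponential QCM-D kinetics are package constructs
chosen to reproduce the qualitative shapes of the measured curves; only
the two thinning laws are the physical models that are also fitted.

`preset_params()` bundles parameters for four representative samples — a
spray-like liquid, a viscous liquid, a gel and diluted human saliva —
whose noiseless summary statistics land on published anchor values for
each class: 50 s$^{-1}$ viscosities of 0.025, 0.548, 5.4 and 0.0025 Pa s;
breakup times of order 0.03, 0.31, 24 and 2 s; QCM-D plateaus of 20.6,
21.6, 50.0 and 63.6 Hz with removal fractions 0.28, 0.23, 0.46 and 0.04;
saturation times from ~12 to ~54 min. Where no measured value pins a
generator parameter (noise levels, transition speeds and sharpness,
desorption time constant of 60 s, sampling rates), values were chosen
once at instrument-realistic magnitudes and are not tuned thereafter.
For the viscous-liquid thinning preset, the power law evaluated too far
before breakup would exceed the plate diameter, so its initial plateau
ends at 0.15 s, the earliest time at which the model fits between the
plates; the generator raises an error for parameter sets that violate
this constraint. The saliva preset classifies as a *liquid* (0.0025 Pa s
is far below the 0.10 Pa s threshold) — real saliva is not a "product
class" of its own.

What passing tests on these synthetic data do **not** show: real traces
carry drift, non-lognormal outliers, inertio-capillary oscillations
early in thinning, partial-slip tribology artifacts and viscoelastic
QCM-D responses that the generators deliberately omit. The pipeline's
robustness features (median plateaus, artifact masking, persistence
rules) address these qualitatively, but parameter-recovery accuracy on
real instruments should be expected to be worse than the synthetic
recovery bounds below.

## Verification strategy and problem sizes

The test suite checks three layers, all on data generated in code:
exact/closed-form identities (Hertz ratios, $U = \Omega R$, Hencky
strain values, linear-thinning $\eta_{ext} = K/2\phi_0$, desorption
scale invariance); noiseless round trips (generate-and-refit recovers
Cross, elastic and power-law parameters to well under 1%); and noisy
recovery at the default noise levels over 50 seeds per case, where the
median errors are required below 5% for $\lambda_c$, $(K, n, t_b)$ and
the boundary friction coefficient, within 2 percentage points for the
removal percentage, and within 10% of the closed-form value for the
saturation time. Traces use 300–2500 samples per run — comparable to
real instrument exports — and the whole suite completes in seconds.

## Orchestration

`run_benchmark()` executes all four analyses over a YAML (or list)
manifest mixing preset-generated and file-based samples, isolating
per-sample failures into a `note` column; `reduction_matrix()` compares
boundary friction pairwise against a reference class; and
`render_benchmark()` writes a stable CSV, a YAML run log and overlay
plots. Replicate flow curves are averaged pointwise before analysis
(at least three replicates per modality is the usual experimental
design), and a `p_value` column is left as a hook for externally
computed significance tests (Kruskal–Wallis/Dunn), which are standard
off-the-shelf procedures outside this package's scope.

## Known limitations

Only the fundamental QCM-D frequency shift is modelled — no dissipation,
overtones or Sauerbrey mass conversion, so adsorbed amounts are reported
in Hz, not mass. Oscillatory shear, yield stresses and thixotropy are
out of scope for the flow-curve module; elastohydrodynamic film-thickness
theory and wear are out of scope for tribology; image-based filament
detection is out of scope for CaBER. The power-law prefactor
$2\phi_0 = 0.284$ is implemented as the thinning law states it, although
half that coefficient is also common in the visco-capillary literature —
users fitting literature data should check which convention their source
uses, since $K$ scales proportionally.
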