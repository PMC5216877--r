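---
title: "Models and methods behind deerquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deerquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerquant)
```

## The scientific problem

ABC exporters pump substrates across membranes by coupling ATP binding and
hydrolysis at their nucleotide-binding domains (NBDs) to a conformational
switch of the transmembrane domains between an inward-facing (IF) and an
outward-facing (OF) state. Pulsed double electron-electron resonance (DEER)
on spin-labeled pairs reads this switch out as a change in the inter-label
distance distribution: NBD and intracellular pairs shorten on closure, and
extracellular pairs lengthen (and broaden) as the outer gate opens. When a
frozen sample contains a *mixture* of IF and OF transporters, the distance
distribution is bimodal, and the relative areas of the two modes measure
the conformational equilibrium under each nucleotide condition.

`deerquant` implements the quantitative chain from time-domain DEER traces
to those population fractions, together with the ATPase inhibition
kinetics (IC50, Cheng-Prusoff K~i~, turnover bookkeeping) that accompany
such studies of heterodimeric transporters with one degenerate and one
consensus ATP site.

## Forward model

A normalized DEER trace is modeled as

$$V(t) = \left[(1 - \lambda) + \lambda \int K(t, r)\, P(r)\, dr\right]
  \cdot B(t)$$

with modulation depth $\lambda$, intermolecular background $B$, and the
powder-averaged dipolar kernel

$$K(t, r) = \int_0^1 \cos\!\left[(3x^2 - 1)\,\omega(r)\, t\right] dx,
  \qquad \omega(r) = \frac{2\pi D}{r^3},$$

evaluated in closed form with Fresnel integrals. The dipolar constant is
fixed at $D = 52.04$ MHz nm^3^ (free-electron $g \approx 2.006$), exposed
as `DIPOLAR_CONSTANT_MHZ_NM3`. Orientation averaging is assumed isotropic,
appropriate for Q-band measurements with a large pump-observer frequency
offset. Time is in microseconds and distance in nanometers throughout;
default grids are $t \in [0, 2.5]$ us in 8 ns steps and
$r \in [1.5, 10]$ nm in 0.05 nm steps.

The background is a stretched exponential
$B(t) = \exp(-k\, t^{d/3})$ with homogeneous dimension
$d \in [1.5, 3]$: $d = 3$ for a three-dimensional bath of spins
(detergent solution), lower dimensions for spins confined to membranes.
Two parameterizations are in circulation, $k\,t^{d/3}$ and $(k\,t)^{d/3}$;
this package uses $\exp(-k\,t^{d/3})$ consistently in both simulation and
fitting, so $k$ carries units of $\mathrm{us}^{-d/3}$.

## Background correction

`fit_background()` fits $(1 - \lambda) B(t)$ to the trace tail (default
window: the last 60% of the trace), where the intramolecular oscillation
has dephased. Two practical caveats are built in:

* With `d` free, the three parameters are nearly collinear on short traces
  or in the presence of slowly decaying long-distance components: smooth
  dipolar decay is then absorbed into the background and $\lambda$
  collapses. For homogeneous (detergent) samples `d_fix = 3` removes this
  degree of freedom and recovers $\lambda$ to about $\pm 0.03$ under
  typical noise.
* Traces must be long enough for the distances probed: a component at
  distance $r$ completes one dipolar period only after
  $t = r^3 / D$, so panels containing ~4.8 nm components are simulated
  with 4 us traces.

`form_factor()` divides the fitted background out and renormalizes to
$F(0) = 1$.

## Model-free inversion

`tikhonov_invert()` extracts the dipolar part
$S(t) = (F(t) - (1 - \lambda)) / \lambda$ and solves

$$P = \operatorname*{argmin}_{P \ge 0}
  \left\|W\,(K_w P - S)\right\|^2 + \alpha^2 \left\|L_2 P\right\|^2$$

with trapezoidal quadrature weights folded into $K_w$, the
second-difference operator $L_2$ penalizing curvature, and an optional
diagonal weight $W$. Non-negativity is enforced *exactly* by a
Lawson-Hanson active-set solve of the stacked augmented system (clipping a
signed solution would distort the areas that later become population
fractions). Returned distributions are area-normalized (trapezoidal
integral 1 within 1e-9).

Because noise that is white on $V(t)$ is amplified by $1/B(t)$ after
background division, the pipeline weights data residuals by the fitted
$B(t)$ (a generalized-least-squares correction); this measurably
stabilizes both the inversion and the Gaussian fits below.

`select_alpha()` picks the regularization parameter at the L-curve corner:
the point of maximum Menger curvature of
$(\log\|K_w P - S\|, \log\|L_2 P\|)$ along a log-spaced $\alpha$ grid,
computed on a wide three-point stencil with the grid ends excluded (both
choices damp spurious corners from point-to-point noise). A structureless
form factor leaves the residual norm nearly independent of $\alpha$; this
degenerate case falls back to the median $\alpha$ with a warning. L-curve
selection was chosen over generalized cross-validation because it is
deterministic and directly unit-testable against a reconstruction-error
oracle.

Peak positions are reported by `peak_position()`, the first moment of the
contiguous region around the global mode above 10% of its maximum; a
whole-grid first moment would be dominated by the low-amplitude far-field
ripple that any regularized inversion leaves.

## Two-Gaussian population quantification

The population analysis fits a two-component Gaussian mixture *through the
forward model to the time-domain form factor* (distance-domain fits of an
inverted $P(r)$ inherit the regularization bias of the inversion). The
procedure mirrors how vanadate-trapped reference states are used
experimentally:

1. `fit_reference_state()` fits all five mixture parameters (two means,
   two widths, one relative area) on the reference condition where the OF
   state dominates. The larger-area component is labeled OF; an exact tie
   is broken toward the shorter mean distance, since NBD closure shortens
   distances at NBD and intracellular pairs. Merged solutions
   ($|\mu_1 - \mu_2| < \max(\sigma_1, \sigma_2)/2$) are rejected as
   degenerate.
2. `fit_constrained_state()` freezes the OF mean and width at the
   reference values for every other condition; only the OF area and the
   second component's position and width vary, with areas summing to 1.
3. `of_fraction()` reports $100 \cdot a_{\mathrm{OF}}$, and
   `rank_conditions()` aggregates pairs into per-condition means with
   standard deviations across pairs as the dispersion, sorts ascending,
   and flags adjacent conditions whose means differ by less than the sum
   of their dispersions as ties.

Both fits co-estimate three nuisance parameters by default: the modulation
depth (the reference analysis software refits it per state; whether the
original analyses did is unknowable, and refitting makes the procedure
self-consistent), a residual background tilt $e^{-\delta k\, t}$, and an
overall scale. These absorb the small systematic distortions that
sequential background division leaves (imperfect decay constant;
renormalization of $F$ by its noisy first point), which would otherwise
leak directly into the area ratio. Component areas are computed
analytically per truncated-and-renormalized component on the fitting grid,
so the mixture weight *is* the component's area without edge leakage.
Component means are bounded by the resolvability limit
$r \le (D\, t_{\max})^{1/3}$ — a component whose dipolar period does not
fit inside the trace is indistinguishable from a modulation-depth offset
and would reappear as a spurious edge peak.

Gaussian fits use deterministic multi-start local least squares
(Levenberg-Marquardt from a coarse grid of component-mean starting
values), keeping the best non-degenerate solution.

## Synthetic data

The generators exist so that every stage is testable without instrument
data; they emulate the statistical structure of a nucleotide-condition
panel, not the physics of any specific spectrometer:

* Distance distributions are two-Gaussian IF/OF mixtures. Default pair
  presets (NBD consensus 3.5 IF / 2.4 OF nm; NBD degenerate 2.5 / 2.2;
  intracellular 4.0 / 3.2; extracellular 3.0 / 4.0 with a broad 0.55 nm
  OF width) encode the qualitative fingerprints of heterodimeric
  exporters: shortening at NBD/intracellular pairs, lengthening with a
  broad OF mode extracellularly.
* The default six-condition preset assigns true OF fractions
  5, 5, 25, 45, 55 and 90% to ADP-Mg, AMP-PNP-Mg, ATP-EDTA, ATPgS-Mg,
  ATP-Mg and ATP-Vi-Mg. Only the *ordering* (with the first two tied) is
  constrained by published rankings; the numerical values are generator
  choices spread widely enough that recovery errors cannot reorder
  adjacent conditions.
* Backgrounds default to $k = 0.25$, $d = 3$, $\lambda = 0.35$ (the middle
  of the 0.3-0.4 modulation-depth band typical of well-labeled samples).
  Noise is additive white Gaussian on the real channel;
  the signal-to-noise ratio is defined as modulation depth over noise SD,
  with default SNR 30 (typical published Q-band quality). Panels use 4 us
  traces at the 8 ns dwell so that the longest components (≈4.8 nm)
  complete a dipolar period well inside the trace.
* ATPase generators draw technical replicates
  $\mathcal{N}(\mu, (cv \cdot \mu)^2)$ around the Michaelis-Menten or
  competitive-inhibition mean ($v = v_{max} S / (K_m (1 + I/K_i) + S)$)
  and report per-point means and SDs, emulating
  three-replicate malachite-green assays. The noiseless half-inhibition
  point of the mechanistic generator is $K_i (1 + S/K_m)$, which ties the
  generator analytically to the Cheng-Prusoff relation.

All generators are deterministic under a fixed seed and record their
ground truth in trace metadata / panel manifests.

What passing recovery tests on these synthetics does **not** show:
robustness to orientation selection, nuclear modulation (ESEEM) artifacts,
phase/zero-time errors, vendor file formats, more-than-two-component
ensembles, or the temperature-dependent broadening physics of NBD
disengagement at high temperature (emulated only as broad mixtures).

## Kinetics

`fit_michaelis_menten()` and `fit_hyperbolic_inhibition()` are
Levenberg-Marquardt least-squares fits of
$f = v_{max} x / (K_m + x)$ and $f = y_0 + a \cdot IC_{50} / (IC_{50} + x)$
with standard errors from the fit covariance $s^2 (J^\top J)^{-1}$.
Fits are unweighted by default (matching common commercial-package
defaults, and it is unknown whether the original fits were weighted);
$1/\mathrm{SD}^2$ weighting is available by flag. Initialization follows
the usual heuristics ($v_{max} \leftarrow \max y$; $K_m \leftarrow$ the
concentration nearest half-saturation). A fitted $y_0 < 0$ triggers a
clip-at-zero refit with a warning, and $y_0 + a$ deviating from 100% by
more than 10 flags a normalization problem.

`cheng_prusoff_ki()` converts $IC_{50}$ to a competitive inhibition
constant, $K_i = IC_{50} / (1 + [S]/K_m)$, and propagates both input
standard errors:

$$\sigma_{K_i}^2 = \left(\frac{K_m}{K_m + [S]}\right)^2 \sigma_{IC_{50}}^2
 + \left(\frac{[S]\, IC_{50}}{(K_m + [S])^2}\right)^2 \sigma_{K_m}^2 .$$

The analytic propagation agrees with a Monte-Carlo oracle to well under 5%
whenever relative SEs are below 20%.

A numerical note on reproducing printed K~i~ tables from printed
$K_m$/$IC_{50}$ inputs: because the inputs are themselves rounded to three
significant digits, the recomputed K~i~ can differ from the printed one by
one unit in the last printed digit (this package's tests treat that as the
attainable agreement; most entries reproduce exactly).

Turnover bookkeeping is arithmetic: `molar_turnover()` converts specific
activity (nmol P~i~/min/mg) to min^-1^ via the molecular weight in kDa;
the shipped `default_mw_kda` values are *derived* from published
activity-turnover row ratios, not measured masses, and are user inputs
everywhere they are consumed.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen as the smallest sizes at which the statistical claims
are meaningful: 50 x 50 kernel-oracle grids, 100-replicate
inversion-recovery runs at SNR 30, one 6-condition x 3-pair panel (18
traces of 501 points), and 25-replicate kinetics loops. Every random draw
derives from an explicit seed, and `scripts/acceptance.R` recomputes all
headline quantities from scratch under a caller-supplied seed.

## Known limitations

* Two-component mixtures only; genuinely multimodal ensembles (e.g.
  high-temperature NBD disengagement spanning 2-8 nm) are summarized, not
  resolved.
* The background model assumes a single homogeneous spin bath; excluded-
  volume effects and multi-phase backgrounds are out of scope.
* No error bands on $P(r)$ (no validation/bootstrap machinery); the
  dispersion reported by `rank_conditions()` is across label pairs, not a
  per-fit confidence interval.
* Distance-domain two-Gaussian fitting is available only through
  `model_distribution()` comparisons, not as a first-class fitting mode;
  time-domain fitting is the supported route because it propagates the
  correct noise model.
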