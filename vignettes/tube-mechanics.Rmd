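---
title: "Pollen-tube micro-indentation: models, synthesis, and inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-tube micro-indentation: models, synthesis, and inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubecfm)
```

## The measurement and its ambiguity

A growing pollen tube is a turgid, thin-walled cylindrical cell. Indenting
its flank with a sub-micron tip (800 nm diameter, loads up to 5 µN) yields a
force–displacement record whose slope near maximum load — the *apparent
stiffness*, in N/m — conflates four things: the cell-wall Young's modulus
`E`, the wall thickness `t`, the turgor pressure `p`, and the tube diameter
`d`. `tubecfm` implements the full chain from raw recordings to cohort
statistics, plus a mechanical forward model and its inversion, which together
quantify exactly how ambiguous the modulus attribution is.

Because no raw recordings from the original assay are public, the package
ships a first-class synthetic-data generator whose defaults *are* the study
conditions: a growing group of 19 tubes / 135 indentations with pooled
loading mean/median 2.20/1.73 N/m and unloading 3.28/2.98 N/m, a non-growing
group of 11 tubes / 71 indentations with loading mean 0.69 N/m, lily tube
diameters 17.4 ± 2.5 µm, a 5 µN / 2 µm/s protocol, and an 800 nm tip.

## The synthetic-data generator

### Truth distributions

Per-tube true stiffness is lognormal. A lognormal is pinned down uniquely by
a mean and a median (`meanlog = log(median)`,
`sdlog² = 2 log(mean/median)`); `lognormal_from_mean_median()` implements
this and `truth_params()` applies it to the published group statistics. Only
means were published for the non-growing group, so its `sdlog` per phase is
reused from the growing group and `meanlog = log(mean) − sdlog²/2` — the
minimal assumption preserving the mean.

Loading/unloading pairs are coupled by a Gaussian copula with correlation
0.8 (configurable). One consequence deserves emphasis: the published
loading marginal has the *heavier* right tail (`sdlog` 0.693 vs 0.438), so
no coupling whatsoever can make `k_unload ≥ k_load` hold almost surely while
matching both marginals. The default therefore preserves the marginals
exactly — the ordering holds in distribution and for roughly 90% of tubes —
and `strict_hysteresis = TRUE` offers the alternative trade-off (clipping,
which biases the unloading mean up by about 3%).

Wall thickness is uniform on 0.1–0.3 µm and turgor uniform on 0.1–0.4 MPa by
default. Neither was printed in the main text of the study; both ranges
follow the lily pollen-tube literature and are plain function arguments, not
constants.

### Curve synthesis

`synthesize_curve()` builds one recording sample-by-sample at the protocol's
rate. The stage advances at constant speed, contacts the tube after
`contact_offset`, and the contact force follows

    F(δ) = k₀ · δ · (1 + β δ / δ_max),

a mildly nonlinear law (β = 0.1 by default; β = 0 gives exact straight lines
for closed-form tests). The recorded displacement is the series-spring sum

    z = contact_offset + δ + F / k_sensor,

so the generator embeds precisely the compliance the processing must cancel.
A weak capillary background (default 1% of the cohort's median stiffness,
i.e. two orders below the sample stiffness) and Gaussian force noise
(10 nN SD) complete the record. Unloading follows the same law with the
(generally stiffer) unloading truth from the turning point down, reaching
zero force at a residual indentation.

One calibration choice matters for everything downstream: with β = 0.1 the
ordinary-least-squares slope over the top-20%-force window is 1.18 × the
linear coefficient k₀. If the truth parameter were k₀ itself, every
recovered statistic would be ~18% above the values the truth distribution
was matched to. The generator therefore *defines* the truth as the window
slope: it divides the curve's linear coefficient by the analytic factor
`window_slope_factor(β, w)` so that a noiseless fit at the reference window
recovers `k_true` exactly. With β = 0 the factor is 1 and all series-spring
closed forms hold verbatim.

On the apical dome the contact angle between indentation direction and wall
drops below 90°, reducing the sensed reaction force; the generator
multiplies the effective stiffness by `apex_attenuation(x, R) = min(x/R, 1)²`
(0 at the pole, 1 on the shank). Group statistics are always generated on
the shank (distances ≥ 50 µm by default), matching where they were measured.

### What the generator does not emulate

Thermal drift, adhesion pull-off on retraction, viscoelastic creep at the
load plateau, oscillatory growth of the tube during the measurement,
instrument vibration, and any apex-specific wall-maturity gradient (the
built-in dome attenuation is purely geometric). Passing recovery tests
therefore demonstrates that the *processing chain is unbiased under the
stated noise model*, not that it is robust to every artifact of real
recordings.

## Curve processing

`detect_contact()` fits a baseline line to the early approach (removing the
capillary slope), initially the first 20% of it, and shrinks that window
iteratively if the detected contact would fall inside it — on soft samples
the stage travels far beyond contact, and a fixed fraction would swallow
contact data and inflate the noise estimate. Contact is the first run of 5
samples exceeding 5 baseline SDs; since a pure threshold crossing is
systematically late by ~threshold/slope, the contact displacement is refined
by a piecewise-linear hinge fit (flat baseline, then a ramp) over a window
that grows until the force is well clear of the noise. On noiseless curves
this is exact to one sample; under the default noise the error is well below
3 sample spacings even for the softest tubes. Note that the window slope is
translation-invariant, so small contact-point errors do not bias the
stiffness itself.

`cancel_sensor()` applies `δ = (z − z0) − F/k_sensor` and splits phases at
the force maximum. The capillary *slope* is deliberately not subtracted
(matching the instrument analysis, which neglects it); the resulting
relative bias is `cap · (1 + k/k_s)(1/k + 1/k_s)`, about 1–1.8% at the
study's stiffness levels against the 10 N/m default sensor. The
`(1 + k/k_s)²` scaling means samples much stiffer than the sensor would need
a stiffer sensor for the neglect to stay harmless.

`apparent_stiffness()` is the OLS slope over samples with
`F ≥ (1 − w) F_max`, separately per phase. The published analysis names "the
region of maximum load" but not a window; `w = 0.2` is the default and a
plain argument everywhere, and the β-calibration above is tied to that
reference value — processing at a different `w` changes recovered values by
`O(β · Δw)`, about 1% per 0.1 of window.

Cohort statistics are pooled over indentations (not per-tube means),
matching the "n tubes, m indentations" reporting convention. Group
comparison uses a two-sided label-permutation test on the difference of
means — the distributions are right-skewed, so no t test — with exhaustive
enumeration for small groups and an add-one-corrected random version
otherwise.

## The forward model

The shank is modelled as a linear-elastic, thin-walled circular cylinder
(radius `R = d/2`, thickness `t`, length `L = 20R`, simply supported ends)
pre-tensioned by turgor (`N_θ = pR`, `N_x = pR/2`) and loaded by a uniform
radial pressure over a circular patch of radius `a = 0.4` µm (half the tip
diameter — a finite patch both matches the tip and regularizes the
solution). Linearized Donnell shallow-shell theory gives the modal stiffness

    K(λ, κ) = D k⁴ + E t λ⁴ / (R² k⁴) + N_x λ² + N_θ κ²,   k² = λ² + κ²,

with bending rigidity `D = E t³ / 12(1 − ν²)`: bending, membrane stretching
induced by curvature, and pretension. The deflection under the load centre
is a double Fourier series (sines axially, cosines circumferentially; the
patch contributes `2 J₁(ka)/(ka)` per mode), and
`k_model = F / w(centre)`. The series is truncated adaptively — the cutoff
wavenumber grows by 1.6× until the relative change drops below 10⁻⁴ — and
convergence is reported, never silent. Working units are µm/µN/MPa, in which
stiffness lands in N/m with no conversion factors.

Choices made where the original study's finite-element setup was not
reproducible: Poisson ratio ν = 0.3 (not printed; configurable); simply
supported ends at `L = 20R` (end effects decay within the pretension/bending
boundary layer — halving or doubling `L` moves the stiffness by well under
1%); and the stiffness is the *small-deflection tangent* at the pressurized
state, whereas a 5 µN load on a soft wall may enter a geometrically
nonlinear regime the linear model cannot represent. That discrepancy risk is
confined to the inversion endpoints and flagged there.

The independent check, `shell_stiffness_fd()`, discretizes the same
equations by second-order finite differences on the developed surface
(13-point biharmonic as the squared 5-point Laplacian, periodic
circumferentially, simply supported axially) with the coupled
deflection/Airy-stress form, samples the patch on the grid, and solves the
resulting system exactly — a DFT diagonalizes the periodic direction and
each circumferential mode costs one banded sparse solve. The discretization
shares no code or convergence behaviour with the Fourier path; the two agree
to about 1% at `h = 0.1` µm in spot checks, and the suite asserts 5%
agreement across a 3×3×3 (E, t, p) grid spanning the physiological box. At `p = 0` and vanishing curvature (fixed axial span, growing
radius) both solvers approach an independent Navier plate series from above,
monotonically, as the membrane "foundation" `~Et/R²` fades.

## Inversion

`k_model` is continuous and strictly increasing in `E` (asserted numerically
by `monotonicity_scan()`), so `invert_modulus()` is a guarded Brent root
search on `log E` to a relative 10⁻³, against a frozen Fourier basis whose
truncation is converged at the *bottom* of the modulus bracket (the most
demanding point — the pretension boundary layer is sharpest there). Targets
outside the attainable range return an `"incompatible"` status with the
attainable range, not an error: at high turgor even a vanishing modulus
leaves the shell stiffer than a soft target, and that is information, not a
failure.

`compatible_set()` grids the physiological box (defaults: `t` 0.1–0.3 µm,
`p` 0.1–0.4 MPa, `d` 12.4–22.4 µm = mean ± 2 SD, 10 points per axis,
modulus bracket 1–1000 MPa) and inverts at every node. "Similar stiffness"
is operationalized as agreement within 10% of the target (no matching
tolerance was published; the value is an argument); grid nodes whose
attainable range misses the target by no more than that at a bracket edge
contribute the edge modulus. At the growing-group loading mean of 2.20 N/m
the compatible moduli span far more than an order of magnitude — the
package's restatement, with its own shell model, of the conclusion that a
20–400 MPa modulus spread reproduces the same measured stiffness. The exact
endpoints are model-dependent (an unpublished commercial FEM with unknown
nonlinearity settings stood behind the original figures), so the suite
asserts the order-of-magnitude property and reports the endpoints
informatively. Only the loading stiffness is inverted; the unloading branch
carries viscoelastic history the elastic model does not represent.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and is exactly reproducible
under it, including byte-identical pipeline output files. The test suite and
the acceptance script use the study's own cohort sizes (19/135 and 11/71),
20 replicate cohorts for the recovery checks (the replicate spread estimates
the per-cohort Monte-Carlo standard error, and recovery is asserted within
twice that), a 3×3×3 (E, t, p) grid for the cross-solver comparison, a
64-point Latin hypercube for the inversion round trip (< 1% recovery), and
the full 10³ grid for the compatible-set scan.
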