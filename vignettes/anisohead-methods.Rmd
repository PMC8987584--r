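---
title: "Methods: the brain material law, triad strain, signal rating, and injury risk functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the brain material law, triad strain, signal rating, and injury risk functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisohead)
```

`anisohead` is a desk-scale toolkit for head injury biomechanics. It
implements, at the material-point and signal level, the computational
pieces that in a full crash simulation would live inside a finite element
head model: the anisotropic visco-hyperelastic constitutive law used for
brain white matter, the marker-triad method for extracting Green strain
histories from tracked tissue markers, a corridor/cross-correlation
rating for comparing response curves, and the logistic/Weibull injury
risk functions ("crash-induced injury indices", CIIs) for cerebral
contusion and acute subdural hematoma (ASDH). No mesh, contact, or FE
solution is involved: deformation histories are prescribed, which is what
makes every component testable on a laptop.

Units everywhere: time in ms, length in mm, stress in kPa (bulk modulus
registered in GPa), strain dimensionless, strain rate in 1/s.

## The constitutive model

The brain tissue model is a fiber-reinforced Mooney–Rivlin solid with a
logarithmic volumetric term and stress-decay viscoelasticity. With
$F$ the deformation gradient, $J = \det F$, $B = FF^T$, $C = F^TF$, and
the deviatoric invariants $\bar I_1 = J^{-2/3}\,\mathrm{tr}\,B$,
$\bar I_2 = J^{-4/3}\,\tfrac12[(\mathrm{tr}B)^2 - \mathrm{tr}B^2]$, the
strain energy density is

$$W = C_1(\bar I_1 - 3) + C_2(\bar I_2 - 3) + F_\mathrm{fib}(\lambda)
      + \tfrac12 K (\ln J)^2 ,$$

where $\lambda = \sqrt{a_0 \cdot C a_0}$ is the stretch along the
reference fiber (axonal) direction $a_0$. We deliberately use the
deviatoric invariants (the `*MAT_SOFT_TISSUE` convention): with plain
invariants the reference configuration is not stress-free, while this
form is, and it preserves the small-strain shear modulus
$\mu_0 = 2(C_1 + C_2)$. The volumetric term uses
$\tfrac12 K(\ln J)^2$, which gives the hydrostatic Cauchy pressure
$K \ln J / J$ — the dimensionally consistent member of the family of
printed variants of this energy.

The fiber reinforcement is one-sided and piecewise:

$$\frac{\partial F_\mathrm{fib}}{\partial\lambda} =
\begin{cases}
0 & \lambda < 1 \\
\dfrac{C_3}{\lambda}\left[e^{C_4(\lambda-1)} - 1\right] & 1 \le \lambda \le \lambda^* \\
C_5 + C_6/\lambda & \lambda > \lambda^*
\end{cases}$$

Fibers cannot resist compression, stiffen exponentially through a toe
region, and turn linear above the critical stretch
$\lambda^* = 1.06$. $C_6$ is not a free parameter: `resolve_c6()`
derives it from continuity of the two branches at $\lambda^*$,
$C_6 = \lambda^*[(C_3/\lambda^*)(e^{C_4(\lambda^*-1)}-1) - C_5]$. The
boundary $\lambda = \lambda^*$ is assigned to the exponential branch,
which is immaterial after the continuity solve. The exponential branch
has no elementary antiderivative, so `fiber_energy()` integrates it with
adaptive quadrature; the stress path never needs it.

Stress is computed as the analytic derivative $P = \partial W/\partial F$
(nominal) and $\sigma = J^{-1} P F^T$ (Cauchy). We treat the
finite-difference derivative of $W$ as the arbiter of correctness: the
test suite checks the analytic stress against a central-difference energy
gradient (step $10^{-6}$) to $10^{-4}$ relative on batches of random
admissible deformations. This is deliberate — the printed closed-form
stress expressions for this family of models are notoriously
typo-prone, while the energy is unambiguous.

### Registered parameters

`material_registry()` ships one row per brain structure. The shear
moduli $2(C_1+C_2)$ are 2.20 kPa (gray matter and subcortical white
matter), 2.74 kPa (corpus callosum, about 25% stiffer), and 4.58 kPa
(brainstem, about 110% stiffer). $C_1$ is negative in all brain rows;
this makes convexity non-global, so protocol drivers default to moderate
amplitudes ($|\,\lambda - 1| \le 0.5$) and the constructor warns when
$2(C_1+C_2) \le 0$. The bulk moduli ($0.034$–$0.1764$ GPa) are taken
from the registry as tabulated; they are of the order implied by
near-incompressibility but are not exactly the value a Poisson ratio of
0.49999 would give from the long-term shear modulus — the two published
statements are not mutually consistent, and we follow the table. One
registry unit note: $C_5$ is stored and used in kPa; a GPa-scale $C_5$
would be six orders of magnitude stiffer than every other fiber constant
and is physically implausible for brain tissue.

`beta_s` is tabulated as a bare 0.005; we interpret it as $1/\mathrm{ms}$
(head-impact simulations run on a millisecond base), treat it as a
constant, and record the unit in the registry metadata.

### Viscoelastic update

The decay laws $\dot s_I = \dot s - \beta_s s_I$ (deviatoric part of the
Cauchy stress) and $\dot p_I = \dot p - \beta_p p_I$ (pressure) are
advanced with an exponential integrator,
$s_I^{n+1} = s_I^n e^{-\beta \Delta t} + \dot s\,(1-e^{-\beta\Delta t})/\beta$,
which is exact when the elastic stress is linear in time over the step
and reduces to $s_I = s$ identically when $\beta = 0$. Under a held
deformation the deviatoric stress therefore decays exactly as
$e^{-\beta_s t}$, reaching $e^{-1}$ of its initial value at
$t = 1/\beta_s = 200$ ms for the brain rows. $\beta_p$ defaults to 0
(only the deviatoric coefficient is tabulated for brain). Objective-rate
corrections are omitted: protocols apply finite rotations to the whole
state, and frame indifference is verified as a property
($\sigma(RF) = R\,\sigma(F)\,R^T$), but large rotations *during* decay
would require a corotational treatment this point driver does not have.
This is a documented limitation, acceptable at the material-point scale.

### Calibration

`calibrate()` recasts the published FE calibration loop at the material
point: free parameters (a subset of $C_1, C_2, C_3, C_4, \beta_s$) are
searched within user-supplied bounds to maximize the mean overall signal
rating of model responses against reference curves. The rating objective
is piecewise linear (corridor) and piecewise constant (phase), so the
optimizer is Nelder–Mead (Brent in one dimension) with bound clamping
plus a quadratic out-of-bounds penalty, not a gradient method. With the
default wide corridors the objective saturates at 1 near the optimum;
for discriminative fitting, tighten `inner_corridor`/`outer_corridor`
(the self-recovery tests use 0.002/0.05).

## Triad strain (the NDT method)

Implanted neutral density targets (NDTs) in cadaver brains are tracked
by high-speed x-ray; triangles ("triads") of markers — canonically 12
triangles over 7 markers — act as null shell elements whose in-plane
deformation measures tissue strain. For each triad, `triad_gmps()`
builds the 2D deformation gradient mapping the reference triangle edges
(first sample by default) onto the current edges, each expressed in its
own instantaneous triangle plane, forms
$E = \tfrac12(F_{2d}^T F_{2d} - I)$, and reports the larger principal
value, clipped at zero. The positive-part convention follows how maximum
principal strain is reported in the validation literature; pure
contraction reads 0. Because each triangle is measured in its own plane,
rigid motion cancels exactly (the tests require $< 10^{-12}$) and any
homogeneous affine motion gives every triad the identical closed-form
strain. Out-of-plane bending enters only through edge-length changes.
Degenerate current triangles (area below $10^{-6}$ of the reference
area) are excluded from the 12-triad arithmetic mean and counted.

`mps_rate()` differentiates the averaged history with central
differences (one-sided at the ends, local spacing on non-uniform grids)
and forms the pointwise MPS × MPSR product. `topk_peak()` implements the
top-$k$ (default 10) element-peak average used to suppress single-element
numerical artifacts. `diffuse_injury_report()` compares structure peaks
against the packaged reference levels — low risk: MPS 0.65, MPSR
61.52/s, product 22.43/s; AIS 4+: 0.74, 213/s, 107/s. These are
reference points from reconstructed cases, not a fitted risk curve (too
few diffuse-injury cases exist to fit one), so the report emits
qualitative flags with inclusive comparisons (a $10^{-9}$ relative guard
keeps a peak computed to sit exactly at a level from falling below it in
floating point).

## Signal rating

`rate_signals()` scores a model curve against a reference on a common
grid (linear resampling) with four sub-ratings combined as

$$S_\mathrm{overall} = 0.4\,S_\mathrm{corridor}
 + 0.2\,(S_\mathrm{phase} + S_\mathrm{magnitude} + S_\mathrm{slope}).$$

Corridor: per-sample score 1 inside an inner corridor (default 5% of the
reference peak), 0 outside the outer (50%), linear between, averaged
over the window. Phase: the integer-sample shift maximizing normalized
cross-correlation within ±20% of the window, scored linearly in
$|\delta|/\delta_\mathrm{max}$ and tie-broken toward zero shift.
Magnitude and slope: one minus the relative L2-norm mismatch of the
aligned signals and of their derivatives, floored at 0. "Shape" in the
published weight formula corresponds to the slope sub-rating. These
internals follow the public CORA convention but are not bit-compatible
with any specific CORA release (whose corridor constants are
configurable anyway); all constants are exposed in `rating_config()`. A
reference that is identically zero has no peak-relative corridors and
raises an error directing the user to `absolute_corridor`.

## Injury risk functions

`risk_registry()` ships the four fixed CII models: logistic
($P(t) = [1 + e^{-(\kappa t + \delta)}]^{-1}$) and Weibull
($P(t) = 1 - e^{-(t/\lambda)^\rho}$) for cerebral contusion (predictor:
coup intracranial pressure, kPa) and for ASDH (predictor: bridging-vein
stretch ratio). The Weibull scale is the predictor level at which risk
is $1 - 1/e = 63.2\%$. `invert_risk()` is closed-form in every family;
the 50%/5% contusion thresholds evaluate to 161 and 38 kPa and the ASDH
thresholds to 0.46 and 0.14, which the acceptance script recomputes at
run time. Registry models are provenance-tagged `paper-fixed` and never
overwritten by refits.

Fitting: `fit_logistic()` is unpenalized binomial ML via `glm`;
perfect separation is flagged, not silently repaired, and a constant
predictor returns $\kappa = 0$ with the intercept at the logit of
prevalence. `fit_survival()` wraps `survival::survreg` for the Weibull,
log-normal, and log-logistic families, reparameterized to
(scale, shape). Censoring scheme: an injured case is an event at its
predictor value; an uninjured case is right-censored there (it tolerated
at least that response). The underlying repeated-impact test design
would support interval censoring, but per-case histories are not
published, so right-censoring is the defensible choice and is stated
here rather than hidden.

`roc_auc()` computes AUC as Mann–Whitney pairwise concordance with ties
counted ½ (rank formula; the tests check it against an exhaustive
pairwise enumeration and against `pROC`). `classify_metrics()` applies
an inclusive probability cutoff (default 0.5) and reports the standard
confusion ratios; `fracture_check()` compares element fields against the
packaged bone failure thresholds (strain 0.0088 for skull tables, 0.0078
for facial cortical bone and nasal septum; stress 20 MPa for diploe and
spongy bone).

## The synthetic-data generators

All test inputs are generated, with ground truth, by `make_marker_field()`,
`make_case_table()`, and `make_signal_pair()`; presets live in one
versioned YAML (`inst/extdata/presets.yaml`) so tests and examples pin
identical conditions. A root seed fans out to fixed per-kind substreams,
so adding a generator never shifts existing streams and identical specs
are bit-reproducible.

* **Marker fields** move a 7-marker, ~10 mm cluster under a prescribed
  homogeneous affine history. The default is an isotropic in-plane
  stretch pulse, so every triad carries the identical closed-form strain
  $(\lambda^2-1)/2$ and the generator can return the exact truth. The
  `pmhs` preset peaks at GMPS 0.076 (the experimental mean peak over the
  seven cadaver impact cases; the reported band is ±0.02) over a 40 ms
  pulse, with 0.02 mm Gaussian marker jitter — within x-ray NDT tracking
  precision. Jitter inflates recovered peaks slightly (a
  max-of-noisy-signal bias through the thinner center triads), which is
  why the preset jitter is kept small relative to the cluster size.
  What this generator does *not* emulate: heterogeneous strain fields,
  skull-relative motion, marker dropout, or x-ray digitization outliers —
  passing tests show the triad arithmetic is right, not that real NDT
  data are this clean.
* **Case tables**: two-group presets draw predictors from
  truncated-positive normals. The ASDH preset uses the published group
  means (0.533 injured, 0.268 uninjured; n = 6/9); the published record
  gives no group SDs, so both are set once to 0.12, which yields
  overlapping groups consistent with the reported discrimination
  (AUC ≈ 0.8) and with the scatter of bridging-vein failure strains
  (0.25–0.50). The contusion preset brackets the 161 kPa threshold with
  coup-ICP-scale groups (210 ± 50 vs 110 ± 40 kPa, n = 8/5). Generative
  presets draw from a known logistic (the ASDH coefficients, n = 500)
  and a known Weibull (n = 1000, uncensored) for parameter-recovery
  tests.
* **Signal pairs**: a damped-sinusoid reference (50 Hz, 12 ms decay,
  40 ms window) with the model a scaled/shifted/noised copy.

## Numerical choices and degenerate inputs

* Finite-difference oracle: central differences, step $10^{-6}$,
  tolerance $10^{-4}$ relative; random deformations confined to
  $J \in [0.95, 1.05]$.
* Fiber-law continuity is tested to $10^{-10}$ relative at both branch
  boundaries.
* `uniaxial_stress_free()` solves the traction-free lateral stretch by
  Brent root-finding to $10^{-12}$; with registry bulk moduli, $J$ stays
  inside $[0.999, 1.001]$ under kPa-scale loading.
* Degenerate deformations ($\det F \le 0$), non-monotone time grids,
  zero references, single-class case tables, all-censored tables, and
  empty fields are hard errors naming the offence; degenerate triangles
  are excluded-and-counted rather than fatal.
* Problem sizes in the shipped tests — 100 random deformations for the
  energy oracle, 20 seeds for the stochastic strain/recovery bands,
  n = 500/1000 for the fitting recovery checks — were chosen as the
  smallest sizes at which the checked statistics are stable.

## Known limitations

* No FE solution: nothing here predicts a real head impact; the toolkit
  evaluates the constitutive/statistical machinery under prescribed
  histories.
* The point driver omits objective-rate corrections during viscous decay
  (see above).
* The rating is CORA-like, not CORAplus-identical; third-decimal
  differences from any particular release are expected.
* The published validation statistics that depend on the proprietary
  mesh and unpublished per-case reconstructions (average rating scores,
  peak-pressure traces, AUC values of the fitted models) are out of
  scope by construction; the shipped fixed risk models and thresholds
  are the published ones and are recomputed, not re-derived, here.
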