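---
title: "Stochastic parametric skeletal dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic parametric skeletal dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsdose)
```

## The problem

Bone-seeking beta emitters such as ⁸⁹Sr and ⁹⁰Sr (with its daughter ⁹⁰Y in
secular equilibrium) deposit in trabecular and cortical bone and irradiate
the active (hematopoietic) marrow. Dose reconstruction for exposed cohorts
needs *dose factors* — conversions from activity concentration in a source
tissue to dose rate in active marrow,

$$DF(AM \leftarrow s), \quad s \in \{TBV, CBV\},$$

in units of $10^{-11}$ Gy s⁻¹ per Bq g⁻¹ of parent nuclide, together with a
defensible uncertainty statement. Because epidemiological risk models treat
population-common ("shared") and individual ("unshared") uncertainty
differently, the uncertainty must be budgeted by origin: components
*introduced* by the modeling approach (shape stylization, voxelization,
restricted transport geometry, the uniform-cortical-thickness assumption)
are shared; components reflecting *inherent* individual variability
(micro/macro architecture, bone density, chemical composition, the
distribution of active marrow over skeletal sites) are unshared.

The toolkit implements the full chain: stylized segment phantoms →
segment-level dose factors via analytic surrogates → site and skeletal
averaging with active-marrow weights → shared/unshared budget → lognormal
interval statements and a two-dimensional Monte Carlo.

Electron-photon transport itself is out of scope: phantoms can be exported
(raw voxel grid + JSON sidecar) for an external transport code, and
segment-level dose factors are evaluated with the analytic surrogates that
summarize the transport results for segments with spongiosa dimensions
above two mean electron pathlengths (~0.46 cm).

## Phantom geometry

A bone segment is a stylized solid (box, elliptic cylinder, deformed
cylinder, ellipsoid, triangular pyramid or tube) with a cortical shell and a
spongiosa interior. Conventions chosen here:

* **Full-axis dimensions.** Elliptic-cylinder dims `a × b × H` and ellipsoid
  dims `l × m × n` are full axes; volumes are $\pi/4\,abH$ and
  $\pi/6\,lmn$. The deformed cylinder is the ruled solid between two
  parallel ellipses whose major axes lie in perpendicular planes; its
  volume has the closed form $\frac{\pi H}{24}(2ab + ac + db + 2dc)$
  (a cone frustum is the circular special case), and its lateral area is
  evaluated by quadrature over the ruling.
* **Shells by inward offset.** The cortical shell is the set of points
  within the surface-specific thickness of a covered outer surface; the
  spongiosa is the same shape family with axes reduced by twice the lateral
  thickness and the height trimmed at covered bases. For elliptical
  cross-sections the axis-reduction is the stylized-phantom convention (the
  exact offset curve of an ellipse is not an ellipse); it makes the
  spongiosa volume closed-form and testable. For the triangular pyramid a
  uniform inward offset is an exact similarity about the incenter with
  scale $(r-t)/r$, $r = 3V/A_{tot}$.
* **Per-face randomization.** For boxes a per-face thickness vector is
  accepted and rescaled so its mean over covered faces equals the requested
  mean thickness — the protocol used to study the
  uniform-cortical-thickness assumption.
* **Trabecular lattice.** Spongiosa microstructure is a rod lattice: three
  orthogonal families of cylindrical rods on grids with spacing
  `Tb.Sp + Tb.Th`, positions jittered with the separation SD, diameters
  lognormal with mean `Tb.Th` and the thickness SD. The original rod
  generator's placement rules are unpublished, so the lattice is calibrated
  by one uniform thickness scale, chosen by point sampling inside the
  spongiosa so the realized bone volume fraction lands inside the
  segment's admissible `bvtv_range`; an unreachable window is an explicit
  error, never a silent clamp.
* **Voxelization.** Voxel labels are assigned by the voxel-center test
  (outside / cortical / trabecular / marrow), matching the lattice-input
  convention of transport codes and making aligned grids exactly testable.
  Resolutions above `0.75 × Tb.Th` bias dose factors and trigger a warning
  (not an error); the voxelization uncertainty below that rule is 1 %.
* **Surfaces.** The spongiosa surface area `SS` is analytic whenever a
  partitioned solid is available. From a voxel grid, face counting is
  corrected by the Cauchy projection factor 2/3: raw face counting
  overestimates smooth boundaries by 3/2 (exactly, in the limit, for a
  sphere), and the corrected estimator is exact for spheres while biased
  low (up to −1/3) for axis-aligned flat faces. The analytic route is
  always preferred. For tubes, `SS` counts both the inner and outer lateral
  spongiosa boundaries.

## Individual variability sampling

Macro parameters (linear dimensions, cortical thickness) vary normally;
micro parameters (`Tb.Th`, `Tb.Sp`) vary lognormally. Macro parameters are
positively correlated (default 0.5, the inter-bone correlation of skeletal
dimensions); `Tb.Th` and `Tb.Sp` are negatively correlated (default −0.5:
separation grows as trabeculae thin; only the signs are established, so the
magnitudes are configurable). Correlation is induced by a Gaussian copula:
correlated standard normals are mapped through each marginal's quantile
function. Draws are truncated to the central 90 % confidence mass of every
varying marginal — a draw outside any marginal's central band is rejected
and redrawn. Truncation is applied *after* the correlation-inducing
transform (the alternative, truncating before correlating, would destroy
the copula's rank structure); the joint-rejection protocol attenuates both
the realized CV (by the closed-form doubly-truncated-normal factor ≈ 0.79
at 90 %) and the realized rank correlation, which is why the moment- and
correlation-recovery tests run at truncation 1.0 and only sign preservation
is asserted at 0.90.

Each realization must remain anatomically plausible: its *implied* bone
volume fraction has to stay inside the segment's `bvtv_range`, with
rejected draws resampled (cap 1000 per realization). The implied BV/TV is
the quantized three-family rod-lattice bone fraction of the realized
parameters, scaled so the population-mean parameters reproduce the
population-mean BV/TV. This surrogate captures the two real amplification
channels — the $(Tb.Th/(Tb.Th+Tb.Sp))^2$ micro dependence, amplified by the
negative correlation, and rod-count quantization driven by the 16–17 %
dimension variability — and on the reference box model (1.1 × 0.6 × 3 cm,
`Tb.Th` 0.009, `Tb.Sp` 0.09) it turns 4 % micro variation into a BV/TV CV
of about 10–11 %. The generator that produced the original phantom sets
reported roughly 16 % under the same inputs; the residual gap is attributable
to its unpublished placement internals, so the test asserts amplification
into a band rather than the exact figure.

**Sample sizing.** How many random realizations are enough is decided by
the relative variance of the variance estimator (VOV), bootstrapped from
the dose-factor realizations: the variance about the population-mean dose
factor is resampled with replacement, and the smallest `n` with
`VOV(n) < 0.15` is the minimum sample size. For lognormal dose-factor
populations with CV 0.25 this lands at or below 12–20, consistent with the
12-realizations-per-segment design used for the adult phantom sets.

## Dose-factor surrogates

For segments with all spongiosa dimensions above $2\lambda(\bar E)$, the
trabecular-source dose factor depends on the bone volume fraction only:

$$DF(AM \leftarrow TBV) = a\,(1 - e^{-b\,BV/TV}),
\qquad (a, b) = \begin{cases}(28,\ 0.897) & {}^{90}\text{Sr}+{}^{90}\text{Y}\\
(13.9,\ 1.06) & {}^{89}\text{Sr}\end{cases}$$

on BV/TV ∈ [0.01, 0.52], with the residual law
$\delta = 0.063 + 0.1\,e^{-0.373\,DF}$ (5–15 %; 7.4 % at the average
BV/TV 0.265). The mean electron pathlength in spongiosa is
$\lambda = 0.112 + 0.099\,e^{-1.526\,BV/TV}$ cm and the maximum pathlength
$5\lambda \le 1.1$ cm — the bound that justifies segment-by-segment
transport in the first place.

The cortical-source factor composes the trabecular surrogate with the
energy-deposition ratio $F_c(Ct.Th) = a_F e^{-b_F\,Ct.Th}$
((0.435, 4.98) for ⁹⁰Sr, (0.431, 6.915) for ⁸⁹Sr; Ct.Th ∈ [0.01, 0.41] cm)
and the source-volume ratio:

$$DF(AM \leftarrow CBV) = DF(AM \leftarrow TBV)\; F_c(Ct.Th)\;
\frac{V_{CBV}}{V_{TBV}},$$

with uncertainty from the quadrature of the energy-ratio residual (10 % on
average, at Ct.Th = 0.21 cm; the 4–20 % range is not published as a
function, so the average is a configurable constant) with the trabecular
residual — below 13 % over typical parameter combinations. The composition
is the canonical path; the rounded closed-form coefficients (12.2, 6)
appear only in tests, avoiding double rounding. Outside the stated fit
intervals both surrogates extrapolate with a warning rather than failing.

Small segments (spongiosa surface ≤ 6 cm²) lose crossfire from adjacent
bone; the trabecular factor is multiplied by $(SS_{ext}/SS)^{0.28}$, where
$SS_{ext}$ extends every linear dimension of the spongiosa by $2\lambda$
(applied to all dimensions — the alternative of extending only sub-1.1 cm
dimensions is not specified anywhere and the all-dimension reading is the
conservative one). The adjustment carries a 5 % uncertainty.

## Size classes and the uncertainty budget

Stylization uncertainty depends on segment size. Segments are classified by
circumscribed-box edges and spongiosa volume: TBV1 (all edges > 1.1 cm,
stylization neglected), TBV2/TBV3 (one/two edges below 1.1 cm: 15 %/13 %),
TBV4 ($V_s$ < 1.1 cm³: 7 %); and CBV1–CBV6 analogously against 2.8/1.5/1.1
cm edges and 1.6/0.2 cm³ volumes (0, 15, 10, 14, 9, 4 %). The printed
grouping rules overlap textually; they are evaluated top-down with the
volume rules dominating, so a sub-1.1 cm³ spongiosa is TBV4 even when all
edges exceed 1.1 cm. Where only a range is printed for a component, the
group-resolved value is used, and the conservative upper end is the default
for anything left unresolved.

The remaining components are: voxelization 1 %; restricted geometry 5 %
when the crossfire adjustment is in use; cortical-thickness uniformity 7 %
(cortical source; the side-to-side randomization study shows ≤ 7 % effect
at typical thicknesses); chemical composition 4 % (a dentin-like
composition shifts dose factors ≤ 3.3 %, assigned conservatively); bone
density 4 % (large trabecular) / 6 % (small trabecular) / 13 % (small
cortical) / neglected (large cortical, where the mass-ratio and
energy-deposition effects cancel); and micro/macro-architecture variability
(20 % on average, 5–60 % across segments — overridden per segment by its
own variability RMSD when realizations are available). Components combine
in quadrature within their shared/unshared class; the overall uncertainty
is the quadrature of the class totals.

## Skeletal aggregation and the two-dimensional Monte Carlo

Segment dose factors are averaged within a site with normalized
bone-marrow-mass weights, then across sites with normalized active-marrow
fractions. The adult AM distribution covers ten hematopoietic sites with
per-site CVs (average 0.39); sites missing a CV receive that average, and
sites absent from a distribution are dropped with renormalization and a
warning (a mismatch is usually an upstream labeling issue, not an error
worth aborting a run for). Site dose factors correlate across sites
(skeletal dimensions and masses co-vary; mean correlation ≈ 0.5, exposed as
`rho`), so the propagation includes cross terms:

$$\sigma_i = DF_i W_i \sqrt{\delta_{w_i}^2 + \delta_{DF_i}^2},\qquad
\delta = \frac{\sqrt{\sum_i \sigma_i^2 + \sum_{i \ne l} \rho\,
\sigma_i \sigma_l}}{\sum_i DF_i W_i}.$$

This equals the covariance-matrix quadratic form with an equicorrelated
correlation matrix (property-tested at $10^{-10}$). The shared/unshared
split runs the same machinery twice: shared components with zero weight
uncertainty (the AM-fraction variability is individual anatomy, hence
unshared), unshared components with the AM CVs included.

Interval statements use the lognormal parameterized by arithmetic mean and
CV, $\mu = \ln(m/\sqrt{cv^2+1})$, $s = \sqrt{\ln(cv^2+1)}$. The
two-dimensional Monte Carlo draws one shared multiplicative perturbation
per population realization — Normal(1, $\delta_{sh}$), truncated at zero;
the sub-zero mass is negligible for shared levels ≤ 16 %, and the normal
form is the stated approximation for the shared component — and individual
dose factors from the lognormal with mean scaled by that draw and CV
$\delta_{un}$. The product's overall CV obeys
$cv^2 = (1+\delta_{sh}^2)(1+\delta_{un}^2) - 1$, the moment-algebra oracle
used in tests.

Pooled standardized dose factors $(\overline{DF} - DF_k)/\sigma_{var}$ can
be fit by a normal or a shifted (3-parameter) lognormal with a likelihood
comparison; the lognormal is fit in both skew orientations because the
pooling transform reflects the sign of the underlying skew.

## Numerical choices and problem sizes

* Calibration of the lattice thickness scale uses 8 000 interior sample
  points and at most 30 bisection-style corrections; the quoted realized
  BV/TV is the point-sampled estimate, and the voxelized value agrees
  within the admissible window at rule-compliant resolutions.
* Moment/correlation recovery tests use 10 000 sampler draws; distribution
  checks use 3 000–4 000. Voxel grids in tests stay below ~3 M voxels
  (resolutions 0.005–0.08 cm on centimeter-scale solids). The
  two-dimensional MC defaults to 400 × 250 realizations; tests use up to
  800 × 150. These sizes were chosen so every stochastic assertion sits
  several standard errors away from its threshold.
* Degenerate inputs are first-class: zero CVs reproduce the means exactly;
  a zero BV/TV target with window `[0, 0]` yields an all-marrow spongiosa;
  zero cortical thickness leaves the spongiosa filling the solid; a
  constant dose-factor series has VOV 0 and the minimum admissible sample
  size (5).
* All randomness is seeded per call and restores the caller's RNG state;
  identical seeds give byte-identical phantoms, realizations and MC output.

## What the synthetic data do and do not show

The bundled 47-segment adult library (`synthetic_segments_adult`) is a
constructed stand-in assembled from published morphometric envelopes
(`Tb.Th` 75–290 μm, BV/TV windows, typical shape proportions); it is *not*
the anatomical segment set behind the published skeletal averages, which
was never printed. Tests built on it check machinery (classification,
budgets, aggregation bounds, the ≤ 16 % shared-component ceiling), not
anatomical accuracy; skeletal means computed from it should not be read as
reference dose factors. Likewise, passing tests demonstrate that the
surrogates, budget and propagation reproduce the published relationships —
they cannot validate the underlying transport results, which would require
re-running an electron-photon transport code on the exported phantoms.

Known limitations: plate-like trabeculae and marrow cellularity are not
modeled; bone-surface sources (relevant for short-lived emitters) are out
of scope; the rod-lattice BV/TV variability amplification is reproduced
only approximately (see above); and the deformed-cylinder spongiosa under
covered bases uses the trimmed-height approximation of the ruled solid.
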