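---
title: "Methods: film-based SBRT dosimetry audit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: film-based SBRT dosimetry audit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrtaudit)
```

## The problem

An end-to-end stereotactic body radiotherapy (SBRT) dosimetry audit
delivers a facility's clinical plan to an anthropomorphic phantom and
compares the measured dose against the treatment plan. The measurement
chain is radiochromic film (2D absolute dose and geometry) plus a point
detector (microDiamond) inside the target. `sbrtaudit` implements the
analysis side of such an audit — film calibration and quality control,
medium-dependent dose corrections, film-to-plan registration, gamma /
distance-to-agreement / point-dose metrics, tiered outcome scoring and
cohort reporting — together with a synthetic-data generator that emulates
the three audit cases, so the full chain is testable without any measured
data.

The three cases are:

* **soft tissue** — a 2.5 cm diameter cylindrical PTV in homogeneous
  plastic water; 45 Gy in 3 fractions; prescription isodose covering at
  least 95 % of the PTV.
* **spine** — a vertebral body CTV with a 2 mm margin, the PTV excluding
  the spinal-cord PRV (a wrap-around target) with an anterior esophagus
  structure; 24 Gy in 2 fractions; coverage at least 80 % (ideally 90 %);
  cord PRV 0.03 cc maximum 14 Gy, esophagus 18 Gy.
* **lung** — a 2 cm sphere in low-density lung with a 1 cm isotropic
  margin (4 cm PTV); 48 Gy in 4 fractions; coverage at least 98 %.

All cases require the maximum dose between 110 % and 140 % of
prescription and 2D conformity indices CI100 ≤ 1.2 and CI50 ≤ 5.0. All
planes in the pipeline are **single-fraction** doses: the audit measures
one delivery, so every metric is normalized to the per-fraction
prescription (15, 12 and 12 Gy respectively).

## Synthetic planned dose

No analytic form of a planned dose is prescribed by the audit protocol —
any distribution satisfying the constraint set is a valid plan. We chose
a plateau with a logistic penumbra in distance $d$ from the target
centre,

$$D(d) = \frac{A\,D_p}{1 + e^{(d - r_0)/k}},$$

with $A = 1.15$ (the dose maximum as a fraction of the per-fraction
prescription $D_p$, inside the 110–140 % window), $k$ set by the 80–20 %
penumbra width (default 3 mm, $k = w / (2\ln 4) \approx 1.08$ mm — a
typical composite SBRT penumbra), and $r_0$ placed so the prescription
isodose sits at $1.03\,r_\mathrm{PTV}$. The form is differentiable and
every isodose radius has a closed form
(`analyticIsodoseRadius()`), which the test suite uses as an independent
oracle for conformity indices and DTA expectations. One caveat is
documented here because it shapes two tests: a radial logistic has a
slope kink at $d = 0$ unless the plateau is saturated, so smoothness
arguments apply away from the exact centre.

The spine case multiplies in a rotationally symmetric trough around the
cord,

$$T(d_c) = t_{\min} + (1 - t_{\min})\,\sigma\!\left(\frac{d_c - r_c}{k_c}\right),$$

with $t_{\min} = 0.30$, $r_c = 6$ mm, $k_c = 0.8$ mm. These three values
were chosen once so that (i) the dose at the cord-PRV boundary stays
below the 14 Gy / 2 fraction limit (12.6 Gy at the boundary, 9.7 Gy at
the centre), and (ii) PTV coverage remains above 90 % (91.1 % on the
default grid). Every generated plan is verified against its own
constraint set by `checkPlanConstraints()`; an infeasible parameter
combination errors with the violated constraint named.

Grids default to 200 × 200 pixels at 0.5 mm isotropic spacing with
pixel-centre coordinates in mm and the origin at the plane centre.
Matrix rows index the anterior–posterior (y) axis, columns left–right
(x).

## Forward film model and calibration

The generator's film response is a saturating rational curve per RGB
channel,

$$\mathrm{netOD}(D) = \frac{a\,D}{1 + b\,D} \cdot
  \left(1 + c \ln \frac{t}{t_\mathrm{ref}}\right),$$

with defaults $a = (0.085, 0.055, 0.030)\,\mathrm{Gy}^{-1}$,
$b = (0.065, 0.035, 0.015)\,\mathrm{Gy}^{-1}$ (red most sensitive,
saturating first — EBT3-like), darkening coefficients
$c = (0.018, 0.015, 0.012)$ referred to $t_\mathrm{ref} = 24$ h, and
Gaussian scanner noise of 0.003 netOD. The noise default was set so the
converted per-pixel dose noise at 12 Gy is about 0.6 %, comfortably
inside the ± 2.5 % ($k=1$) film uncertainty the audit quotes; the tests
assert that bound rather than the design value.

Calibration fits dose(netOD) per channel from a 12-level dataset
(0–20 Gy, including a zero-dose film). The response form is a
**pluggable registry** (`registerCalibrationForm()`):

* `"rational"` (default): $D = x / (a - b x)$, the exact inverse family
  of the forward model, fitted by exact linear least squares (the
  relation $x = aD - b\,D x$ is linear in $a, b$). With this form the
  generator's parameters are recovered to machine precision and the
  end-to-end film chain round-trips within 0.5 % at zero noise for any
  delay in the validated range — properties the module asserts.
* `"power"`: $D = p_1 x + p_2 x^{p_3}$, the familiar radiochromic
  calibration polynomial, fitted by relative least squares. Against
  saturating rational data its best fit leaves 1–2.3 % relative residual
  (worst in the red channel), which is why it is the alternative, not
  the default: with it as default the 0.5 % round-trip guarantee would
  not hold.

Monotonicity of the fitted response is verified on a dense netOD grid,
and a maximum level residual above 3 % raises a calibration-quality
error. Channel combination for conversion is an inverse-variance
weighted average using each channel's local response slope (scanner
noise is channel-constant in netOD, so dose variance scales with the
squared slope); a red-only mode is available.

The darkening correction divides by $1 + c\ln(t/t_\mathrm{ref})$;
generator and corrector share the form, so the correction is exact by
construction and the form itself is replaceable. Delays outside
$[t_\mathrm{ref}/4,\,10\,t_\mathrm{ref}]$ are corrected but flagged with
a warning, not an error.

**Check-film QC.** Two films irradiated to chamber-verified doses
(10 and 15 Gy) in the same scan session anchor the calibration by a
single through-origin least-squares factor. The 5 % control limit is
*inclusive* (a factor exactly at 0.95 or 1.05 passes) because the limit
names the boundary of acceptability; conversion refuses to run outside
the limit ("rescan required"), mirroring the operational rule that
rescanning resolves scanner drift. A through-origin residual above 2 %
flags the pair itself as inconsistent.

## Registration

The audit's manual film-to-CT alignment is replaced by landmark least
squares: fiducial cut-out positions on the film paired with their
plan-frame positions, solved as a 2D orthogonal Procrustes problem
(SVD of the centred cross-covariance, reflection excluded). The
dual-observer check is modelled as two independently entered landmark
sets; agreement is evaluated at the four film corners — the worst case
for a rotation difference — with `extentMm` defined as the
centre-to-corner distance, and requires a maximum discrepancy strictly
below 0.5 mm. Resampling onto the plan grid uses bilinear interpolation
(the single interpolation rule shared by the generator, the resampler
and the gamma engine); pixels off the film are masked invalid and a
fit covering less than half the plan grid is rejected.

## Medium corrections

Film in bone or lung media does not report the plan algorithm's dose
quantity directly; multiplicative $k_\mathrm{med}$ factors, specific to
(material, reporting mode), convert the reading. The shipped table is an
explicit placeholder (all factors 1.0) because validated values are
measurement-derived and must be supplied by the user; the synthetic
tests embed known non-unity factors through the reciprocal map so the
correction arithmetic is fully exercised regardless. The water-to-tissue
factor 0.992 applies to plastic-water film regions of the soft-tissue
and spine cases only — the lung film plane receives none, following the
audit's stated practice. Dose-to-water-in-medium
($D_{w,m}$) reporting is deliberately unsupported. Point-detector
corrections (cross-calibration, orientation, material) are scalar and
combine multiplicatively; orientation corrections are not modelled for
the cord trough point, where open-field characterizations do not apply.

## Gamma, DTA and dose differences

**Gamma.** Global 2D gamma at 5 % / 2 mm with a 10 % low-dose threshold,
all relative to the per-fraction prescription. Roles follow the audit
convention: gamma is evaluated at *measured* pixels searching the
*planned* distribution, and the threshold applies to the measured dose —
the audit scores the measurement. The planned distribution is bilinearly
sub-sampled; the effective pitch is `spacing / ceiling(spacing /
subsample)` so measured pixel centres lie on the fine lattice (never
coarser than the requested 0.2 mm), and the search disc is defined on
the integer lattice (radius `floor(R/pitch)` nodes) so the candidate set
is implementation-independent. The search radius is 3 × DTA; boundary
pixels whose disc exits the planned grid are marked invalid rather than
failed. The production engine (C++) visits candidates in order of
increasing distance with an early exit; `gammaOracle()` is an
independent pure-R implementation that sweeps the same lattice
exhaustively (separable 1D interpolation, unsorted sweep) and exists
only to bound the engine's per-pixel error in tests — the two agree to
machine precision, well inside the 0.02 test bound. Gamma is not
symmetric under swapping roles, and no symmetry is assumed.

**DTA.** Isodose crossings at 70 % of the per-fraction prescription are
found by linear interpolation along dense (spacing/10) profile samples
and paired planned-to-measured by proximity. The sign convention is
planned − measured, matching the dose-difference convention, so an
injected +s mm shift reads as −s mm DTA. Per case: soft tissue scores
the mean over the L–R and A–P profiles through the PTV centre; spine
scores the maximum |DTA| over A–P profiles sampled across the PTV/cord
interface plus the mean L–R DTA at the same interface (crossings
restricted to the trough window so the outer field edge cannot
contaminate the interface metric); lung scores A–P only, since the film
pin obstructs the L–R 70 % isodose.

**Dose differences.** Local = (planned − measured)/measured; global =
(planned − measured)/prescription-per-fraction; both in percent. Region
statistics average over the in-plane PTV (the area bound by the
prescription isodose of the planned plane), a 6 mm diameter cord ROI, or
an out-of-field band. Conformity indices are 2D surrogates: the ratio of
the area inside the 100 % (50 %) isodose to the PTV area; the volumetric
definitions cannot be computed from one film plane, and the area form
reproduces the analytic $(r/r_\mathrm{PTV})^2$ of the dose model on the
default grids to about 1 %.

## Scoring and cohorts

The gamma pass rate sets the base outcome — optimal at ≥ 95 %, action at
90–95 %, out of tolerance below 90 % (inclusive lower bounds) — and the
DTA and point-dose upper limits override to out-of-tolerance when
breached: > 3.0 mm (soft tissue, lung) or > 2.0 mm (spine interface) on
the absolute displacement, and > 8 % absolute point-dose difference.
All upper limits are strict: a value exactly at the limit passes.

Failure-mode tagging operationalizes the audit's human post-hoc
analysis as ordered rules with config-exposed thresholds: mean |DTA| (or
recovered shift) ≥ 2 mm → IGRT mismatch; a rotation above 1° → other
shift/misalignment; mean in-PTV global difference beyond ±2.5 % →
in-volume dose difference (low when the plan exceeds the measurement,
high when the measurement exceeds the plan); measured out-of-field dose
more than 5 % of prescription above the plan → out-of-field (high);
otherwise unclassified. When a synthetic plan carries injected ground
truth, agreement is recorded.

Cohort percentages are rounded half away from zero to one decimal. Two
printed values in the source tabulations (21.6 % for 13/60 and 41.6 %
for 25/60) are not reproducible under any half-rounding rule (both give
x.7); the package keeps round-half-up and reports 21.7 / 41.7, and the
tests assert the arithmetic values. The two-sample comparison is the
pooled-variance t-test (`stats::t.test(var.equal = TRUE)`), two-sided,
with significance strictly below p = 0.05; degenerate zero-variance
series return p = 1 when the means agree and are flagged otherwise.

## The end-to-end synthetic audit

`runAudit()` chains everything: phantom → planned dose → perturbed
delivery (shift/rotation by bilinear resampling, global / in-PTV /
out-of-field scaling, seeded noise) → reciprocal-k_med medium embedding
→ film placement on the scanner (a small seeded rigid transform) →
forward film model with darkening and scanner noise → calibration,
check films, QC and conversion → dual-observer landmark registration →
medium correction → metrics → outcome and failure mode. Every
stochastic component draws from a counter-derived sub-seed of one
integer master seed, so runs are bit-reproducible, and the perturbation
ground truth travels with the result.

What the generator emulates: realistic per-case geometry and
prescriptions, a monotone film response with time darkening and scanner
noise, film placement and landmark-entry uncertainty, scanner response
drift caught by the check-film QC, and parameterized delivery errors.
What it does not emulate: TPS dose-calculation errors in heterogeneous
media, scanner lateral-response artefacts, film batch variation,
non-rigid film deformation, intra-fraction motion (excluded by the audit
design) and 3D effects off the film plane. Passing synthetic tests
therefore demonstrates the *analysis* chain is correct and
self-consistent at the audit's stated uncertainties; it says nothing
about any facility's delivery accuracy.

## Numerical choices and problem sizes

Default grids are 200 × 200 at 0.5 mm (audits) and 51–101 pixel planes
at 0.5–1 mm in tests; the gamma oracle is restricted to ≤ 101 × 101.
Cohort-scale checks use 60–100 unperturbed plans and 30–45
fault-injected plans — large enough for the all-optimal and ≥ 90 %
recovery assertions to be meaningful, small enough to keep the whole
suite inside a few minutes on one core. Isodose crossings interpolate
linearly between samples at a tenth of the pixel pitch; ties in crossing
pairing resolve by smallest distance first. Doses are clamped
non-negative after noise; out-of-range pixels after conversion are
masked NA and excluded from metrics.

## Known limitations

* The k_med table ships as placeholders; results in bone/lung regions
  are only as good as the user-supplied factors.
* Conformity indices and OAR maxima are 2D film-plane surrogates of
  volumetric quantities.
* The DTA sign convention (planned − measured) is config-free; cohorts
  imported from systems with the opposite convention must be negated
  upstream.
* DICOM RT Dose import is not provided; planned doses enter through the
  plain-text grid format.
* The failure-mode rules are deliberately simple, ordered heuristics;
  they recover cleanly injected single-mode errors but are not a
  substitute for human review of mixed-mode failures.
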