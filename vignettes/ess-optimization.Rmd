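---
title: "Field output factors and effective spot size tuning for small MLC fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field output factors and effective spot size tuning for small MLC fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallfof)
```

## Scope and model

This package analyzes output factors of small symmetric rectangular
fields shaped by a multileaf collimator (MLC), with the jaws parked at a
fixed larger opening (4.4 × 4.4 cm² against a 4 cm maximum MLC field) so
that jaw scatter to the monitor chamber is constant and the MLC is the
collimating device.  Fields are named Y × X, where X is the leaf-motion
(leaf-end) direction and Y the leaf-side direction; the reference design
is the 7 × 7 grid of sides {0.5, 1, 1.5, 2, 2.5, 3, 4} cm — 49 settings —
measured at isocenter, 10 cm depth.

### Output factors

The field output factor of a test field relative to the 4 × 4 cm²
machine-specific reference (msr) field follows the TRS-483
intermediate-field formalism

$$\Omega \;=\; \frac{M_{clin}}{M_{msr}}\; k,$$

where $M$ are mean detector readings and $k$ is the detector's output
correction factor at the *equivalent square field size* of the test
field.  `compute_fof()` enforces the validity band $k \in [0.95, 1.05]$;
`filter_ocf_validity()` discards tabulated factors more than 5% from
unity, and `ocf_lookup()` interpolates the remaining table
piecewise-linearly.  Linear interpolation is a package convention chosen
for exact reproducibility; published OCF tables are dense and smooth
enough over this range that the scheme is not a meaningful error source.
Queries below a detector's smallest tabulated side are a hard error: the
detector validity limits (microDiamond to 0.4 cm; unshielded diode to
0.5–0.6 cm; small ion chamber to 0.8–1 cm, per beam energy) are enforced
as table-domain limits, never clamped.

### Equivalent square field of elongated fields

The TRS-483 equivalent-area rule $\sqrt{AB}$ only holds for aspect ratios
$A/B \in (0.7, 1.4)$ (an open interval, enforced by
`area_equivalent_square()`).  For elongated fields the package uses the
empirical modification of the Sterling formula

$$ESF \;=\; \frac{2\,\min(A,B)^{a}\,\max(A,B)^{2-a}}{A+B},
\qquad a = 1.12,$$

which is symmetric in its arguments, equals the side for squares at any
exponent, and reduces exactly to Sterling's $2AB/(A+B)$ at $a = 1$.  The
exponent default is 1.12 (empirically determined for small elongated MLC
fields) and is overridable per call.  Two properties deserve care, since
they are weaker than one might assume:

* boundedness ($\min \le ESF \le \max$) holds at $a = 1.12$ for all
  realistic aspect ratios, but **not** for every exponent in $[1, 2]$ —
  at $a = 2$, $ESF = 2\min^2/(A+B) < \min$ whenever the field is
  elongated;
* $ESF$ increases with either side only up to aspect ratio
  $(2-a)/(a-1) \approx 7.3$; beyond that the long side ceases to add
  equivalent size (the short side dominates the output), and $ESF$
  saturates and slowly decays.  The 0.5 × 4 cm² field sits essentially at
  this turnover.

The sides $A, B$ should be the *dosimetric* (FWHM) field dimensions when
measured profiles are available; callers record which was used through
`dosimetric_size()`'s `source` field.  All field sides are
isocenter-plane centimeters; profile positions are millimeters (the
conversion factor is exactly 10).  Sides below 0.01 cm are rejected
rather than extrapolated — they lie below any OCF table domain.

### Profile metrics

`beam_center()`, `fwhm()` and `penumbra_20_80()` use linear interpolation
between samples, normalize to the profile maximum (for small fields this
is indistinguishable from the central-axis value, and matches the
practice of positioning the detector at the profile maximum), and locate
level crossings moving outward from the beam center.  Non-monotone
shoulders use the crossing nearest the field edge, with a warning; no
smoothing is ever applied implicitly (`median_filter_profile()` exists
for noisy measured data, and logs itself).  For a Gaussian-blurred edge
the 20–80% penumbra equals $[z(0.8)-z(0.2)]\,\sigma = 1.68324\,\sigma$,
which the suite verifies to within 1% at 0.05 mm sampling.

## The synthetic forward engine

Real commissioning compares measurements against a commercial dose
engine.  To make every stage of the workflow exercisable without one,
`central_dose()` implements a closed-form source-occlusion model: the
rectangular aperture is convolved with the projected Gaussian focal spot
and a multi-Gaussian lateral scatter kernel, giving

$$D \;=\; \sum_k w_k\,
  \mathrm{erf}\!\left(\frac{X}{2\sqrt2\,s_{x,k}}\right)
  \mathrm{erf}\!\left(\frac{Y}{2\sqrt2\,s_{y,k}}\right),
\qquad s_k = \sqrt{(ESS\cdot m)^2 + \sigma_k^2}.$$

Choices behind this engine, and what they mean for interpreting results:

* **ESS interpretation.**  "Width of the Gaussian" is ambiguous; the
  package defaults to $\sigma$ and offers a FWHM mode
  ($\sigma = \mathrm{width}/2.3548$), recording the choice in outputs.
* **Projection.**  The focal-spot blur is magnified to the isocenter
  plane by $m = (SAD - d_c)/d_c$; the defaults (SAD 1000 mm, collimator
  at 500 mm) give $m = 1$, so ESS values act at isocenter scale.
* **Default kernel.**  Two components, weights (0.88, 0.12), isotropic
  sigmas 1.5 mm and 18 mm.  These were chosen once so that the synthetic
  6X grid is qualitatively like measured HD-MLC data (output factors of
  0.6–0.8 at 0.5 cm sides) and were not revisited.  No quantitative
  fidelity to any commercial engine is claimed: the engine's contract is
  *parameter recovery* (an ESS pair used to generate data must be
  recoverable from that data), verified against brute-force 2-D
  quadrature to a relative 10⁻³.
* **Noise.**  Synthetic "measurements" multiply each non-msr cell by
  $1+\epsilon$, $\epsilon \sim N(0, sd)$ with $sd = 1.8\%$ for fields
  whose smallest side is below 1 cm and $0.9\%$ otherwise — the combined
  type A+B uncertainties of diamond-detector small-field measurements.
  Draws are scoped to one named integer seed; global random state is
  never touched.
* **What is deliberately omitted.**  Rounded leaf ends, tongue-and-groove
  and interleaf leakage, off-axis softening, depth dependence, and the
  1 mm dose-grid quantization of clinical systems (profiles default to
  0.1 mm sampling precisely because the synthetic engine is not bound by
  a TPS grid).  Passing tests therefore demonstrate the *procedure* is
  sound, not that any specific clinical engine is accurately emulated.

One subtlety: because output factors are ratios to the msr field, a
sharper spot does not majorize a blurrier one on *every* cell — for
near-reference cells the normalization direction reverses at the
$10^{-4}$ level.  The over/under-estimation law (spot too small ⇒
calculated dose too high) holds cleanly for every small-field cell.

## The sequential ESS optimization

The X spot component is isolated by the 4 × 0.5 cm² field (short side
along X; the 4 cm Y side saturates the Y blur) and vice versa.  The
procedure (`optimize_sequential()`):

1. start from the vendor-style pair (ESSx 0.5, ESSy 0.7) mm;
2. sweep ESSx over the candidate grid
   {0, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.5} mm and pick the value
   minimizing the *absolute* calc−meas FOF difference of the
   4 × 0.5 cm² field;
3. fix that value and sweep ESSy against the 0.5 × 4 cm² field.

"Smallest difference" is read as smallest absolute difference; whether a
signed zero-crossing reading was ever intended is undocumented, so
`sign_diagnosis()` exposes the crossing explicitly.  Candidates whose
objective lies within `tie_tolerance_pct` (default 0.02 percentage
points) of the minimum are reported as an interval: a clinical beam model
can quantize its spot internally and produce bit-identical output at
adjacent candidates, and a reimplementation cannot reproduce that
quantization, so ties are detected in objective space rather than by
output identity.  The exact tolerance under which two adjacent candidates
should be called "identical" is not externally specified; 0.02 points is
deliberately below any dosimetrically meaningful difference.
`optimize_joint()` cross-checks the sequential result by exhaustive
search over the candidate product grid (`max_abs` or `sum_abs`
scalarization), and on noiseless synthetic data the two agree.

The engine interface is abstract: the optimizer accepts the synthetic
forward model, a directory of precomputed per-ESS grids as exported from
a real planning system, or difference tables directly
(`table_diff_engine()`), which is how the packaged reference sweep
tables are replayed.  Replaying those tables lands both axes on 0.7 mm
(tied with 0.8 mm) with residuals of 0.01–0.02%.

### Identifiability under measurement noise

With the default kernel, one 0.1 mm candidate step changes the
extreme-field output factor by roughly 0.7–1.5%, while the small-field
measurement SD is 1.8%.  The one-step recovery probability per axis is
therefore about 0.7, and jointly about 0.5 — noiseless recovery is exact
(81/81 truth pairs), but a single noisy measurement of each extreme field
cannot pin the spot to one candidate step.  This is a genuine
signal-to-noise limit of the procedure at this grid resolution, not an
implementation artifact; it is the same limit that makes interval-valued
optima (0.7–0.8 mm) the honest way to report results on real data.
Averaging repeated measurements of the two extreme fields (the SD scales
as $1/\sqrt{n}$) is the practical remedy.

## Packaged reference data

`reference_fof_grid()`, `reference_diff_grid()` and
`reference_ess_sweeps()` carry transcriptions of a published HD-MLC
commissioning dataset (measured 6X/6FFF output-factor grids, the
difference grids at the optimized spot size, and the three 6X sweep
tables); `emit_fixtures()` writes them in the package's CSV dialects, and
the same files ship under `inst/extdata/`.  The sweep tables are sparse —
only the combinations actually evaluated carry values — and are stored
exactly as printed, rows indexed by ESSy and columns by ESSx.  The percent
differences in these tables are used as printed; whether they are relative
or absolute-in-points is not stated in the source (the two coincide near
output factor 1 but differ near 0.64), so `difference_grid()` makes the
convention explicit for grids computed in-package and summaries record it.

```{r}
summarize_diff(reference_diff_grid("6X"))
summarize_diff(reference_diff_grid("6FFF"), exclude_msr = TRUE)
```

The msr cell is identically zero in any difference grid, and is included
in summaries by default; `exclude_msr` exists because a published range
minimum of 0.1% for the 6FFF grid is only reproducible with the
trivially-zero reference cell excluded.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 1000 random side pairs for
the equivalent-square properties; 20 random parameter sets for the
quadrature cross-check of `central_dose()` (midpoint rule at 0.05 mm over
the aperture); 50 random truths each for noiseless and noisy parameter
recovery; 600 Monte-Carlo replicates for the noise-calibration check.
These sizes make every stochastic check stable under its fixed seed while
keeping a full run in tens of seconds.  Report rounding is half-away-from-
zero to one decimal in percent; all internal values keep full precision.
Grid CSV round-trips are bit-exact.

## Known limitations

* The forward engine is a deliberately minimal stand-in; its kernel is
  not fitted to any clinical engine (though `fit_kernel()` can fit one to
  a measured grid).
* Only on-axis, symmetric, collimator-0° fields are modelled; spot
  rotation with the collimator is not represented.
* The optimizer's candidate grid is discrete by design (mirroring how a
  planning system is configured); no continuous refinement is attempted.
* Detector response physics (volume averaging aside) is out of scope: OCF
  tables are inputs, never computed.
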