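---
title: "Film dosimetry QA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Film dosimetry QA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radfilm)
```

This vignette documents the scientific model behind each stage of the
pipeline, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real film.

## Scan processing

A radiochromic film is scanned four times in transmission mode, rotating
the film between scans (original landscape, vertical flip, horizontal flip,
and both flips). Rotation decorrelates direction-dependent scanner response
and film grain, so the average of the four registered scans has lower noise
and less directional bias than any single scan. Because each flip is known
exactly from its tag, the default registration is the exact inverse flip;
an optional integer-pixel cross-correlation refinement (±5 px search,
`average_scans(register = TRUE)`) absorbs mechanically imperfect
repositioning between scans. Guide strips on the scanner bed keep that
residual drift small in practice, which is why sub-pixel registration is
not implemented.

Net optical density per channel is the universal radiochromic convention

$$\mathrm{netOD} = \log_{10}\frac{PV_\mathrm{unexposed}}{PV_\mathrm{exposed}}$$

computed from averaged 16-bit pixel values. Pixel values are floored at 1
before the ratio so dead pixels cannot produce infinities; floored pixels
are counted in the result (`n_floored`). The unexposed reference can be a
companion unexposed film or an unirradiated margin of the exposed film
(`background =`); neither is canonical, both are supported, and for uniform
scanner response they differ only by the margin's local response. 8-bit
scans are upscaled by exactly 257 so that white (255) maps to white
(65535). No scanner uniformity correction map is applied; the lateral
response of the scanner is instead treated as an uncertainty and is
available in the synthetic model (below).

## Calibration

The calibration film carries a 3 × 3 grid of square blocks at nine dose
levels, 3–21 Gy. The block-interior mean netOD is extracted per block after
shrinking each block by `margin_fraction` (default 0.25) on every side, so
penumbra and registration slop at block borders cannot contaminate the
mean. The default geometry (40 mm blocks at 60 mm pitch) fills a
20.3 × 25.4 cm sheet; the geometry is fully configurable because grid
dimensions are a clinic-protocol choice, not a constant of nature.

Nine (netOD, dose) pairs per channel are fitted with an unweighted
ordinary-least-squares cubic, dose as a function of netOD — the direction
needed to convert measured films to dose. The constant term is left free
rather than forced through the origin: a forced zero would propagate any
baseline mismatch between the calibration film's unexposed reference and
the QA film's into every converted dose. Monotonicity of the fitted cubic
is checked numerically at 1000 points across the fitted netOD span; a
non-monotone fit is flagged with a warning but returned, since the
monotone-span portion may still be usable.

The red channel response is steepest below roughly 10 Gy and the green
channel above, so `select_channel()` returns red when the plan maximum is
≤ 10 Gy and green otherwise; blue is carried through for completeness but
never auto-selected. Curves are compared by sampling both cubics at 200
uniform netOD values over their common span and computing the Pearson
correlation; the result is insensitive to the sampling density beyond a few
dozen points because both curves are smooth cubics.

## Dose conversion

`apply_calibration()` evaluates the fitted cubic per pixel. netOD above the
largest fitted calibration point is clamped to that point and the pixel
counted as saturated, because cubic extrapolation diverges rapidly outside
the fitted span; doses that evaluate negative below the span are floored at
0 Gy and counted separately. Both counts are surfaced by
`saturation_report()` so a QA report can state how much of the film was
outside the calibrated range.

## Dose planes, registration and I/O

Planes use pixel-center coordinates, x to the right, y up, isocenter at
(0, 0), row 1 at the top — the anterior-view coronal convention. The
plain-text plane dialect (unit, spacing, origin headers plus rows of
values) keeps every test fixture human-readable and round-trips to 1e-6 Gy;
a flat binary container with a JSON sidecar round-trips exactly. DICOM RT
Dose files are read with a minimal little-endian parser (explicit or
implicit VR) that applies `DoseGridScaling`; in-plane geometry comes from
`PixelSpacing`, while patient-coordinate placement is out of scope for
planar QA — planes are centered on the isocenter unless an origin is given.

Registration is deliberately manual: the film's laser-marked crosshair, a
rotation and an optional left-right flip define a rigid transform, and the
film is resampled bilinearly onto the plan grid. Automatic dose-based
registration is intentionally absent — it would optimize away exactly the
spatial errors gamma analysis exists to detect. Bilinear interpolation is
used for all resampling (it reproduces affine dose ramps exactly and
introduces no overshoot); nearest-neighbor is available behind the method
argument.

## Gamma analysis

For each reference (plan) pixel $m$ above the dose threshold,

$$\gamma(m) = \min_{c}\sqrt{\frac{\lVert r_c - r_m\rVert^2}{\Delta d^2}
  + \frac{\left(D_e(c) - D_r(m)\right)^2}{\Delta D^2}},$$

with $\Delta d$ the distance criterion and $\Delta D$ the dose criterion as
a percentage of the **reference maximum** (global normalization). The
choices that need stating:

* **Reference vs evaluated.** The plan is the reference: it defines the
  evaluation points, the threshold and $D_{global}$. This keeps the number
  of evaluated points independent of film noise.
* **Threshold.** Default 10 % of the reference maximum; only reference
  pixels above it are evaluated.
* **Search.** Candidates lie on a subgrid of step
  `min(dta/10, evaluated spacing)` within radius `gamma_cap × dta`;
  evaluated dose is interpolated bilinearly. γ is capped at 2 — values
  above the cap cannot change pass/fail. Candidates are visited in order of
  increasing distance, and the search stops when the pure distance term
  exceeds every pixel's current minimum; this pruning changes nothing about
  the result and is verified against `brute_force_gamma()`, which
  enumerates every candidate with no pruning and its own interpolation
  code.
* **Pass rule.** γ ≤ 1 passes, boundary inclusive, with a 1e-9 numerical
  slack: a plane that is uniformly hot by exactly the dose criterion has
  γ = 1 up to floating-point rounding (≈ 2e-15) and must pass.
* **Relative mode.** The evaluated plane is rescaled by
  `max(reference)/max(evaluated)` before evaluation. The maximum is taken
  as the mean of the top 0.5 % of pixels by default because the exact
  maximum of a noisy film is an extreme order statistic; the exact maximum
  is available via `exact_max = TRUE`. Note that any max-type estimate of a
  noisy plateau is biased high by a few tenths of the noise sigma times the
  selection intensity, so with pixel noise the relative mode carries a
  small systematic scaling error — an inherent property of normalizing to a
  measured maximum, visible as lower relative-mode pass rates in gradient
  regions.
* **Discretization.** Near a dose crossing, the discrete candidate search
  quantizes γ by roughly (dose gradient × step / ΔD), so γ converges only
  linearly in the candidate step, and penumbra-scale gradients need
  impractically fine steps for per-pixel convergence much below ~0.1. Pass
  rates are far more stable than worst-pixel γ values (the tests assert
  both the monotone shrinkage of refinement differences and pass-rate
  stability). The implementation and the oracle therefore always use the
  same candidate step when compared. For the same reason `pass_table()`
  evaluates all criteria with one shared step, which also makes criteria
  dominance (looser criteria ⇒ pointwise smaller γ) exact rather than
  approximate.

## Profile analysis

Profiles are bilinear samples along the central axes at native spacing,
normalized to the mean over the central 5 mm when a dimensionless
comparison is wanted. Percent dose differences use

$$\mathrm{diff}_i = 100\,\frac{D_{i,\mathrm{meas}}\cdot SF -
  D_{i,\mathrm{ref}}}{D_{global}},$$

with $SF = \max(\mathrm{ref})/\max(\mathrm{meas})$ in `relative_sf` mode
(same robust-max policy as gamma) and $SF = 1$ in absolute mode;
$D_{global}$ is the reference-profile maximum. Summary statistics are the
mean and maximum of the absolute per-point differences — the sign
convention for "mean difference" is genuinely ambiguous in QA practice, so
the signed vector is retained in the result for reports that want it.
Field width (FWHM) is the distance between 50 % crossings and penumbra the
20–80 % falloff distance per edge, both relative to the central-axis value
(not the profile maximum), which keeps small fields — where the central
5 mm already samples falloff — measured correctly.

## Synthetic data: what it emulates, and what it does not

Open fields use a separable error-function model,
$D(x,y) = D_{max}\,E(x; w_x)\,E(y; w_y)$ with
$E(t; w) = \tfrac12[\mathrm{erf}((t+w/2)/\sigma\sqrt2) -
\mathrm{erf}((t-w/2)/\sigma\sqrt2)]$ — a boxcar convolved with a Gaussian
of width σ (default 1.5 mm, a typical linac penumbra at depth). For fields
much wider than σ the central value reaches $D_{max}$; for the smallest
clinical fields (0.83 cm) it correctly does not, reproducing small-field
output loss in shape (not in absolute magnitude — no beam model is
implied). The default plane spacing, 0.39 mm, matches a 512-pixel planar
TPS export of a mid-size field.

The film model maps dose to netOD per channel by numerically inverting a
monotone cubic — the same functional family the calibration module fits, so
a noiseless loop through the whole pipeline must recover the source dose
almost exactly; the tests require 0.1 % of $D_{max}$ and achieve ~0.04 %,
the residual being 16-bit quantization. The inversion uses a 4096-knot
lookup for the initial guess plus Newton iterations to machine precision.
Default coefficients give netOD ≈ 0.45 at 10 Gy (red) and ≈ 0.55 at 21 Gy
(green) — plausible magnitudes, explicitly synthetic, never presented as a
measured film response. Scanner noise is multiplicative Gaussian on pixel
values (default 1 % where enabled), drawn independently for each of the
four orientation scans. The lateral-response artifact is modeled as a
parabolic multiplicative netOD bias peaking at the left/right film edges
(opt-in, default amplitude 0), the dominant flatbed uncertainty for films
that span the full scan width.

What passing synthetic tests shows: the processing chain is
self-consistent, the gamma implementation matches an exhaustive oracle, the
statistics follow their formulas, and the pipeline's sensitivity to
injected errors (scaling, translation, hotspots) behaves as gamma theory
predicts. What it does not show: real film-lot variation, scanner warm-up
drift, developer-time kinetics, triple-channel corrections, or the actual
dose response of any physical film — those require measured calibrations.

## Problem sizes and determinism

Every generator is a deterministic function of its arguments and seed. The
test suite and the acceptance script use planes between 20 × 20 and
221 × 221 pixels and 20–50 seeded random fields per property; these sizes
were chosen so that the exhaustive gamma oracle (the slow path,
O(points × candidates)) completes in seconds while still exercising
penumbra, plateau and threshold behavior. Verdict tolerance for the QA
report defaults to a 90 % pass rate, the conventional internal action
level; clinical criteria default to 3%/3 mm for conventional plans and
3%/1 mm for SBRT.

## Known limitations

* Single-channel dosimetry only; no triple-channel correction model.
* Rigid registration only; no deformable registration (intentional for QA).
* The DICOM reader targets planar RT Dose exports; it is not a general
  DICOM implementation (no sequences-within-sequences, big-endian, or
  compressed transfer syntaxes).
* Relative-mode normalization to a measured maximum is biased under noise,
  as discussed above; absolute mode is the default everywhere.
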