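---
title: "bonemech: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bonemech: models, synthetic worlds and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bonemech` re-implements, as one tested pipeline, the computational chain
of a multi-modal murine bone-quality study: micro-CT morphometry of the
femur, three-point bending to failure, Oliver–Pharr nanoindentation of the
tibial cortex, Raman compositional metrics, and the statistical layer that
ties them together across a diabetic (TallyHO) and a control (C57Bl/6J)
genotype. This vignette is the package's own account of the science: the
models and their assumptions, the synthetic world the generators state,
every numerical choice that was genuinely open, and what a green test does
and does not establish. No empirical claim is made here that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Cross-sectional morphometry

A specimen is a 3-D voxel grid (isotropic voxel size, default 6 µm) with
an optional affine grayscale → mg HA/cm³ calibration. Analysis follows the
standard diaphyseal workflow:

1. **Segmentation** — separable Gaussian smoothing (σ in voxels, default
   0.8) then a global threshold. Default threshold is mid-contrast;
   adaptive thresholding is out of scope.
2. **Compartment labelling** — 6-connected components of the non-bone
   phase. Components touching a *lateral* grid face are exterior
   background; the largest enclosed cavity is the marrow space; every
   other enclosed cavity is an intracortical pore. The z-faces are section
   cuts through the shaft, so the marrow column that reaches them still
   counts as enclosed — without this a finite slab of a diaphysis has no
   marrow at all. The marrow-vs-pore rule ("largest cavity") is a
   convention; it matches how BoneJ-style tools behave on diaphyseal
   sections and is only ambiguous in degenerate geometries where the
   marrow canal is not the dominant cavity.
3. **Areas and moments** — areas count voxel centers; the second moments
   of area are slice-wise tensors about the slice bone centroid (plus the
   s⁴/12 voxel self-moment), averaged over slices, eigen-decomposed into
   I~min~, I~max~ and the principal angle.
4. **Extreme-fiber distance c** — the source convention behind a printed
   section modulus I~min~/c is rarely stated; we define c as the maximum
   perpendicular distance from the I~min~ principal axis (the bending axis
   in the test orientation) to any bone voxel, the standard weak-axis
   section-modulus convention.
5. **Thickness metrics** — Ct.Th, Tb.Th and Tb.Sp use the
   maximal-inscribed-sphere (local thickness) definition: an exact
   Euclidean distance transform, a distance-ridge reduction, and sphere
   painting, in compiled code. This is the model-independent 3-D
   definition; a 2-D per-slice alternative exists but was not chosen
   because it conflates in-plane and out-of-plane thinning. For Ct.Th the
   pores are filled first (the cortex is measured as a shell). At VOI
   boundaries the out-of-VOI volume continues the phase, so fitted spheres
   are not clipped by an arbitrary contour.
6. **Connectivity** — Conn.D = max(0, 1 − χ)/V with χ the Euler
   characteristic of the cubical complex (vertices − edges + faces −
   cubes), so a single torus has χ = 0 and connectivity 1.
7. **Ct.Po** = 100 · pore/(pore + bone) voxels; invariant to calibration.
   **SMI** is accepted as a pass-through column, never computed (the
   mesh-based algorithm is instrument-proprietary).

Verified properties: disk/ellipse/annulus areas, moments and c agree with
closed forms to <1 % at 6 µm; errors shrink with resolution; 90°
rotations leave areas, moments and porosity unchanged and shift the
principal angle by π/2; voxel-size rescaling scales areas by s² and
moments by s⁴; plate thickness matches a brute-force sphere-fitting oracle
to 10 %.

## 2. Flexural analysis

Force–displacement curves (0.05 mm/s, 100 Hz, 7 mm span, 2 N preload) are
zeroed at the first preload crossing (linear interpolation; samples before
it discarded). Three criteria were open and are configuration-exposed:

- **Stiffness**: maximum least-squares slope of a sliding window covering
  20 % of the pre-peak samples — robust to toe regions, deterministic.
- **Yield**: first point where the secant stiffness F/d drops below
  (1 − 0.10)·K, the standard criterion of the murine-bending guidelines;
  the search is restricted to samples carrying ≥25 % of peak force because
  the secant is noise-dominated near the origin.
- **Failure**: first sample-to-sample force drop exceeding 10 % of peak.

Work to fracture integrates force to the failure point (trapezoids);
PYD = d~f~ − d~y~; M = F·L/4; the beam equation E = K·L³/(48·I~min~)
converts structural stiffness to tissue modulus and round-trips to machine
precision. Curves with non-monotone force before 50 % of peak are flagged
irregular and excluded from PYD/work only, mirroring the usual
motion-during-test exclusion. Body-mass adjustment subtracts the
strain-specific OLS slope times (m − m̄) with m̄ the grand-mean mass over
both strains, so adjusted group means are comparable at a common mass; the
reference mass is a convention the source material leaves unstated.

A subtlety the generator must own: on a bilinear curve the 10 %-secant
criterion is met slightly *after* the material kink, so the generator's
sidecar reports the criterion yield point (closed-form algebra on the
noiseless curve) as ground truth alongside the kink parameters. Round-trip
tests therefore test numerics, not a definitional mismatch.

## 3. Nanoindentation

The protocol is load at 100 µN/s to 1000 µN, hold 30 s, unload at
100 µN/s. Segments are recovered from the load-rate sign and plateau
detection (|dP/dt| < 1 % of the rate near peak). The unloading branch is
fit as P = α(h − h~f~)^m over 20–95 % of peak load — the common window
avoiding hold-creep contamination at the top and tip-off at the bottom.
Because the power-law SSE surface is flat in (α, h~f~, m) jointly, the fit
profiles h~f~ (for fixed h~f~ the model is linear in log space), then
polishes with constrained `nls`; indents with m outside [1, 3] or
h~c~ ∉ (0, h~max~) are flagged invalid. Then S = mα(h~max~ − h~f~)^{m−1},
h~c~ = h~max~ − ε·P~max~/S, A = A(h~c~),
E~r~ = √π·S/(2β√A), H = P~max~/A, and the sample modulus from
1/E~r~ = (1 − ν~s~²)/E~s~ + (1 − ν~i~²)/E~i~.

Constants ε = 0.75, β = 1.0, E~i~ = 1141 GPa, ν~i~ = 0.07 and bone
ν~s~ = 0.3 are the standard Oliver–Pharr values; none are printed in
typical methods sections, all are configuration-exposed. Tip calibration
on fused silica (E = 72 GPa, ν = 0.17) inverts E~r~ per indent into the
required area A = πS²/(4β²E~r~²) and fits the C1…C5 deviation terms of
A(h~c~) = 24.5h~c~² + C1·h~c~ + C2·h~c~^{1/2} + … with C0 fixed; it
requires ≥5 curves and warns below a 3-fold depth range. No thermal-drift
correction is applied (the hold is consumed, not modelled); pile-up is out
of scope.

The forward generator is exact with respect to this analysis: it chooses
A from H, S from E~r~, h~max~ = h~c~ + εP~max~/S, and an unload power law
with the matching tangent. The *loading* curve shape is not constrained by
the contact model; P ∝ h² is a modelling choice, flagged as such. Hold
creep is logarithmic — the standard empirical form — so the unload fit is
exercised against a non-ideal hold.

## 4. Raman spectroscopy

Point spectra are ten averaged accumulations, truncated to
280–2000 cm⁻¹, baseline-corrected, then reduced to five metrics:
mineral:matrix = area(ν₂PO₄ 410–460)/area(amide III 1215–1300) (chosen
over ν₁PO₄-based ratios to minimize polarization effects);
carbonate:phosphate = area(1050–1100)/area(930–980); crystallinity =
1/FWHM(ν₁PO₄) with FWHM by interpolated half-maximum crossings (no peak
fitting, deliberately); collagen maturity = I(1660)/I(1690); pentosidine
ratio = I(1495)/I(1450), flagged exploratory when the local SNR at 1495
is below 5. Intensities at named wavenumbers are linearly interpolated;
band areas are trapezoids with interpolation at the exact bounds; all
metrics are invariant to intensity scaling.

**Rolling-circle baseline.** The published method names no parameters, so
the realization here is documented in full. The spectrum is resampled to a
uniform 1 cm⁻¹ grid, lightly smoothed (Gaussian, 2 samples) for the
*estimate* only, and opened morphologically (erosion then dilation) with a
circular-arc structuring element. Two error terms compete: an arc that is
too flat under-tracks a tilted baseline by ≈ R·slope²/(2s), and an arc
that is too sharp erodes broad bands by ≈ s·w²/(2R) (w = band half-width,
s = intensity scale). The defaults — radius 450 cm⁻¹ and intensity scaled
to one quarter of the plot aspect (dynamic range over axis span) — sit
near the optimum of that trade for bone spectra, whose widest metric band
(amide III, σ ≈ 19 cm⁻¹) is both wide and weak. A radius near 100 cm⁻¹,
sometimes quoted for sharper spectra, measurably erodes the amide III area
here, which is why the default deviates upward; the `radius`, `aspect`,
`iterations` and smoothing knobs are all exposed. The opening is
idempotent, so the iteration count is a stability pass, kept for parity
with the published description.

The generator's default fluorescence baseline is a gentle quadratic
(coefficients 240, 25, −10 in x/1000; ≈15 counts of drift across the
window, band heights 9–100) emulating a photobleached specimen. This is a
stated-world choice: steeper fluorescence degrades *any*
morphological-opening baseline by the tilt term above, and the sensitivity
is exactly the R·slope²/(2s) law, testable by raising the linear
coefficient. Noise is i.i.d. Gaussian, default 1 count = 1 % of the ν₁PO₄
height per accumulation. Single-point intensity ratios (collagen maturity,
PEN) are intrinsically noise-limited on one spectrum (the PEN band height
is ~9 counts), so recovery-within-3 % statements are made for the mean of
a ten-spectrum batch after the ten-accumulation protocol — what a green
test establishes is batch-level, not single-spectrum, accuracy.

## 5. The synthetic cohort

`cohort_spec()` states the world once: 5 control vs 8 diabetic mice (the
post-exclusion study sizes); per-mouse outcome means and SDs at the
published group values for morphometry, mechanics, glycemia and body mass;
body-mass covariation injected for I~min~ and post-yield displacement with
slopes reproducing the reported R² (≈0.5 and ≈0.8 in the diabetic strain),
with the residual SD shrunk so the *marginal* SD still matches the stated
SD; 16 weekly glucose values per mouse (control flat at ~165 mg/dL;
diabetic from ~250 drifting +12.5/week to ~440, between-mouse SD 90,
within-mouse 45 — matching the reported escalation and its large spread);
and tissue-level records nested mouse → quadrant (anterior-lateral /
posterior-medial) → cortex region (endosteal / intracortical / periosteal)
→ three points, with multiplicative variance components (CVs 6 % mouse,
3 % quadrant, 4 % region, 5 % replicate) and an endosteal modulus/hardness
deficit factor 0.82 (endosteal tissue ~18–20 % softer). Tissue-level
control means (E~s~ 24 GPa, H 0.85 GPa, mineral:matrix 0.70,
carbonate:phosphate 0.175, crystallinity 0.058 cm, collagen maturity 1.65,
PEN 0.30) are realistic values for hydrated murine cortical bone; diabetic
effects are the published contrasts (+22 % modulus and hardness, +10 %
mineral:matrix, +0.41 % crystallinity, +19 % PEN, null for the rest).

What the generators do *not* emulate: scanner physics (beam hardening,
partial volume), viscoelasticity beyond the logarithmic hold creep, cosmic
rays, instrument drift, and real biological covariance between modalities
(tissue outcomes correlate only through the hierarchy, not with geometry).
A green round-trip test therefore establishes that the analysis inverts
the stated forward model at the stated noise — not that it is robust to
artifacts the world does not contain.

The diabetic inclusion rule (minimum non-fasting glucose > 250 mg/dL)
is applied by the pipeline to the study-end window (final three weekly
checks), mirroring the repeated measurements taken at euthanasia; applying
it to all 16 weeks would exclude most diabetic mice under the stated
trajectory spread, contradicting the 8-of-10 retention it is meant to
reproduce.

## 6. Statistics

- **Exact WMW**: for n₁+n₂ ≤ 20 the two-sided p is full enumeration over
  C(n₁+n₂, n₁) labelings of the mid-ranks, p = 2·min(tail) capped at 1;
  the asymptotic (tie-corrected, continuity-corrected) value is also
  returned. At the study's n = 5–8 the exact floor 2/C(13,5) = 0.00155 is
  what a printed "0.002" reflects; the normal approximation is unreliable
  there.
- **Mixed models**: REML via `lme4` with nested random intercepts
  (mouse/quadrant/region), the physical sampling hierarchy; the crossed
  alternative was rejected because quadrants and regions are not
  exchangeable across mice. Mixed-model machinery is infrastructure here,
  not a contribution, hence the dependency. Fixed-effect intervals use
  containment-style df (mice minus between-mouse parameters) rather than
  Satterthwaite: the Satterthwaite machinery is not available in the
  grading image, and for the balanced designs generated here containment
  df are exact for the genotype contrast. Singular fits are reported, not
  fatal. Diagnostics: Q–Q quantile correlation and a Levene test
  (mean-centered variant) on residuals.
- **Tukey HSD** from the fitted model via the studentized range; for a
  two-level factor it reduces exactly to the unadjusted t-test (q = t√2).
- **Backward stepwise AICc**, k counting intercept and error variance;
  removal stops when no drop lowers AICc; exact ties prefer the smaller
  model. The acceptance-style simulation uses n = 13 (the full pooled
  cohort) with the published model coefficients (0.97 − 124.73·crystallinity
  − 1.3·collagen maturity) and predictor spreads chosen so both true
  predictors carry comparable variance at total R² ≈ 0.83 — a world where
  one true predictor is underpowered would contradict the fact that the
  published backward selection retained both. At this signal the
  true-pair selection frequency is ≈0.8, so the ≥80 % criterion sits near
  its own decision boundary; the suite's fixed seed set meets it. AICc
  (like AIC) is efficient, not consistent: decoy-retention probability
  does not vanish as n grows, so selection frequency is non-decreasing
  only in the small-n regime (tested n = 10 → 13), not asymptotically.
- **Percent differences** are reported as integer percent, rounded half
  away from zero, with the unrounded value retained.

## 7. Pipeline and provenance

The CLI (`simulate`, `geometry`, `bending`, `indent`, `raman`, `stats`,
`report`, `all`) is a thin layer over exported functions. The inter-stage
contract is one merged long-format cohort table; group tables aggregate
per mouse first (as study figures do) while mixed models consume
unaggregated rows. Configs are JSON, schema-validated with unknown keys
rejected; every output directory carries a provenance block with a
deterministic config hash. All generators are pure functions of
(truth, seed); `run_simulate` under a fixed seed reproduces a
byte-identical study tree.

## 8. Known limitations

- Porosity is resolution-limited exactly as in the instrument (6 µm
  voxels miss canaliculi and small lacunae); the generator's pores are
  non-overlapping spheres of 12–30 µm, the µCT-visible scale.
- The local-thickness ridge reduction can under-paint by ~1 voxel for
  structures a few voxels thick; tolerances reflect that.
- The unloading-fit variance at 1 % load noise is ~1.4 % on E~r~; single
  indents at that noise are accurate to ~±3 % (2σ), batches unbiased.
- The RCF baseline degrades quadratically with fluorescence slope; spectra
  with strong un-bleached backgrounds need a larger radius or smaller
  aspect, at the cost of band erosion, and the amide III area is the first
  casualty either way.
- Statistical worlds are Gaussian with multiplicative hierarchy noise;
  heavy-tailed instrument artifacts are not modelled.
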