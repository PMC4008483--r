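---
title: "Automatic PC-MRI scan positioning: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic PC-MRI scan positioning: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmriplan)
```

## The problem

Whole-brain cerebral blood flow can be quantified with four
phase-contrast MRI scans, one per feeding artery (left/right internal
carotid, left/right vertebral), each slice placed perpendicular to the
vessel near its entry into the skull. The prescription of those slices
from a 3-D time-of-flight (TOF) survey angiogram is normally done by a
trained operator on maximum-intensity projections. `pcmriplan`
automates it: volume in, six prescription parameters per artery out
(off-center mm along RL/AP/FH plus angulation degrees), with an
explicit abort status when the data do not support a safe
prescription.

The coordinate convention is fixed package-wide: the first array axis
runs left→right, the second anterior→posterior, the third feet→head;
all geometry is in mm with voxel centres at
`origin + (index - 1) * spacing`.

## Pipeline and assumptions

1. **Body mask.** Otsu's threshold on a 256-bin histogram of the whole
   volume separates body from air. Assumption: the intensity histogram
   is bimodal air/tissue, which holds for neck TOF acquisitions.
2. **Adaptive artery threshold.** With `mu_O`, `sigma_O` the mean and
   population SD over body voxels, arteries are voxels above
   `T_j = mu_O + j * sigma_O`. `j` starts at 5 (few tissue voxels
   exceed 5 SD) and decreases to 3 (below that, tissue clusters become
   indistinguishable from vessels); the first `j` at which all four
   identified arteries cover at least 60% of the slice range in z is
   accepted. The coverage rule exists to guarantee that the VA segment
   between its two cervical bends is captured. z-coverage is measured
   as slice extent `(z_max - z_min + 1) / N_z` per identified artery —
   not arc length — because the criterion's purpose is coverage of the
   scan range. If even `j = 3` fails, the `j = 3` mask is carried
   forward and the ≥3-artery rule decides whether the run aborts.
3. **Artery identification** on the middle axial slice
   (`floor(N_z / 2) + 1`): among the eight largest 26-connected
   objects, VA candidates are those with exactly one 8-connected
   cross-section (the carotid objects carry the external carotid
   branch and show two). The most posterior candidate in each x-half
   is the VA; the largest remaining sectioned object per half is the
   carotid, and its centre-closest section seeds the ICA. Assumptions:
   the subject is roughly centred and not grossly rotated, and the
   ICA/ECA bifurcation lies below the middle slice. "Most posterior"
   is operationalized as the largest A–P centroid; "image centre" as
   the in-plane midpoint of the grid.
4. **Centerlines** are centres of geodesic-distance level sets on the
   vessel's voxel graph (26-connectivity, physical edge lengths),
   binned at `max(spacing)` width, smoothed with a 3-point moving
   average, and constrained to non-decreasing z. Side branches are
   removed with a two-distance test (see *Numerical choices*). This
   reproduces the centres-of-level-curves construction without any
   surface meshing, which keeps the result deterministic and cheap.
5. **Turning points.** The VA centerline's A–P coordinate is resampled
   uniformly in z (step = slice spacing) and differentiated centrally;
   matching this derivative profile against a population template by
   normalized cross-correlation (offsets with ≥50% template overlap)
   gives a rough region (template turn indices ± padding `P`). Within
   it, the two turning points are the exact minimizer of the
   three-segment within-variance, computed by dynamic programming over
   prefix sums; correctness is guarded by an exhaustive-search oracle
   in the tests.
6. **Planes.** The VA plane centre is the centerline point at the
   profile-index midpoint `floor((k1 + k2) / 2)` of the two turns; the
   ICA plane centre is the ICA point at the z level of the same-side
   VA's upper turn (falling back to the other VA when necessary — one
   VA suffices to fix that level, which is also why the pipeline
   aborts without any VA). Normals come from the first principal
   direction of the centerline points within ±5 points, signed to a
   positive F–H component. Angulation uses the convention
   `normal = (cos a sin b, sin a, cos a cos b)` (a about L–R, then b
   about A–P, in-plane angle ≡ 0); the unit normal is always emitted
   alongside so the output is convention-proof.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `jHigh`, `jLow` | 5, 3 | SD units | bounds of the threshold search (tissue-exclusion vs vessel-inclusion) |
| `lengthFraction` | 0.6 | fraction | minimum z coverage per artery |
| `candidates` | 8 | objects | candidate pool for identification |
| template padding `P` | 10 | samples | rough-region half-width around the template turns |
| `Lmin` | 2 | samples | minimum subregion length, so each variance term is defined on ≥2 points |
| tangent `window` | 5 | points | tangent neighbourhood; small enough not to smooth across a bend |
| profile axis | A–P | — | the cervical VA bends are predominantly posterior; configurable to L–R |
| profile step `dz` | slice spacing | mm | template and subject profiles must share `dz` and axis (enforced) |

## The phantom

`phantomSpec()` describes a 96 × 96 × 47 grid at 0.8 × 0.8 × 1.5 mm —
47 slices being the typical acquisition depth for this protocol — with
four bright tubes over a noisy tissue ellipse: ICAs (radius 2.2 mm)
with gentle lateral bowing and an ECA branch leaving a common trunk at
30% of the z extent; VAs (radius 1.4 mm) with two C¹ bends at 35% and
60% of the z extent (the C2/C1 levels), displacing 6 mm posteriorly
and 3 mm medially between them. Bends blend parabolically over ±2.25
mm so the true tangent is analytic everywhere. Intensities: tissue
`100 ± 20` (Gaussian texture), arteries `tissue mean + 8 tissue SD`
with optional linear taper mimicking flow-saturation signal loss,
plus additive Gaussian noise (SD 5) and clamping at zero. Degradation
flags emulate the observed failure modes: dropped arteries,
uniformly scaled-down ("small") VAs, motion-like A–P blurring.
Gaussian rather than Rician noise is used deliberately: the algorithm
only thresholds high-intensity voxels, where the distinction is
immaterial.

The in-plane extent is smaller than a clinical neck FOV; it is chosen
so that the artery-to-body voxel ratio (≈1.5%) keeps `sigma_O`
realistic, which is what the adaptive threshold actually depends on.

What the phantom does **not** emulate: pulsatility and flow-dependent
saturation, bone/airway structures, tortuous or hypoplastic anatomy
beyond the provided flags, intensity inhomogeneity other than the
linear taper. Passing the phantom suite therefore demonstrates
correctness of the geometry and detection machinery under controlled
conditions, not clinical-grade robustness; the identification
heuristics in particular (posterior-most VA, centre-closest ICA) can
misfire on anatomies the phantom does not model, exactly as the
ECA-for-ICA confusion observed in practice.

`generateProfilePopulation()` draws jittered VA geometries (turn
heights SD 2 mm, bend displacements SD 1 mm) and computes their
derivative profiles from the analytic centerlines with the same
`derivativeProfile()` operation the pipeline uses; templates built
from such populations (`buildTemplate()`, aligned on turning-index
midpoints, cropped to common support, averaged) ship with the package
as `inst/extdata/template_*_synthetic.json`, labelled synthetic
because they stand in for subject-derived templates.

## Numerical choices

- **Population SD** for `sigma_O` (negligible vs sample SD at volume
  scale, simpler contract). Threshold comparison is strict (`> T_j`),
  making masks nested in `j` by construction.
- **Branch exclusion:** with `d_src` the geodesic distance from the
  inferior source and `d_seed` from the seed cross-section, a voxel is
  kept iff `|d_seed - |d_src - d_src(seed)|| ≤ 3 * max(spacing)`;
  on-trunk and on-continuation voxels satisfy this identity, side
  branches accumulate twice their distance past the bifurcation and
  drop out. The tolerance absorbs in-lumen path spread (~1 radius).
- **Ties:** connected objects order by count, then smaller minimal z,
  then discovery order; cross-correlation ties take the smallest
  offset; the DP minimizer takes the lexicographically smallest
  `(k1, k2)` (a constant segment yields `(Lmin, 2 Lmin)`).
- **Degenerate inputs** fail loudly and specifically: constant volumes
  (no Otsu threshold), empty body masks or ROIs, zero-variance
  correlation overlaps, centerlines under 5 level sets or spanning
  under `10 dz`. Pipeline-level failures never throw: they become
  per-artery statuses with reasons, and the overall status follows
  the ≥3-arteries/≥1-VA rule.
- **Tangent window shrink:** when ±5 points are not available the
  window shrinks symmetrically to at least 3 points, with a message.
- The derivative-profile endpoints use one-sided differences; the
  turning search never relies on them because the rough region is
  interior by construction.

## Open design decisions

Several quantities are not pinned down by the method description and
were fixed once here: the normalization of the cross-correlation
(zero-mean, unit-norm over the overlap, so amplitude and offset
differences between subject and template cannot bias the match); the
rough-region padding `P = 10` samples; `Lmin = 2`; the transverse
axis of the derivative profile (A–P, configurable); the "middle point
of the two turning points" read as the profile-index midpoint rather
than the arc-length midpoint (sub-voxel difference at slice-spacing
steps); and the two-replicate CoV defined as
`100 |F1 - F2| / mean(F1, F2)` — note the alternative SD-based
convention differs by √2, so reported CoVs must name their formula.
Bland–Altman agreement is computed on natural-log-transformed
measurements (the spread of flux differences grows with flux), with
1.96 SD limits and the geometric mean ratio `exp(mean log-difference)`
as the multiplicative bias.

## Problem sizes

The shipped test-and-evaluation runs use 96 × 96 × 47 phantoms: 20
seeded noisy runs plus 5 noiseless runs for ground-truth recovery, 20
held-out phantoms for the two-template agreement check, 100 random
segments (lengths 12–200) for the DP-vs-exhaustive oracle, and 10 000
Monte-Carlo pairs for the Bland–Altman limit coverage. These sizes
make every stochastic check stable at the asserted tolerances while a
full evaluation completes in well under a minute.

## Limitations

The tool plans slices; it does not talk to a scanner, read vendor
export dialects (input is NIfTI-1 only), or draw PC-MRI ROIs. The
abort rule means subjects with two hypoplastic VAs are, by design, not
plannable. Statistics helpers implement exactly the analyses named
here (CoV, log-scale Bland–Altman, Pearson chi-square without
continuity correction, success accounting); repeated-measures ANOVA
and t-tests are standard R fare and deliberately not wrapped.
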