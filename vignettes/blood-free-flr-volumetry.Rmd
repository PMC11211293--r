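---
title: "Blood-free FLR volumetry: models, phantoms and design choices"
author: "flrvolumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-free FLR volumetry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flrvolumetry)
```

## The assessment being modeled

CT volumetry of the future liver remnant (FLR) underlies the decision to
perform a major hepatectomy: a patient is a candidate when the FLR exceeds
a condition-dependent share of the nontumor-bearing liver — strictly more
than 20% for a healthy liver, 30% for steatosis, 40% for cirrhosis. CT
measures a *blood-filled* liver: the large hepatic and portal veins, around
9% of liver volume, are counted as parenchyma, whereas the resected or
transplanted graft is weighed *blood-free*. The package implements the full
blood-free correction pipeline and the statistics used to compare settings
and segmentation methods:

$$FLR\% = 100\cdot\frac{FLR}{TLV - V_{Lesion}},\qquad
  FLR\%_{B\text{-}free} = 100\cdot\frac{FLR_{B\text{-}free}}
  {TLV_{B\text{-}free} - V_{Lesion}},\qquad
  FLR\%_{B\text{-}filled} = 100\cdot\frac{FLR_{B\text{-}filled}}
  {TLV_{B\text{-}filled} - V_{Lesion}}.$$

$V_{Lesion}$ is a single quantity reused in both denominators; lesion
voxels count toward TLV in both settings and toward FLR only when they lie
on the remnant side. The blood-free setting removes every intrahepatic
hepatic- and portal-vein voxel from both FLR and TLV. IVC voxels and the
extrahepatic course of the main portal vein are never counted in either
setting.

## The phantom generator

No imaging data ships with the package; the study conditions are emulated
by a synthetic cohort whose defaults mirror a surgical-candidate population:
conditions drawn 27/3/2 (healthy/fatty/cirrhotic) and resections 10/21/1
(left/right/extended-right hepatectomy) per 32 patients.

One phantom is built on a 128³ grid at 1 mm isotropic spacing (clinical
reconstructions are 1–1.25 mm; the grid size keeps a full cohort tractable
on one CPU). The liver is an ellipsoid with semi-axes 58/45/38 mm deformed
by a smooth Gaussian random field. Liver condition modulates shape only
qualitatively — cirrhosis shrinks the organ by 12% and roughens its
surface, fatty liver enlarges it slightly. **These condition effects are
placeholders**: no quantitative morphology for diseased livers is claimed,
and nothing downstream depends on them beyond producing distinguishable
subgroups.

Vessels are grown as capsule-swept polylines: each of the five hepatic
veins (RHV, MHV, LHV, SRHV, IRHV) starts near the posterior-superior
surface and marches into its territory; the main portal vein enters at the
hilum from outside and bifurcates into RPV and LPV inside. Trees carry a
trunk plus primary branches (with short secondary-origin stubs), matching
an annotation protocol that reaches the second ramification. Radii taper by
0.6 per generation with a hard floor of 1 mm radius — the 2 mm minimum
vessel diameter of the annotation protocol. Hepatic-vein tubes are clipped
to the liver; the IVC is a vertical landmark tube placed strictly outside
it. After rasterization, all radii are rescaled (at most four iterations,
radii floored) until the labeled blood pool reaches the 9% target within
10% relative — comfortably inside the ±25% band the generator promises.
The remnant/resect split is an oblique plane in physical coordinates whose
offset is chosen by a liver-volume quantile: the presets remove 35% (left),
60% (right) and 72% (extended right) of the liver. A spherical lesion
(radius 12–25 mm, emulating the large masses of resection candidates) is
placed on the resect side.

Each voxel carries one label. Where structures compete, vessels beat lesion
beats parenchyma, and among vessels the first writer wins (fixed order
RHV…LPV), as in single-label clinical annotation. Intrahepatic versus
extrahepatic status only matters for the MPV; it is decided by a six-ray
enclosure test (a voxel is intrahepatic when at least four of its six
axis-parallel rays hit parenchyma or lesion), which is exact for interior
tunnel voxels and ambiguous only within about a voxel of the hilum entry.

## The segmentation simulator

Trained segmentation models are out of scope; their error structure is
simulated. Each structure's signed distance field is thresholded after
adding a smooth noise field: `mask(s) = {sdt + s·g > 0}`. For a fixed
field, the set of flipped voxels grows monotonically with `s`, so Dice
against the truth is non-increasing and a bisection on `s` can hit any
reachable Dice target; the achieved group Dice must land within 0.05 of the
target or the call fails. Defaults calibrate the liver to DSC 0.95 and the
hepatic/portal vein groups to 0.66/0.67 — the performance band reported for
3D U-Net segmentation of these vessels on external validation CT.
Optionally, whole primary branches are dropped with a configurable
probability before noise is applied, mimicking how automated models miss
small branches; a Dice target of 1 is then refused as unreachable. The
perturbed parenchyma is re-split by the patient's resection plane and the
IVC is copied unchanged.

What the simulator does *not* reproduce: intensity-dependent failure modes
(contrast timing, tumour-adjacent blur), anatomically correlated errors
across structures, and the systematic volume under-estimation some models
show. Passing tests therefore demonstrate that the *assessment pipeline* is
correct and well-calibrated under controlled error levels — not that any
particular segmentation model performs at a given level on real CT.

## Continuity classification

A predicted vessel is classified as accurate when at least 3/4 of the trunk
length and at least 1/2 of each primary branch's length are covered by the
prediction *in one contiguous run*. The criterion was originally applied by
readers looking at renderings; the package operationalizes "accurately
annotated" as centerline-sample containment in the prediction dilated by
one voxel, sampling at half the smallest voxel spacing to avoid aliasing
runs. Thresholds are inclusive (`>= 3/4`, `>= 1/2`): a run of exactly
three-quarters of the trunk passes. A vessel's branch row passes only if
*every* primary branch passes — the conservative reading of a per-vessel
branch judgement; vessels without branches (MPV, IVC) report "not
applicable". Per-vessel accuracies are summarized with Wald 95% intervals
clipped to [0, 100], which back-calculates the familiar
"98.88 (97.31, 100.00)" presentation of classification tables.

## Statistics

* **Bland–Altman**: bias = mean difference, limits of agreement
  `bias ± 1.96·SD` with the sample SD (n−1); the bias p-value is a
  two-sided one-sample t-test, and a zero-variance difference set returns
  `p = 1` rather than failing.
* **Exact McNemar**: `p = min(1, 2·P(X ≤ min(b,c)))`, `X ~ Binom(b+c, ½)`;
  `p = 1` with no discordant pairs, which is how a fully concordant 2×2
  candidacy table yields the reported `p > 0.99` bound.
* **Mann–Whitney U**: midranks for ties; for `n1+n2 ≤ 20` the two-sided
  p-value is exact by full enumeration of group assignments (valid under
  ties, which rules out `wilcox.test`'s exact path); larger samples use the
  normal approximation with tie and continuity corrections.
* **Kruskal–Wallis** (via `stats::kruskal.test`) serves as the omnibus
  subgroup comparison; the all-ties degenerate case returns `H = 0, p = 1`.
  Comparisons between manual and automated FLR values are unpaired
  (Mann–Whitney) to match how such cohorts are reported, though the data
  are nominally paired.
* **Wald intervals** for proportions, chosen because clipping reproduces
  published interval endpoints; the `k = 0`/`k = n` zero-width pathology is
  documented, not patched.

## Numerical choices and degenerate inputs

* Distances use an exact Euclidean distance transform (separable
  lower-envelope algorithm, compiled); a large finite constant stands in
  for infinity so empty scan lines stay well-defined.
* Two empty masks have DSC = VS = 1 (perfect agreement on absence); one
  empty mask gives VS = 0.
* Physical coordinates are `(index − 1) × spacing` (0-based voxel model);
  volumes are `mm³/1000`, reported in mL.
* Centerline extraction builds a 26-connected voxel graph, takes the
  geodesic between the two mutually farthest voxels, trims both ends by the
  inscribed tube radius (the geodesic otherwise reaches the rounded cap
  tips) and lightly smooths the zigzag; disconnected or branched masks are
  rejected rather than guessed at.
* All randomness flows from explicit seeds; per-patient seeds derive from
  the master seed, so any patient can be regenerated alone and repeated
  runs are bit-identical.

## Problem sizes

Cohort experiments run 32 patients at 128³ by default — the scale used in
the package's own acceptance checks (a full run takes a few minutes on one
CPU). The test suite exercises geometry-heavy properties on 96³ phantoms at
1.25 mm spacing, which preserves the physical extent while keeping the
suite fast; the metric and statistics oracles use tiny grids and simulated
samples (1000 repeats for type-I error checks, n = 10 000 for the
Bland–Altman recovery check).

## Known limitations

* Condition-specific liver morphology is qualitative; subgroup contrasts in
  synthetic cohorts reflect the simulator, not pathology.
* The resection partition is a plane; real resection planes follow vessel
  territories, and the discrepancy between assumed and actual planes is not
  modeled.
* Lesion volume is measured once and reused in both FLR% denominators, even
  when a lesion abuts a vessel.
* The simulator's errors are spatially smooth and volume-neutral by
  construction; it does not emulate systematic under-segmentation of
  vessels unless branch dropout is enabled.
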