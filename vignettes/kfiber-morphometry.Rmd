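---
title: "Quantifying k-fiber and microtubule organisation in 3D spindle reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying k-fiber and microtubule organisation in 3D spindle reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfibergraph)
```

## The problem

Serial-section electron tomography of a mitotic cell yields a *spatial
graph*: every microtubule (MT) in the spindle traced as a 3D polyline, with
annotated centrioles and kinetochores. A metaphase spindle in a human
tissue-culture cell contains on the order of 6000 MTs, of which ~14% are
kinetochore microtubules (KMTs) — MTs whose plus end makes end-on contact
with a kinetochore. The KMTs attached to one kinetochore form a bundle, the
k-fiber, that connects the chromosome toward a spindle pole.

`kfibergraph` turns such a spatial graph into the quantities that
characterise k-fiber architecture: KMT counts and length distributions,
minus-end positions relative to the poles, tortuosity, cross-section
geometry along the fiber, and distance-thresholded MT–MT association
patterns. A parametric generator produces synthetic spindles with recorded
ground truth so that every estimator in the package can be validated by
parameter recovery rather than by eye.

## Data model and conventions

Coordinates are micrometres throughout; readers convert from nm when the
file header declares it. A track is an ordered polyline with one terminal
vertex designated the plus end; the other terminal vertex is the minus end
(the pole-proximal end for spindle MTs). The kinetochore *centre* is never
stored: it is recomputed as the component-wise median of the attached KMT
plus-end positions, which makes it deterministic under track edits. (The
geometric median would also be defensible; the component-wise form was
chosen because it is exactly reproducible and cheap.)

Plastic sections collapse in the electron beam, so reconstructions carry a
*Z-factor*: the nominal stack thickness (microtome feed x section count)
divided by the measured thickness. `apply_z_expansion()` multiplies every z
coordinate by this factor about z = 0; all downstream statistics operate on
expanded coordinates. Tracks with an endpoint within 100 nm of the
tomogram bounding box most likely leave the imaged volume and are discarded
by `filter_border_tracks()` before analysis (on realistic data this removes
well under 1% of tracks).

## The pole model

The edge of a spindle pole is not visible as a sharp boundary, so it is
defined statistically: the distribution of non-KMT minus-end distances to
the nearest mother centriole peaks about a micron from the pole and then
falls to a flat bulk level. `fit_pole_model()` bins those distances
(default 0.1 um), fits a Gaussian to the density around the interior mode
and sets the border of the *MT-centrosome interaction area* at

cutoff = peak centre + 2 x HWHM,  HWHM = sigma * sqrt(2 ln 2).

Two numerical choices matter here and are deliberate:

* **A constant baseline is fitted together with the Gaussian.** The peak
  sits on a flat bulk of minus ends; a pure Gaussian fitted locally absorbs
  that baseline into sigma and overestimates the width substantially. The
  offset term removes that bias. The cutoff definition itself is unchanged.
* **The fitting window adapts to the width estimate.** The window is
  mu +- 4 sigma, iterated until sigma stabilises. It must extend past the
  peak into the bulk on both sides, otherwise the baseline is not
  identifiable; 4 sigma recovers planted (mu, HWHM) within 5% at n = 10^4
  across seeds, which is the acceptance bar the package tests.

With HeLa-like geometry the fitted cutoff is ~1.7 um; `pole_model_fixed()`
provides that constant when fitting is disabled, and a `cutoff_rule`
option computes the sensitivity variant `2 x HWHM` measured from zero.
Whether the original analysis fitted counts or normalised density is not
documented; density is the default here and the distinction does not move
the cutoff at realistic n.

## Tortuosity

Global tortuosity is spline length over end-to-end distance: 1 for a
straight MT, pi/(2 sqrt 2) ~ 1.11 for a quarter circle, pi/2 ~ 1.57 for a
half circle. Local tortuosity cuts each KMT into consecutive 500-nm
arc-length windows anchored at the kinetochore end (the trailing residual
shorter than one window is discarded — the windows are non-overlapping, a
choice the source data description leaves open) and reports the arc/chord
ratio per window together with the window midpoint's position on the
pole-to-kinetochore axis.

## Cross-section geometry

The fiber centerline is the per-station component-wise median of the
member KMTs, sampled at matched normalized arc fractions. Cross-section
planes are taken perpendicular to the centerline tangent — the plane
convention is not stated by the field's descriptions, and the tangent-normal
plane is the only orientation that is well-defined for curved fibers. KMT
hits in the plane are polygonised with a 2D alpha shape (`alpha = 10` in
coordinate units, i.e. micrometres); at fiber scale (~0.3 um spread) this
is effectively the convex hull, and the tests pin the equivalence against
an independent hull/shoelace oracle. The planar polygon area equals the
1-um prism-extrusion volume divided by the prism height, so the area is
reported directly. Alpha is configurable because the coordinate scale of
other data sets may differ.

KMT *enclosure* along the fiber uses the minimum circle enclosing all hits
at the kinetochore station (computed exactly, Welzl), doubled to allow for
fiber flexing, centred on the centerline median at each station; KMTs that
no longer cross a station plane count as not enclosed, so the profile
reflects both splaying and KMT termination. Nearest-neighbour KMT spacing
defaults to the first neighbour (k = 1); the underlying K-nearest-neighbour
machinery accepts other ranks.

Kinetochore position on the metaphase plate is zoned by projecting
kinetochore centres on the X/Z plane (configurable, or auto-selected
orthogonal to the pole-to-pole axis), fitting an ellipse by direct least
squares (Halir–Flusser), and thresholding the relative elliptical radius at
0.50 and 0.75 into central / intermediate / peripheral zones.

## Interaction analysis

Associations are distance-thresholded at the conventional set
{25, 30, 35, 45, 50, 75, 100} nm. End-to-lattice distances are exact
point-to-polyline minima, not point-to-resampled-point: at a 25-nm
threshold the sub-step error of resampling would be material.
Lattice–lattice pairing resamples each track at 20-nm arc steps, finds the
partners within the threshold at each step, and merges maximal runs of
consecutive in-contact steps into records whose contact length is
20 nm x (run size − 1); single-step contacts fall below the 20-nm minimum
interaction length and are discarded. One step may contribute to runs with
several partners simultaneously.

End-mode counts are normalised by the local MT density: the number of
distinct tracks crossing the 0.001-um^3 voxel centred on the end (the
natural reading of "potential interactions"; counting polyline vertices
instead would depend on sampling density). Axis profiles use 0.05-wide
bins of relative axis position; for lattice modes the per-bin count is
divided by the number of distinct tracks present in the bin. Performance
comes from per-track bounding boxes expanded by the threshold in front of
fully vectorised distance kernels; the tests require the results to be
*identical* to a naive all-pairs brute-force scan on spindles of up to 100
MTs, so the pruning is an optimisation, never an approximation. The
end–lattice search excludes only the end's own track by default; a flag
also excludes lattices of the same fiber, since the original convention is
not documented.

## The synthetic spindle world

The generator states one fixed world, chosen to mirror the published HeLa
metaphase statistics, and the defaults are not tuned afterwards:

| parameter | default | why |
|---|---|---|
| pole distance | 9.0 um | mean reported spindle length |
| sister pairs | 50 (100 kinetochores) | per-spindle kinetochore counts of 90–110 |
| KMTs per kinetochore | trunc. normal(9, 2.2), min 1 | reported 8.5 +- 2.2 |
| KMT length | uniform on [0.2, 7.2] um | broad, flat distribution of KMT lengths |
| non-KMT count | 5400 | makes KMTs ~14% of ~6300 MTs |
| non-KMT length | exponential, mean 2 um | reported non-KMT length law |
| shell minus ends | 38% at N(1.0, 0.297) um from a pole | peak at ~1 um; mu + 2 HWHM = 1.7 um |
| KMT packing | 74 nm centre-to-centre, hexagonal | reported kinetochore spacing |
| inter-kinetochore | N(1.13, 0.24) um | reported sister separation |
| curvature | theta = kappa L, kappa ~ trunc. normal(0.35, 0.15) rad/um | bend grows with length; mean tortuosity ~1.1 |

KMTs are circular arcs whose *chord* runs from the kinetochore toward the
pole, bowing sideways in a random plane. This keeps two things true at
once: minus ends accumulate near the pole the way real k-fibers converge
there, and the true tortuosity has the closed form (theta/2)/sin(theta/2),
so the ground-truth table carries exact per-KMT values rather than
re-measurements. Non-KMT endpoints keep a 0.3-um clearance from
kinetochore centres — chromosome bodies exclude MT ends in real cells, and
without this the marker-based classifier would have an irreducible
false-positive floor that manually classified data does not have.

What the generator does *not* emulate: tracing and stitching errors,
section-boundary endpoint artefacts (these are planted explicitly in the
QC tests instead), anisotropic point noise, pericentriolar material, and
any MT dynamics. A green recovery test therefore establishes that the
estimators measure what they claim on clean geometry of realistic scale
and composition — not that they are robust to segmentation error.

## Aggregation conventions

Pooling across spindles follows two rules, inferred from reproducing the
published pooled values and configurable: spindle-level quantities (MT
counts, pole distance, pole-association and curved-KMT percentages) pool
as unweighted means across spindles; per-object quantities (KMT length,
KMTs per kinetochore, spacing, tortuosity, inter-kinetochore distance)
pool as n-weighted means with the per-spindle object counts. The bundled
`hela_spindle_tables()` fixture carries the printed per-spindle values and
the acceptance test recomputes every pooled number from it.

## Degenerate inputs and tie-breaks

* Tortuosity of a closed polyline (coincident endpoints) is undefined and
  rejected rather than returned as infinity.
* Cross-sections with fewer than three plane hits have no polygon; the
  area is recorded as missing, not zero.
* Single-KMT fibers get an enclosure radius from a 0.05-um floor.
* Sister pairing uses mutual nearest neighbours *across* the plate
  (candidates restricted to the opposite side of the spindle-axis median);
  ambiguous kinetochores stay unpaired and are skipped with a warning —
  never mis-paired.
* Terminal vertices within 20 nm of a cutting plane count as plane hits
  even without a sign change, so kinetochore-station sections include the
  plus ends that define them.
* Relative axis positions beyond the axis endpoints keep their signed
  out-of-range values (minus ends do overshoot poles).

## Known limitations

The Amira reader supports the ASCII spatial-graph subset (vertices, edges,
per-edge point runs) and skips unknown sections with a warning; label
conventions for KMT/fiber membership in deposited files are treated as
optional annotations. Figure-style loess smoothing is out of scope; raw
profiles (and simple moving averages for presentation) are produced
instead. Published per-MT raw distributions cannot be reproduced without
the deposited tomography data; the package substitutes property-based
validation (oracle equivalence, parameter recovery) for those quantities.
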