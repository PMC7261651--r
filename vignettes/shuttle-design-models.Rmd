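---
title: "Modelling insertion shuttles: buckling, vascular damage, kinematics and SNR"
author: "shuttlemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling insertion shuttles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuttlemech)
```

# The problem

Flexible polymer electrode arrays record well chronically but cannot
penetrate the dura mater or epineurium on their own. A rigid *shuttle*
carries the array through the membrane and is then retracted. The shuttle
must satisfy two opposing requirements: stiff enough not to buckle while
piercing a tough collagenous membrane, and as small as possible to limit
acute damage — above all, transection of the microvessels that densely
permeate nervous tissue. A T-shaped cross-section in a very stiff
thin-film material (ultrananocrystalline diamond, E of order 800 GPa)
resolves the trade-off: the vertical fin raises the second moment of area
at little added cross-sectional area.

This package implements the four quantitative models behind that design
argument, each usable on its own:

1. exact section properties (area, centroid, second moment) of rectangles
   and T-beams, with a polygon-integration oracle;
2. Euler buckling with boundary-condition effective-length factors;
3. a Monte Carlo model of microvascular transection by an arbitrary
   footprint dropped at random over a projected 3-D vessel network, with
   a seeded synthetic network generator;
4. closed-form insertion kinematics and a spike-SNR metric.

# Section properties and the composite T-beam

Units are micrometres internally, everywhere; conversions happen only at
I/O boundaries. The section plane has x lateral and y as depth, positive
downward from the probe's top surface; contours are stored as simple
polygons with implicit closure (first vertex not repeated).

For a rectangle, $A = bh$ and $I = bh^3/12$ about the centroidal
horizontal axis. For the T-beam — a planar rectangle with a trapezoidal
fin (top width $a$, tip width $b$, depth $d$) centred beneath it — the
package uses standard composite-beam theory: own-axis second moments of
the two parts plus parallel-axis transfers to the common area-weighted
centroid. The trapezoid's own-axis moment is
$d^3(a^2 + 4ab + b^2) / (36(a+b))$.

```{r}
tb <- tbeam_section(65, 11, 27.5, 16, 2)   # the study geometry
si <- rect_section(65, 34)
c(area_tb = section_area(tb), area_si = section_area(si),
  reduction_pct = area_reduction_percent(tb, si))
```

Every closed form is checked against an independent polygon oracle:
`polygon_second_moment()` integrates $\int y^2\,dA$ exactly from the
vertex list (shoelace-type formulas), so a bug in the composite algebra
cannot hide. The test suite runs this cross-check on 1000 random valid
sections at 0.1% tolerance; agreement is in practice at machine
precision.

`equivalent_rect_thickness()` inverts $EI$ matching:
$h = (12\,EI_\text{target}/(E b))^{1/3}$. With the composite $I$ above
and a silicon modulus of 169 GPa (the common $\langle 110\rangle$ value;
silicon is anisotropic, so this is exposed as a parameter rather than
hard-wired), the 962.5-µm² T-beam at 800 GPa matches a silicon rectangle
of about 38.4 µm thickness. Design studies in this space often quote an
equivalent nearer 34 µm, obtained under different (unpublished) moment
conventions; we deliberately do not force that agreement — both the
modulus and the $I$ formula are exposed, and the area-reduction headline
(56% against the 65 × 34 µm reference) is computed from the printed
reference geometry itself.

# Euler buckling and boundary conditions

$$P_{cr} = \frac{\pi^2 E I}{(K L)^2}$$

with E in GPa, I in µm⁴ and L in mm, the result is returned in mN
(conversion factor $10^{-6}$, audited in a test against the same
computation in SI units). The effective-length factor K encodes the tip
boundary condition: 0.699 (fixed–pinned, tip embedded in tissue), 1
(fixed–guided, tissue moves with the pinned tip), 2 (fixed–free, tip
slips). K is always explicit — no silent default — because the failure
mode the model warns about is precisely designing for fixed–pinned and
then meeting fixed–free on a curved, tough membrane: a $(2/0.699)^2
\approx 8.2$-fold loss of buckling strength. `worst_case_load()` applies
that ratio as a derived convenience.

```{r}
buckling_load(shuttle_beam(tb, material_uncd(), 1.5, "fixed-pinned"))
head(design_space_sweep(function(h) rect_section(65, h), seq(5, 52, 1),
                        material_uncd(), 1.5, "fixed-pinned"), 3)
```

# The vessel-damage Monte Carlo

The model treats insertion as vertical and straight, so the 3-D vessel
network is orthographically projected along the insertion axis (default
z; the anatomical axis used for any given dataset is a user choice). Per
trial the footprint contour is rotated uniformly in $[0, 2\pi)$ about its
centroid and its centroid translated to a uniform position; a vessel
segment is damaged when the placed contour meets it, and each segment
counts at most once. Per-trial counts over (by default) 1000 trials are
summarized by a Gaussian fit.

Two transection predicates are provided because "the probe crossed the
vessel" admits readings:

* **centerline** (default): the segment's centreline meets the open
  interior of the polygon. Simple, unambiguous, monotone in the
  footprint.
* **full-width**: the polygon must reach across the whole vessel,
  operationalized as hitting the interior of *both* offset lines at
  $\pm$ diameter/2 (the vessel walls). This is stricter for wide vessels
  clipped at a polygon corner.

Both are reported in practice; when they differ materially the choice
should be stated with the result, which is why the criterion is logged in
every `damage_distribution`. Boundary tangencies (zero interior overlap)
do not count under the default open-boundary policy — such
configurations have probability zero under continuous random placement,
and excluding them keeps the predicate stable under floating-point
perturbation. A closed-boundary variant exists for completeness.

Placement uses the projected bounding box shrunk by the footprint's
circumscribed-circle radius ("inset"), so a rotated footprint never
leaves the observed region and edge bias is avoided; an "unclipped" mode
drops the inset for fidelity to analyses whose edge policy is unknown.
Counting offers an all-pairs brute-force path and a bounding-box
prefiltered path; they apply the identical predicate and are verified
identical on random networks — the prefilter is purely conservative.

```{r}
net <- generate_synthetic(synth_network_config(box_um = c(600, 600, 600),
                                               seed = 1))
seg <- project_to_plane(net)
d_tb <- run_simulation(tb, seg, n_trials = 200, seed = 2)
d_si <- run_simulation(si, seg, n_trials = 200, seed = 3)
compare_geometries(d_tb, d_si)
```

`fit_gaussian()` reports the sample mean and the sample standard
deviation (n−1 denominator — the Gaussian MLE up to the $n/(n{-}1)$
convention; one convention, stated once, used everywhere). A
least-squares histogram-curve variant is available for comparison with
curve-fit summaries. Counts are discrete, so normality is only ever a
descriptive report, never an assertion.

## The synthetic network generator

The generator emulates exactly the statistical structure the damage model
assumes, nothing more: straight segments, midpoints homogeneous-Poisson
in a box, isotropic orientations (uniform azimuth, uniform cosine of the
polar angle), i.i.d. lengths and diameters. Defaults — lognormal lengths
with median 60 µm (sdlog 0.5), lognormal diameters with median 6 µm
(sdlog 0.4), length density $10^{-4}$ µm/µm³ in a 400-µm box — are
documented placeholders in the range reported for cortical
microvasculature, fixed once and exposed through
`synth_network_config()`. The segment count is Poisson with mean (density
× volume / mean segment length), so expected total centreline length
matches the density target; segments whose midpoints fall near the box
face may protrude past it, which is why the object distinguishes the
generation `domain` (used for length density) from the endpoint bounding
box.

What the generator does **not** emulate: vessel connectivity and
branching, spatial correlation (real capillary beds are locally
anti-clustered), depth-dependent density, vessel tortuosity, and the
arteriole/venule diameter mixture. Tests passing on synthetic networks
therefore validate the counting geometry and its statistics under the
model's stated assumptions — they do not by themselves certify damage
predictions for a particular brain region; for that, feed a measured
network through `read_network()`.

An exact stereological identity pins the whole chain down: for an
isotropic Poisson segment process of areal intensity $\lambda$ and mean
projected length $\bar\ell$, the expected centerline-mode count for a
*convex* footprint of area $A$ and perimeter $P$ is
$\lambda\,(A + \bar\ell P/\pi)$ (mean projection width of a convex body
is $P/\pi$). The test suite verifies this within 3 Monte Carlo standard
errors over independent network replicates. For non-convex footprints
such as the T, $P$ must be read as the convex-hull perimeter; the test
uses rectangles so the identity is exact as written.

## Reading measured networks

Published microvascular reconstructions are distributed as plain-text
node/segment topology files. `read_network()` is driven by a declarative
column map (`network_dialect()`) — segment records carrying id, type,
from-node, to-node, diameter; node records carrying id and coordinates;
each block preceded by a count line — so a layout drift between mirrors
produces a parse error naming the offending line rather than silently
corrupted coordinates. A small synthetic example in this dialect ships
under `inst/extdata/` (labelled synthetic; it is generated output of this
package, not measured data). The canonical interchange form is a
per-segment CSV (`write_network()`), lossless to well below $10^{-6}$ µm.

# Insertion kinematics

Position along the insertion axis is $p(t) = v t + \tfrac{A_{pp}}{2}
\sin(2\pi f t)$: a linear ramp with a superimposed uniaxial sinusoid.
Amplitude is stored peak-to-peak because actuator specifications quote it
that way (70 µm PP at full drive is the default ceiling, overridable);
phase starts at zero, which is irrelevant to the peaks. The closed-form
extrema are $v + \pi f A_{pp}$ for speed and $(2\pi f)^2 A_{pp}/2$ for
acceleration; `trajectory()` returns exact derivatives on any time grid,
and tests confirm that dense numeric sampling converges to the closed
forms.

```{r}
pr <- insertion_profile(0.01, 200, 70)
c(peak_speed_mm_s = peak_speed(pr), peak_accel_m_s2 = peak_acceleration(pr))
```

The point of the model: 200-Hz, 70-µm oscillation turns a 0.01 mm/s crawl
into a 44 mm/s peak tool speed at the tissue interface, which is the
mechanism credited for reduced tissue compression. Probe–tissue coupling
itself (compression, friction, cutting force) is measured, not modelled,
and is out of scope here.

# Noise floor and unit SNR

The noise floor of a recording channel is the RMS of five 100-ms
snippets of filtered, spike-free data joined into one 500-ms block; a
unit's SNR is its waveform peak-to-peak voltage over three times that
floor. Snippet selection is the caller's responsibility by design — the
defining property ("contains no sorted units, no saturation") depends on
upstream spike sorting — but `flag_artifacts()` automates a 5-sigma
(MAD-based) and rail screen. Vrms is computed on the trace exactly as
provided (any re-referencing is upstream), and band-pass filtering is
deliberately out of scope: it is standard signal processing, not part of
the metric.

```{r}
st <- synth_trace(1, 2e4, noise_sd = 10, seed = 5)
w <- cbind(start = seq(0, 0.4, 0.1), end = seq(0.1, 0.5, 0.1))
vrms <- noise_floor(st$trace, w)
unit_snr(unit_waveform(c(-45, 75)), vrms)
```

# Numerical choices and limitations

* Geometric predicates use strict inequalities (open interiors, proper
  crossings). Configurations on the boundary between verdicts are
  measure-zero under the continuous placement distribution; no epsilon
  tolerances are introduced.
* Polygons are validated simple (O(n²) pairwise edge check — contours
  here have ≤ 8 vertices) with positive area; degenerate sections are
  rejected at construction.
* Seeds: every stochastic entry point (`generate_synthetic()`,
  `run_simulation()`, `synth_trace()`) takes an explicit seed, records it
  in its output, and restores the caller's RNG state.
* Problem sizes in the shipped tests — 1000 random sections for the
  geometry oracle, 100 networks for the counting-oracle equivalence, 24
  networks × 50 trials for the stereological identity, 1000-trial damage
  runs in the acceptance script — were chosen so the full suite completes
  in well under a minute while keeping Monte Carlo standard errors small
  relative to the tested tolerances.
* The damage model is acute and geometric only: no bleeding, tissue
  mechanics, angled tracks, or chronic response. The buckling model is
  linear-elastic Euler theory: no post-buckling deflection or fracture
  prediction.
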