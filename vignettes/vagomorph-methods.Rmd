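---
title: "Methods: nerve cross-section morphometry and CNAP prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nerve cross-section morphometry and CNAP prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagomorph)
```

vagomorph takes segmented contours of peripheral-nerve cross-sections —
perineurium outer/inner borders, myelin sheath outer/inner outlines,
unmyelinated axon outlines — and computes fascicle- and fiber-level
morphometrics, then predicts the compound nerve action potential (CNAP) a
cuff electrode would record from those fibers. This vignette documents the
models, the numerical choices, and the design decisions that were genuinely
open.

## The contour-table format

No open standard exists for planar nerve segmentations, so the package
defines its own: a UTF-8 CSV with one row per vertex and columns
`entity_id, role, parent_id, fascicle_id, vertex_index, x_um, y_um`, plus a
JSON sidecar for donor metadata (`donor_id`, `side`, `sex`). Polygons are
implicitly closed (a duplicated terminal vertex is tolerated and dropped on
load) and normalized to counter-clockwise orientation; coordinates are
planar micrometres with y increasing upward and an arbitrary per-section
origin — every computed quantity is translation- and rotation-invariant, and
the test suite checks this.

Two conventions deserve emphasis. Myelin inner/outer pairing is *explicit*
(`parent_id` on the inner contour): with thin sheaths and tightly packed
fibers, geometric containment is ambiguous, so geometry is only ever used to
verify a pairing, never to infer one. Fiber-to-fascicle assignment, by
contrast, *is* geometric — point-in-polygon of the fiber centroid against
the inner perineurium (sub-fascicle compartments are tested before the
parent) — and is deterministic and independent of file row order.

`validateCrossSection()` checks every domain invariant (simple polygons,
nested perineurium, inner myelin smaller than outer, G-ratio in (0, 1),
centroids inside their compartment, pairwise-disjoint fascicles and
sub-fascicles) and returns a violation table; it never throws, so a single
bad fiber does not hide the remaining problems.

## Morphometry

Areas use the shoelace formula and perimeters the exact polygon edge
lengths, both on the raw vertices: no smoothing is applied anywhere, because
a smoothing step would introduce a tunable parameter the downstream
quantities would silently depend on. Feret diameters are computed on the
convex hull — the maximum as the largest vertex-pair distance, the minimum
by rotating calipers over hull edge directions.

The five circularity metrics follow the standard definitions (see the
README). Two identities hold exactly and are enforced as tests across
random polygons: `roundness == compactness^2` and
`formFactor * shapeFactor^2 == 4 * pi`. Note that for a square the aspect
ratio is `1 / sqrt(2)`, since the maximum Feret diameter is the diagonal.

### Shape-adjusted ellipse (SAE) diameter

A fiber sectioned obliquely presents an ellipse whose minor diameter is the
true fiber caliber. The SAE correction therefore solves, for measured area
$A$ and perimeter $P$,

$$\pi a b = A, \qquad P_\text{Ramanujan}(a, b) = P, \qquad a \ge b,$$

and reports $2b$. With the aspect ratio $t = b/a$ as the unknown, the
perimeter at fixed area is strictly decreasing in $t$, so the inversion is a
bracketed one-dimensional root find; it is polished until the perimeter
residual satisfies $|\Delta P| / P \le 10^{-10}$. Ramanujan's second
approximation (relative error below $10^{-5}$ at every eccentricity) is the
default perimeter model because digitization noise dominates its error by
orders of magnitude; an exact elliptic-integral backend
(`method = "exact"`) is available.

Digitized near-circular contours can have $P$ slightly *below* the
equal-area circle bound $2\sqrt{\pi A}$, which no ellipse attains. Within a
relative $10^{-6}$ of the bound the input is clamped to the circle
($2\sqrt{A/\pi}$); beyond it, the input is rejected as infeasible rather
than silently truncated, since a grossly sub-circular perimeter indicates a
segmentation artifact.

G-ratio is the ratio of the axon and fiber SAE diameters; myelin thickness
is half their difference. Size distributions use right-open bins of fixed
width from zero; modality is the number of local maxima of the 3-bin moving
average of the counts (zero-padded ends, plateaus collapsed), a deliberately
simple and parameter-light rule — the width of 3 bins is fixed, not tuned.

## The action potential model

The prediction layer is heuristic by design: it captures latency dispersion,
amplitude scaling and superposition, not membrane biophysics.

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `kMyelinated` | 6 | m/s per um | linear (Hursh-type) velocity law `v = k D` on the outer SAE diameter |
| `cUnmyelinated`, `alphaUnmyelinated` | 1.7, 0.5 | m/s, — | power law `v = c d^alpha` for unmyelinated axons |
| `ampExpMyelinated` / `ampExpUnmyelinated` | 2 / 1 | — | SFAP peak proportional to diameter^p, arbitrary units |
| `durationScale` | 0.3 | ms·(m/s) | waveform width `durationScale / v` |
| `template` | Ricker | — | negative second derivative of a Gaussian; a single-cycle biphasic sine is selectable |
| `sampleRate` | 100 | kHz | shared uniform time grid |

The default coefficients place large myelinated fibers in the classical
A-fiber velocity range, small myelinated fibers in the A-delta/B range and
unmyelinated axons below 3 m/s. They are configuration values, not
anatomical claims; every acceptance-level property of the package
(superposition, latency law, classification partition) is independent of the
template and of the particular coefficients.

Both templates have their negative main peak exactly at the conduction
latency `distance / v`, so the *latency law* — negative-peak latency equals
`conduction_distance / velocity` within one sample period — holds by
construction. The waveform width is floored at two sample periods: a
sub-sample-wide waveform could otherwise fall entirely between grid points
and lose its peak, which would silently break the latency law for the
fastest fibers at moderate sampling rates.

Differential (bipolar cuff) recordings return
`V(t - d/v) - V(t - (d+s)/v)`, proximal contact minus distal — the sign
convention is fixed so peak polarities are reproducible. The recording
window auto-sizes to `(d + s)/v_min + 5` waveform widths of the slowest
fiber; an explicitly configured window that cannot contain the waveform is
extended with a warning, never silently truncated. When comparing CNAPs of
different fiber subsets (e.g. sub-fascicles against the whole fascicle),
pass an explicit window so all predictions share one grid.

The CNAP is the pointwise sum of single-fiber waveforms. The per-bin
decomposition partitions fibers by diameter, separately for myelinated and
unmyelinated populations, and the total is computed as the sum of the
per-bin traces, so the decomposition identity is exact. Automatic binning
minimizes total within-bin variance over contiguous partitions of the sorted
diameters with an exact dynamic program — deterministic, unlike iterative
clustering, so rerunning an analysis can never shuffle bin boundaries.
Populations above 4096 fibers are first collapsed onto 1024 weighted
quantile prototypes (the boundaries this yields are indistinguishable at
histogram resolution, and the step stays deterministic).

The velocity-domain display re-parameterizes time as
`v = conduction_distance / t`, carrying amplitudes over unchanged and
dropping the `t = 0` sample. Classification uses right-open velocity
intervals (a boundary velocity belongs to the faster class): A-alpha
[70, 120), A-beta [30, 70), A-gamma [15, 30), A-delta [3, 15) for
myelinated fibers, B [3, 15) for fibers flagged preganglionic, C (0, 3) for
unmyelinated; velocities outside every interval are "unclassified" rather
than force-fitted.

Out of scope, deliberately: stimulation thresholds and recruitment (all
predictions assume maximal activation of the selected fibers),
volume-conductor or finite-element lead fields (no 1/r attenuation — an
insulating cuff dominates the lead field, and the cuff inner diameter is
carried as metadata only), and noise models.

## The synthetic generator

The generator exists so that every pipeline stage is testable against known
ground truth. It emulates, per fascicle: lognormal-mixture myelinated
calibers (default bimodal, modes near 2 and 9.5 um — small-fiber-dominated
compositions with a secondary large-fiber mode), unimodal unmyelinated
calibers near 1 um, truncated-normal G-ratios on (0.4, 0.9) with mean 0.6,
target endoneurium/fascicle area ratios (defaults near 0.76-0.81), optional
sub-fascicle compartments, and unmyelinated-majority compositions. The
bilateral cohort preset adds right-dominant and female-dominant fascicle
counts (Poisson means 7.9/2.9 right/left for males, 17.1/8.6 for females),
side-specific circumference lognormals chosen to match per-fascicle mean
circumferences near 930 um (right) and 1170 um (left) while keeping the
pooled first quartile below 300 um, a 15.5% sub-fascicle probability, and
per-fascicle fiber censuses drawn log-uniformly within 4-3311 (myelinated)
and 21-15646 (unmyelinated) — the censuses are recorded in the ground-truth
ledger but not geometrically rendered at cohort scale.

Geometry: fascicle shells are smoothly perturbed ellipses whose inner
border is the outer scaled by `sqrt(ratio)`, so the area ratio is exact.
Fibers are rendered as perturbed ellipse polygons (64 vertices, random
aspect 0.75-1 emulating oblique sectioning, a low-order radial ripple) and
each polygon is scale-calibrated so its *measured* SAE diameter equals the
drawn diameter exactly. An earlier candidate — regular polygons with
independent per-vertex radial noise — was rejected on analysis: white
vertex noise inflates the perimeter quadratically, and near the circle
bound the SAE minor diameter responds to the perimeter excess as a square
root, so even 1% vertex noise biases recovered diameters by several
percent. Smooth perturbations plus calibration keep the generator's 1%
recovery contract with margin and still exercise the SAE inversion on
genuinely non-circular shapes.

Placement is dart throwing (uniform proposals, 1000 retries per fiber,
failure raises an error suggesting a lower density), largest fibers first,
with myelin outer enclosures kept disjoint. Auto-sized compartments get
area `sum(pi r^2) / packingFraction` plus a boundary-margin term
proportional to the largest fiber radius — the margin dominates for
few-fiber compartments, and sub-fascicle compartment circles use a
conservative 0.25 fill fraction because dart-throwing 2-3 near-equal
circles fails well below the theoretical packing bound. All randomness
flows from the single section seed.

What the generator does **not** emulate: realistic Schwann-cell nuclei or
Remak bundle substructure (nuclei are plain ellipses for format
completeness), fiber clustering or spatial gradients within the
endoneurium (placement is uniform), perineurium thickness variation along
the border, and measurement noise of a real segmentation workflow. Passing
tests on synthetic sections therefore demonstrate the correctness of the
geometry, bookkeeping and statistics — not that the defaults reproduce any
particular donor's nerve.

## Cohort statistics

All summaries are mean ± SE with the sample (n−1) standard deviation. Group
comparisons use the tie-corrected Kruskal-Wallis test; post-hoc pairwise
comparisons use Dunn's z on the joint ranks,

$$z_{ij} = \frac{\bar R_i - \bar R_j}
{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
\left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},$$

with Bonferroni adjustment over the compared pairs by default (the
correction family is configurable — conventions differ between software
packages, so the choice is stated in the report header). Paired right/left
donor comparisons use the two-sided Wilcoxon signed-rank test, exact for up
to 25 untied pairs; a nonparametric paired test matches the nonparametric
character of the rest of the analysis. Frequency comparisons use Pearson's
chi-squared without continuity correction. Regressions are ordinary least
squares with R² equal to the squared Pearson correlation, an optional
log10 transform of x, and a pointwise 95% confidence band for the mean
response. Significance is declared at p < 0.05 throughout.

`reproduceReport()` wires these into the standard groupings for a bilateral
donor cohort — right vs left (section- and fascicle-level), donor-paired
sides, and female vs male fascicle counts combined and per side. Missing
measures or single-sided cohorts yield explicitly flagged unavailable rows,
not a truncated report.

## Problem sizes and tolerances used in the tests

The test suite generates everything it needs at run time: sections up to
~700 fibers for mixture-recovery checks (component means within 2%, G-ratio
mean within 0.02), 3×317 shell-only fascicles for the sub-fascicle
frequency band, 1000-case property loops for the geometric identities and
the SAE round trip (relative error below 1e-8), and a 10^4-shuffle
permutation null for the Kruskal-Wallis p. Superposition identities are
checked to 1e-9 relative; I/O round trips to 1e-9 um (the writer emits 9
decimals). These sizes keep a full run within a couple of minutes while
leaving each check statistically meaningful.

## Known limitations

- The SAE model assumes an elliptical oblique section; strongly crenellated
  or infolded sheaths violate it and will read low.
- The velocity and amplitude laws are stylized; absolute CNAP amplitudes
  are arbitrary units and only relative comparisons are meaningful.
- Self-intersection checking is O(n²) per contour; very high-resolution
  contours (beyond ~10^4 vertices) make validation slow, though loading
  stays fast.
- The classification table is a configuration default; boundary velocities
  in the literature vary by species, nerve and temperature.
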