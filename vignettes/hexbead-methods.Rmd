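---
title: "Models and methods behind hexbead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexbead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexbead)
```

# Scope

`hexbead` implements, end to end, the bead-level processing and quality
diagnostics for BeadArray section images: chip geometry and neighbour
graphs, vendor-dialect intensity extraction, registration and
annotation-remapping diagnostics, spatial artefact detectors, an
idealized-bead digitization study, robust two-pass summarization, and a
ground-truthed simulator.  This vignette records the models, the
conventions, and the choices that were genuinely open, so a reader can
judge exactly what the package computes and what the passing test suite
does and does not demonstrate.

# Geometry and conventions

Pixels are 0-based and pixel $(i, j)$ covers $[i, i+1) \times
[j, j+1)$; a bead centre is a continuous $(x, y)$ whose integer parts
select the *anchor* pixel.  This makes the fractional-part foreground
weighting well defined.  Grid row $r$, column $c$ of a segment maps to

$$x = o_x + c\,p + (r \bmod 2)\,p/2, \qquad y = o_y + r\,p\sqrt{3}/2,$$

with pitch $p$ (default 6 px): rows parallel to the x-axis, odd rows
offset half a pitch, every nearest-neighbour distance exactly $p$.  The
true row-parity convention of vendor chips is not documented in what we
work from; we fix this one and note it is unverified against vendor
layout files.  It is consistent with the observable constraint that a
17 × 17 px window over a pitch-6 lattice can contain at most 12 bead
centres (`lattice_window_capacity()` verifies this by brute force).

Two platform layouts are built in: the six-sample expression chip
(9 segments of 326 × 397 = 129,422 beads per section) and the
two-sample copy-number chip (4 segments of 333 × 443 = 147,519 beads).
Segments are treated as independent images; no whole-chip mosaic is
modelled.

# Intensity extraction

The extraction follows the vendor's published outline; the exact vendor
coefficients are not public, so the concrete laws below are declared
dialects, exposed as options so an alternative can be swapped in.

* **Sharpening**: convolution with centre 5, $-1$ at the four edge
  neighbours, 0 at corners; borders edge-replicated; output clipped at
  0.  The kernel sums to one, so flat fields are fixed points.
* **Foreground**: weighted average of sharpened intensities over the
  4 × 4 window (anchor − 1 .. anchor + 2 on each axis).  Column weights
  $(1-f, 1, 1, f)$ and row weights $(1-g, 1, 1, g)$, outer product,
  normalized — $f, g$ the fractional parts of the centre.  This law
  satisfies the two printed constraints (the centre 2 × 2 always takes
  the maximal unnormalized weight; the outer pixels are driven by the
  fractional part) and degrades to a 3 × 3 mean at zero fraction.  Note
  that under the corner-anchored pixel convention the weight centroid
  tracks the bead centre with a constant half-pixel lag; because the
  renderer and the extractor share the convention this is internally
  consistent, and it is precisely what keeps the offset-dependence of
  the foreground small (below).
* **Background**: a summary of the five lowest of the 289 pixels in the
  17 × 17 window of the *raw* image around the anchor pixel (the
  fractional part plays no role here).  The default is the vendor's
  mean-of-five; the median-of-five (3rd order statistic), a general
  rank-$k$, and a trimmed mean are available because the mean of
  extreme order statistics is not robust — a single aberrant low pixel
  moves it, which is exactly the low-pixel artefact the diagnostics
  look for.
* Final intensity = foreground − background, negative values preserved;
  log-domain summaries mask non-positive values instead.

# Registration diagnostics

Per segment, decoded bead pixel coordinates are fit by least squares as
affine functions of the lattice coordinates, and the departure
statistic is the Euclidean residual norm $d = \sqrt{r_x^2 + r_y^2}$.
Because of the hex stagger, raw $(c, r)$ are not affine predictors of
$x$; we use the effective coordinate $c + (r \bmod 2)/2$ so a perfect
lattice has zero residuals.  The printed form of the original model is
typographically corrupted in our source; this affine-plus-Euclidean
reconstruction is the only reading under which "departure from the
grid" is a distance, and it is documented as a reconstruction.

Whole-segment annotation scrambles are repaired by exhaustive search
over integer shifts (default ±10 grid steps): a candidate $(\Delta c,
\Delta r)$ re-annotates each bead with the recorded ID that many steps
away, and the objective is the mean within bead-type variance of log2
intensity over types with at least two annotated beads.  Being out by a
single row or column scrambles the annotation completely, so the
profile shows one sharp minimum at the true shift; exhaustive search is
deliberate — the full profile *is* the diagnostic.  Correlation of
candidate type medians with a replicate segment is reported as
confirmation, not used as the objective; with both printed desiderata
available, variance is the one that needs no second segment.

Simplified registration (`register_grid()`) detects bright local
maxima, refines them to intensity-weighted centroids, assigns
provisional lattice indices, and fits origin/pitch/row-height by least
squares with one re-assignment pass.  The recovered origin is anchored
at the topmost detected bead row, which on a clean rendered section is
the first grid row.  The full vendor registration algorithm is out of
scope by design.

Two-colour sections get a per-bead shift field (red minus green
coordinates), a local median over a sliding window in grid coordinates
(half-width 5 by default), per-bead discordance from that local median
(flag threshold 2 px), and a linear trend of shift against grid
position whose slope measures "variable pixel size".  Identical
red-channel coordinates on two beads are flagged unconditionally.

# Spatial artefact detectors

* **Non-decoded clusters.** Seeds are non-decoded beads whose six
  neighbours are all non-decoded; flood fill over non-decoded beads
  from the seeds yields maximal networks, reported at ≥ 50 members
  (configurable).  The seed rule means scattered non-decoded singletons
  never trigger detection.  Detected clusters are expanded 2 graph hops
  (default) into their decoded halo; the true extent of intensity
  inflation around real clusters is unknown, so the ring count and the
  simulator's halo magnitude are parameters, not claims.
* **Bright features.** Threshold at mean + 5 sd (the notion of "bright"
  is not quantified in our source), connected components via
  `EBImage::bwlabel`, keep mass ≥ 40 px and circularity
  $4\pi A / P^2 \ge 0.8$ with the perimeter estimated as the
  boundary-pixel count (≈ 1 for digitized discs, far lower for
  streaks), then flag the mapped bead and all its neighbours.
* **Low pixels.** The modal background is the histogram mode of the
  lower half of intensities; pixels below half of it (default) are
  reported, and every bead whose 17 × 17 window contains one — where it
  necessarily ranks among the five lowest — is flagged.
* **Twins.** Same-type neighbouring pairs are counted once per edge;
  the idealized i.i.d.-uniform expectation is $n \bar k / 2 / T$.  The
  permutation null holds the graph and the decoded positions fixed and
  permutes decoded identities, preserving the type multiset exactly;
  p-values use the add-one rule.  The twin flag is informational by
  default and excluded from the summarization mask, since an excess of
  twins indicts the decoding globally rather than any particular bead.

# The digitization study

An idealized bead is a sphere evenly covered in probes; under
orthographic imaging its flux density at planar distance $d$ from the
centre is proportional to the chord depth $\sqrt{r^2 - d^2}$.
`digitize_bead()` integrates this over each pixel square (midpoint
quadrature, 32 × 32 sub-samples per pixel) and rounds to integers;
`offset_profile()` sweeps the bead's fractional offset over a grid and
recomputes the weighted foreground at the known centre each time.  Log
base 2 is used throughout the package (the scale of the original
claim is unspecified; base 2 is the field's convention and is
configurable in spirit via `profile_range()` operating on any log).

One deliberate choice: the study's default computes the foreground on
the digitized image *without* sharpening.  The idealized-bead procedure
is digitize → foreground; with the sharpening dialect interposed the
radius trend inverts between radius 2 and 1.5 px, while without it all
three qualitative behaviours hold simultaneously — the foreground is
maximal near zero fractional offset, the full range for a radius-3 px
bright bead is ≈ 0.07 (small, ≤ 0.2 in log2), and the range grows
monotonically as the bead shrinks from 3 to 1.5 px, where the 4 × 4
aperture's capture becomes phase-sensitive.  `offset_profile(sharpen =
TRUE)` restores the sharpened variant for comparison.

# Summarization and detection

Two passes: (1) remove beads carrying mask flags (and count
non-positive intensities as masked), (2) apply a generic outlier rule
within each type on the log2 scale, then mean/median/sd of the
survivors.  The default outlier rule is median ± 3 scaled MADs — with
the convention that a zero MAD (all replicates tied) flags any
dissenter; the mean ± 3 sd alternative mirrors vendor-style rules and
is the right comparator when studying masking, because heavily inflated
replicates widen the sd band enough to escape it ("self-masking"), and
single-replicate types never have outliers.  Detection calls score each
type by the empirical fraction of negative-control summaries exceeding
it (expressed when the score < 0.05); at least 20 control values are
required for the empirical tail to be meaningful.

# The simulator

The generator exists to provide ground truth, and its defaults are the
package's fixed study conditions: a 60 × 60 bead segment at pitch 6 px,
150 bead-types assigned uniformly, 3% decoding failure, type means
drawn from $N(10, 1.5^2)$ on the log2 scale with replicate spread
$N(0, 0.25^2)$ — typical of replicate beads on expression arrays — over
a Gaussian background floor of 400 ± 10 pixel units (background
variability on real sections is low), spots rendered with the same
projected-sphere profile at radius 2.5 px, and non-decoded beads
fluorescing at a low fixed level of 150 (decoding failure is
independent of hybridization).  Test fixtures shrink the grid (12–35
beads per side) to keep the default suite fast; those sizes are stated
in the tests themselves.

Injectable artefacts record complete truth (every affected bead and
pixel): non-decoded cluster with a ×4 intensity halo two rings deep,
near-saturation bright bead with an enlarged spot, low pixels, whole
segment annotation shifts (recorded ID at $(r, c)$ becomes the true
type of $(r - \Delta r, c - \Delta c)$, so the remap search recovers
exactly the injected $(\Delta c, \Delta r)$), per-bead jitter of
recorded centres, channel-shift gradients, and local ID scrambles.

What the simulator does *not* emulate bounds what the tests show:
no scanner point-spread function or depth of field, no spatially
structured background, no chip-to-chip batch effects, and no model of
*why* real arrays show more twins than the random-assembly expectation.
Passing tests demonstrate that the algorithms recover what was
injected under these conditions — not that real vendor software would
produce byte-identical intensities, which is explicitly a non-goal
since the vendor's exact coefficients are unpublished.

# Numerical notes

* Degenerate inputs: grids must be non-empty; grid fits need ≥ 10
  non-collinear beads; windows clipped by the image raise errors that
  direct callers to `flag_out_of_image()` rather than silently
  truncating; types with no positive intensities summarize as missing,
  never zero.
* The remap search errors only when no candidate shift leaves two
  annotated beads on the grid; ties in the variance profile are broken
  by the first minimum in row-major order (on real profiles the minimum
  is unique, and the tests assert it).
* The locs dialect is a plain little-endian float32 stream with a
  4-byte magic and a record count; it is a stand-in with documented
  structure, not a reader for vendor binaries.
* Mask unions are idempotent; every flag carries a reason traceable to
  the diagnostic that produced it.
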