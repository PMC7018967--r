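---
title: "Optic-axis entropy for PS-OCT: model, processing chain and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic-axis entropy for PS-OCT: model, processing chain and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaentropy)
```

## The problem and the measurement model

Dermal fibrosis replaces the loose, heterogeneously oriented collagen of
normal skin with densely packed, uniformly oriented fiber bundles.
Polarization-sensitive OCT (PS-OCT) senses collagen through its
birefringence: the local retardance rate tracks collagen density, and the
optic axis (OA) tracks fiber orientation. Classical scalar metrics
(retardance, degree of polarization) depend strongly on the dermal depth at
which they are read out, which makes them fragile when dermal thickness
itself changes with disease. The quantity implemented here is instead the
*Shannon entropy of the OA orientation histogram* inside tissue voxels: low
when fibers are locally co-aligned (organized fibrosis), high when
orientations are heterogeneous (normal dermis, or the disorganized early
deposition phase), and — because orientation is stable across depth while
signal quality is not — much less depth-sensitive than retardance or DOP.

A fiber-based PS-OCT acquisition probes each A-line with two alternating
polarization states. The detected Jones vector from depth $z$ is modeled as

$$E_{det}(z) \;=\; U\, J_{cum}^{T}(z)\, J_{cum}(z)\, U \, E_{in}\, a(z),$$

where $J_{cum}(z)$ is the ordered product of the linear-retarder Jones
matrices of the tissue above $z$, the transpose encodes the reciprocal
double pass of a reflective geometry, $U$ is the unknown unitary of the
single-mode fiber (applied on both paths), and $a(z)$ the depth-decaying
backscattering amplitude. On the Poincaré sphere a linear retarder with
real-space fast axis $\phi$ acts as a rotation about the equatorial axis
$(\cos 2\phi, \sin 2\phi, 0)$; double pass doubles the rotation angle, and
the fiber conjugates everything by a fixed rotation.

## Processing chain and its parameters

| stage | parameter | default | why |
|---|---|---|---|
| Stokes filtering | Gaussian sd | 28 µm | speckle/noise averaging at the scale of a collagen bundle |
| local birefringence | depth offset $\Delta z$ | 20 µm | differential baseline; realized as `round(20/dz)` pixels |
| validity | $\varepsilon$ | $10^{-3}$ | below this cross-product/weight scale the axis is noise-dominated |
| entropy voxel | transverse block | 100 µm | biologically meaningful bundle-scale ROI |
| entropy voxel | depth window | 120–190 µm below surface | mid-dermis, below the epidermal junction |
| histogram | bins | 256 | fine enough that quantization does not limit discrimination |
| voxel validity | `min_count` | 16 | entropy below ~16 samples is bias-dominated |

The Gaussian filter is applied in the **two transverse dimensions only**:
axial smoothing would correlate the two depths used by the $\Delta z$
differential and bias the retardance estimate. The kernel is truncated at
3 sd and edges are handled by renormalized convolution (unit DC gain
everywhere); consequently, filtered values within 3 sd of the volume edge
are averages over fewer pixels.

**DOP.** The degree of polarization is computed as
$\lVert(Q,U,V)_{filt}\rVert / I_{filt}$, clamped to $[0,1]$ and averaged
over the two input states. (A literal "unfiltered over filtered" norm ratio
would be $\ge 1$; the conventional filtered-polarization-over-intensity
form is used instead and the discrepancy is documented rather than
resolved.)

**Two-state geometric solution.** With unit polarization vectors
$s_a(z), s_b(z)$ of the two probe states, the tissue slab between $z$ and
$z+\Delta z$ acts as a common rotation; its axis is obtained from the cross
product of the difference vectors
$D_{a,b} = s_{a,b}(z{+}\Delta z) - s_{a,b}(z)$, and its angle as the
weighted mean (weights: squared perpendicular components) of the per-state
rotation angles about that axis. Local retardance is reported as
**double-pass Stokes rotation per micrometer of depth** (deg/µm): a uniform
layer of single-pass rate $r$ reads out as $2r$. This convention is fixed
and stated because instrument papers rarely agree on one.

Two design choices here were genuinely open:

* **Probe states.** The two probes must be 90° apart on the Poincaré
  sphere, but *which* pair matters: with two linear probes every linear
  sample axis lies in the probes' common great circle, the two difference
  vectors are collinear at every depth, and the cross-product construction
  is degenerate everywhere — an unknown fiber rotation does not help,
  because the failure depends only on the relative geometry of axis and
  probes, which a global rotation preserves. The default is therefore
  linear horizontal + right circular, the classic non-degenerate
  configuration. The one remaining special case (sample axis exactly on the
  linear probe) is handled explicitly: the vanishing difference vector
  itself identifies the probe as the eigen-axis.
* **Axis sign.** A rotation by $\psi$ about $A$ equals one by $-\psi$ about
  $-A$, so the cross product alone leaves a sign ambiguity — and a sign
  flip shifts the projected angle of Eq. (2) below by $\pi/2$, which would
  corrupt orientation histograms if resolved frame-dependently (e.g. by a
  fixed hemisphere rule). The sign is therefore fixed *physically*: the
  axis about which the measured rotation angle is positive. This makes the
  recovered axis field exactly equivariant under fiber rotations, which is
  what the entropy's rotation invariance rests on. A hemisphere rule
  (Q ≥ 0, then U, then V) remains only as a tie-break for numerically
  degenerate pixels.

**Plane fit and angle projection.** All valid axes of an acquisition are
pooled (the fiber rotation is global within an acquisition) and the plane
through the origin containing them is found by least squares — the normal
is the smallest-eigenvalue eigenvector of $\sum_i v_i v_i^T$. In the plane
basis $(e_1, e_2)$ each axis becomes the scalar angle

$$\theta = \tfrac{1}{2}\,\mathrm{atan2}(S_2, S_1) \bmod \pi \in [0, \pi),$$

the half-angle undoing the sphere's angle doubling. The raw range of the
half-angle atan2 is $(-\pi/2, \pi/2]$; the modulo maps it onto $[0,\pi)$
while preserving the circular (period-$\pi$) topology of fiber
orientations. $e_1$ is the projection of the Q-axis onto the plane (U-axis
fallback when degenerate): the reference direction is arbitrary, which is
harmless because entropy is invariant under a common angle offset up to bin
quantization.

**Entropy.** Within each voxel the angles are binned into `n_bins` equal
left-closed bins over $[0,\pi)$ (an angle of exactly $\pi$ wraps to the
first bin) and $H = -\sum_{p_i>0} p_i \log_2 p_i$ is computed in bits.
Counts are normalized to probabilities first — raw counts would make $H$
depend on voxel occupancy and break cross-sample comparison — and
zero-count bins are dropped ($0\log 0 = 0$). Blocks overhanging the volume
edge are kept when ≥ 50% of their transverse area is inside. A
single-plane mode (one z-sample per A-line) is provided alongside the
volumetric depth-window mode; en-face maps of either kind can be searched
for the extreme-mean block (largest retardance / smallest entropy, sliding
stride of one voxel, ties broken in row-major order) to localize the most
fibrotic region. Volume means over voxels are unweighted; sample-count
weighting was considered and rejected to keep boundary voxels from
dominating.

## The phantom simulator

The phantom stands in for the instrument: layered linear retarders below a
flat or sloped surface, each layer with a single-pass retardance rate and a
transverse orientation field — `uniform`, `random` (smoothed Gaussian pair,
uniform marginal, configurable correlation length), `von_mises`
(wrapped-normal spatial field matched to an axial von Mises concentration
$\kappa$; exact von Mises sampling is used for direct angle draws), or
`radial` (fibers radiating from an injection site, with the same jitter
model). Signal amplitude decays exponentially with depth (default length
200 µm), additive complex Gaussian channel noise has sd 0.1 relative to a
unit surface reflection (≈ 17 dB intensity SNR at the surface — deliberately
modest, so that DOP degrades visibly with depth), and optional fully
developed speckle multiplies each pixel by a circular complex Gaussian
factor. All randomness derives from one seed; identical specs give
bit-identical volumes.

The preset cohort emulates a bleomycin skin-fibrosis time course (3
samples per group in the classic design): dermal thickness 200→400 µm and
retardance rate 0.15→0.55 deg/µm increase with injection day; orientation
progresses from `random` (control, day 7; 60 µm correlation) through a
*more* disorganized `random` field (day 14; 35 µm correlation — the early
deposition of randomly arranged fibrils) to concentrated `radial` patterns
(day 21, $\kappa=16$; day 28, $\kappa=64$). Preset grids are 56 × 56 × 64
px at 10 × 10 × 5 µm — a 0.56 mm field, large enough that blocks adjacent
to the radial singularity at the injection site are a small minority, with
an imaged depth (320 µm) covering the analysis window while thicker dermes
extend below it, as in practice. These sizes keep a full 15-sample cohort
run to well under a minute on one CPU.

What the phantom does **not** emulate: diattenuation, depolarization by
multiple scattering, confocal/roll-off PSFs, spectral sampling, speckle
*decorrelation* statistics of real tissue, epidermal layering, or
instrument galvo artifacts. Passing tests therefore demonstrate the
correctness and internal consistency of the processing chain and the
qualitative discriminative behavior of the entropy metric — not
instrument-grade realism of the simulated data.

## Numerical choices and degenerate inputs

* Surface detection thresholds at `floor + 4·sd`, both estimated robustly
  (median/MAD) from the quietest axial slice; A-lines without a crossing
  are masked, and the index map is regularized with a 5 × 5 median filter.
* Depth windows are half-open `[start, stop)` and referenced per A-line to
  the detected surface (the surface pixel has depth 0).
* $\Delta z$ is realized as a whole number of axial pixels; the actual
  micrometer value is recorded in the output.
* Plane fits with fewer than 3 valid axes, or with collinear axes, raise
  distinct errors; zero-birefringence inputs yield `valid = FALSE`
  everywhere rather than axes.
* Voxels under `min_count` valid samples and blocks under the 80% validity
  fraction (best-block search) are excluded, not imputed.
* Group statistics use one-way ANOVA with Tukey HSD post-hoc comparisons
  and paired/unpaired t-tests for two-group depth profiles; degenerate
  groupings produce the summary table with tests skipped and a notice.

## Known limitations

* The entropy floor of measured (as opposed to true) orientations is set by
  axis noise; at low DOP the metric saturates upward and contrast between
  organization levels compresses.
* The plane fit assumes sample axes are linear (coplanar on the sphere);
  strong out-of-plane components (chiral structures, deep multiple
  scattering) inflate the fit residual, which is reported and should be
  inspected.
* Retardance estimates on heterogeneous orientation fields are biased
  upward by decorrelation between the two depths of the differential; the
  1%-accuracy regime is homogeneous tissue.
* The half-angle projection reports orientation *within the fitted plane*;
  absolute real-space orientation is recoverable only up to the arbitrary
  in-plane reference.
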