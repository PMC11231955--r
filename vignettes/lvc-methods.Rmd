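---
title: "Lung vessel connectivity maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung vessel connectivity maps: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcmap)
```

## The problem

Lung lobe segmentation on chest CT is hard where it matters most: at the
lobar fissures, which are thin, often incomplete, and poorly contrasted.
The pulmonary vascular tree offers an indirect cue — each lobe has its
own vessel subsystem, and the subsystems run in characteristically
different directions. `lvcmap` turns that anatomical observation into a
computable prior: a voxel-wise unit-vector field (the *lung vessel
connectivity* map, LVC) that summarizes, for every vessel voxel, the
direction of its strongest connection back toward the heart. The field
can be handed to a segmentation model as extra input channels, and its
per-lobe orientation statistics can be tested directly.

## Fuzzy-connectedness propagation

The map starts from a fuzzy-connectedness (FC) computation over the
vessel intensity window. Voxels with HU strictly inside $(0, 200)$ are
*active*; everything else (parenchyma around $-850$ HU, air, bone) is
deactivated and excluded. Each active voxel $v$ gets an objectness score

$$g(v) = \frac{\mathrm{HU}(v) - 0}{200 - 0} \in [0, 1],$$

the affinity of an edge between neighbouring active voxels is
$\mu(u,v) = \min(g(u), g(v))$, and the connectivity strength of $v$ is
the max-min path strength

$$\mathrm{str}(v) = \max_{\pi: s \rightsquigarrow v} \; \min_{(a,b)\in\pi} \mu(a,b),$$

with $s$ the seed voxel (placed in the heart). The functional form of
$g$ is deliberately the simplest monotone choice over the window; it is
an argument of `compute_fc()` state, not a constant of the method, and
the max-min composition is what carries the structure.

We compute the fixed point by best-first expansion (Dijkstra with min
composition instead of summation) in compiled code. This visits each
voxel once and is equivalent to iterative relaxation; on a $96^3$
volume with a few thousand active voxels it runs in milliseconds.

Each reached voxel stores a *neighbour code* in $0..26$ — the
lexicographic index of the $3\times3\times3$ offset
($\mathrm{code} = 9(d_x{+}1) + 3(d_y{+}1) + (d_z{+}1)$, so 13 is the
voxel itself) — naming the direction from the voxel toward its
predecessor on an optimal path. The seed, deactivated voxels, and
unreached voxels all carry code 13, which makes them fixed points of
the walk below.

### Tie-breaking

Max-min strengths are highly degenerate: on any plateau of similar
intensities, many predecessors achieve the same path strength, and in
the limiting case of a uniform-intensity vessel *every* spanning tree
of the plateau is "optimal". A naive deterministic rule (e.g. lowest
code first) then produces predecessor trees that follow memory order
rather than geometry, and the resulting vectors are meaningless. We
therefore resolve ties with a cascade chosen to respect the physics of
the propagation:

1. higher path strength (the actual objective);
2. higher *predecessor* strength — the neighbour with the strongest
   connectivity of its own, which is what the neighbour code is meant
   to identify;
3. fewer propagation steps — the growing-wavefront order, which makes
   predecessor trees geodesic on exact plateaus;
4. lowest code, as the final deterministic fallback.

The cascade is fully deterministic, so identical inputs give
bit-identical maps; the suite asserts this, along with exact agreement
of the strengths with a brute-force max-min path closure on small
grids (the closure is tie-free, so only codes need the cascade).

## The generational walk and the LVC field

A single neighbour code can only express 26 directions. Following the
stored directions $x$ times (the $x$'th-generation strongest
neighbourhood) expands the expressible direction set to $26^x$ and
correspondingly shrinks the angular quantization error. The package
default is three generations. The LVC vector at $v$ is the normalized
displacement to the walk's endpoint,

$$\vec V(v) = \frac{V_f - v}{\lVert V_f - v \rVert},$$

or exactly $(0,0,0)$ when the walk does not move. Vectors are computed
only on the supplied vessel mask and are zero elsewhere. Displacements
are measured in voxel-index space by default because the walk itself is
a grid operation; `world_space = TRUE` rescales by the voxel spacing
before normalizing, which matters only for anisotropic acquisitions.

With the seed in the heart, walks flow from distal vessels toward the
hilum, so LVC vectors point on average toward the heart — the property
that makes per-lobe averages separable. On the bundled phantom the mean
dot product between LVC vectors and the unit direction toward the seed
is about 0.95.

## Per-lobe orientation statistics

For lobe $j$ the average orientation is the normalized resultant

$$\vec V_{sum}^j = \sum_{i: v_i \in j} \vec v_i, \qquad
  \vec V_{avg}^j = \vec V_{sum}^j / \lVert \vec V_{sum}^j \rVert,$$

flagged degenerate when the sum cancels. Averages are converted to
spherical coordinates (azimuth $\mathrm{atan2}(v_y, v_x)$, elevation
$\arcsin v_z$; azimuth 0 at the poles by convention) and lobe
separability is tested with a one-way MANOVA on the bivariate
(azimuth, elevation) response using Wilks'
$\Lambda = \det(W)/\det(W+B)$ and Rao's F approximation.

Two design choices deserve note:

* **Observation unit.** One (subject, lobe) average per observation,
  matching a cohort design where the claim is about lobes across
  subjects. A per-voxel variant would inflate the sample size with
  heavily dependent observations.
* **Azimuth circularity.** Azimuth is an angle; a linear MANOVA can
  manufacture a spurious lobe effect purely from the $-\pi/\pi$ cut.
  `lobe_manova()` therefore recentres azimuths on their circular mean
  before testing (toggleable with `center = FALSE`). Elevation is
  bounded away from wrap-around and is used as is.

The implementation is validated three ways: $\Lambda = 1$ exactly when
between-group scatter is zero, agreement to $10^{-10}$ with an
independent covariance-based recomputation, and agreement with
`stats::manova()`'s Wilks statistic and p-value. Type-I error on
label-permuted null data sits at the nominal 5% level (the suite
checks the rate over 200 permutations).

## Segmentation metrics

`dice()` is the standard overlap $2|A\cap B|/(|A|+|B|)$, defined as 1
when both masks are empty so batch tables never propagate NaN (the
report notes such lobes instead). `asd()` is the *symmetric* mean
surface distance: surfaces are mask voxels with at least one
face-adjacent (6-connectivity) outside voxel, grid borders counting as
outside; distances are Euclidean in millimetres via the voxel spacing,
computed with an exact separable distance transform (Felzenszwalb's
parabola envelope, extended to anisotropic spacing); the two directed
means are averaged. The symmetric form was chosen because it is
order-independent — the common convention when a directed variant is
not stated. `fissure_from_lobes()` derives fissure ground truth for
multitask training as the face-adjacency interface between anatomically
paired lobes (left oblique LU|LL, right oblique RU|RL and RM|RL, right
horizontal RU|RM), excluding lung–background contact.

## Preprocessing

The dataset-fingerprint steps mirror self-configuring segmentation
pipelines: componentwise median of the cohort's voxel spacings (lower
median on even counts, so the target is a spacing that occurs) as the
resampling target, trilinear interpolation for intensities and nearest
neighbour for labels, then intensity clipping to the $[0.5, 99.5]$
percentile range followed by z-scoring with the mean and SD of the
clipped population:

$$I' = \mathrm{clip}(I, I_{0.5p}, I_{99.5p}), \qquad
  I_{norm} = (I' - \mu)/\sigma.$$

Percentiles use linear interpolation between order statistics (R's
type 7), stated so that tests can be exact. The fingerprint can be fit
per volume or on a pooled dataset; pooled is the default. LVC maps are
never intensity-normalized — their components are already in $[-1,1]$ —
and `apply_normalization()` refuses them outright rather than silently
rescaling. The multitask loss combiner is the weighted sum
$L = w_l L_{lobe} + w_f L_{fissure}$ with default weights $(0.7, 0.3)$
and the $(0.5,0.5)$/$(0.9,0.1)$ ablation settings; network training
itself is out of scope.

## The phantom: what it emulates and what it does not

Real cohorts for this problem are clinical and private, so the package
ships a synthetic generator that reproduces the *geometry* the method
relies on: five wedge-shaped lobes around a hilum, a bright heart
sphere containing the seed, and per-lobe vascular trees grown along
planted unit directions with per-branch angular jitter, rasterized as
tubes. Defaults (chosen once, as the package's study conditions):

* grid $96^3$ at 1 mm isotropic spacing;
* planted directions: LU/LL/RU/RL at $\pm 45^\circ$ in the x–z plane
  and RM lateral-anterior $(0.966, 0.259, 0)$, every pair $\ge 45^\circ$
  apart;
* 8 branches per lobe, jitter up to $10^\circ$, tube radius 1.1 voxels;
* vessels at 100 HU mid-tree with an 80 HU hilum-to-distal contrast
  taper (distal vessels are thinner and dimmer in real CT; the taper
  also gives the propagation a physically meaningful gradient so that
  predecessor choices are not pure tie-breaks);
* parenchyma $-850$ HU, body $-1000$ HU, both safely outside the
  activation window; optional Gaussian noise is clipped so vessels
  never leave the window.

The tube radius matters more than one might expect: inside a wide
uniform tube the greedy descent drifts laterally toward corner offsets
before the wall stops it, biasing individual vectors. At radius 1.1 the
walk is forced to track the tube axis. A residual bias of roughly
$15{-}20^\circ$ remains for the RM lobe, whose planted direction is the
only one not aligned with a lattice diagonal — a genuine footprint of
the 26-neighbourhood angular discretization that three generations
shrink but do not remove. The recovery criterion (per-lobe average
within $20^\circ$ of the reversed planted direction) passes for
$\ge 96\%$ of (subject, lobe) pairs on 10-subject cohorts.

What the phantom does **not** model: airways, fissures as thin plates,
lesions, respiratory deformation, scanner noise texture, or anatomical
left–right asymmetry. Passing tests on the phantom therefore validate
the algorithmic chain — propagation, walk, statistics, metrics — not
clinical segmentation accuracy.

## Problem sizes used in validation

The shipped validation uses $5^3$ grids against the brute-force max-min
closure (50 grids), a $96^3$ phantom for structural invariants, a
10-subject cohort for orientation recovery and the MANOVA, 200 label
permutations for calibration, 100 random $16^3$ mask pairs against the
all-pairs surface-distance oracle, and a $64^3$ double pipeline run for
byte-identical determinism. These sizes were chosen so the full suite
exercises every claim at cohort structure comparable to a small
clinical study while remaining quick to run on one CPU.

## Known limitations

* The objectness function $g$ is a stand-in for a tuned vesselness
  cost; it is monotone and windowed, which is all the max-min
  composition needs, but it ignores contrast non-uniformity across
  scanners.
* Orientation averages treat antipodal vectors as opposites (they
  cancel), which is correct for flow-like fields such as LVC but would
  be wrong for axial (undirected) orientation data.
* The MANOVA treats (azimuth, elevation) as Euclidean after circular
  recentring; strongly dispersed direction data would call for proper
  directional statistics, which are out of scope here.
* `resample()` clamps at the grid border rather than padding, so a
  downsample–upsample round trip is only compared away from borders.
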