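---
title: "Evaluating traced root system architectures against virtual MRI ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating traced root system architectures against virtual MRI ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Root system architectures (RSAs) recovered from 3D soil imaging — MRI scans
of plants growing in soil columns — are traced either by software or by
humans, and the tracings must be scored against a known ground truth to
quantify how faithful they are. Two difficulties make this harder than it
sounds. First, a tracing is not a voxel mask but a *topological* object: a
forest of polyline organs (a taproot and its laterals), and a good score
should reward getting the organs right, not just overlapping the right
voxels. Second, a fair benchmark needs a ground truth that is known exactly,
which real scans never provide; the standard device is a *virtual MRI*: a
synthetic scan rendered from a simulated root system, optionally corrupted
with realistic water noise, so that every trait of the underlying RSA is
known to machine precision.

`rsaeval` implements that full loop: an RSML-based RSA data model, a
segment-distance matching procedure, penalized matched-length scores,
trait measures, a virtual MRI phantom generator, and a parametric RSA
generator with a tracing-error perturbation model so the whole pipeline can
be validated end to end in code.

## Matching model

Both architectures are decomposed into straight segments between
consecutive polyline nodes. For ground-truth segments indexed by $i$ and
traced segments by $j$, the base metric is the matrix

$$D_{ij} = \min_{x, y \in [0,1]} \lVert a_i(x) - b_j(y) \rVert_2,$$

the minimal Euclidean distance between the two closed segments. We compute
it in closed form (the clamped-quadratic closest-approach solution, solved
for all pairs at once), and keep a dense grid search over $(x, y)$ as an
independent test oracle. A formulation that optimizes over an open interval
of offsets along each segment direction differs from the closed-segment
minimum only on a measure-zero set of configurations, so the closed form is
used throughout.

Segment correspondences are assigned in two phases: every traced segment is
first matched to its nearest ground-truth segment when within the distance
threshold (yielding one-to-many sets per ground-truth segment); segments
still unmatched are then reconsidered against ground-truth segments holding
exactly one correspondence, under a configurable relaxation factor that
defaults to 1 (no relaxation — the conservative reading of an ambiguous
procedure; the factor exists precisely because the procedure admits more
than one reading). Ties always break towards the lowest segment index, so
matching is deterministic.

Root-level matching gives the scores their topological meaning. The
*cumulative distance* $d(m, n)$ between ground-truth root $n$ and traced
root $m$ is the length-weighted mean, over $n$'s segments, of each
segment's minimal distance to $m$'s segments. A length-weighted mean (rather
than a sum) keeps $d(m,n)$ on the scale of segment distances, so one
threshold works for long and short roots alike; unweighted-mean and sum
aggregations are available as options. Stage 1 solves the globally optimal
one-to-one assignment minimizing total cumulative distance (a rectangular
linear assignment, solved exactly; a greedy ascending-distance mode exists
for comparison) and keeps pairs with $d(m,n) \le d$. Stage 2 attaches each
remaining traced root to the already-matched ground-truth root of least
cumulative distance when within the threshold, which absorbs roots traced
as several fragments into a single one-to-many pair.

The threshold default follows the 15-voxel convention: at the default
0.05 cm voxel size, $d = 0.75$ cm. The API takes cm; `voxel_threshold_to_cm()`
converts.

## Scores

Let $I_{GC}$ be the matched ground-truth roots, $I_{TC}$ the traced roots
matched to them, and $L_{GC}, L_{TC}, L_{FN}, L_{FP}$ the whole-root length
totals of matched ground truth, matched tracing, unmatched ground truth and
unmatched tracing. Note $L_{GC} \ne L_{TC}$ in general: they sum different
root sets. The penalized scores are

$$R = \frac{L_{GC}}{L_{GC} + L_{FN} + \max(0,\, L_{GC} - L_{TC})}, \qquad
  P = \frac{L_{GC}}{L_{GC} + L_{FP} + \max(0,\, L_{TC} - L_{GC})}, \qquad
  F_1 = \frac{2PR}{P + R}.$$

The recall penalty activates when the matched tracing is shorter than the
matched ground truth (under-tracing); the precision penalty when it is
longer (over-tracing). A `literal-min` mode replaces $\max(0,\cdot)$ with
$\min(0,\cdot)$: that variant appears in print, but it evaluates to exactly
zero in the very situations described as penalized and can push scores
above 1, so the max form — which realizes the described penalties and keeps
both scores in $[0,1]$ — is the default, and the literal form is retained
behind a flag for forensic comparison. Zero denominators yield a score of
0, so an empty tracing scores $R = P = F_1 = 0$.

Scores are computed from whole-root lengths over the matched/unmatched root
sets, not from per-segment correspondences; the segment correspondences are
diagnostic output.

## Traits

`total_length()`, `average_root_length()`, `lateral_count()` (order ≥ 1
roots passing a minimum-length filter, default 3 cm — a 4 cm variant
circulates, so the cutoff is a parameter) and `inter_lateral_distance()`
mirror the measures usually reported for such benchmarks. Inter-lateral
distance is computed on the taproot only: each lateral's attachment is
expressed as an arc-length position along the taproot polyline — the
recorded attachment when present, otherwise the lateral's first node
projected onto the taproot — and the mean of consecutive differences of the
sorted positions is returned. Arc length was chosen over straight-line
distance between branch points because the measure is defined *along* the
organ; for a gently curved taproot the two differ by a few percent at most,
but arc length is the one that is invariant under bending.

## Virtual MRI phantom

`voxelize()` renders the RSA into a scalar volume by a partial-volume
heuristic: each segment is a capsule (linearly interpolated radius between
node radii, hemispherical caps), and each voxel's value is the fraction of
a regular `supersampling`³ sub-grid of points falling inside the union of
capsules (max of memberships, so branch junctions are not double-counted).
The estimate is deterministic — no Monte Carlo — so phantom volumes are
bit-reproducible. At the default supersampling of 4, the total signal mass
of an interior capsule reproduces the analytic capsule volume to within a
few percent (asserted in the tests at 5%).

`seed_water_noise()` emulates blob-like water signal inside a soil cylinder
(default 1.5 cm diameter, vertical, around the plant axis): signed unit
impulses at 2% of the cylinder voxels, followed by `weierstrass_transform()`
— convolution with a normalized isotropic Gaussian (default bandwidth
0.05 cm, one voxel), implemented separably with sparse band matrices and
zero padding, which preserves the mass of interior-supported fields.

No standard definition of MRI SNR applies to such a phantom, so the package
fixes one and uses it consistently on both sides: **SNR = peak smoothed
clean signal in the dilated noise region ÷ RMS of (noisy − clean) in the
region**, both evaluated after the Gaussian smoothing at the configured
bandwidth. `seed_water_noise()` calibrates the impulse amplitude per seed
against the post-smoothing RMS of its own unit-noise field, so the measured
SNR of the final phantom closes the loop at the configured value (default
4.3) by construction; `measure_snr()` verifies it independently on the
generated volumes. Since smoothing is linear, this calibration is exact up
to floating point, and the across-seed spread of the measured SNR is
essentially zero — the 20-seed average reported by the acceptance script is
a consistency check of generator and meter, not a statistical estimate.

## Synthetic root systems and tracing errors

The generator replaces a full functional–structural plant model on purpose:
the exact simulation parameterization behind any given study is typically
unpublished, so the fixtures here are parameter-transparent instead — every
trait of a generated system is known from its `generator_params()`. The
defaults describe a small faba-bean-like plant: one 15 cm taproot, 25
first-order laterals spaced 0.5 cm apart starting 1 cm below the collar,
lateral lengths 4 ± 1 cm (truncated at 0.5 cm), branching angles 65° ± 10°
at uniform azimuths, 0.25 cm node spacing, tortuosity 0.1 (the per-step
direction perturbation of a gravitropically biased random walk), taproot
diameter 0.2 cm and lateral diameter 0.1 cm, both tapering to 40% at the
tip. These are illustrative, realistic values chosen once — not a
replication of any particular simulated plant. A per-lateral diameter
override reproduces the classic "one very thin, nearly invisible root"
failure case. With all variability parameters at zero, every trait is
recovered exactly from its generating parameter (asserted at 2% and exact
counts in the tests), which is what makes the generator usable as a
ground-truth oracle.

`perturb_tracing()` applies artifact classes observed in human tracings, in
a fixed order so seeds reproduce: (1) lateral dropping, (2) per-node
Gaussian jitter (suboptimal pathing; note jitter also inflates traced arc
length, which is itself a realistic artifact and engages the precision
penalty), (3) tip over-/under-tracing by a signed fraction of root length,
(4) spurious short branches, (5) free-floating false-positive roots placed
by default inside the water-noise column (mimicking clicks into the water
signal). All-zero parameters return the input bit-exactly. What the model
does *not* emulate: systematic curvature bias, merged/split topology errors
at branch points, or spatially correlated jitter along an organ — so a pass
on synthetic tracings bounds, but does not certify, behaviour on human
data.

## Numerical choices and degenerate inputs

- Zero-length segments are rejected at validation; the distance code never
  sees them. The closed-form distance falls back to clamped endpoint
  projections when the segments are near-parallel (denominator below
  machine precision).
- Ties in nearest-segment and nearest-root selection break towards the
  lowest index; matching is fully deterministic given the distance matrix.
- The linear assignment is solved as maximum-weight bipartite matching on
  weights $C_{\text{big}} - d(m,n)$ with $C_{\text{big}}$ exceeding the sum
  of all finite costs, which makes maximum weight equivalent to maximum
  cardinality first, minimum total distance second; exhaustive enumeration
  on small instances is kept as a test oracle.
- Scores define 0/0 as 0. Inter-lateral distance is undefined (an error,
  `NA` in `rsa_traits()`) below two laterals; multiple taproots are an
  ambiguity error rather than a silent choice.
- The Weierstrass kernel is truncated at 4σ and renormalized; σ = 0 is the
  identity.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration (26-root systems,
roughly 550 segments, 0.05 cm voxels) for matching and scoring, and
deliberately small grids (a few hundred thousand voxels) for voxelization
and noise tests, where the behaviour under test is resolution-independent.
The jitter-monotonicity property uses 20 seeds per jitter level
{0, 0.05, 0.1, 0.2, 0.4} cm; the SNR contract is checked over 20 noise
seeds. The acceptance script regenerates the full-size default phantom
(about 10⁷ voxels) and reports the 20-seed mean measured SNR.

## Known limitations

- The matched-length scores are insensitive to geometry errors *within* a
  matched root once it is within threshold — a wiggly but matched tracing
  scores the same R as a straight one (though length inflation still hits
  P through the penalty).
- Root matching compares whole roots; a tracing that merges two laterals
  into one polyline is scored as one matched root plus one false negative,
  which is the intended reading but not the only defensible one.
- The phantom emulates partial-volume signal and water noise only: no
  relaxation physics, coil profiles, slab stitching, or ferromagnetic
  signal gaps.
- RSML time-series annotations are out of scope; one static scene per file.
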