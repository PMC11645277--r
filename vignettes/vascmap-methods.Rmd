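---
title: "Decoding combinatorial smFISH and quantifying vessels with vascmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding combinatorial smFISH and quantifying vessels with vascmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascmap)
```

## The measurement model

Combinatorial smFISH encodes each gene as a binary code over imaging rounds
and color channels. With the default geometry — eight rounds, two channels —
a code has 16 slots, of which a fixed number (weight, default 4) are "on".
A transcript is a diffraction-limited fluorescent spot that appears at the
same physical position in exactly the on-bit images of its gene's code.
Decoding therefore amounts to (i) finding spots, (ii) aligning rounds so a
position means the same thing in every image, (iii) reading each voxel's
16-value intensity profile and matching it to the codebook, and (iv) turning
matched pixel groups back into discrete transcript calls.

Because a fraction of valid codes is deliberately left unassigned
("unused codes"), the decoder carries an internal false-positive control:
signals that match an unused code cannot be real transcripts. The
specificity ratio reported by `estimate_specificity()` is the per-code rate
of unused-code hits divided by the per-code rate of used-code hits; 0 means
perfectly specific decoding, 1 means assignments are indistinguishable from
chance.

Downstream, transcripts are aggregated on a square tile grid (50 px,
about 7 µm at the instrument's pixel size) rather than segmented into
cells: in tissues whose cells span up to 100 µm and lack reliable membrane
segmentation signal, fixed bins give a deterministic, comparable unit of
co-expression. Marker rules subset bins into compartments (e.g. arterial
endothelium = VWF and GJA5 co-expressed), single-linkage clustering turns
marker-positive bins into vessel objects, and bin count is the caliber
proxy: vessels with more than 30 bins are "larger", the rest "smaller".
Group differences in percent-expressing and mean expression (over
expressing bins only) are tested with two-sided Wilcoxon rank-sum tests,
Benjamini–Hochberg adjusted across all tests of a run.

## Codebook generation

`make_codebook()` selects fixed-weight codes under a minimum pairwise
Hamming distance. Two equal-weight codes always differ in an even number of
bits, so a requested minimum of 3 or 4 means "distance at least 4", i.e. no
two codes may share more than `weight - 2` on-bits. When the code length is
a power of two we draw from the parity pool: codes whose on-bit positions,
read as vectors in GF(2)^m, XOR to zero. Two distinct parity codes can
never differ in a single on-bit move, so the pool guarantees distance >= 4
while reaching the maximal constant-weight code size (140 codes of weight 4
in 16 slots — comfortably above the 120 needed for 100 genes plus 20 unused
codes). For other geometries, or stricter distances, a seeded randomized
greedy selection with restarts is used; the final selection is always
re-verified against the distance bound. Generation is deterministic per
seed.

## Spot detection choices

The detection contract fixes the budget (per-plane maxima capped at
`floor(area_um2 * 0.5)`, a volume-based feature target) and the brightness
attributes, but leaves their estimators open. The package's choices:

* a *local maximum* is strictly greater than every pixel within a square
  radius of 2 px;
* `Bback` is the median of an annulus of inner radius 3, outer radius 5 px;
  `Bperi` is the mean of the 8-neighbor ring;
* maxima on adjacent planes within 2 px in xy form a z-group; singleton
  groups are discarded (a real 3D spot spans at least two planes at the
  axial sampling this assay uses);
* the iterative filter raises one threshold scalar applied jointly to
  `Babs - Bback` and `(Bperi - Bback) / 0.25` by bisection (<= 30
  iterations) until at most the target number of groups survives with >= 2
  members. Ties in brightness break by (z, y, x) order, so detection is
  deterministic;
* each surviving group contributes its brightest member, refined to
  sub-pixel position by a background-subtracted 3x3 intensity centroid.
  The refinement is a centroid, not a Gaussian fit; it exists because
  rigid registration averages many correspondences and profits from
  feature positions better than the voxel grid, whereas transcript calls
  remain voxel-level.

## Registration

Rounds are aligned to round 1 with rigid ICP: mutual-nearest-neighbor
correspondences, a closed-form orthogonal Procrustes update, convergence at
rms change < 1e-6 or 100 iterations. One property of this assay shapes the
variant: each round images only the transcripts whose codes are "on" in
that round, so two rounds share roughly half their spots and naive ICP gets
dragged by spurious correspondences. Each update therefore keeps the best
40% of mutual pairs by current distance and further drops pairs beyond
3x the median kept distance. On full-overlap clouds this reduces to exact
ICP (a planted 3° / (5, −2, 1) px offset on 200 points is recovered to
machine precision); on partially overlapping rendered rounds it recovers
planted offsets to under 0.2 px mean error. Axial accuracy is limited by
plane quantization: z offsets are recovered to the nearest plane, which is
why the registered stacks tolerate sub-plane axial drift rather than
correct it.

Stacks are resampled under the fitted transform by tri-linear
interpolation (out-of-bounds voxels read 0), with the interpolation plan
computed once per round and shared by its channels.

## Decoding choices

The profile filter realizes "variance from zero normalized by total
brightness" as the scale-invariant concentration score
`s = n * sum(v^2) / sum(v)^2`: a flat profile scores 1, a one-hot profile
scores `n`, a clean weight-w code scores `n / w` (4 of 16 gives 4). The
default cutoff 2 sits between flat background (1) and the ideal code
response (4). Code matching uses cosine similarity with a 0.7 floor and a
unique-argmax tie rule, making assignments invariant to uniform intensity
scaling. Pixel groups use 6-connectivity; a group survives if it has at
least two voxels, every member touches another face-on, and its bounding
box spans at least 2 px along at least two axes — the interpretation
adopted for "number of dimensions with size of two pixels".

Transcript localization takes *all* local 3D maxima of the summed on-bit
intensity within a group (26-neighborhood, plateau ties broken by linear
index), so two same-gene molecules a few pixels apart yield two calls
rather than one merged call; each candidate must be supported by an
intensity local maximum within 2 px in at least `weight - 1` of its on-bit
images. All thresholds (`min_score`, `min_match`, `k_required`,
connectivity radii) are exposed as arguments.

## What the synthetic generator emulates — and what it does not

`make_vessel_scene()` plants vessel cross-sections as annular rings on the
50-px tile lattice. Every ring tile emits one pan-endothelial (VWF) and one
type-marker transcript (GJA5 for arteries, ACKR1 for veins), placed
uniformly inside the tile; a designated caliber gene (SULF1 analogue) is
emitted per tile as a Bernoulli draw — rate 0.6 in vessels whose ring
exceeds the caliber threshold, 0.2 otherwise. These defaults give the
planted effect the direction and a magnitude comparable to what the
percent-expressing comparison is meant to detect, while leaving the
mean-expression-per-expressing-bin comparison null. Background transcripts
are uniform in space and over the gene panel. `render_rounds()` draws each
transcript as a Gaussian spot (sd 1.2 px lateral, 0.8 plane axial —
the smallest structure the detector must resolve) into its on-bit images,
applies per-round rigid offsets from round 2 on, and adds constant
background plus Gaussian noise.

The generator does not emulate tissue autofluorescence, chromatic
aberration, depth-dependent PSF changes, probe-efficiency differences
between genes, or optical crowding beyond what random placement produces.
Passing tests on these scenes therefore demonstrate the correctness of the
algorithms under the stated image model, not instrument-level performance
on tissue. Two deliberate consequences: decoding recovery is only expected
to be complete when spots are resolvable (the bundled fixtures enforce a
minimum spot separation of about 7 px), and same-gene molecules closer
than the PSF merge — as they would physically.

## Statistics

`compare_groups()` delegates to the standard two-sided Wilcoxon rank-sum
test: exact enumeration when the smaller group has at most 8 observations
and there are no ties, tie-corrected normal approximation with continuity
correction otherwise; when every observation is tied the test carries no
evidence and p = 1 is returned. `bh_adjust()` validates its input and
applies the Benjamini–Hochberg step-up rule; the adjustment family is all
tests of one comparison run. Because the caliber boxplots report
"expressing bins only", `compare_vessel_groups()` offers both the
per-vessel variant (each vessel one number — the primary analysis) and a
pooled-bin variant (each expressing bin one count), labeled
`mean_expressing_pooled_bins`, so the replicate unit is always explicit.

## RNAscope background chain

The three steps run in fixed order: subtract a σ = 50 Gaussian blur of the
raw image (negatives clipped to 0 — the clipping is this package's choice),
subtract a radius-50 rolling-ball background, zero every value below the
8-bit floor of 40. The Gaussian is a separable convolution whose truncated
kernel is renormalized at the borders, so constant images are fixed points
at any image size. The rolling ball is implemented as grayscale opening
with a *flat* disc (membership `dx^2 + dy^2 <= r^2`) — the standard flat
structuring-element form of the classical operation — with in-bounds
(clamped) border semantics enforced by edge-replication padding around each
morphological step. EBImage performs the erosion and dilation; since its
grayscale morphology clamps data to [0, 1] the image is affinely normalized
and restored, which is exact for flat structuring elements. The output
contains no value strictly between 0 and the floor, a property the tests
assert directly.

## Problem sizes and budgets

Desk-scale runs use fields of 192–256 px square with 3–6 planes for
image-level fixtures (about 0.4–1.7 million voxels through the 16-image
decoder), 150–200 point clouds for registration, and 12-vessel scenes of
about 4800 x 2000 px binned at pitch 50 for the vessel statistics; these
sizes were chosen so the full test suite and the acceptance script each
complete in a few minutes on one CPU while leaving every algorithmic path
exercised at realistic densities. The caliber threshold is a parameter
(default 30 bins, the reported operating point); small-field end-to-end
fixtures scale it down together with the vessel geometry rather than
rendering multi-millimeter fields.

## Known limitations

* No error-correcting decoding: a profile that matches no code within the
  cosine floor is dropped rather than rescued by bit-flip search.
* Registration is globally rigid; per-tile deformation is out of scope.
* Axial (z) drift is corrected only to the nearest plane.
* `estimate_specificity()` is undefined when no used-code hits exist; the
  result is flagged rather than silently zero.
* The rank-sum exact path requires tie-free data; counts data with heavy
  ties always take the corrected normal approximation.
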