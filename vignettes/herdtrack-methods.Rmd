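---
title: "Tracking a herd from detections: models and methods in herdtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a herd from detections: models and methods in herdtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtrack)
```

## The problem

Long-term monitoring of cattle on a pasture — for welfare, health, or
estrus detection ahead of artificial insemination — requires knowing
*which* animal is where over hours of video. Modern detectors localise
animals per frame very reliably, but they carry no notion of identity:
tracking-by-detection is the task of stitching per-frame boxes into
persistent identities. Black cattle make this unusually hard. The animals
are nearly identical in appearance, change posture frequently (standing
versus lying changes the box shape abruptly), pack densely so that boxes
overlap and detectors merge neighbours, and any individual can disappear
behind a larger animal for seconds at a time.

`herdtrack` implements two trackers over a common geometry and
evaluation core, plus the machinery needed to test them without access
to farm video:

* a **light-weight geometry tracker** that associates detections by a
  motion-and-shape cost, with a periodic re-matching stage that lets
  identities survive occlusion gaps;
* a **SORT-family tracker** with a constant-velocity Kalman filter, a
  bounded appearance gallery and a Tentative/Confirmed/Deleted track
  lifecycle;
* an **appearance stage**: a deterministic 128-dimensional embedding, an
  architecture descriptor for the convolutional re-identification
  network the embedding stands in for, and an unsupervised identity
  split for building re-ID datasets from raw detections;
* **CLEAR evaluation** (MOTA, identity switches, fragmentations) and
  detection metrics (precision/recall/F1, AP, mAP);
* a **herd simulator** that generates ground truth and corrupted
  detections under a controlled error model.

## The association cost

For a track with recent history of boxes $(x_i, y_i, w_i, h_i)$ at steps
$i$, and a candidate detection appended as the current step, the cost of
the pairing is

$$\mathrm{COST} = L_{dist} + Ar_{dist},$$

where $L_{dist}$ is the mean Euclidean distance between consecutive box
centroids over the last $N$ steps and $Ar_{dist}$ is the mean absolute
change of the aspect ratio $Ar = w/h$ over the same window. $L_{dist}$
is in pixels and $Ar_{dist}$ is dimensionless; they are summed raw,
which keeps the formula simple and makes the location term dominant at
ordinary scales — optional weights `weights = c(w_L, w_Ar, w_mask)`
are exposed for anyone who wants to normalise, and a third channel (the
mean absolute change in segmentation-mask area) is computed when masks
are available but carries weight 0 by default, since shape and location
already decide every case we have examined and mask areas are detector
dependent.

Two reading choices deserve a note. First, the window: the sum runs over
the last $N$ *consecutive* steps ending at the candidate, divided by
$N$, i.e. an average step length; $N$ defaults to 5 and is configurable
(`history_window`). Second, gaps: when a track has missed frames, its
stored entries are treated as consecutive steps regardless of the frame
gap between them. This is deliberate — it makes the cost of re-attaching
to a stationary animal after an occlusion near zero, which is exactly
the case re-matching must handle — but it also means a long gap over a
*moving* animal is judged as one giant step and will fail the gate,
which is the honest failure mode of any geometry-only tracker.

IoU (intersection over union) between the candidate and the track's most
recent box is computed alongside and exposed as a second gate
(`iou_gate`, default 0, i.e. disabled: association is cost-driven).

### Gates and their calibration

The cost gate rejects associations no plausible motion could produce.
The paper-style cost has no intrinsic scale, so the gate must be
calibrated against the motion model: under the default simulator scale a
fast walk moves a box about 6 px/frame, and the default
`cost_gate = 25` is roughly four times that. Because the cost averages
the candidate step with up to $N-1$ historical steps, a gate of $g$
admits single-step jumps up to about $g \cdot N$ pixels from a
previously smooth track; 25 therefore rejects jumps to a neighbouring
animal (body spacing is well above $25 \times 5$ px only for distant
animals, but the *averaged* competing costs of true continuations are an
order of magnitude smaller, so the optimal assignment takes the right
pair whenever it is feasible). Users tracking at other image scales
should scale the gate accordingly.

## Matching and the assignment problem

Per frame, every active track is scored against every detection and a
one-to-one assignment is chosen that (1) uses only pairs passing both
gates, (2) maximises the number of matched pairs, and (3) among such
matchings minimises the total cost. The solver is the $O(n^3)$
augmenting-path Hungarian algorithm, implemented in the package because
no installed dependency provides a linear-sum-assignment solver; it is
verified in the test suite against exhaustive enumeration over all
feasible partial matchings (up to $6 \times 6$). Determinism: rows are
processed in creation order, so equal-cost optima resolve toward
lower track IDs and lower detection indices. A greedy
nearest-cost solver is available (`assignment = "greedy"`) as an
ablation.

Maximum cardinality before minimum cost matters: a pure minimum-cost
partial matching would happily match nothing (cost 0). The
implementation pads infeasible pairs with a constant larger than any
feasible total, which makes the Hungarian optimum match as many feasible
pairs as possible first.

## Track lifecycle and re-matching

A track is **active** while matched, becomes **lost** when unmatched,
and is **deleted** once lost longer than `max_lost_age` frames (default
1500, one minute at 25 fps; the age test is strict, so a track exactly
at the limit survives). IDs are issued monotonically and never reused.

Unmatched detections receive a *provisional* fresh ID immediately — so
no detection goes unlabelled — and every `rematch_period` frames
(default 30, about 1.2 s at 25 fps) the re-matching stage runs:
provisional tracks are compared, with the same gated assignment, against
lost tracks, using the lost track's history extended by the provisional
track's *first* box (the detection whose appearance created it, closest
in time to the identity's loss). A successful match rewrites the
provisional track's records — in the in-memory buffer only — to the
lost track's ID and reactivates it; failures simply establish the fresh
ID. Three details here came out of adversarial testing rather than the
original design:

* Lost *provisional* tracks are valid re-match targets. Otherwise a
  track interrupted within the same 30-frame window it was created in
  can never reclaim its fragment, and the two resulting tracks duel for
  one animal indefinitely.
* Re-matching iterates in rounds at each boundary. A missed animal can
  fragment more than once between boundaries; after a fragment merges,
  the next fragment in the chain becomes mergeable and is picked up in
  the following round.
* A merge whose target was itself absorbed earlier in the same round is
  skipped and retried in the next round; executing it would resurrect a
  retired ID and emit duplicate records.

Re-matching never steals from an active track, and a merge is only
feasible when the fragment begins strictly after the target was last
seen, so one ID can never hold two boxes in one frame.

## The SORT-family tracker

The comparison tracker follows the classic deep-appearance SORT design:
an 8-dimensional constant-velocity Kalman state
$(c_x, c_y, a, h, \dot c_x, \dot c_y, \dot a, \dot h)$ with process and
measurement noise proportional to box height (`std_weight_position`
1/20, `std_weight_velocity` 1/160), two-stage association, and a
lifecycle with parameters `max_dist = 0.9`, `max_iou_distance = 0.8`,
`max_age = 1500`, `n_init = 1`, `nn_budget = 100`. Stage 1 matches
confirmed tracks to detections by the minimum cosine distance between
the detection's embedding and the track's gallery (a FIFO store capped
at `nn_budget`), gated at `max_dist`; stage 2 matches the remainder by
$1 - \mathrm{IoU}$ of predicted versus detected boxes, gated at
`max_iou_distance`. Both stages use the same gated Hungarian solver. The
matching cascade by time-since-update that the original deep-appearance
tracker used is omitted on purpose: its successor design dropped the
cascade, and a global per-stage assignment is simpler and at least as
good in our tests.

With `n_init = 1` a track is confirmed on its very first association —
an aggressive choice that suits high-precision detectors (nearly every
detection is a real animal) but would flood the output with clutter
tracks under a noisy detector; `max_dist = 0.9` is likewise a very
permissive appearance gate, effectively letting the Hungarian ranking
rather than the gate decide. Both are kept as defaults for comparability
and flagged here: with a noisier detector, raise `n_init` and lower
`max_dist`.

Records are emitted for confirmed tracks at the frames they are matched,
using the detection's box (not the filtered state): emitting raw
associated boxes keeps the output exactly comparable with the
light-weight tracker's.

## The appearance stage

The re-identification network that motivates the appearance stage is a
10-layer CNN taking 128 x 128 crops to a 128-dimensional embedding
(two 3 x 3 convolutions, max-pool, four residual blocks, dense
projection, batch norm, ReLU). The package ships this as a validated
*descriptor* (`reid_architecture()`): training it requires the original
imagery and a GPU, both out of scope. The descriptor's published
per-layer stride annotations are internally inconsistent with its output
sizes for the residual blocks (a known annotation convention problem
with residual downsampling), so `validate_reid_architecture()` derives
each layer's effective stride from consecutive output shapes and checks
integer downsampling, non-decreasing channels, and flat-width
consistency instead of trusting the stride column.

In its place the package uses a handcrafted embedding satisfying the
same contract (`embed_crop()`): the crop is cut into a 4 x 4 grid and
each cell contributes an 8-bin intensity histogram, L2-normalised into a
unit 128-vector. It is deterministic, which is the only property the
tracker's gallery logic requires, and on rendered scenes it separates
animals whose coats differ in shade or texture. It is *not* a trained
re-identifier: it has no invariance to illumination or pose, and
tests that pass with it demonstrate the plumbing and the benefit of *a*
discriminative appearance signal, not field-ready re-identification.

`split_identities()` implements the unsupervised grouping used to build
a re-ID dataset from raw detections: crops are processed in (frame,
detection) order; each joins the group whose mean embedding is most
similar if that similarity reaches the threshold, preferring among
passing groups one seen within the last 5 frames within 150 px (spatial
continuity), else founds a new group. The threshold enters only through
raw appearance similarity, so the procedure degenerates predictably:
threshold 0 yields a single group, any threshold above 1 yields
singletons. `export_reid_dataset()` writes folder-per-identity crops
with a deterministic 80/20 train/test manifest split keyed on a path
hash, so re-exports are idempotent.

## Evaluation

Detection quality: per-frame Hungarian matching of predictions to
ground truth maximising total IoU over pairs at or above the threshold
(default 0.5) gives TP/FP/FN; precision, recall and F1 follow. A ratio
with a zero denominator is returned as `NA` with a classed warning —
never a silent 0, which would corrupt aggregate tables. Average
precision uses the conventional confidence-descending greedy sweep and
all-points interpolation, and mAP averages AP over classes and, for
mAP@0.5:0.95, over the closed threshold grid 0.50, 0.55, ..., 0.95 —
the standard 10-point grid detectors report.

Tracking quality: the CLEAR accumulator keeps each ground-truth
identity's last matched predicted ID; pairings still valid at the gate
persist (preventing spurious switch counts from jitter), the remainder
is matched by gated Hungarian on IoU, and

$$\mathrm{MOTA} = 1 - \frac{\sum_t (FN_t + FP_t + IDSW_t)}{\sum_t GT_t}.$$

The error ratio itself is also returned. An identity switch is counted
when a ground-truth identity's matched predicted ID differs from the
last one it was matched with, gaps notwithstanding; a fragmentation is a
tracked-to-untracked transition that is later re-tracked (a gap that
runs to the end of the sequence is termination, not fragmentation). The
accumulator is verified in the tests against two independent oracles: a
brute-force enumeration counter in R and a separately written
NumPy/SciPy implementation, with exact agreement required on event
counts.

`count_tracked()` reports the number of predicted identities persisting
at least `min_length` frames (default 25 — one second), the per-clip
"animals found" count. `extract_contacts()` mines proximity contacts —
maximal runs of frames in which two identities' centroids lie within a
distance threshold, filtered by a minimum duration — and
`plot_trajectories()` draws the per-identity movement map; together they
are the behavioural endpoint the tracking exists for.

## The herd simulator

The simulator generates the conditions the trackers must survive, at
defaults chosen to emulate a fixed overhead camera over a paddock of
10-25 black cattle: 20 animals, 2560 x 2048 px arena, body boxes around
180 x 115 px with per-animal size variation, 25 fps implied throughout.
Motion is waypoint-seeking — each animal walks toward a private random
waypoint with Gaussian heading noise (sd 0.25 rad), alternating walking
and resting bouts (switch probability 0.01/frame), drawing a fresh
waypoint on arrival — which produces the smooth-but-occasionally-abrupt
paths that make frame-to-frame association nontrivial. Posture flips
(default 0.005/frame) jump the box between a standing shape and a wider,
taller lying shape. Animals repel each other below 0.8 body lengths,
as physical bodies must; boxes may still overlap (they are axis-aligned
hulls), but centroids cannot coincide, which keeps ground truth
physically meaningful.

Detector corruption is applied independently per frame: each box dropped
with `miss_rate`; survivors jittered (centroid and size, sd
`jitter_sd` = 2 px); surviving boxes overlapping at IoU
`occlusion_merge_iou` (default 0.6) or more collapse into one merged
hull detection carrying the union area as `mask_area` — the signature
failure of detectors on touching animals; Poisson(`fp_rate` = 0.2)
clutter boxes per frame; confidences uniform in [0.5, 1] (detector
confidences are near 1 and only their ranking matters to the rank-based
metrics, so the distribution is immaterial and kept simple). All
randomness flows from the single config seed; the simulator saves and
restores the caller's RNG state.

`crossing_scenario()` scripts the canonical hard case — two animals
crossing paths while the detector merges them — and `render_frame()`
rasterises scenes as dark textured ellipses on a speckled lighter
ground, with each identity's coat texture (base shade, stripe frequency,
direction, contrast) derived deterministically from its ID and anchored
to the body centre so it moves with the animal. Rendering exists to
exercise the appearance stage; it is deliberately not photorealistic —
no fisheye distortion, no illumination cycles, no perspective change —
so appearance results transfer to real imagery only qualitatively.

What passing tests on the simulator do and do not show: they show the
association logic, ID lifecycle, re-matching, metric bookkeeping and
appearance plumbing are correct under a controlled error model whose
every knob is known; they do not show robustness to real detector error
structure (correlated misses, duplicate boxes, box drift), lighting, or
true cattle appearance, all of which require real footage.

## Problem sizes and test design

The test suite runs the full pipeline at the scales the package is meant
for: metric equivalence against the independent oracles on 100 random
scenarios of 5-25 targets over 200 frames; perfect-input recovery on 20
targets over 1500 frames (one minute of video), which must give exactly
MOTA 1.0 with zero switches; assignment optimality on 1000 random gated
instances up to 6 x 6; a scripted 40-frame occlusion healed at the next
re-match boundary; degradation monotonicity of mean MOTA over 10 seeds
at miss rates 0, 0.05, 0.10, 0.20 (10 cattle, 250 frames) for both
trackers; and 20 rendered crossing scenarios on which the appearance
stage must not increase total identity switches over IoU-only tracking.
These sizes were chosen to exercise every code path at full herd density
while keeping the whole suite comfortably runnable on a laptop.

## Known limitations

* Geometry-only re-matching cannot recover an identity that moved far
  during its occlusion; that is what the appearance stage is for, and
  the handcrafted embedding is a stand-in, not a trained re-identifier.
* The cost sums pixels with dimensionless aspect units; at very small or
  very large image scales the default gate and weights need rescaling.
* The CLEAR accumulator follows the switch-counting convention in which
  a re-acquired identity that returns under its old predicted ID after a
  gap counts no switch; tools following other conventions may
  report slightly different IDSW on the same data.
* The simulator's false positives are uniform clutter, while real
  detectors produce structured false positives (double boxes, shadows);
  FP-driven results should be read qualitatively.
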