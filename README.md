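# herdtrack

Multi-object tracking and evaluation for livestock surveillance video.

Modern detectors (YOLO, Detectron-style instance segmentation) localise
cattle in every frame of a barn camera but carry no notion of identity.
`herdtrack` is the association layer on top: it stitches per-frame
bounding-box detections into persistent animal identities, evaluates the
result against ground truth, and — because farm video is rarely
shareable — ships a synthetic herd simulator so the whole pipeline is
testable end to end. It is aimed at precision-livestock researchers who
have detector output in hand and need trajectories, identity-switch
counts, and contact/behaviour summaries out the other end.

## What is inside

**Light-weight geometry tracker.** Detections are associated frame to
frame by a cost combining two windowed step distances,

    COST = L_dist + Ar_dist

where `L_dist` is the mean Euclidean distance between consecutive box
centroids over the last *N* steps (pixels) and `Ar_dist` the mean
absolute change in the aspect ratio `Ar = w/h` (dimensionless), solved
as a gated minimum-cost one-to-one assignment (Hungarian). Unmatched
detections get provisional IDs; every 30 frames a re-matching stage
reconciles them against lost tracks so identities survive occlusion.

**SORT-family tracker.** A constant-velocity Kalman filter on
`(cx, cy, a, h)`, two-stage association (appearance gallery with cosine
distance, then IoU), and the Tentative/Confirmed/Deleted lifecycle with
defaults `MAX_DIST 0.9`, `MAX_IOU_DISTANCE 0.8`, `MAX_AGE 1500`,
`N_INIT 1`, `NN_BUDGET 100`.

**Appearance stage.** A validated descriptor of the 10-layer re-ID CNN
(128 x 128 crops to a 128-d embedding), a deterministic handcrafted
embedding with the same contract for desk-scale work, an unsupervised
identity split for building re-ID datasets, and a folder-per-identity
exporter with a deterministic 80/20 manifest split.

**Evaluation.** CLEAR tracking metrics — `MOTA = 1 − (ΣFN + ΣFP +
ΣIDSW)/ΣGT`, identity switches, fragmentations — plus detection
precision/recall/F1, AP and mAP@0.5:0.95, per-clip tracked-animal
counts, proximity-contact extraction and trajectory maps. The CLEAR
accumulator is cross-checked in the test suite against a brute-force
counter and an independent NumPy/SciPy implementation.

**Simulator.** Waypoint-seeking herd motion with posture flips and body
exclusion in a 2560 x 2048 arena, plus a detector-corruption model
(misses, jitter, occlusion merging, clutter) and a renderer with
per-identity coat textures. Everything is driven by one seed.

**I/O and CLI.** MOT-Challenge and YOLO text formats, YAML configs, and
a command-line entry point (`inst/cli/herdtrack`, or `ht_main()` from R)
with `simulate`, `track`, `evaluate` and `reid-split` subcommands.

## Worked example

```r
library(herdtrack)

# a 10-head herd for 20 s at 25 fps, with detector corruption
cfg <- sim_config(n_cattle = 10, n_frames = 500, miss_rate = 0.05,
                  seed = 4)
sc  <- simulate_scenario(cfg)

tracks <- track_lite(sc$detections, lite_config(), n_frames = 500)
evaluate_tracking(sc$gt, tracks)
#> Tracking report: MOTA 0.9256 | IDSW 13 | FN 256 | FP 103 | GT 5000 |
#>   frag 243 | tracks >= min length: 10
```

Read it as: of 5000 ground-truth boxes, 256 were never covered (mostly
the simulated detector misses), 103 predicted boxes were spurious, and
identities were confused 13 times, giving a multi-object tracking
accuracy of 92.6%; all 10 animals were recovered as persistent tracks.
The same detections through the Kalman tracker:

```r
sorted <- run_sort(sc$detections, sort_config(), n_frames = 500)
evaluate_tracking(sc$gt, sorted)
#> Tracking report: MOTA 0.9282 | IDSW 0 | FN 256 | FP 103 | GT 5000 |
#>   frag 243 | tracks >= min length: 10
```

Contacts and movement maps for behaviour analysis:

```r
contacts <- extract_contacts(tracks, distance_threshold = 250,
                             min_duration = 25)
plot_trajectories(tracks, arena = cfg$arena)
```

From the shell:

```sh
Rscript inst/cli/herdtrack simulate --seed 5 --n-cattle 20 \
    --out-gt gt.txt --out-dets dets.txt
Rscript inst/cli/herdtrack track --method lite --dets dets.txt --out tracks.txt
Rscript inst/cli/herdtrack evaluate --gt gt.txt --pred tracks.txt \
    --report report.json
```

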