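# Scenario builders shared across test files.

# a randomized tracking instance for metric tests: simulator ground truth
# plus a perturbed prediction set with known kinds of errors (drops,
# jitter, identity swaps, clutter tracks)
make_tracking_instance <- function(seed, n_targets = NULL, n_frames = 200L) {
  set.seed(seed)
  if (is.null(n_targets)) n_targets <- sample(5:25, 1)
  cfg <- sim_config(n_cattle = n_targets, n_frames = n_frames,
                    miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                    occlusion_merge_iou = 1, seed = seed)
  gt <- simulate_herd(cfg)
  pred <- gt
  # localization jitter (keeps IoU high, perturbs matching costs)
  pred$x <- pred$x + rnorm(nrow(pred), 0, 2)
  pred$y <- pred$y + rnorm(nrow(pred), 0, 2)
  # random drops
  pred <- pred[runif(nrow(pred)) > 0.05, , drop = FALSE]
  # identity swaps: from a random frame on, swap two ids
  for (k in seq_len(sample(0:3, 1))) {
    ids <- sample(seq_len(n_targets), 2)
    from <- sample(seq_len(n_frames), 1)
    sel1 <- pred$id == ids[1] & pred$frame >= from
    sel2 <- pred$id == ids[2] & pred$frame >= from
    pred$id[sel1] <- ids[2]; pred$id[sel2] <- ids[1]
  }
  # clutter tracks with fresh ids
  n_clutter <- sample(0:2, 1)
  for (k in seq_len(n_clutter)) {
    f0 <- sample(seq_len(n_frames - 20L), 1)
    len <- sample(5:20, 1)
    pred <- rbind(pred, data.frame(
      frame = f0:(f0 + len - 1L), id = n_targets + k,
      x = runif(1, 0, cfg$arena[1] - 200), y = runif(1, 0, cfg$arena[2] - 150),
      w = 180, h = 115, conf = 1))
  }
  pred <- pred[order(pred$frame, pred$id), , drop = FALSE]
  list(gt = gt, pred = pred)
}

# scripted occlusion: one animal's detections removed for a frame span
make_occlusion_scenario <- function(seed = 5L, n_cattle = 5L,
                                    n_frames = 120L, hide_id = 3L,
                                    hide_frames = 20:59) {
  cfg <- sim_config(n_cattle = n_cattle, n_frames = n_frames,
                    miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                    occlusion_merge_iou = 1, speed_scale = 1, seed = seed)
  gt <- simulate_herd(cfg)
  dets <- gt[!(gt$id == hide_id & gt$frame %in% hide_frames), , drop = FALSE]
  dets$id <- -1L
  list(gt = gt, dets = dets, cfg = cfg)
}

unit_embedding <- function(i, dim = 128L) {
  v <- numeric(dim); v[((i - 1L) %% dim) + 1L] <- 1
  v
}

# one-hot embedder keyed on ground-truth identity: emulates a perfectly
# discriminative appearance model for detections that coincide with gt
make_gt_embedder <- function(gt) {
  force(gt)
  function(t, dets) {
    g <- gt[gt$frame == t, , drop = FALSE]
    emb <- matrix(0, nrow(dets), 128)
    for (j in seq_len(nrow(dets))) {
      d2 <- (g$x + g$w / 2 - (dets$x[j] + dets$w[j] / 2))^2 +
        (g$y + g$h / 2 - (dets$y[j] + dets$h[j] / 2))^2
      emb[j, ] <- unit_embedding(g$id[which.min(d2)])
    }
    emb
  }
}
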