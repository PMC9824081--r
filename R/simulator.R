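#' Herd simulator configuration
#'
#' Parameters of the synthetic herd: long-lived targets in a fixed arena
#' seen from a fixed overhead camera, waypoint-seeking smooth motion with
#' occasional abrupt posture changes, and a detector-corruption model
#' (misses, localisation jitter, occlusion merging, clutter). Defaults
#' emulate a barn paddock filmed at 2560 x 2048 and 25 fps with 10-25
#' animals: 20 animals, body boxes around 180 x 115 px, walking steps of a
#' few pixels per frame.
#'
#' @param n_cattle Number of animals (default 20).
#' @param n_frames Sequence length in frames.
#' @param arena `c(width, height)` in pixels (default `c(2560, 2048)`).
#' @param speed_scale Mean step length of a walking animal, pixels/frame
#'   (default 4).
#' @param posture_change_rate Probability per frame of a posture flip
#'   (standing/lying), which jumps the box aspect ratio (default 0.005).
#' @param body_size Mean `c(w, h)` of a standing animal's box in pixels.
#' @param miss_rate Probability a ground-truth box is dropped by the
#'   detector (default 0.05).
#' @param fp_rate Expected number of clutter (false-positive) boxes per
#'   frame (default 0.2).
#' @param jitter_sd Localisation noise sd in pixels applied to centroid
#'   and size of surviving detections (default 2).
#' @param occlusion_merge_iou Ground-truth pairs overlapping at or above
#'   this IoU emit a single merged detection; `>= 1` disables merging
#'   (default 0.6).
#' @param seed Integer seed; every random draw in the simulator flows
#'   from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cattle = 20L, n_frames = 500L,
                       arena = c(2560, 2048), speed_scale = 4,
                       posture_change_rate = 0.005,
                       body_size = c(180, 115),
                       miss_rate = 0.05, fp_rate = 0.2, jitter_sd = 2,
                       occlusion_merge_iou = 0.6, seed = 1L) {
  stopifnot(n_cattle >= 1, n_frames >= 1, all(arena > 0),
            miss_rate >= 0, miss_rate <= 1,
            posture_change_rate >= 0, posture_change_rate <= 1,
            fp_rate >= 0, jitter_sd >= 0, speed_scale >= 0)
  if (n_cattle * prod(body_size) > 0.5 * prod(arena))
    stop("infeasible density: animals cannot fit the arena", call. = FALSE)
  structure(list(n_cattle = as.integer(n_cattle),
                 n_frames = as.integer(n_frames),
                 arena = as.numeric(arena), speed_scale = speed_scale,
                 posture_change_rate = posture_change_rate,
                 body_size = as.numeric(body_size),
                 miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd,
                 occlusion_merge_iou = occlusion_merge_iou,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate ground-truth herd trajectories
#'
#' Each animal seeks a random waypoint with Gaussian heading noise,
#' alternating between resting (near-zero speed) and walking bouts;
#' reaching a waypoint draws a new one. Boxes are clamped to the arena.
#' Posture flips (probability `posture_change_rate` per frame) jump the
#' box between a standing shape and a wider lying shape. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Ground-truth track records (`mot_records`): every animal
#'   present in every frame, `conf = 1`.
#' @export
simulate_herd <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cattle; tt <- cfg$n_frames
    W <- cfg$arena[1]; H <- cfg$arena[2]
    bw <- cfg$body_size[1]; bh <- cfg$body_size[2]
    # per-animal statics
    size_f <- stats::runif(n, 0.85, 1.15)      # body size variation
    speed_f <- stats::runif(n, 0.6, 1.4)       # temperament
    px <- stats::runif(n, bw, W - bw)
    py <- stats::runif(n, bh, H - bh)
    wx <- stats::runif(n, bw / 2, W - bw / 2)  # waypoints
    wy <- stats::runif(n, bh / 2, H - bh / 2)
    lying <- stats::runif(n) < 0.3
    walking <- stats::runif(n) < 0.5
    heading <- stats::runif(n, 0, 2 * pi)
    res <- vector("list", tt)
    for (t in seq_len(tt)) {
      # bout switching: short memory keeps motion smooth but not constant
      flip <- stats::runif(n) < 0.01
      walking <- ifelse(flip, !walking, walking)
      goal <- atan2(wy - py, wx - px)
      heading <- goal + stats::rnorm(n, 0, 0.25)
      step <- ifelse(walking,
                     pmax(0, stats::rnorm(n, cfg$speed_scale * speed_f,
                                          cfg$speed_scale / 4)),
                     abs(stats::rnorm(n, 0, 0.03 * cfg$speed_scale)))
      px <- px + step * cos(heading)
      py <- py + step * sin(heading)
      # body exclusion: animals steer around each other rather than
      # passing through, as physical bodies must
      if (n > 1) {
        d_min <- 0.8 * bw
        for (pass in 1:2) {
          dd <- as.matrix(stats::dist(cbind(px, py)))
          diag(dd) <- Inf
          close <- which(dd < d_min, arr.ind = TRUE)
          close <- close[close[, 1] < close[, 2], , drop = FALSE]
          if (!nrow(close)) break
          for (k in seq_len(nrow(close))) {
            i <- close[k, 1]; j <- close[k, 2]
            d <- max(dd[i, j], 1e-6)
            push <- (d_min - d) / 2
            ux <- (px[j] - px[i]) / d; uy <- (py[j] - py[i]) / d
            px[i] <- px[i] - push * ux; py[i] <- py[i] - push * uy
            px[j] <- px[j] + push * ux; py[j] <- py[j] + push * uy
          }
        }
      }
      # new waypoint when reached
      arrived <- (px - wx)^2 + (py - wy)^2 < (4 * cfg$speed_scale)^2
      nw <- sum(arrived)
      if (nw) {
        wx[arrived] <- stats::runif(nw, bw / 2, W - bw / 2)
        wy[arrived] <- stats::runif(nw, bh / 2, H - bh / 2)
      }
      # posture flips change the box aspect abruptly
      pf <- stats::runif(n) < cfg$posture_change_rate
      lying <- ifelse(pf, !lying, lying)
      w <- ifelse(lying, bw * 0.85, bw) * size_f
      h <- ifelse(lying, bh * 1.35, bh) * size_f
      px <- pmin(pmax(px, w / 2), W - w / 2)
      py <- pmin(pmax(py, h / 2), H - h / 2)
      res[[t]] <- data.frame(frame = t, id = seq_len(n),
                             x = px - w / 2, y = py - h / 2,
                             w = w, h = h, conf = 1)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    class(out) <- c("mot_records", "data.frame")
    out
  })
}

# exact union area of up to a handful of overlapping boxes
# (inclusion-exclusion truncated at pairs; exact for 2 boxes)
union_area <- function(boxes) {
  a <- sum(boxes$w * boxes$h)
  if (nrow(boxes) > 1) {
    pr <- utils::combn(nrow(boxes), 2)
    for (k in seq_len(ncol(pr))) {
      b1 <- boxes[pr[1, k], ]; b2 <- boxes[pr[2, k], ]
      ix <- min(b1$x + b1$w, b2$x + b2$w) - max(b1$x, b2$x)
      iy <- min(b1$y + b1$h, b2$y + b2$h) - max(b1$y, b2$y)
      if (ix > 0 && iy > 0) a <- a - ix * iy
    }
  }
  max(a, 0)
}

#' Corrupt ground truth into detector-like output
#'
#' Emulates an imperfect detector: each ground-truth box is independently
#' dropped with `miss_rate`; survivors receive Gaussian jitter on centroid
#' and size (`jitter_sd`); groups of surviving boxes that mutually overlap
#' at `occlusion_merge_iou` or more collapse into a single merged
#' detection spanning their hull, carrying the union of their areas as
#' `mask_area`; `Poisson(fp_rate)` clutter boxes per frame are added at
#' random positions; confidences are uniform in `[0.5, 1]`. Deterministic
#' given `cfg$seed` (a corruption-stage seed is derived from it).
#'
#' @param gt Ground-truth records from [simulate_herd()].
#' @param cfg The same [sim_config()].
#' @return Detections as `mot_records` (`id = -1`) with a `mask_area`
#'   column.
#' @export
corrupt_detections <- function(gt, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gt <- as.data.frame(gt)
  with_seed(cfg$seed + 1000003L, {
    W <- cfg$arena[1]; H <- cfg$arena[2]
    bw <- cfg$body_size[1]; bh <- cfg$body_size[2]
    frames <- split_frames(gt, cfg$n_frames)
    res <- vector("list", length(frames))
    for (t in seq_along(frames)) {
      g <- frames[[t]]
      keep <- g[stats::runif(nrow(g)) >= cfg$miss_rate, , drop = FALSE]
      boxes <- data.frame(x = numeric(0), y = numeric(0),
                          w = numeric(0), h = numeric(0),
                          mask_area = numeric(0))
      if (nrow(keep)) {
        cx <- keep$x + keep$w / 2 + stats::rnorm(nrow(keep), 0, cfg$jitter_sd)
        cy <- keep$y + keep$h / 2 + stats::rnorm(nrow(keep), 0, cfg$jitter_sd)
        w <- pmax(keep$w + stats::rnorm(nrow(keep), 0, cfg$jitter_sd), 4)
        h <- pmax(keep$h + stats::rnorm(nrow(keep), 0, cfg$jitter_sd), 4)
        boxes <- data.frame(x = cx - w / 2, y = cy - h / 2, w = w, h = h)
        boxes$mask_area <- boxes$w * boxes$h
        if (cfg$occlusion_merge_iou < 1 && nrow(boxes) > 1) {
          iou <- bbox_iou_matrix(boxes, boxes)
          # connected components of the occlusion graph
          comp <- seq_len(nrow(boxes))
          for (i in seq_len(nrow(boxes) - 1))
            for (j in (i + 1):nrow(boxes))
              if (iou[i, j] >= cfg$occlusion_merge_iou)
                comp[comp == comp[j]] <- comp[i]
          merged <- lapply(unique(comp), function(cc) {
            b <- boxes[comp == cc, , drop = FALSE]
            if (nrow(b) == 1) return(b)
            x1 <- min(b$x); y1 <- min(b$y)
            data.frame(x = x1, y = y1,
                       w = max(b$x + b$w) - x1, h = max(b$y + b$h) - y1,
                       mask_area = union_area(b))
          })
          boxes <- do.call(rbind, merged)
        }
      }
      n_fp <- stats::rpois(1, cfg$fp_rate)
      if (n_fp > 0) {
        fw <- stats::runif(n_fp, bw * 0.3, bw * 1.2)
        fh <- stats::runif(n_fp, bh * 0.3, bh * 1.2)
        fp <- data.frame(x = stats::runif(n_fp, 0, W - fw),
                         y = stats::runif(n_fp, 0, H - fh),
                         w = fw, h = fh)
        fp$mask_area <- fp$w * fp$h
        boxes <- rbind(boxes, fp)
      }
      if (nrow(boxes))
        res[[t]] <- data.frame(frame = t, id = -1L, boxes[c("x", "y", "w", "h")],
                               conf = stats::runif(nrow(boxes), 0.5, 1),
                               mask_area = boxes$mask_area)
    }
    out <- do.call(rbind, res)
    if (is.null(out)) {
      out <- empty_mot_records(); out$mask_area <- numeric(0)
    }
    rownames(out) <- NULL
    class(out) <- c("mot_records", "data.frame")
    out
  })
}

#' Simulate a complete scenario (ground truth + detections)
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_scenario"`: `gt`, `detections`, `config`.
#' @export
simulate_scenario <- function(cfg) {
  gt <- simulate_herd(cfg)
  structure(list(gt = gt, detections = corrupt_detections(gt, cfg),
                 config = cfg),
            class = "sim_scenario")
}

#' Scripted two-target crossing scenario
#'
#' Two animals approach from opposite sides, overlap mid-arena and walk
#' past each other. While their ground-truth boxes overlap at
#' `merge_iou` or more the detector reports one merged box, so a
#' geometry-only tracker must survive a coverage gap exactly when the
#' targets are most confusable. Used to probe identity preservation
#' through occlusion.
#'
#' @param seed Integer seed (controls jitter only; the paths are fixed).
#' @param arena `c(width, height)` pixels (default `c(640, 512)`).
#' @param n_frames Sequence length (default 80).
#' @param speed Pixels per frame along x (default 6).
#' @param body `c(w, h)` box size (default `c(90, 60)`).
#' @param merge_iou Merge threshold (default 0.4).
#' @param jitter_sd Detection jitter sd (default 1).
#' @return A `sim_scenario` list (`gt`, `detections`, `config`).
#' @export
crossing_scenario <- function(seed = 1L, arena = c(640, 512), n_frames = 80L,
                              speed = 6, body = c(90, 60),
                              merge_iou = 0.4, jitter_sd = 1) {
  W <- arena[1]; H <- arena[2]
  yc <- H / 2
  gt <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    x1 <- 10 + speed * (t - 1)
    x2 <- W - 10 - body[1] - speed * (t - 1)
    data.frame(frame = t, id = 1:2,
               x = c(x1, x2),
               y = c(yc - body[2] * 0.625, yc - body[2] * 0.375),
               w = body[1], h = body[2], conf = 1)
  }))
  class(gt) <- c("mot_records", "data.frame")
  cfg <- sim_config(n_cattle = 2, n_frames = n_frames, arena = arena,
                    body_size = body, miss_rate = 0, fp_rate = 0,
                    jitter_sd = jitter_sd, occlusion_merge_iou = merge_iou,
                    seed = seed)
  structure(list(gt = gt, detections = corrupt_detections(gt, cfg),
                 config = cfg),
            class = "sim_scenario")
}

# deterministic per-identity appearance parameters for rendering
identity_texture <- function(id) {
  list(base = 0.10 + 0.10 * ((id * 7) %% 5) / 4,      # coat darkness
       freq = 0.15 + 0.08 * ((id * 3) %% 7),          # stripe frequency
       angle = pi * ((id * 13) %% 8) / 8,             # stripe direction
       amp = 0.06 + 0.02 * ((id * 5) %% 3))           # stripe contrast
}

#' Render one frame of a scenario as a grayscale image
#'
#' Animals are drawn as dark filled ellipses with a subtle per-identity
#' sinusoidal coat texture on a lightly speckled ground, mimicking
#' near-uniformly dark animals that differ only in fine appearance detail.
#' Intensities are in `[0, 1]`; the image matrix is `height x width`.
#'
#' @param scenario A `sim_scenario`.
#' @param t Frame index.
#' @return Numeric matrix (rows = image y, columns = image x).
#' @export
render_frame <- function(scenario, t) {
  cfg <- scenario$config
  W <- round(cfg$arena[1]); H <- round(cfg$arena[2])
  with_seed(cfg$seed + 2000029L + t, {
    img <- matrix(0.72 + stats::rnorm(W * H, 0, 0.02), nrow = H, ncol = W)
  })
  g <- scenario$gt[scenario$gt$frame == t, , drop = FALSE]
  for (k in seq_len(nrow(g))) {
    tex <- identity_texture(g$id[k])
    cx <- g$x[k] + g$w[k] / 2; cy <- g$y[k] + g$h[k] / 2
    rx <- g$w[k] / 2; ry <- g$h[k] / 2
    xs <- max(1L, floor(g$x[k])):min(W, ceiling(g$x[k] + g$w[k]))
    ys <- max(1L, floor(g$y[k])):min(H, ceiling(g$y[k] + g$h[k]))
    if (!length(xs) || !length(ys)) next
    dx <- (xs - cx) / rx
    dy <- (ys - cy) / ry
    inside <- outer(dy^2, dx^2, "+") <= 1
    # texture anchored to the body centre so the coat pattern travels
    # with the animal instead of sliding across it
    u <- outer((ys - cy) * sin(tex$angle), (xs - cx) * cos(tex$angle), "+")
    val <- tex$base + tex$amp * sin(tex$freq * u)
    sub <- img[ys, xs, drop = FALSE]
    sub[inside] <- val[inside]
    img[ys, xs] <- sub
  }
  pmin(pmax(img, 0), 1)
}

#' Render a scenario to PNG files
#'
#' One grayscale PNG per frame, named `frame_000001.png` etc.
#'
#' @param scenario A `sim_scenario`.
#' @param dir Output directory (created if missing).
#' @param frames Frame indices to render (default all).
#' @return Character vector of file paths, invisibly.
#' @export
render_frames <- function(scenario, dir, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(scenario$config$n_frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", frames[i]))
    png::writePNG(render_frame(scenario, frames[i]), paths[i])
  }
  invisible(paths)
}

#' Cut a box crop out of an image
#'
#' @param img Grayscale image matrix (rows = y).
#' @param box A box (`bbox` or `c(x, y, w, h)`).
#' @return The cropped sub-matrix (clamped to the image).
#' @export
crop_box <- function(img, box) {
  b <- as_bbox(box)
  H <- nrow(img); W <- ncol(img)
  xs <- max(1L, floor(b[["x"]])):min(W, ceiling(b[["x"]] + b[["w"]]))
  ys <- max(1L, floor(b[["y"]])):min(H, ceiling(b[["y"]] + b[["h"]]))
  if (!length(xs) || !length(ys)) stop("box lies outside the image",
                                       call. = FALSE)
  img[ys, xs, drop = FALSE]
}
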