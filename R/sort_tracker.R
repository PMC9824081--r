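#' SORT-family tracker configuration
#'
#' Parameters of the Kalman + appearance tracker. Defaults are the
#' long-occlusion farm settings: a permissive appearance gate (0.9 cosine
#' distance), IoU distance gate 0.8, tracks confirmed on their first
#' association (`n_init = 1`), identities kept alive for 1500 frames (one
#' minute at 25 fps) without association, and a 100-member appearance
#' gallery per track.
#'
#' @param max_dist Appearance-distance gate: a detection may join a track
#'   in the appearance stage only if its minimum cosine distance to the
#'   track's gallery is at most this (default 0.9).
#' @param max_iou_distance IoU-stage gate on `1 - IoU` (default 0.8).
#' @param max_age Frames a track survives without association
#'   (default 1500).
#' @param n_init Associations required to confirm a track (default 1).
#' @param nn_budget Appearance gallery capacity, FIFO-evicted
#'   (default 100).
#' @param std_weight_position,std_weight_velocity Kalman noise scales
#'   relative to box height (SORT convention).
#' @return A list of class `"sort_config"`.
#' @export
sort_config <- function(max_dist = 0.9, max_iou_distance = 0.8,
                        max_age = 1500L, n_init = 1L, nn_budget = 100L,
                        std_weight_position = 1 / 20,
                        std_weight_velocity = 1 / 160) {
  stopifnot(max_dist > 0, max_dist <= 2,
            max_iou_distance > 0, max_iou_distance <= 1,
            max_age >= n_init, n_init >= 1, nn_budget >= 1)
  structure(list(max_dist = max_dist, max_iou_distance = max_iou_distance,
                 max_age = as.integer(max_age), n_init = as.integer(n_init),
                 nn_budget = as.integer(nn_budget),
                 std_weight_position = std_weight_position,
                 std_weight_velocity = std_weight_velocity),
            class = "sort_config")
}

# ---- constant-velocity Kalman filter on (cx, cy, a, h) ----------------
# 8-dim state: position block + velocity block; dt = 1 frame; process and
# measurement noise scale with box height (SORT convention)

box_to_meas <- function(box) {
  b <- as_bbox(box)
  c(b[["x"]] + b[["w"]] / 2, b[["y"]] + b[["h"]] / 2,
    b[["w"]] / b[["h"]], b[["h"]])
}

meas_to_box <- function(z) {
  h <- z[4]; w <- z[3] * h
  c(x = z[1] - w / 2, y = z[2] - h / 2, w = w, h = h)
}

kf_initiate <- function(box, cfg) {
  z <- box_to_meas(box)
  mean <- c(z, rep(0, 4))
  swp <- cfg$std_weight_position; swv <- cfg$std_weight_velocity
  std <- c(2 * swp * z[4], 2 * swp * z[4], 1e-2, 2 * swp * z[4],
           10 * swv * z[4], 10 * swv * z[4], 1e-5, 10 * swv * z[4])
  list(mean = mean, cov = diag(std^2))
}

#' Kalman prediction step for a track
#'
#' Advances the state one frame under the constant-velocity model and
#' inflates the covariance by height-scaled process noise; the track's
#' `time_since_update` counter is incremented.
#'
#' @param track A `kalman_track` (see [sort_init()]).
#' @param cfg A [sort_config()].
#' @return The updated track; `track$predicted_box` holds the predicted
#'   box.
#' @export
kf_predict <- function(track, cfg = sort_config()) {
  f <- diag(8)
  f[cbind(1:4, 5:8)] <- 1
  h4 <- track$mean[4]
  swp <- cfg$std_weight_position; swv <- cfg$std_weight_velocity
  std <- c(swp * h4, swp * h4, 1e-2, swp * h4,
           swv * h4, swv * h4, 1e-5, swv * h4)
  track$mean <- as.numeric(f %*% track$mean)
  track$cov <- f %*% track$cov %*% t(f) + diag(std^2)
  track$time_since_update <- track$time_since_update + 1L
  track$predicted_box <- meas_to_box(track$mean[1:4])
  track
}

#' Kalman correction step for a track
#'
#' Standard Kalman update of the track state with a measured box; the
#' posterior mean lies between prediction and measurement. Resets
#' `time_since_update` and increments the hit count.
#'
#' @param track A `kalman_track`.
#' @param box The associated detection's box.
#' @param cfg A [sort_config()].
#' @return The updated track.
#' @export
kf_update <- function(track, box, cfg = sort_config()) {
  z <- box_to_meas(box)
  h <- cbind(diag(4), matrix(0, 4, 4))
  swp <- cfg$std_weight_position
  h4 <- track$mean[4]
  rstd <- c(swp * h4, swp * h4, 1e-1, swp * h4)
  r <- diag(rstd^2)
  s <- h %*% track$cov %*% t(h) + r
  k <- t(solve(s, h %*% track$cov))   # Kalman gain, 8 x 4
  innov <- z - as.numeric(h %*% track$mean)
  track$mean <- as.numeric(track$mean + k %*% innov)
  track$cov <- track$cov - k %*% s %*% t(k)
  track$time_since_update <- 0L
  track$hits <- track$hits + 1L
  track
}

new_kalman_track <- function(id, box, cfg, embedding = NULL) {
  kf <- kf_initiate(box, cfg)
  tr <- list(id = id, mean = kf$mean, cov = kf$cov,
             state = "tentative", hits = 1L, time_since_update = 0L,
             gallery = list(), predicted_box = meas_to_box(kf$mean[1:4]))
  if (!is.null(embedding)) tr$gallery <- list(embedding)
  if (cfg$n_init <= 1L) tr$state <- "confirmed"
  class(tr) <- "kalman_track"
  tr
}

gallery_append <- function(track, embedding, cfg) {
  if (is.null(embedding)) return(track)
  if (length(track$gallery) &&
      length(embedding) != length(track$gallery[[1]]))
    stop("embedding dimensionality mismatch", call. = FALSE)
  track$gallery <- c(track$gallery, list(embedding))
  if (length(track$gallery) > cfg$nn_budget)
    track$gallery <- track$gallery[(length(track$gallery) -
                                      cfg$nn_budget + 1L):
                                     length(track$gallery)]
  track
}

# min cosine distance of each detection embedding to the track gallery
gallery_distance <- function(track, emb_matrix) {
  g <- do.call(rbind, track$gallery)
  if (ncol(g) != ncol(emb_matrix))
    stop("embedding dimensionality mismatch", call. = FALSE)
  gn <- g / sqrt(rowSums(g^2))
  en <- emb_matrix / sqrt(rowSums(emb_matrix^2))
  sims <- gn %*% t(en)          # gallery x detections
  1 - apply(sims, 2, max)
}

#' Two-stage association of tracks and detections
#'
#' Stage 1 matches confirmed tracks with non-empty galleries to
#' detections by minimum cosine distance to the gallery, gated at
#' `max_dist`. Stage 2 matches the remaining tracks and detections by
#' `1 - IoU` between predicted and detected boxes, gated at
#' `max_iou_distance`. Both stages use the gated Hungarian assignment.
#' With `embeddings = NULL` stage 1 is skipped (IoU-only tracking).
#'
#' @param tracks List of `kalman_track` objects (already predicted).
#' @param dets Data frame of detections (`x`, `y`, `w`, `h`).
#' @param embeddings Numeric matrix, one row per detection, or `NULL`.
#' @param cfg A [sort_config()].
#' @return List `matches` (track index / detection index matrix),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
sort_associate <- function(tracks, dets, embeddings = NULL,
                           cfg = sort_config()) {
  m <- length(tracks); n <- nrow(dets)
  if (m == 0L || n == 0L)
    return(list(matches = cbind(row = integer(0), col = integer(0)),
                unmatched_tracks = seq_len(m),
                unmatched_detections = seq_len(n)))
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != n)
      stop("one embedding row per detection required", call. = FALSE)
  }
  matches <- cbind(row = integer(0), col = integer(0))
  free_t <- seq_len(m); free_d <- seq_len(n)
  if (!is.null(embeddings)) {
    app_t <- free_t[vapply(tracks[free_t], function(t)
      t$state == "confirmed" && length(t$gallery) > 0, logical(1))]
    if (length(app_t)) {
      cost <- do.call(rbind, lapply(tracks[app_t], gallery_distance,
                                    emb_matrix = embeddings))
      cost <- matrix(cost, nrow = length(app_t))
      res <- gated_assignment(cost, feasible = cost <= cfg$max_dist)
      if (nrow(res$matches)) {
        matches <- rbind(matches,
                         cbind(row = app_t[res$matches[, "row"]],
                               col = res$matches[, "col"]))
        free_t <- setdiff(free_t, app_t[res$matches[, "row"]])
        free_d <- setdiff(free_d, res$matches[, "col"])
      }
    }
  }
  if (length(free_t) && length(free_d)) {
    pred <- do.call(rbind, lapply(tracks[free_t], function(t)
      as.data.frame(as.list(t$predicted_box))))
    iou <- bbox_iou_matrix(pred, dets[free_d, , drop = FALSE])
    cost <- 1 - iou
    res <- gated_assignment(cost, feasible = cost <= cfg$max_iou_distance)
    if (nrow(res$matches)) {
      matches <- rbind(matches,
                       cbind(row = free_t[res$matches[, "row"]],
                             col = free_d[res$matches[, "col"]]))
      free_t <- setdiff(free_t, free_t[res$matches[, "row"]])
      free_d <- setdiff(free_d, free_d[res$matches[, "col"]])
    }
  }
  list(matches = matches, unmatched_tracks = free_t,
       unmatched_detections = free_d)
}

#' Track lifecycle transition
#'
#' Tentative tracks are confirmed once their hit count reaches `n_init`
#' and deleted if they go unmatched while tentative; any track unmatched
#' for more than `max_age` frames is deleted. Matched tracks append the
#' detection's embedding to their gallery, evicting the oldest member
#' beyond `nn_budget`. Deleted is terminal.
#'
#' @param track A `kalman_track`.
#' @param matched Logical: was the track associated this frame?
#' @param cfg A [sort_config()].
#' @param embedding Embedding of the associated detection (optional).
#' @return The updated track.
#' @export
lifecycle_update <- function(track, matched, cfg = sort_config(),
                             embedding = NULL) {
  if (track$state == "deleted")
    stop("deleted tracks cannot transition", call. = FALSE)
  if (matched) {
    if (track$state == "tentative" && track$hits >= cfg$n_init)
      track$state <- "confirmed"
    track <- gallery_append(track, embedding, cfg)
  } else {
    if (track$state == "tentative") track$state <- "deleted"
    else if (track$time_since_update > cfg$max_age) track$state <- "deleted"
  }
  track
}

#' Create an empty SORT tracker state
#'
#' @param cfg A [sort_config()].
#' @return A `sort_state` list.
#' @export
sort_init <- function(cfg = sort_config()) {
  structure(list(cfg = cfg, tracks = list(), next_id = 1L,
                 last_frame = 0L, records = list()),
            class = "sort_state")
}

#' Advance the SORT tracker by one frame
#'
#' Predicts every live track, associates detections (appearance stage
#' then IoU stage), corrects matched tracks with the Kalman update,
#' applies lifecycle transitions, and starts tentative tracks from
#' unmatched detections. Records are emitted for confirmed tracks matched
#' this frame, using the detection's box.
#'
#' @param state A `sort_state`.
#' @param frame Frame index, strictly increasing.
#' @param dets Data frame of detections.
#' @param embeddings Optional matrix of per-detection embeddings.
#' @return The updated state.
#' @export
sort_step <- function(state, frame, dets, embeddings = NULL) {
  frame <- as.integer(frame)
  if (frame <= state$last_frame)
    stop("frames must be presented in increasing order", call. = FALSE)
  cfg <- state$cfg
  dets <- as.data.frame(dets)
  live <- which(vapply(state$tracks, function(t) t$state != "deleted",
                       logical(1)))
  state$tracks[live] <- lapply(state$tracks[live], kf_predict, cfg = cfg)
  res <- sort_associate(state$tracks[live], dets, embeddings, cfg)
  matched_live <- logical(length(live))
  if (nrow(res$matches)) for (k in seq_len(nrow(res$matches))) {
    ti <- live[res$matches[k, "row"]]
    dj <- res$matches[k, "col"]
    tr <- kf_update(state$tracks[[ti]], c(dets$x[dj], dets$y[dj],
                                          dets$w[dj], dets$h[dj]), cfg)
    tr <- lifecycle_update(tr, TRUE, cfg,
                           embedding = if (!is.null(embeddings))
                             embeddings[dj, ] else NULL)
    state$tracks[[ti]] <- tr
    matched_live[res$matches[k, "row"]] <- TRUE
    if (tr$state == "confirmed")
      state$records[[length(state$records) + 1L]] <-
        data.frame(frame = frame, id = tr$id,
                   x = dets$x[dj], y = dets$y[dj],
                   w = dets$w[dj], h = dets$h[dj],
                   conf = if ("conf" %in% names(dets)) dets$conf[dj] else 1)
  }
  for (k in which(!matched_live))
    state$tracks[[live[k]]] <- lifecycle_update(state$tracks[[live[k]]],
                                                FALSE, cfg)
  for (dj in res$unmatched_detections) {
    tr <- new_kalman_track(state$next_id,
                           c(dets$x[dj], dets$y[dj], dets$w[dj], dets$h[dj]),
                           cfg,
                           embedding = if (!is.null(embeddings))
                             embeddings[dj, ] else NULL)
    state$next_id <- state$next_id + 1L
    state$tracks[[length(state$tracks) + 1L]] <- tr
    if (tr$state == "confirmed")
      state$records[[length(state$records) + 1L]] <-
        data.frame(frame = frame, id = tr$id,
                   x = dets$x[dj], y = dets$y[dj],
                   w = dets$w[dj], h = dets$h[dj],
                   conf = if ("conf" %in% names(dets)) dets$conf[dj] else 1)
  }
  state$last_frame <- frame
  state
}

#' Run the SORT-family tracker over a detection sequence
#'
#' @param detections Detections (`mot_records` or per-frame list).
#' @param cfg A [sort_config()].
#' @param embed_fn Optional appearance provider: a function
#'   `(frame_index, dets_data_frame) -> matrix` returning one embedding
#'   row per detection. `NULL` runs IoU-only tracking.
#' @param n_frames Total frame count (default: highest frame seen).
#' @return Track records (`mot_records`).
#' @export
run_sort <- function(detections, cfg = sort_config(), embed_fn = NULL,
                     n_frames = NULL) {
  frames <- if (is.list(detections) && !is.data.frame(detections)) detections
            else split_frames(detections, n_frames)
  state <- sort_init(cfg)
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    emb <- if (!is.null(embed_fn) && nrow(f)) embed_fn(t, f) else NULL
    state <- sort_step(state, t, f, emb)
  }
  if (!length(state$records)) return(empty_mot_records())
  out <- do.call(rbind, state$records)
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mot_records", "data.frame")
  out
}
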