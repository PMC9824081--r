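#' Light-weight tracker configuration
#'
#' The geometry-only tracker associates detections frame to frame with a
#' cost that sums the windowed location distance (pixels) and aspect-ratio
#' distance (dimensionless), then periodically re-matches recently created
#' tracks against lost ones so that identities survive occlusion gaps.
#'
#' @param history_window Number of consecutive steps averaged by the cost
#'   functions (default 5).
#' @param rematch_period Re-matching cadence in frames (default 30; at
#'   25 fps about 1.2 s).
#' @param max_lost_age Frames a lost identity is kept before deletion
#'   (default 1500, i.e. one minute at 25 fps).
#' @param cost_gate Maximum acceptable association cost, calibrated from
#'   the motion model: the default of 25 is about four times the largest
#'   plausible per-step displacement (fast walk, around 6 px/frame at the
#'   default simulator scale), so genuine continuations always pass while
#'   a track whose detection disappeared cannot absorb a neighbouring
#'   animal's detection. Note the cost averages the jump over the history
#'   window, so a gate of g admits single-step jumps up to roughly
#'   g times the window size.
#' @param iou_gate Minimum IoU between the track's last box and the
#'   candidate for a direct match; 0 (the default) disables the gate so
#'   association is purely cost-driven.
#' @param weights `(w_L, w_Ar, w_mask)` cost weights; default `c(1, 1, 0)`
#'   sums the location and aspect terms raw and ignores the mask-area
#'   channel.
#' @param history_capacity Maximum retained history entries per track.
#' @param assignment `"hungarian"` (optimal, default) or `"greedy"`.
#' @return A list of class `"lite_config"`.
#' @export
lite_config <- function(history_window = 5L, rematch_period = 30L,
                        max_lost_age = 1500L, cost_gate = 25,
                        iou_gate = 0, weights = c(1, 1, 0),
                        history_capacity = 60L,
                        assignment = c("hungarian", "greedy")) {
  if (length(weights) == 2) weights <- c(weights, 0)
  assignment <- match.arg(assignment)
  stopifnot(history_window >= 1, rematch_period >= 1, max_lost_age >= 0,
            cost_gate >= 0, iou_gate >= 0, iou_gate <= 1,
            history_capacity >= 2)
  structure(list(history_window = as.integer(history_window),
                 rematch_period = as.integer(rematch_period),
                 max_lost_age = as.integer(max_lost_age),
                 cost_gate = cost_gate, iou_gate = iou_gate,
                 weights = weights,
                 history_capacity = as.integer(history_capacity),
                 assignment = assignment),
            class = "lite_config")
}

#' Create an empty light-weight tracker state
#'
#' @param cfg A [lite_config()].
#' @return A `lite_state` list: track table, next fresh ID, frame cursor,
#'   record buffer and ID alias map.
#' @export
lite_init <- function(cfg = lite_config()) {
  structure(list(cfg = cfg, tracks = list(), next_id = 1L,
                 last_frame = 0L, last_rematch = 0L,
                 records = list(), alias = integer(0)),
            class = "lite_state")
}

# track internal representation: matrix history (frame, x, y, w, h, mask)
new_lite_track <- function(id, frame, det, provisional) {
  hist <- matrix(c(frame, det$x, det$y, det$w, det$h,
                   if (!is.null(det$mask_area)) det$mask_area else NA_real_),
                 nrow = 1,
                 dimnames = list(NULL, c("frame", "x", "y", "w", "h", "mask")))
  list(id = id, hist = hist, last_seen = frame, status = "active",
       provisional = provisional)
}

lite_track_append <- function(tr, frame, det, capacity) {
  row <- c(frame, det$x, det$y, det$w, det$h,
           if (!is.null(det$mask_area)) det$mask_area else NA_real_)
  tr$hist <- rbind(tr$hist, row)
  if (nrow(tr$hist) > capacity)
    tr$hist <- tr$hist[(nrow(tr$hist) - capacity + 1L):nrow(tr$hist), ,
                       drop = FALSE]
  tr$last_seen <- frame
  tr$status <- "active"
  tr
}

lite_track_history <- function(tr) {
  track_history(tr$hist[, "frame"],
                data.frame(x = tr$hist[, "x"], y = tr$hist[, "y"],
                           w = tr$hist[, "w"], h = tr$hist[, "h"]),
                mask_area = if (all(is.na(tr$hist[, "mask"]))) NULL
                            else tr$hist[, "mask"])
}

# vectorised association costs of one track against a frame of detections;
# algebraically identical to match_cost() applied pairwise (the appended
# candidate only contributes the final window step)
lite_costs <- function(tr, dets, cfg) {
  h <- tr$hist
  k <- nrow(h)
  n_eff <- min(cfg$history_window, k)
  cx <- h[, "x"] + h[, "w"] / 2
  cy <- h[, "y"] + h[, "h"] / 2
  ar <- h[, "w"] / h[, "h"]
  hist_l <- 0; hist_a <- 0
  if (n_eff > 1) {
    idx <- (k - n_eff + 2L):k    # last n_eff - 1 historic steps
    hist_l <- sum(sqrt(diff(cx)[idx - 1]^2 + diff(cy)[idx - 1]^2))
    hist_a <- sum(abs(diff(ar)[idx - 1]))
  }
  dcx <- dets$x + dets$w / 2
  dcy <- dets$y + dets$h / 2
  dar <- dets$w / dets$h
  ldist <- (hist_l + sqrt((dcx - cx[k])^2 + (dcy - cy[k])^2)) / n_eff
  ardist <- (hist_a + abs(dar - ar[k])) / n_eff
  cost <- cfg$weights[1] * ldist + cfg$weights[2] * ardist
  if (cfg$weights[3] > 0) {
    mk <- h[k, "mask"]
    hist_m <- if (n_eff > 1) sum(abs(diff(h[, "mask"])[(k - n_eff + 1L):(k - 1L)]))
              else 0
    dm <- if (!is.null(dets$mask_area)) dets$mask_area else rep(NA_real_, nrow(dets))
    cost <- cost + cfg$weights[3] * (hist_m + abs(dm - mk)) / n_eff
  }
  lx <- h[k, "x"]; ly <- h[k, "y"]; lw <- h[k, "w"]; lh <- h[k, "h"]
  ix <- pmin(lx + lw, dets$x + dets$w) - pmax(lx, dets$x)
  iy <- pmin(ly + lh, dets$y + dets$h) - pmax(ly, dets$y)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  list(cost = cost, iou = inter / (lw * lh + dets$w * dets$h - inter))
}

#' Match active tracks to one frame of detections
#'
#' Builds the full track-by-detection cost matrix with [match_cost()]
#' semantics and solves the gated one-to-one assignment: pairs must pass
#' both the cost gate and the IoU gate; among admissible pairs the
#' matching maximises the number of matches and minimises total cost
#' (Hungarian; set `assignment = "greedy"` in the config for the greedy
#' ablation).
#'
#' @param tracks List of internal track objects (see [lite_init()]).
#' @param dets Data frame of one frame's detections (`x`, `y`, `w`, `h`,
#'   optionally `mask_area`).
#' @param cfg A [lite_config()].
#' @return List `matches` (matrix of track index / detection index),
#'   `unmatched_tracks`, `unmatched_detections`.
#' @export
lite_match <- function(tracks, dets, cfg) {
  m <- length(tracks); n <- nrow(dets)
  if (m == 0L || n == 0L)
    return(list(matches = cbind(row = integer(0), col = integer(0)),
                unmatched_tracks = seq_len(m),
                unmatched_detections = seq_len(n)))
  cost <- matrix(Inf, m, n)
  feas <- matrix(FALSE, m, n)
  for (i in seq_len(m)) {
    cc <- lite_costs(tracks[[i]], dets, cfg)
    cost[i, ] <- cc$cost
    feas[i, ] <- cc$cost <= cfg$cost_gate & cc$iou >= cfg$iou_gate
  }
  solver <- if (cfg$assignment == "greedy") greedy_assignment else gated_assignment
  res <- solver(cost, feasible = feas)
  list(matches = res$matches,
       unmatched_tracks = res$unmatched_rows,
       unmatched_detections = res$unmatched_cols)
}

#' Re-match recent tracks against lost identities
#'
#' Invoked at each re-matching boundary (every `rematch_period` frames):
#' every provisional track — one created since the previous boundary,
#' holding a fresh provisional ID — is compared against every lost track
#' not older than `max_lost_age`, using the same gated
#' cost assignment as the matching stage (the lost track's history
#' extended by the provisional track's first box — the detection whose
#' appearance created it). On success the
#' provisional track's records are rewritten, in the in-memory buffer
#' only, to the lost track's ID, which is reactivated; the provisional ID
#' is retired and never reused. Provisional tracks that fail keep their
#' fresh IDs and become established. Lost tracks never steal from active
#' established tracks.
#'
#' @param state A `lite_state`.
#' @return The updated state.
#' @export
lite_rematch <- function(state) {
  cfg <- state$cfg
  now <- state$last_frame
  solver <- if (cfg$assignment == "greedy") greedy_assignment else gated_assignment
  # merge rounds: a provisional that inherits an ID extends that lost
  # track in place, which can make the next provisional in a broken chain
  # mergeable, so iterate until no merge succeeds
  repeat {
    prov_idx <- which(vapply(state$tracks, function(t)
      isTRUE(t$provisional) && t$status != "deleted", logical(1)))
    # merge targets: any lost track within the age limit — including lost
    # provisionals, so a track interrupted in the same inter-boundary
    # window it was created in can still reclaim its fragment
    lost_idx <- which(vapply(state$tracks, function(t)
      t$status == "lost" && (now - t$last_seen) <= cfg$max_lost_age,
      logical(1)))
    if (!length(prov_idx) || !length(lost_idx)) break
    m <- length(lost_idx); n <- length(prov_idx)
    cost <- matrix(Inf, m, n)
    feas <- matrix(FALSE, m, n)
    for (i in seq_len(m)) {
      lt <- state$tracks[[lost_idx[i]]]
      for (j in seq_len(n)) {
        pt <- state$tracks[[prov_idx[j]]]
        # the candidate is the provisional's first box: the detection
        # that appeared, closest in time to the identity's loss
        det <- data.frame(x = pt$hist[1, "x"], y = pt$hist[1, "y"],
                          w = pt$hist[1, "w"], h = pt$hist[1, "h"],
                          mask_area = pt$hist[1, "mask"])
        cc <- lite_costs(lt, det, cfg)
        cost[i, j] <- cc$cost
        # a merge must not create overlapping records for one ID, and a
        # track cannot absorb itself
        feas[i, j] <- cc$cost <= cfg$cost_gate & cc$iou >= cfg$iou_gate &
          pt$hist[1, "frame"] > lt$last_seen & lost_idx[i] != prov_idx[j]
      }
    }
    res <- solver(cost, feasible = feas)
    if (!nrow(res$matches)) break
    executed <- 0L
    for (k in seq_len(nrow(res$matches))) {
      li <- lost_idx[res$matches[k, "row"]]
      pj <- prov_idx[res$matches[k, "col"]]
      lt <- state$tracks[[li]]; pt <- state$tracks[[pj]]
      # the target may itself have merged away earlier in this round;
      # its fragment then retries against the merged track next round
      if (lt$status == "deleted" || pt$status == "deleted") next
      executed <- executed + 1L
      state$alias[as.character(pt$id)] <- lt$id
      lt$hist <- rbind(lt$hist, pt$hist)
      if (nrow(lt$hist) > cfg$history_capacity)
        lt$hist <- lt$hist[(nrow(lt$hist) - cfg$history_capacity + 1L):
                             nrow(lt$hist), , drop = FALSE]
      lt$last_seen <- pt$last_seen
      lt$status <- pt$status
      state$tracks[[li]] <- lt
      pt$status <- "deleted"
      pt$merged <- TRUE
      state$tracks[[pj]] <- pt
    }
    if (executed == 0L) break
  }
  # surviving provisionals become established at the boundary
  for (i in seq_along(state$tracks))
    if (isTRUE(state$tracks[[i]]$provisional) &&
        state$tracks[[i]]$status != "deleted")
      state$tracks[[i]]$provisional <- FALSE
  state$last_rematch <- now
  state
}

#' Delete lost tracks past the age limit
#'
#' Lost tracks with `current_frame - last_seen > max_lost_age` become
#' deleted (the boundary age itself is kept). Deleted tracks are never
#' reactivated and their IDs are never reused.
#'
#' @param state A `lite_state`.
#' @param current_frame Frame index to age against (defaults to the
#'   state's cursor).
#' @return The updated state.
#' @export
lite_prune <- function(state, current_frame = state$last_frame) {
  for (i in seq_along(state$tracks)) {
    tr <- state$tracks[[i]]
    if (tr$status == "lost" &&
        (current_frame - tr$last_seen) > state$cfg$max_lost_age)
      state$tracks[[i]]$status <- "deleted"
  }
  state
}

#' Advance the light-weight tracker by one frame
#'
#' Matches the frame's detections against active tracks, extends matched
#' histories (identities are kept), marks unmatched tracks lost, issues
#' monotonically increasing provisional IDs to unmatched detections, runs
#' the re-matching stage at every `rematch_period` boundary, and prunes
#' expired lost tracks. Frames must be presented in strictly increasing
#' order. The tracker is fully deterministic.
#'
#' @param state A `lite_state` from [lite_init()].
#' @param frame Frame index (1-based, strictly increasing).
#' @param dets Data frame of this frame's detections.
#' @return The updated state; per-frame records accumulate in the state's
#'   buffer and are finalised by [lite_records()].
#' @export
lite_step <- function(state, frame, dets) {
  frame <- as.integer(frame)
  if (frame <= state$last_frame)
    stop("frames must be presented in increasing order", call. = FALSE)
  cfg <- state$cfg
  dets <- as.data.frame(dets)
  active_idx <- which(vapply(state$tracks, function(t) t$status == "active",
                             logical(1)))
  res <- lite_match(state$tracks[active_idx], dets, cfg)
  emitted <- list()
  if (nrow(res$matches)) for (k in seq_len(nrow(res$matches))) {
    ti <- active_idx[res$matches[k, "row"]]
    dj <- res$matches[k, "col"]
    state$tracks[[ti]] <- lite_track_append(state$tracks[[ti]], frame,
                                            dets[dj, ], cfg$history_capacity)
    emitted[[length(emitted) + 1L]] <-
      data.frame(frame = frame, id = state$tracks[[ti]]$id,
                 x = dets$x[dj], y = dets$y[dj],
                 w = dets$w[dj], h = dets$h[dj],
                 conf = if ("conf" %in% names(dets)) dets$conf[dj] else 1)
  }
  for (ti in active_idx[res$unmatched_tracks])
    state$tracks[[ti]]$status <- "lost"
  for (dj in res$unmatched_detections) {
    id <- state$next_id
    state$next_id <- state$next_id + 1L
    state$tracks[[length(state$tracks) + 1L]] <-
      new_lite_track(id, frame, dets[dj, ], provisional = TRUE)
    emitted[[length(emitted) + 1L]] <-
      data.frame(frame = frame, id = id,
                 x = dets$x[dj], y = dets$y[dj],
                 w = dets$w[dj], h = dets$h[dj],
                 conf = if ("conf" %in% names(dets)) dets$conf[dj] else 1)
  }
  if (length(emitted))
    state$records[[length(state$records) + 1L]] <- do.call(rbind, emitted)
  state$last_frame <- frame
  if (frame %% cfg$rematch_period == 0L) state <- lite_rematch(state)
  lite_prune(state)
}

# resolve provisional-ID aliases transitively
resolve_alias <- function(ids, alias) {
  if (!length(alias)) return(ids)
  out <- ids
  repeat {
    mapped <- alias[as.character(out)]
    hit <- !is.na(mapped)
    if (!any(hit)) break
    out[hit] <- mapped[hit]
  }
  out
}

#' Finalised track records of a light-weight tracker run
#'
#' Applies the re-matching ID rewrites to the in-memory record buffer and
#' returns the full set of track records.
#'
#' @param state A `lite_state`.
#' @return A `mot_records` data frame sorted by frame then id.
#' @export
lite_records <- function(state) {
  if (!length(state$records)) return(empty_mot_records())
  out <- do.call(rbind, state$records)
  out$id <- as.integer(resolve_alias(out$id, state$alias))
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mot_records", "data.frame")
  out
}

#' Run the light-weight tracker over a detection sequence
#'
#' @param detections Detections as `mot_records` (identities ignored) or
#'   a per-frame list from [split_frames()].
#' @param cfg A [lite_config()].
#' @param n_frames Total frame count (default: the highest frame seen).
#' @return Track records (`mot_records`).
#' @examples
#' sc <- simulate_scenario(sim_config(n_cattle = 3, n_frames = 40,
#'                                    miss_rate = 0, fp_rate = 0,
#'                                    jitter_sd = 0, seed = 7))
#' tr <- track_lite(sc$detections)
#' evaluate_tracking(sc$gt, tr)$mota
#' @export
track_lite <- function(detections, cfg = lite_config(), n_frames = NULL) {
  frames <- if (is.list(detections) && !is.data.frame(detections)) detections
            else split_frames(detections, n_frames)
  state <- lite_init(cfg)
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    state <- lite_step(state, t, f[!is.na(f$w), , drop = FALSE])
  }
  lite_records(state)
}
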