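#' Accumulate CLEAR tracking events over a sequence
#'
#' Per frame, ground-truth objects are put in correspondence with
#' predicted tracks: pairings remembered from an identity's last matched
#' frame are kept whenever both parties are present and still overlap at
#' the IoU gate (the CLEAR persistence rule, which prevents spurious
#' switch counting when boxes jitter), and the remaining boxes are matched
#' by Hungarian assignment maximising total IoU over pairs at or above the
#' gate. Events per frame: unmatched ground truth are false negatives,
#' unmatched predictions false positives, and an identity switch is
#' counted when a ground-truth identity's matched predicted ID differs
#' from the predicted ID it was last matched with (gaps in between do not
#' reset the memory). A fragmentation is a tracked-to-untracked transition
#' of a ground-truth identity that is tracked again later.
#'
#' @param gt Ground-truth `mot_records` (complete trajectories,
#'   `id >= 1`).
#' @param pred Predicted track `mot_records` (`id >= 1`).
#' @param iou_threshold Association gate (default 0.5).
#' @return An object of class `"mot_event_log"`: a list with `frames`
#'   (data frame `frame`, `gt`, `fn`, `fp`, `idsw`, `matches`),
#'   `fragmentations`, and totals.
#' @export
accumulate_mot <- function(gt, pred, iou_threshold = 0.5) {
  gt <- as.data.frame(gt); pred <- as.data.frame(pred)
  stopifnot(all(gt$id >= 1), all(pred$id >= 1))
  if (nrow(gt) && anyDuplicated(gt[c("frame", "id")]))
    stop("duplicate ground-truth ID within a frame", call. = FALSE)
  n_frames <- max(c(gt$frame, pred$frame, 0L))
  gt_f <- split_frames(gt, n_frames)
  pred_f <- split_frames(pred, n_frames)
  last_match <- integer(0)    # names: gt id -> last matched pred id
  tracked_seq <- list()       # per gt id: logical vector of tracked flags
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    g <- gt_f[[t]]; p <- pred_f[[t]]
    ng <- nrow(g); np <- nrow(p)
    iou <- bbox_iou_matrix(g, p)
    matched_g <- integer(0); matched_p <- integer(0)
    # persistence: keep each identity's last-known pairing if still valid
    if (ng && np && length(last_match)) {
      for (i in seq_len(ng)) {
        pid <- last_match[as.character(g$id[i])]
        if (!is.na(pid) && length(pid)) {
          j <- match(pid, p$id)
          if (!is.na(j) && !(j %in% matched_p) &&
              iou[i, j] >= iou_threshold) {
            matched_g <- c(matched_g, i); matched_p <- c(matched_p, j)
          }
        }
      }
    }
    free_g <- setdiff(seq_len(ng), matched_g)
    free_p <- setdiff(seq_len(np), matched_p)
    if (length(free_g) && length(free_p)) {
      sub <- iou[free_g, free_p, drop = FALSE]
      res <- gated_assignment(-sub, feasible = sub >= iou_threshold)
      if (nrow(res$matches)) {
        matched_g <- c(matched_g, free_g[res$matches[, "row"]])
        matched_p <- c(matched_p, free_p[res$matches[, "col"]])
      }
    }
    idsw <- 0L
    for (k in seq_along(matched_g)) {
      gid <- as.character(g$id[matched_g[k]])
      pid <- p$id[matched_p[k]]
      prev <- last_match[gid]
      if (!is.na(prev) && length(prev) && prev != pid) idsw <- idsw + 1L
      last_match[gid] <- pid
    }
    # coverage flags for fragmentation counting
    if (ng) {
      trk <- seq_len(ng) %in% matched_g
      for (i in seq_len(ng)) {
        gid <- as.character(g$id[i])
        tracked_seq[[gid]] <- c(tracked_seq[[gid]], trk[i])
      }
    }
    rows[[t]] <- data.frame(frame = t, gt = ng,
                            fn = ng - length(matched_g),
                            fp = np - length(matched_p),
                            idsw = idsw, matches = length(matched_g))
  }
  frames <- if (n_frames) do.call(rbind, rows) else
    data.frame(frame = integer(0), gt = integer(0), fn = integer(0),
               fp = integer(0), idsw = integer(0), matches = integer(0))
  frag <- sum(vapply(tracked_seq, function(flags) {
    r <- rle(flags)
    max(0L, sum(r$values) - 1L)   # tracked segments - 1 = completed gaps
  }, integer(1)))
  structure(list(frames = frames,
                 fragmentations = as.integer(frag),
                 totals = c(GT = sum(frames$gt), FN = sum(frames$fn),
                            FP = sum(frames$fp), IDSW = sum(frames$idsw))),
            class = "mot_event_log")
}

#' Multi-object tracking accuracy
#'
#' `MOTA = 1 - (sum FN + sum FP + sum IDSW) / sum GT`, the standard CLEAR
#' definition combining the three error types into a single accuracy that
#' is 1 for perfect tracking and can go negative. The raw error ratio
#' (the un-complemented sum) is returned alongside for transparency.
#'
#' @param log A `mot_event_log` from [accumulate_mot()], or a named
#'   vector/list with `GT`, `FN`, `FP`, `IDSW` totals.
#' @return Named numeric vector `mota`, `error_ratio`.
#' @examples
#' mota(c(GT = 100, FN = 2, FP = 1, IDSW = 1))  # mota 0.96
#' @export
mota <- function(log) {
  tot <- if (inherits(log, "mot_event_log")) log$totals else unlist(log)
  gt <- as.numeric(tot[["GT"]])
  if (gt == 0) {
    v <- undefined_metric("MOTA")
    return(c(mota = v, error_ratio = v))
  }
  err <- (as.numeric(tot[["FN"]]) + as.numeric(tot[["FP"]]) +
            as.numeric(tot[["IDSW"]])) / gt
  c(mota = 1 - err, error_ratio = err)
}

#' Count persistent predicted tracks
#'
#' Number of distinct predicted IDs that appear in at least `min_length`
#' frames — the per-clip animal count a tracker reports, with short
#' spurious tracks excluded.
#'
#' @param pred Predicted track records.
#' @param min_length Minimum number of frames a track must appear in
#'   (default 25, one second at 25 fps).
#' @return Integer count.
#' @export
count_tracked <- function(pred, min_length = 25L) {
  pred <- as.data.frame(pred)
  if (!nrow(pred)) return(0L)
  sum(table(pred$id) >= min_length)
}

#' Full tracking evaluation report
#'
#' Convenience wrapper combining [accumulate_mot()], [mota()] and
#' [count_tracked()].
#'
#' @inheritParams accumulate_mot
#' @param min_length Passed to [count_tracked()].
#' @return A list of class `"tracking_report"`: `mota`, `error_ratio`,
#'   `idsw`, `fn`, `fp`, `gt`, `fragmentations`, `tracked_count`,
#'   `event_log`.
#' @export
evaluate_tracking <- function(gt, pred, iou_threshold = 0.5,
                              min_length = 25L) {
  log <- accumulate_mot(gt, pred, iou_threshold)
  m <- mota(log)
  structure(list(mota = unname(m[["mota"]]),
                 error_ratio = unname(m[["error_ratio"]]),
                 idsw = unname(log$totals[["IDSW"]]),
                 fn = unname(log$totals[["FN"]]),
                 fp = unname(log$totals[["FP"]]),
                 gt = unname(log$totals[["GT"]]),
                 fragmentations = log$fragmentations,
                 tracked_count = count_tracked(pred, min_length),
                 event_log = log),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("Tracking report: MOTA %.4f | IDSW %d | FN %d | FP %d | GT %d | frag %d | tracks >= min length: %d\n",
              x$mota, x$idsw, x$fn, x$fp, x$gt, x$fragmentations,
              x$tracked_count))
  invisible(x)
}

#' Extract proximity contacts between tracked identities
#'
#' Frames where two identities' box centroids lie closer than
#' `distance_threshold` are merged into maximal contiguous intervals per
#' identity pair; intervals shorter than `min_duration` frames are
#' dropped. Used to mine social interactions (mounting, estrus behaviour)
#' from long-term trajectories.
#'
#' @param tracks Track records (`frame`, `id`, `x`, `y`, `w`, `h`).
#' @param distance_threshold Centroid distance in pixels below which two
#'   identities are in contact.
#' @param min_duration Minimum interval length in frames (default 25).
#' @return Data frame `id_a`, `id_b`, `start_frame`, `end_frame`,
#'   `duration` with `id_a < id_b`.
#' @export
extract_contacts <- function(tracks, distance_threshold, min_duration = 25L) {
  tracks <- as.data.frame(tracks)
  out <- data.frame(id_a = integer(0), id_b = integer(0),
                    start_frame = integer(0), end_frame = integer(0),
                    duration = integer(0))
  if (!nrow(tracks) || distance_threshold <= 0) return(out)
  tracks$cx <- tracks$x + tracks$w / 2
  tracks$cy <- tracks$y + tracks$h / 2
  by_frame <- split(tracks, tracks$frame)
  hits <- lapply(by_frame, function(fr) {
    n <- nrow(fr)
    if (n < 2) return(NULL)
    pairs <- utils::combn(n, 2)
    d <- sqrt((fr$cx[pairs[1, ]] - fr$cx[pairs[2, ]])^2 +
                (fr$cy[pairs[1, ]] - fr$cy[pairs[2, ]])^2)
    sel <- which(d < distance_threshold)
    if (!length(sel)) return(NULL)
    data.frame(frame = fr$frame[1],
               id_a = pmin(fr$id[pairs[1, sel]], fr$id[pairs[2, sel]]),
               id_b = pmax(fr$id[pairs[1, sel]], fr$id[pairs[2, sel]]))
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(out)
  for (key in unique(paste(hits$id_a, hits$id_b))) {
    sub <- hits[paste(hits$id_a, hits$id_b) == key, ]
    f <- sort(unique(sub$frame))
    runs <- cumsum(c(TRUE, diff(f) > 1))
    for (r in unique(runs)) {
      ff <- f[runs == r]
      if (length(ff) >= min_duration)
        out <- rbind(out, data.frame(id_a = sub$id_a[1], id_b = sub$id_b[1],
                                     start_frame = min(ff),
                                     end_frame = max(ff),
                                     duration = length(ff)))
    }
  }
  rownames(out) <- NULL
  out[order(out$id_a, out$id_b, out$start_frame), , drop = FALSE]
}

#' Write contact intervals as tab-separated text
#'
#' BED-like layout: `id_a`, `id_b`, `start_frame`, `end_frame`,
#' `duration`, no header.
#'
#' @param contacts Output of [extract_contacts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-identity trajectory polylines
#'
#' Centroid paths per identity, ready for plotting as a trajectory map.
#'
#' @param tracks Track records.
#' @return Data frame `id`, `frame`, `x`, `y` (centroids), sorted.
#' @export
trajectories <- function(tracks) {
  tracks <- as.data.frame(tracks)
  out <- data.frame(id = tracks$id, frame = tracks$frame,
                    x = tracks$x + tracks$w / 2,
                    y = tracks$y + tracks$h / 2)
  out[order(out$id, out$frame), , drop = FALSE]
}

#' Plot a trajectory map
#'
#' One polyline per identity over the arena, the long-term movement map
#' used to inspect individual behaviour patterns.
#'
#' @param tracks Track records.
#' @param arena Optional `c(width, height)` in pixels to fix the panel.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(tracks, arena = NULL) {
  tr <- trajectories(tracks)
  tr$id <- factor(tr$id)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$id,
                                        group = .data$id)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track") +
    ggplot2::theme_minimal()
  if (!is.null(arena))
    p <- p + ggplot2::coord_fixed(xlim = c(0, arena[1]),
                                  ylim = c(arena[2], 0))
  p
}
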