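#' Track history
#'
#' An ordered record of a single target's past boxes, the substrate of the
#' light-weight tracker's cost functions. Frame indices must be strictly
#' increasing; entries are treated as consecutive steps even when detector
#' misses leave gaps between their frame indices.
#'
#' @param frames Integer vector of frame indices, strictly increasing.
#' @param boxes Data frame with columns `x`, `y`, `w`, `h` (one row per
#'   frame) or a list of [bbox()] objects.
#' @param mask_area Optional numeric vector of mask areas (pixels^2).
#' @return A data frame of class `"track_history"` with columns
#'   `frame`, `x`, `y`, `w`, `h` and optionally `mask_area`.
#' @export
track_history <- function(frames, boxes, mask_area = NULL) {
  if (is.list(boxes) && !is.data.frame(boxes))
    boxes <- as.data.frame(do.call(rbind, lapply(boxes, unclass)))
  boxes <- as.data.frame(boxes)
  stopifnot(all(c("x", "y", "w", "h") %in% names(boxes)))
  frames <- as.integer(frames)
  if (length(frames) != nrow(boxes))
    stop("one frame index per box required", call. = FALSE)
  if (length(frames) > 1 && any(diff(frames) <= 0))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (any(boxes$w <= 0) || any(boxes$h <= 0))
    stop("box width and height must be > 0", call. = FALSE)
  h <- data.frame(frame = frames, x = boxes$x, y = boxes$y,
                  w = boxes$w, h = boxes$h)
  if (!is.null(mask_area)) h$mask_area <- as.numeric(mask_area)
  class(h) <- c("track_history", "data.frame")
  h
}

history_append <- function(hist, frame, box, mask_area = NA_real_) {
  box <- as_bbox(box)
  row <- data.frame(frame = as.integer(frame), x = box[["x"]], y = box[["y"]],
                    w = box[["w"]], h = box[["h"]])
  if ("mask_area" %in% names(hist)) row$mask_area <- mask_area
  out <- rbind(as.data.frame(hist), row)
  class(out) <- c("track_history", "data.frame")
  out
}

# last n+1 rows -> n consecutive steps ending at the newest entry
last_steps <- function(hist, n) {
  k <- nrow(hist)
  if (k < 2) stop("track history needs at least 2 entries", call. = FALSE)
  n <- min(as.integer(n), k - 1L)
  if (n < 1) stop("window must cover at least 1 step", call. = FALSE)
  hist[(k - n):k, , drop = FALSE]
}

#' Location distance: mean centroid step length over a window
#'
#' The mean Euclidean distance between consecutive box centroids over the
#' last `n` steps of the history. Measures how far the target has been
#' moving per frame; a candidate detection that continues a track's recent
#' motion keeps this small.
#'
#' @param hist A [track_history()] with at least 2 entries.
#' @param n Number of consecutive steps to average over (capped at the
#'   number of steps available). Default 5.
#' @return Mean step length in pixels (non-negative).
#' @examples
#' h <- track_history(1:3, data.frame(x = c(0, 3, 6), y = c(0, 4, 8),
#'                                    w = 2, h = 2))
#' location_distance(h, n = 2)  # two 3-4-5 steps -> 5
#' @export
location_distance <- function(hist, n = 5L) {
  s <- last_steps(hist, n)
  cx <- s$x + s$w / 2; cy <- s$y + s$h / 2
  mean(sqrt(diff(cx)^2 + diff(cy)^2))
}

#' Aspect-ratio distance: mean aspect step over a window
#'
#' The mean absolute change in aspect ratio (`w / h`) between consecutive
#' entries over the last `n` steps. Posture changes (standing vs lying)
#' show up as aspect jumps, so this term penalises candidates whose shape
#' departs from the track's recent shape dynamics.
#'
#' @inheritParams location_distance
#' @return Mean `|Ar_i - Ar_{i-1}|`, dimensionless, non-negative.
#' @export
aspect_distance <- function(hist, n = 5L) {
  s <- last_steps(hist, n)
  ar <- s$w / s$h
  mean(sqrt(diff(ar)^2))
}

#' Mask-area distance: mean absolute area step over a window
#'
#' Optional third association channel: the mean absolute change in
#' segmentation-mask area between consecutive entries. Only defined when
#' the history carries `mask_area`; entries with missing areas make the
#' distance `NA`.
#'
#' @inheritParams location_distance
#' @return Mean `|A_i - A_{i-1}|` in pixels^2, or `NA` if unavailable.
#' @export
mask_area_distance <- function(hist, n = 5L) {
  if (!"mask_area" %in% names(hist)) return(NA_real_)
  s <- last_steps(hist, n)
  if (anyNA(s$mask_area)) return(NA_real_)
  mean(abs(diff(s$mask_area)))
}

#' Association cost between a track history and a candidate detection
#'
#' Appends the candidate box as the tentative current entry of the history
#' and evaluates the windowed location and aspect-ratio distances; the
#' total cost is their weighted sum, `w_L = w_Ar = 1` by default so the
#' pixel-valued location term and the dimensionless aspect term are summed
#' raw. A mask-area term is computed when both the history and the
#' candidate carry mask areas, but enters the cost only if `weights[3] > 0`
#' (default weight 0). The IoU reported is between the candidate and the
#' most recent history box.
#'
#' @param hist A [track_history()] with at least 1 entry.
#' @param candidate Candidate box ([bbox()] or numeric `c(x, y, w, h)`).
#' @param weights Numeric `(w_L, w_Ar)` or `(w_L, w_Ar, w_mask)`;
#'   default `c(1, 1, 0)`.
#' @param n Window: number of consecutive steps averaged (default 5).
#' @param candidate_mask_area Mask area of the candidate, if any.
#' @return A list of class `"cost_breakdown"` with elements `ldist`
#'   (pixels), `ardist` (dimensionless), `mask_dist` (pixels^2 or `NA`),
#'   `cost` (the gateable total) and `iou`.
#' @examples
#' h <- track_history(1:2, data.frame(x = c(0, 0), y = 0, w = 10, h = 10))
#' match_cost(h, bbox(0, 0, 10, 10))$cost  # stationary continuation -> 0
#' @export
match_cost <- function(hist, candidate, weights = c(1, 1, 0), n = 5L,
                       candidate_mask_area = NA_real_) {
  if (length(weights) == 2) weights <- c(weights, 0)
  stopifnot(length(weights) == 3, all(is.finite(weights)))
  candidate <- as_bbox(candidate)
  if (nrow(hist) < 1) stop("empty track history", call. = FALSE)
  tent <- history_append(hist, hist$frame[nrow(hist)] + 1L, candidate,
                         mask_area = candidate_mask_area)
  ld <- location_distance(tent, n)
  ad <- aspect_distance(tent, n)
  md <- mask_area_distance(tent, n)
  cost <- weights[1] * ld + weights[2] * ad
  if (weights[3] > 0) {
    if (is.na(md))
      stop("mask-area weight > 0 but mask areas unavailable", call. = FALSE)
    cost <- cost + weights[3] * md
  }
  last <- hist[nrow(hist), ]
  structure(list(ldist = ld, ardist = ad, mask_dist = md, cost = cost,
                 iou = bbox_iou(c(last$x, last$y, last$w, last$h), candidate)),
            class = "cost_breakdown")
}
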