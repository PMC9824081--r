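#' Sequence metadata
#'
#' Frame rate and image geometry of a video sequence. Defaults mirror a
#' typical fisheye barn camera: 25 frames per second at 2560 x 2048.
#'
#' @param fps Frames per second.
#' @param image_width,image_height Image size in pixels.
#' @param n_frames Number of frames, if known.
#' @return A list of class `"sequence_meta"`.
#' @export
sequence_meta <- function(fps = 25, image_width = 2560, image_height = 2048,
                          n_frames = NA_integer_) {
  stopifnot(fps > 0, image_width > 0, image_height > 0)
  structure(list(fps = fps, image_width = image_width,
                 image_height = image_height,
                 n_frames = as.integer(n_frames)),
            class = "sequence_meta")
}

#' Read detections or track records in MOT-Challenge text format
#'
#' Parses the standard comma-separated dialect
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z` with 1-based
#' frames and IDs; `id = -1` denotes a raw detection without identity.
#' Trailing columns beyond the tenth are ignored; every line must parse or
#' the reader stops with the offending line number — no line is silently
#' dropped.
#'
#' @param path Path to the text file.
#' @return A data frame with columns `frame`, `id`, `x`, `y`, `w`, `h`,
#'   `conf`, sorted by frame then id, of class `"mot_records"`.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_mot_records())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 6L)
  if (length(bad))
    stop(sprintf("malformed MOT line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  get <- function(k, default = NA_real_) {
    vapply(parts, function(p) {
      if (length(p) >= k) suppressWarnings(as.numeric(p[[k]])) else default
    }, numeric(1))
  }
  frame <- get(1); id <- get(2)
  x <- get(3); y <- get(4); w <- get(5); h <- get(6)
  conf <- get(7, default = 1); conf[is.na(conf)] <- 1
  num_bad <- which(is.na(frame) | is.na(id) | is.na(x) | is.na(y) |
                     is.na(w) | is.na(h))
  if (length(num_bad))
    stop(sprintf("malformed MOT line %d: '%s'", num_bad[1], lines[num_bad[1]]),
         call. = FALSE)
  size_bad <- which(w <= 0 | h <= 0)
  if (length(size_bad))
    stop(sprintf("non-positive box size at line %d: '%s'",
                 size_bad[1], lines[size_bad[1]]), call. = FALSE)
  if (any(frame < 1))
    stop("frame indices must be >= 1", call. = FALSE)
  out <- data.frame(frame = as.integer(frame), id = as.integer(id),
                    x = x, y = y, w = w, h = h, conf = conf)
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mot_records", "data.frame")
  out
}

empty_mot_records <- function() {
  out <- data.frame(frame = integer(0), id = integer(0),
                    x = numeric(0), y = numeric(0),
                    w = numeric(0), h = numeric(0), conf = numeric(0))
  class(out) <- c("mot_records", "data.frame")
  out
}

#' Write track records (or detections) in MOT-Challenge format
#'
#' Records are written sorted by frame then id, one line per record, as
#' `frame,id,x,y,w,h,conf,-1,-1,-1`. Identified records (`id >= 1`) must
#' be unique per `(frame, id)` pair.
#'
#' @param records Data frame with columns `frame`, `id`, `x`, `y`, `w`,
#'   `h` and optionally `conf` (default 1).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(records, path) {
  records <- as.data.frame(records)
  stopifnot(all(c("frame", "id", "x", "y", "w", "h") %in% names(records)))
  if (!"conf" %in% names(records)) records$conf <- 1
  ided <- records[records$id >= 1, ]
  if (anyDuplicated(ided[c("frame", "id")]))
    stop("duplicate (frame, id) pair in track records", call. = FALSE)
  records <- records[order(records$frame, records$id), , drop = FALSE]
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                   as.integer(records$frame), as.integer(records$id),
                   fmt_num(records$x), fmt_num(records$y),
                   fmt_num(records$w), fmt_num(records$h),
                   fmt_num(records$conf))
  writeLines(lines, path)
  invisible(path)
}

# fixed decimal formatting, trailing zeros trimmed ("10" not "10.000000")
fmt_num <- function(v) {
  s <- formatC(v, format = "f", digits = 6)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Read YOLO-style per-frame label files
#'
#' One text file per frame, each line `class cx cy w h [conf]` with
#' centre-form coordinates normalised to `[0, 1]`. Files are mapped to
#' frame indices by the number embedded in their file name (`000001.txt`
#' is frame 1). Boxes are denormalised to pixels using `meta` and
#' converted to corner form. A missing confidence column defaults to 1.
#'
#' @param dir Directory containing `*.txt` label files.
#' @param meta A [sequence_meta()] providing image width/height.
#' @return A `mot_records` data frame of detections (`id = -1`) with an
#'   extra `class` column.
#' @export
read_yolo_frames <- function(dir, meta = sequence_meta()) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  recs <- list()
  for (f in files) {
    fr <- as.integer(sub("\\D*(\\d+)\\D*$", "\\1", basename(f)))
    if (is.na(fr)) stop("cannot infer frame index from file name: ",
                        basename(f), call. = FALSE)
    lines <- readLines(f)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) next
    mat <- do.call(rbind, lapply(seq_along(lines), function(i) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 5)
        stop(sprintf("malformed YOLO line %d in %s", i, basename(f)),
             call. = FALSE)
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals[1:5]))
        stop(sprintf("malformed YOLO line %d in %s", i, basename(f)),
             call. = FALSE)
      c(vals[1:5], if (length(vals) >= 6) vals[6] else 1)
    }))
    if (any(mat[, 2:5] < 0 | mat[, 2:5] > 1))
      stop("YOLO coordinates must lie in [0, 1] (", basename(f), ")",
           call. = FALSE)
    recs[[length(recs) + 1L]] <- data.frame(
      frame = fr, id = -1L,
      x = (mat[, 2] - mat[, 4] / 2) * meta$image_width,
      y = (mat[, 3] - mat[, 5] / 2) * meta$image_height,
      w = mat[, 4] * meta$image_width,
      h = mat[, 5] * meta$image_height,
      conf = mat[, 6], class = as.integer(mat[, 1]))
  }
  if (!length(recs)) {
    out <- empty_mot_records(); out$class <- integer(0)
    return(out)
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mot_records", "data.frame")
  out
}

#' Split MOT records into a per-frame list
#'
#' @param records A `mot_records` data frame.
#' @param n_frames Optional total frame count; frames without records
#'   yield empty entries.
#' @return Named list, one data frame per frame index `1..n_frames`.
#' @export
split_frames <- function(records, n_frames = NULL) {
  records <- as.data.frame(records)
  if (is.null(n_frames))
    n_frames <- if (nrow(records)) max(records$frame) else 0L
  out <- vector("list", n_frames)
  idx <- split(seq_len(nrow(records)), factor(records$frame,
                                              levels = seq_len(n_frames)))
  for (t in seq_len(n_frames)) {
    out[[t]] <- records[idx[[t]], , drop = FALSE]
    rownames(out[[t]]) <- NULL
  }
  names(out) <- seq_len(n_frames)
  out
}

#' Read a tracker configuration file
#'
#' Flat YAML key/value document. Recognised keys mirror the SORT-family
#' parameter names (`MAX_DIST`, `MAX_IOU_DISTANCE`, `MAX_AGE`, `N_INIT`,
#' `NN_BUDGET`) and the light-weight tracker keys (`history_window`,
#' `rematch_period`, `max_lost_age`, `cost_gate`, `iou_gate`, `weights`).
#' Unknown keys are carried through untouched.
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key/value mapping", call. = FALSE)
  cfg
}
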