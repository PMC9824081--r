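#' Axis-aligned bounding box
#'
#' Boxes are stored in MOT-Challenge convention: continuous pixel
#' coordinates, origin at the top-left of the image, `(x, y)` the left/top
#' edge and `(w, h)` the width/height. Width and height must be strictly
#' positive so the aspect ratio `w / h` is always finite and positive.
#'
#' @param x,y Left and top edge, in pixels.
#' @param w,h Width and height, in pixels; must be `> 0`.
#' @return A named numeric vector of class `"bbox"` with elements
#'   `x`, `y`, `w`, `h`.
#' @examples
#' b <- bbox(10, 20, 50, 80)
#' bbox_centroid(b)
#' bbox_aspect(b)
#' @export
bbox <- function(x, y, w, h) {
  v <- c(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
  if (any(!is.finite(v)))
    stop("bbox coordinates must be finite", call. = FALSE)
  if (v[["w"]] <= 0 || v[["h"]] <= 0)
    stop("bbox width and height must be > 0", call. = FALSE)
  class(v) <- "bbox"
  v
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n",
              x[["x"]], x[["y"]], x[["w"]], x[["h"]]))
  invisible(x)
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  b <- as.numeric(b)
  if (length(b) != 4) stop("expected 4 box coordinates", call. = FALSE)
  bbox(b[1], b[2], b[3], b[4])
}

#' Box centroid
#'
#' @param b A [bbox()] (or any numeric `c(x, y, w, h)`).
#' @return Numeric `c(x, y)` centre of the box in pixels.
#' @export
bbox_centroid <- function(b) {
  b <- as_bbox(b)
  c(x = b[["x"]] + b[["w"]] / 2, y = b[["y"]] + b[["h"]] / 2)
}

#' Box aspect ratio (width over height)
#'
#' @inheritParams bbox_centroid
#' @return `w / h`, dimensionless.
#' @export
bbox_aspect <- function(b) {
  b <- as_bbox(b)
  b[["w"]] / b[["h"]]
}

#' Intersection over union of two boxes
#'
#' The usual overlap-area over union-area ratio used both as an
#' association gate and as the detection/ground-truth match criterion.
#' Symmetric, 1 for identical boxes, 0 for disjoint boxes.
#'
#' @param a,b Boxes ([bbox()] or numeric `c(x, y, w, h)`).
#' @return Ratio in `[0, 1]`.
#' @examples
#' bbox_iou(bbox(0, 0, 2, 2), bbox(1, 0, 2, 2))  # 1/3
#' @export
bbox_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  ix <- min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]]) - max(a[["x"]], b[["x"]])
  iy <- min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]]) - max(a[["y"]], b[["y"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter)
}

#' Pairwise IoU matrix
#'
#' Vectorised IoU between every row of `a` and every row of `b`.
#'
#' @param a,b Data frames (or matrices) with columns `x`, `y`, `w`, `h`.
#' @return A `nrow(a) x nrow(b)` matrix of IoU values.
#' @export
bbox_iou_matrix <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  ax2 <- a$x + a$w; ay2 <- a$y + a$h
  bx2 <- b$x + b$w; by2 <- b$y + b$h
  for (j in seq_len(nb)) {
    ix <- pmin(ax2, bx2[j]) - pmax(a$x, b$x[j])
    iy <- pmin(ay2, by2[j]) - pmax(a$y, b$y[j])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    out[, j] <- inter / (a$w * a$h + b$w[j] * b$h[j] - inter)
  }
  out
}
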