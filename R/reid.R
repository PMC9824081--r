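#' Re-identification CNN architecture descriptor
#'
#' The 10-layer convolutional network used to learn cattle appearance
#' embeddings from 128 x 128 crops: two 3x3 convolutions, a max-pool,
#' four residual blocks, and a dense projection to a 128-dimensional
#' descriptor followed by batch normalisation and ReLU. The descriptor is
#' data, not a model: it specifies layer names, patch size/stride and
#' output shapes for anyone wiring a deep-learning backend, and is
#' validated by [validate_reid_architecture()]. Training metadata (Adam,
#' learning rate 1e-5, batch 128, early stop at 100 epochs) is attached
#' as attributes.
#'
#' @return A data frame with columns `layer`, `name`, `patch_stride`,
#'   `channels`, `height`, `width` (spatial layers) — `height`/`width`
#'   `NA` for flat layers — and attribute `training`.
#' @export
reid_architecture <- function() {
  arch <- data.frame(
    layer = 1:10,
    name = c("Conv 1", "Conv 2", "Max Pool", "Residual 4", "Residual 5",
             "Residual 6", "Residual 7", "Dense 8",
             "Batch Normalization", "Relu"),
    patch_stride = c("3 x 3/1", "3 x 3/1", "3 x 3/2", "3 x 3/1", "3 x 3/1",
                     "3 x 3/2", "3 x 3/1", "-", "3 x 3/1", "3 x 3/1"),
    channels = c(32L, 32L, 32L, 32L, 64L, 64L, 128L, 128L, 128L, 128L),
    height = c(128L, 128L, 64L, 64L, 32L, 32L, 16L, NA, NA, NA),
    width = c(128L, 128L, 64L, 64L, 32L, 32L, 16L, NA, NA, NA))
  attr(arch, "input_size") <- c(128L, 128L)
  attr(arch, "embedding_dim") <- 128L
  attr(arch, "training") <- list(optimizer = "Adam", learning_rate = 1e-5,
                                 batch_size = 128L, max_epochs = 100L)
  class(arch) <- c("reid_architecture", "data.frame")
  arch
}

#' Validate shape chaining of an architecture descriptor
#'
#' Checks that each spatial layer's input (the previous layer's output)
#' downsamples to its output by an integer factor, that channel width
#' never decreases, that flat layers preserve the embedding width, and
#' that the final width equals the declared embedding dimension. The
#' effective stride is derived from consecutive output sizes; published
#' per-layer stride annotations for residual blocks are not trusted, as
#' residual downsampling is conventionally annotated inconsistently.
#'
#' @param arch A [reid_architecture()]-shaped data frame.
#' @return `TRUE` invisibly; stops with a message on the first
#'   inconsistency.
#' @export
validate_reid_architecture <- function(arch = reid_architecture()) {
  inp <- attr(arch, "input_size")
  prev <- list(channels = NA_integer_, height = inp[1], width = inp[2],
               flat = FALSE)
  for (i in seq_len(nrow(arch))) {
    row <- arch[i, ]
    flat <- is.na(row$height)
    if (flat) {
      if (!prev$flat && i > 1 && is.na(prev$channels))
        stop("flat layer before any feature layer", call. = FALSE)
      if (prev$flat && row$channels != prev$channels)
        stop(sprintf("layer %d changes flat width %d -> %d", i,
                     prev$channels, row$channels), call. = FALSE)
    } else {
      if (prev$flat)
        stop(sprintf("layer %d is spatial after flattening", i),
             call. = FALSE)
      for (dim in c("height", "width")) {
        ratio <- prev[[dim]] / row[[dim]]
        if (ratio %% 1 != 0 || ratio < 1)
          stop(sprintf("layer %d %s %d does not divide input %d", i, dim,
                       row[[dim]], prev[[dim]]), call. = FALSE)
      }
      if (!is.na(prev$channels) && row$channels < prev$channels)
        stop(sprintf("layer %d shrinks channels %d -> %d", i,
                     prev$channels, row$channels), call. = FALSE)
    }
    prev <- list(channels = row$channels, height = row$height,
                 width = row$width, flat = flat)
  }
  if (prev$channels != attr(arch, "embedding_dim"))
    stop("final width does not match declared embedding dimension",
         call. = FALSE)
  invisible(TRUE)
}

#' Resize a crop to the embedding input size
#'
#' @param img Grayscale image matrix.
#' @param size Target side length (default 128).
#' @return A `size x size` matrix.
#' @export
resize_crop <- function(img, size = 128L) {
  if (!is.matrix(img) || !nrow(img) || !ncol(img))
    stop("crop must be a non-empty matrix", call. = FALSE)
  out <- EBImage::resize(img, w = size, h = size)
  matrix(as.numeric(out), size, size)
}

#' Handcrafted 128-dimensional appearance embedding
#'
#' A deterministic descriptor satisfying the same contract as a trained
#' re-identification network: 128 x 128 grayscale crop in, L2-normalised
#' 128-vector out. The crop is divided into a 4 x 4 spatial grid and an
#' 8-bin intensity histogram is taken per cell (4 x 4 x 8 = 128), which
#' keeps coarse spatial layout and coat-shade information while being
#' invariant to nothing in particular — identical crops map to identical
#' vectors, which is all the tracker's gallery requires.
#'
#' @param crop A 128 x 128 numeric matrix with values in `[0, 1]`
#'   (use [resize_crop()] first if needed).
#' @return Numeric vector of length 128 with unit L2 norm.
#' @export
embed_crop <- function(crop) {
  if (!is.matrix(crop) || nrow(crop) == 0 || ncol(crop) == 0)
    stop("crop must be a non-empty matrix", call. = FALSE)
  if (nrow(crop) != ncol(crop))
    stop("crop must be square; resize_crop() first", call. = FALSE)
  if (nrow(crop) != 128L) crop <- resize_crop(crop)
  breaks <- seq(0, 1, length.out = 9)
  v <- numeric(128)
  idx <- 1L
  bounds <- round(seq(0, 128, length.out = 5))
  for (gi in 1:4) for (gj in 1:4) {
    cell <- crop[(bounds[gi] + 1):bounds[gi + 1],
                 (bounds[gj] + 1):bounds[gj + 1]]
    counts <- tabulate(findInterval(pmin(pmax(cell, 0), 1 - 1e-9), breaks,
                                    rightmost.closed = TRUE),
                       nbins = 8)
    v[idx:(idx + 7L)] <- counts
    idx <- idx + 8L
  }
  v / sqrt(sum(v^2))
}

#' Cosine distance between embeddings
#'
#' @param a,b Numeric vectors of equal length.
#' @return `1 - cos(a, b)`, in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("embedding dimensionality mismatch", call. = FALSE)
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Unsupervised identity split of detection crops
#'
#' Greedy agglomeration used to build a re-identification dataset without
#' manual labels: crops are processed in `(frame, detection)` order and
#' each joins the existing group whose medoid (mean embedding,
#' renormalised) is most similar, provided the cosine similarity exceeds
#' `threshold`; otherwise it founds a new group. Among groups passing the
#' threshold, a group seen within the last `adjacency` frames whose last
#' box centroid lies within `spatial_gate` pixels is preferred (spatial
#' continuity); the threshold itself is evaluated on raw appearance
#' similarity only, so the split degenerates predictably: threshold 0
#' gives one group, threshold above 1 gives singletons.
#'
#' @param crops A list; each element a list with `crop` (matrix), `frame`
#'   (integer) and `box` (`c(x, y, w, h)`).
#' @param threshold Cosine-similarity cutoff for joining a group.
#' @param spatial_gate Centroid distance (pixels) considered continuous
#'   (default 150).
#' @param adjacency Frame window for the spatial-continuity preference
#'   (default 5).
#' @return A list of class `"identity_split"`: `assignment` (integer
#'   vector, group per crop), `groups` (list of crop index vectors), and
#'   `n_groups`.
#' @export
split_identities <- function(crops, threshold, spatial_gate = 150,
                             adjacency = 5L) {
  n <- length(crops)
  assignment <- integer(n)
  if (!n) return(structure(list(assignment = assignment, groups = list(),
                                n_groups = 0L), class = "identity_split"))
  ord <- order(vapply(crops, function(cr) cr$frame, numeric(1)),
               seq_len(n))
  emb <- lapply(crops, function(cr) embed_crop(cr$crop))
  groups <- list()   # each: sum_emb, n, last_frame, last_centroid, members
  for (i in ord) {
    e <- emb[[i]]
    fr <- crops[[i]]$frame
    ctr <- bbox_centroid(crops[[i]]$box)
    best <- 0L; best_key <- -Inf
    for (g in seq_along(groups)) {
      med <- groups[[g]]$sum_emb / sqrt(sum(groups[[g]]$sum_emb^2))
      sim <- sum(med * e)
      if (sim >= threshold) {
        near <- (fr - groups[[g]]$last_frame) <= adjacency &&
          sqrt(sum((ctr - groups[[g]]$last_centroid)^2)) <= spatial_gate
        key <- sim + if (near) 2 else 0   # continuity outranks raw sim
        if (key > best_key) { best_key <- key; best <- g }
      }
    }
    if (best == 0L) {
      groups[[length(groups) + 1L]] <-
        list(sum_emb = e, n = 1L, last_frame = fr, last_centroid = ctr,
             members = i)
      assignment[i] <- length(groups)
    } else {
      groups[[best]]$sum_emb <- groups[[best]]$sum_emb + e
      groups[[best]]$n <- groups[[best]]$n + 1L
      groups[[best]]$last_frame <- fr
      groups[[best]]$last_centroid <- ctr
      groups[[best]]$members <- c(groups[[best]]$members, i)
      assignment[i] <- best
    }
  }
  structure(list(assignment = assignment,
                 groups = lapply(groups, `[[`, "members"),
                 n_groups = length(groups)),
            class = "identity_split")
}

# deterministic path hash for the train/test split
split_hash <- function(path) {
  codes <- utf8ToInt(path)
  (sum(codes * seq_along(codes)) * 2654435761) %% 2^31
}

#' Export an identity-split crop set as a re-ID dataset
#'
#' Writes one directory per identity group containing the group's crops
#' as PNG files, plus a plain-text manifest (`path<TAB>identity<TAB>split`)
#' with a deterministic 80/20 train/test split keyed on each crop's
#' relative path hash. Empty groups are skipped; re-exporting over the
#' same directory is idempotent.
#'
#' @param split An `identity_split` from [split_identities()].
#' @param crops The same crop list the split was computed from.
#' @param dir Output directory.
#' @return The manifest as a data frame, invisibly; written to
#'   `dir/manifest.tsv`.
#' @export
export_reid_dataset <- function(split, crops, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  seen <- character(0)
  for (g in seq_along(split$groups)) {
    members <- split$groups[[g]]
    if (!length(members)) next
    gdir <- sprintf("id_%03d", g)
    dir.create(file.path(dir, gdir), showWarnings = FALSE)
    for (m in members) {
      rel <- file.path(gdir, sprintf("crop_%05d.png", m))
      if (rel %in% seen)
        stop("output path collision: ", rel, call. = FALSE)
      seen <- c(seen, rel)
      png::writePNG(pmin(pmax(crops[[m]]$crop, 0), 1), file.path(dir, rel))
      manifest[[length(manifest) + 1L]] <-
        data.frame(path = rel, identity = g,
                   split = if (split_hash(rel) %% 5 == 0) "test" else "train")
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(path = character(0), identity = integer(0),
               split = character(0))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Crop detections out of a rendered frame and embed them
#'
#' Convenience appearance provider for [run_sort()]: renders the
#' scenario's frame, cuts each detection's crop, resizes to 128 x 128 and
#' embeds with [embed_crop()].
#'
#' @param scenario A `sim_scenario` (rendered on the fly).
#' @return A function `(frame_index, dets) -> embedding matrix` suitable
#'   as `embed_fn`.
#' @export
scenario_embedder <- function(scenario) {
  force(scenario)
  function(t, dets) {
    img <- render_frame(scenario, t)
    do.call(rbind, lapply(seq_len(nrow(dets)), function(j) {
      embed_crop(resize_crop(crop_box(img, c(dets$x[j], dets$y[j],
                                             dets$w[j], dets$h[j]))))
    }))
  }
}
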