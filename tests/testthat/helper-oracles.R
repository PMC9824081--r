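# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: assignments are found by exhaustive
# enumeration and CLEAR events are counted by a direct transcription of
# the definitions.

# all injective partial mappings rows -> cols of a given cardinality
enumerate_matchings <- function(n, m, k) {
  if (k == 0L) return(list(cbind(row = integer(0), col = integer(0))))
  out <- list()
  rowsets <- utils::combn(n, k, simplify = FALSE)
  colperms <- perms_of(seq_len(m), k)
  for (rs in rowsets) for (cp in colperms)
    out[[length(out) + 1L]] <- cbind(row = rs, col = cp)
  out
}

perms_of <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_of(v[-i], k - 1L))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# cache of enumerated matchings, keyed by "n:m:k"; each entry holds the
# row and column index matrices (one matching per row)
.matching_cache <- new.env(parent = emptyenv())

matching_index_sets <- function(n, m, k) {
  key <- paste(n, m, k, sep = ":")
  if (!is.null(.matching_cache[[key]])) return(.matching_cache[[key]])
  mm <- enumerate_matchings(n, m, k)
  rows <- do.call(rbind, lapply(mm, function(x) x[, "row"]))
  cols <- do.call(rbind, lapply(mm, function(x) x[, "col"]))
  out <- list(rows = matrix(rows, ncol = k), cols = matrix(cols, ncol = k))
  .matching_cache[[key]] <- out
  out
}

# exhaustive maximum-cardinality minimum-cost feasible matching
brute_gated_assignment <- function(cost, feasible) {
  n <- nrow(cost); m <- ncol(cost)
  for (k in min(n, m):1) {
    ms <- matching_index_sets(n, m, k)
    lin <- as.vector(ms$rows + (ms$cols - 1L) * n)
    ok <- rowSums(matrix(feasible[lin], ncol = k)) == k
    if (!any(ok)) next
    tot <- rowSums(matrix(cost[lin], ncol = k))
    tot[!ok] <- Inf
    best <- which.min(tot)
    return(list(matches = cbind(row = ms$rows[best, ],
                                col = ms$cols[best, ]),
                total_cost = tot[best]))
  }
  list(matches = cbind(row = integer(0), col = integer(0)), total_cost = 0)
}

brute_iou <- function(a, b) {
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  ix * iy / (a[3] * a[4] + b[3] * b[4] - ix * iy)
}

# brute-force CLEAR event counter: persistence of last-known pairs, then
# exhaustive max-cardinality max-total-IoU matching (small frames only)
brute_clear_counts <- function(gt, pred, iou_thr = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  last_match <- list()
  fn <- 0L; fp <- 0L; idsw <- 0L; gt_tot <- 0L
  for (t in frames) {
    g <- gt[gt$frame == t, , drop = FALSE]
    p <- pred[pred$frame == t, , drop = FALSE]
    ng <- nrow(g); np <- nrow(p)
    gt_tot <- gt_tot + ng
    iou <- matrix(0, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np))
      iou[i, j] <- brute_iou(as.numeric(g[i, c("x", "y", "w", "h")]),
                             as.numeric(p[j, c("x", "y", "w", "h")]))
    mg <- integer(0); mp <- integer(0)
    for (i in seq_len(ng)) {
      pid <- last_match[[as.character(g$id[i])]]
      if (is.null(pid)) next
      j <- match(pid, p$id)
      if (!is.na(j) && !(j %in% mp) && iou[i, j] >= iou_thr) {
        mg <- c(mg, i); mp <- c(mp, j)
      }
    }
    fg <- setdiff(seq_len(ng), mg); fpj <- setdiff(seq_len(np), mp)
    if (length(fg) && length(fpj)) {
      sub <- iou[fg, fpj, drop = FALSE]
      res <- brute_gated_assignment(-sub, sub >= iou_thr)
      if (nrow(res$matches)) {
        mg <- c(mg, fg[res$matches[, "row"]])
        mp <- c(mp, fpj[res$matches[, "col"]])
      }
    }
    for (k in seq_along(mg)) {
      gid <- as.character(g$id[mg[k]])
      pid <- p$id[mp[k]]
      prev <- last_match[[gid]]
      if (!is.null(prev) && prev != pid) idsw <- idsw + 1L
      last_match[[gid]] <- pid
    }
    fn <- fn + ng - length(mg)
    fp <- fp + np - length(mp)
  }
  c(GT = gt_tot, FN = fn, FP = fp, IDSW = idsw)
}

# reference all-points-interpolated AP from an ordered TP/FP flag vector
brute_ap <- function(tp_flags, n_gt) {
  cum_tp <- cumsum(tp_flags)
  rec <- cum_tp / n_gt
  prec <- cum_tp / seq_along(tp_flags)
  total <- 0
  r_prev <- 0
  for (i in seq_along(tp_flags)) {
    p_env <- max(prec[i:length(prec)])
    total <- total + (rec[i] - r_prev) * p_env
    r_prev <- rec[i]
  }
  total
}

# run the independent Python/SciPy CLEAR accumulator over a directory of
# scenario subdirectories each holding gt.txt and pred.txt
python_clear_counts <- function(root, iou_thr = 0.5) {
  script <- system.file("oracle", "clear_mot_oracle.py",
                        package = "herdtrack")
  out <- suppressWarnings(
    system2("python", c(script, "--root", shQuote(root),
                        "--iou", iou_thr),
            stdout = TRUE, stderr = FALSE))
  jsonlite::fromJSON(paste(out, collapse = ""))
}
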