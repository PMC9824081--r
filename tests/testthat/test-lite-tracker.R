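test_that("first frame issues consecutive IDs, one per detection", {
  dets <- data.frame(x = c(0, 100, 200), y = 0, w = 20, h = 20, conf = 1)
  st <- lite_step(lite_init(), 1, dets)
  rec <- lite_records(st)
  expect_equal(rec$id, 1:3)
  expect_equal(rec$frame, rep(1L, 3))
})

test_that("a stationary detection keeps its track at zero cost", {
  st <- lite_init()
  box <- data.frame(x = 50, y = 50, w = 20, h = 20, conf = 1)
  for (t in 1:5) st <- lite_step(st, t, box)
  rec <- lite_records(st)
  expect_equal(unique(rec$id), 1L)
  expect_equal(nrow(rec), 5)
})

test_that("matching pairs nearest tracks and respects gates", {
  cfg <- lite_config()
  st <- lite_init(cfg)
  st <- lite_step(st, 1, data.frame(x = c(0, 100), y = 0, w = 10, h = 10))
  st <- lite_step(st, 2, data.frame(x = c(2, 98), y = 0, w = 10, h = 10))
  rec <- lite_records(st)
  # nearest pairing: track 1 follows x 0 -> 2, track 2 follows 100 -> 98
  expect_equal(rec$id[rec$frame == 2 & rec$x == 2], 1L)
  expect_equal(rec$id[rec$frame == 2 & rec$x == 98], 2L)
  # a detection beyond the cost gate opens a new track
  st2 <- lite_init(cfg)
  st2 <- lite_step(st2, 1, data.frame(x = 0, y = 0, w = 10, h = 10))
  st2 <- lite_step(st2, 2, data.frame(x = 5000, y = 0, w = 10, h = 10))
  rec2 <- lite_records(st2)
  expect_equal(sort(unique(rec2$id)), 1:2)
})

test_that("lite_match equals brute-force optimum on small instances", {
  set.seed(404)
  cfg <- lite_config(cost_gate = 50)
  for (rep in 1:60) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    tracks <- lapply(seq_len(m), function(i) {
      x0 <- runif(1, 0, 300); y0 <- runif(1, 0, 300)
      herdtrack:::new_lite_track(i, 1L,
        data.frame(x = x0, y = y0, w = 20, h = 20), FALSE)
    })
    dets <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300),
                       w = 20, h = 20)
    res <- lite_match(tracks, dets, cfg)
    cost <- matrix(Inf, m, n); feas <- matrix(FALSE, m, n)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      cb <- match_cost(herdtrack:::lite_track_history(tracks[[i]]),
                       c(dets$x[j], dets$y[j], dets$w[j], dets$h[j]),
                       n = cfg$history_window)
      cost[i, j] <- cb$cost
      feas[i, j] <- cb$cost <= cfg$cost_gate && cb$iou >= cfg$iou_gate
    }
    ref <- brute_gated_assignment(cost, feas)
    expect_equal(nrow(res$matches), nrow(ref$matches))
    if (nrow(res$matches))
      expect_equal(sum(cost[res$matches]), ref$total_cost,
                   tolerance = 1e-9)
  }
})

test_that("fast cost path agrees with match_cost on random histories", {
  set.seed(505)
  cfg <- lite_config()
  for (rep in 1:40) {
    len <- sample(1:8, 1)
    xs <- cumsum(runif(len, -5, 5)) + 100
    ys <- cumsum(runif(len, -5, 5)) + 100
    ws <- runif(len, 10, 30); hs <- runif(len, 10, 30)
    tr <- herdtrack:::new_lite_track(1L, 1L,
      data.frame(x = xs[1], y = ys[1], w = ws[1], h = hs[1]), FALSE)
    if (len > 1) for (k in 2:len)
      tr <- herdtrack:::lite_track_append(tr, k,
        data.frame(x = xs[k], y = ys[k], w = ws[k], h = hs[k]), 60L)
    dets <- data.frame(x = runif(3, 50, 150), y = runif(3, 50, 150),
                       w = runif(3, 10, 30), h = runif(3, 10, 30))
    fast <- herdtrack:::lite_costs(tr, dets, cfg)
    for (j in 1:3) {
      ref <- match_cost(herdtrack:::lite_track_history(tr),
                        c(dets$x[j], dets$y[j], dets$w[j], dets$h[j]),
                        n = cfg$history_window)
      expect_equal(fast$cost[j], ref$cost, tolerance = 1e-9)
      expect_equal(fast$iou[j], ref$iou, tolerance = 1e-9)
    }
  }
})

test_that("perfect detections of separated targets track cleanly", {
  cfg <- sim_config(n_cattle = 2, n_frames = 100, miss_rate = 0,
                    fp_rate = 0, jitter_sd = 0, occlusion_merge_iou = 1,
                    seed = 42)
  sc <- simulate_scenario(cfg)
  rec <- track_lite(sc$detections, n_frames = 100)
  rep <- evaluate_tracking(sc$gt, rec)
  expect_equal(rep$mota, 1)
  expect_equal(rep$idsw, 0L)
  expect_equal(rep$tracked_count, 2L)
})

test_that("an occluded target regains its ID at the re-match boundary", {
  occ <- make_occlusion_scenario(seed = 5, hide_id = 3,
                                 hide_frames = 20:59)
  rec <- track_lite(occ$dets, n_frames = 120)
  rep <- evaluate_tracking(occ$gt, rec)
  expect_equal(rep$idsw, 0L)
  expect_equal(length(unique(rec$id)), 5L)
  expect_equal(rep$fragmentations, 1L)
  # the re-appearing detections ended up under the original ID
  expect_true(all(sort(unique(rec$id)) == 1:5))
})

test_that("a far-away new detection gets a fresh ID at re-match", {
  st <- lite_init(lite_config(rematch_period = 10))
  # one track, lost from frame 3
  st <- lite_step(st, 1, data.frame(x = 0, y = 0, w = 10, h = 10))
  st <- lite_step(st, 2, data.frame(x = 0, y = 0, w = 10, h = 10))
  for (t in 3:9) st <- lite_step(st, t,
                                 data.frame(x = numeric(0), y = numeric(0),
                                            w = numeric(0), h = numeric(0)))
  st <- lite_step(st, 10, data.frame(x = 4000, y = 4000, w = 10, h = 10))
  rec <- lite_records(st)
  expect_equal(sort(unique(rec$id)), c(1L, 2L))
  # in-place reappearance instead: the old ID is restored
  st2 <- lite_init(lite_config(rematch_period = 10))
  st2 <- lite_step(st2, 1, data.frame(x = 0, y = 0, w = 10, h = 10))
  st2 <- lite_step(st2, 2, data.frame(x = 0, y = 0, w = 10, h = 10))
  for (t in 3:9) st2 <- lite_step(st2, t, data.frame(x = numeric(0),
                                                     y = numeric(0),
                                                     w = numeric(0),
                                                     h = numeric(0)))
  st2 <- lite_step(st2, 10, data.frame(x = 0, y = 0, w = 10, h = 10))
  rec2 <- lite_records(st2)
  expect_equal(unique(rec2$id), 1L)
})

test_that("one lost track cannot give its ID to two new detections", {
  st <- lite_init(lite_config(rematch_period = 10))
  st <- lite_step(st, 1, data.frame(x = 0, y = 0, w = 10, h = 10))
  st <- lite_step(st, 2, data.frame(x = 0, y = 0, w = 10, h = 10))
  for (t in 3:9) st <- lite_step(st, t, data.frame(x = numeric(0),
                                                   y = numeric(0),
                                                   w = numeric(0),
                                                   h = numeric(0)))
  st <- lite_step(st, 10, data.frame(x = c(0, 12), y = 0, w = 10, h = 10))
  rec <- lite_records(st)
  last <- rec[rec$frame == 10, ]
  expect_equal(nrow(last), 2)
  expect_equal(sum(last$id == 1L), 1)   # exactly one inherits
})

test_that("pruning deletes lost tracks strictly past the age limit", {
  cfg <- lite_config(max_lost_age = 5, rematch_period = 1000)
  st <- lite_init(cfg)
  st <- lite_step(st, 1, data.frame(x = 0, y = 0, w = 10, h = 10))
  st <- lite_step(st, 2, data.frame(x = 0, y = 0, w = 10, h = 10))
  empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0))
  for (t in 3:7) st <- lite_step(st, t, empty)   # age now 7 - 2 = 5
  expect_equal(st$tracks[[1]]$status, "lost")
  st <- lite_step(st, 8, empty)                  # age 6 > 5
  expect_equal(st$tracks[[1]]$status, "deleted")
})

test_that("IDs are strictly increasing and never reused", {
  set.seed(77)
  cfg <- sim_config(n_cattle = 6, n_frames = 120, miss_rate = 0.1,
                    fp_rate = 0.3, jitter_sd = 2, seed = 99)
  sc <- simulate_scenario(cfg)
  frames <- split_frames(sc$detections, 120)
  st <- lite_init()
  seen_new <- integer(0)
  for (t in seq_along(frames)) {
    prev_next <- st$next_id
    st <- lite_step(st, t, frames[[t]])
    if (st$next_id > prev_next)
      seen_new <- c(seen_new, prev_next:(st$next_id - 1L))
  }
  expect_identical(seen_new, sort(unique(seen_new)))  # monotone issue
  rec <- lite_records(st)
  # within any frame: no duplicate ids, no duplicate detections
  per_frame <- split(rec$id, rec$frame)
  expect_true(all(vapply(per_frame, anyDuplicated, integer(1)) == 0))
})

test_that("the tracker is deterministic", {
  cfg <- sim_config(n_cattle = 5, n_frames = 80, seed = 31)
  sc <- simulate_scenario(cfg)
  r1 <- track_lite(sc$detections, n_frames = 80)
  r2 <- track_lite(sc$detections, n_frames = 80)
  expect_identical(r1, r2)
})

test_that("out-of-order frames are rejected", {
  st <- lite_init()
  st <- lite_step(st, 5, data.frame(x = 0, y = 0, w = 10, h = 10))
  expect_error(lite_step(st, 5, data.frame(x = 0, y = 0, w = 10, h = 10)),
               "increasing order")
})

test_that("greedy assignment option runs and stays one-to-one", {
  cfg <- sim_config(n_cattle = 4, n_frames = 50, seed = 13)
  sc <- simulate_scenario(cfg)
  rec <- track_lite(sc$detections, lite_config(assignment = "greedy"),
                    n_frames = 50)
  per_frame <- split(rec$id, rec$frame)
  expect_true(all(vapply(per_frame, anyDuplicated, integer(1)) == 0))
})
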