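test_that("IoU matches hand-computed areas and rejects degenerate boxes", {
  expect_equal(bbox_iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1)
  expect_equal(bbox_iou(bbox(0, 0, 10, 10), bbox(100, 100, 5, 5)), 0)
  # overlap 1x2 = 2, union 4 + 4 - 2 = 6
  expect_equal(bbox_iou(bbox(0, 0, 2, 2), bbox(1, 0, 2, 2)), 1 / 3)
  expect_error(bbox(0, 0, 0, 5), "width and height")
  expect_error(bbox(0, 0, 5, -1), "width and height")
  expect_error(bbox(Inf, 0, 1, 1), "finite")
})

test_that("IoU is symmetric and bounded on random boxes", {
  set.seed(42)
  for (i in 1:200) {
    a <- bbox(runif(1, -50, 50), runif(1, -50, 50), runif(1, 0.1, 30),
              runif(1, 0.1, 30))
    b <- bbox(runif(1, -50, 50), runif(1, -50, 50), runif(1, 0.1, 30),
              runif(1, 0.1, 30))
    ab <- bbox_iou(a, b)
    expect_identical(ab, bbox_iou(b, a))
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
  a <- bbox(3, -2, 7, 5)
  expect_equal(bbox_iou(a, a), 1)
})

test_that("centroid is the box midpoint", {
  expect_equal(unname(bbox_centroid(bbox(0, 0, 10, 20))), c(5, 10))
  expect_equal(unname(bbox_centroid(bbox(3, 4, 0.5, 0.5))), c(3.25, 4.25))
  expect_equal(unname(bbox_centroid(bbox(-5, -5, 10, 10))), c(0, 0))
})

test_that("location distance averages consecutive centroid steps", {
  h <- track_history(1:3, data.frame(x = c(0, 3, 6), y = c(0, 4, 8),
                                     w = 2, h = 2))
  expect_equal(location_distance(h, 2), 5)         # two 3-4-5 steps
  expect_equal(location_distance(h, 1), 5)         # last step only
  h1 <- track_history(1:2, data.frame(x = c(0, 0), y = c(0, 7),
                                      w = 2, h = 2))
  expect_equal(location_distance(h1, 1), 7)
  stat <- track_history(1:6, data.frame(x = rep(5, 6), y = 5, w = 3,
                                        h = 2))
  expect_equal(location_distance(stat, 5), 0)
  single <- track_history(1L, data.frame(x = 0, y = 0, w = 1, h = 1))
  expect_error(location_distance(single), "at least 2")
})

test_that("aspect distance averages absolute aspect-ratio steps", {
  # Ar sequence 1.0, 1.5, 1.0
  h <- track_history(1:3, data.frame(x = 0, y = 0, w = c(2, 3, 2), h = 2))
  expect_equal(aspect_distance(h, 2), 0.5)
  const <- track_history(1:4, data.frame(x = 1:4, y = 1, w = 4, h = 2))
  expect_equal(aspect_distance(const, 3), 0)
  h2 <- track_history(1:2, data.frame(x = 0, y = 0, w = c(4, 2), h = 2))
  expect_equal(aspect_distance(h2, 1), 1)          # Ar 2 -> 1
})

test_that("match_cost sums weighted distances and reports IoU", {
  h <- track_history(1:2, data.frame(x = c(0, 0), y = 0, w = 10, h = 10))
  cb <- match_cost(h, bbox(0, 0, 10, 10))
  expect_s3_class(cb, "cost_breakdown")
  expect_equal(cb$cost, 0)
  expect_equal(cb$iou, 1)
  # weight projection: (0, 1) leaves only the aspect term
  h2 <- track_history(1:2, data.frame(x = c(0, 3), y = c(0, 4),
                                      w = c(2, 3), h = 2))
  full <- match_cost(h2, bbox(6, 8, 2, 2))
  ar_only <- match_cost(h2, bbox(6, 8, 2, 2), weights = c(0, 1))
  expect_equal(ar_only$cost, ar_only$ardist)
  expect_equal(full$cost, full$ldist + full$ardist)
  expect_gt(full$ldist, 0)
})

test_that("cost is translation invariant and scales like the units", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    xs <- cumsum(runif(n, -5, 5)); ys <- cumsum(runif(n, -5, 5))
    ws <- runif(n, 2, 8); hs <- runif(n, 2, 8)
    h0 <- track_history(seq_len(n), data.frame(x = xs, y = ys, w = ws,
                                               h = hs))
    cand <- bbox(xs[n] + 1, ys[n] + 2, ws[n], hs[n])
    c0 <- match_cost(h0, cand)
    # joint translation
    dx <- runif(1, -100, 100); dy <- runif(1, -100, 100)
    ht <- track_history(seq_len(n), data.frame(x = xs + dx, y = ys + dy,
                                               w = ws, h = hs))
    ct <- match_cost(ht, bbox(xs[n] + 1 + dx, ys[n] + 2 + dy, ws[n], hs[n]))
    expect_equal(ct$cost, c0$cost, tolerance = 1e-12)
    # scaling by s multiplies Ldist by s, leaves Ardist unchanged
    s <- runif(1, 0.5, 3)
    hs2 <- track_history(seq_len(n), data.frame(x = xs * s, y = ys * s,
                                                w = ws * s, h = hs * s))
    cs <- match_cost(hs2, bbox((xs[n] + 1) * s, (ys[n] + 2) * s,
                               ws[n] * s, hs[n] * s))
    expect_equal(cs$ldist, s * c0$ldist, tolerance = 1e-9)
    expect_equal(cs$ardist, c0$ardist, tolerance = 1e-9)
  }
})

test_that("distances are zero only for a constant windowed history", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    mov <- track_history(seq_len(n),
                         data.frame(x = cumsum(c(0, runif(n - 1, 0.5, 3))),
                                    y = 0, w = 2, h = 2))
    expect_gt(location_distance(mov, n - 1), 0)
    expect_gte(aspect_distance(mov, n - 1), 0)
  }
})

test_that("history validates frame ordering and box sizes", {
  expect_error(track_history(c(1, 1), data.frame(x = 0:1, y = 0, w = 1,
                                                 h = 1)),
               "strictly increasing")
  expect_error(track_history(1:2, data.frame(x = 0:1, y = 0, w = c(1, 0),
                                             h = 1)),
               "> 0")
})

test_that("mask-area channel is optional and enters cost only when weighted", {
  h <- track_history(1:3, data.frame(x = rep(0, 3), y = 0, w = 2, h = 2),
                     mask_area = c(100, 90, 110))
  cb0 <- match_cost(h, bbox(0, 0, 2, 2), candidate_mask_area = 100)
  expect_equal(cb0$cost, 0)             # default weight 0
  expect_false(is.na(cb0$mask_dist))
  cbw <- match_cost(h, bbox(0, 0, 2, 2), weights = c(1, 1, 1),
                    candidate_mask_area = 100)
  expect_equal(cbw$cost, cbw$mask_dist)
  h2 <- track_history(1:2, data.frame(x = c(0, 0), y = 0, w = 2, h = 2))
  expect_error(match_cost(h2, bbox(0, 0, 2, 2), weights = c(1, 1, 1)),
               "mask")
})
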