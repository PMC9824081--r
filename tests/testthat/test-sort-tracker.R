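new_track <- function(box = c(10, 10, 20, 40), id = 1L,
                      cfg = sort_config()) {
  herdtrack:::new_kalman_track(id, box, cfg)
}

test_that("prediction keeps a zero-velocity box in place and inflates noise", {
  cfg <- sort_config()
  tr <- new_track()
  tr1 <- kf_predict(tr, cfg)
  expect_equal(unname(tr1$predicted_box), c(10, 10, 20, 40),
               tolerance = 1e-9)
  expect_equal(tr1$time_since_update, 1L)
  # covariance trace strictly increases under predict without update
  tr2 <- kf_predict(tr1, cfg)
  expect_gt(sum(diag(tr2$cov)), sum(diag(tr1$cov)))
})

test_that("two exact updates teach the filter a velocity", {
  cfg <- sort_config()
  tr <- new_track(c(0, 0, 20, 40))
  tr <- kf_predict(tr, cfg)
  tr <- kf_update(tr, c(10, 0, 20, 40), cfg)   # moved +10 in x
  tr <- kf_predict(tr, cfg)
  tr <- kf_update(tr, c(20, 0, 20, 40), cfg)   # +10 again
  tr <- kf_predict(tr, cfg)
  # prediction continues the constant-velocity motion
  expect_equal(unname(tr$predicted_box[1]), 30, tolerance = 1.5)
  expect_equal(unname(tr$predicted_box[2]), 0, tolerance = 0.5)
})

test_that("update with the predicted measurement leaves the mean unchanged", {
  cfg <- sort_config()
  tr <- kf_predict(new_track(), cfg)
  z <- herdtrack:::meas_to_box(tr$mean[1:4])
  tr2 <- kf_update(tr, z, cfg)
  expect_equal(tr2$mean[1:4], tr$mean[1:4], tolerance = 1e-9)
  expect_equal(tr2$time_since_update, 0L)
  expect_equal(tr2$hits, tr$hits + 1L)
  # covariance of measured components does not increase
  expect_lte(sum(diag(tr2$cov)[1:4]), sum(diag(tr$cov)[1:4]) + 1e-12)
})

test_that("repeated identical measurements converge to that box", {
  cfg <- sort_config()
  tr <- new_track(c(0, 0, 20, 40))
  target <- c(100, 60, 30, 30)
  for (i in 1:60) {
    tr <- kf_predict(tr, cfg)
    tr <- kf_update(tr, target, cfg)
  }
  expect_equal(unname(herdtrack:::meas_to_box(tr$mean[1:4])), target,
               tolerance = 0.5)
})

test_that("appearance stage gates at the configured cosine distance", {
  cfg <- sort_config(max_dist = 0.9)
  e1 <- unit_embedding(1)
  tr <- herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg,
                                     embedding = e1)
  tr <- kf_predict(tr, cfg)
  # identical embedding: distance 0, matched in stage 1 despite zero IoU
  far_det <- data.frame(x = 500, y = 500, w = 10, h = 10)
  res <- sort_associate(list(tr), far_det, matrix(e1, 1), cfg)
  expect_equal(nrow(res$matches), 1)
  # distance 0.95 > 0.9: stage 1 forbidden; stage 2 fails too (IoU 0)
  e_far <- sqrt(1 - 0.05^2) * unit_embedding(2) + 0.05 * e1
  res2 <- sort_associate(list(tr), far_det, matrix(e_far, 1), cfg)
  expect_equal(nrow(res2$matches), 0)
})

test_that("IoU stage gates at the configured IoU distance", {
  cfg <- sort_config(max_iou_distance = 0.8)
  tr <- kf_predict(herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg),
                   cfg)
  # IoU 1/3 -> distance 2/3 <= 0.8: allowed
  near <- data.frame(x = 5, y = 0, w = 10, h = 10)
  expect_equal(nrow(sort_associate(list(tr), near, NULL, cfg)$matches), 1)
  # IoU 0.1 -> distance 0.9 > 0.8: forbidden
  thin <- data.frame(x = 0, y = 0, w = 100, h = 10)  # IoU 10x10/100x10 = 0.1
  expect_equal(nrow(sort_associate(list(tr), thin, NULL, cfg)$matches), 0)
})

test_that("embedding dimensionality mismatches are rejected", {
  cfg <- sort_config()
  tr <- kf_predict(herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg,
                                                embedding = unit_embedding(1)),
                   cfg)
  expect_error(sort_associate(list(tr), data.frame(x = 0, y = 0, w = 10,
                                                   h = 10),
                              matrix(1, 1, 64), cfg),
               "dimensionality")
})

test_that("lifecycle confirms at n_init, deletes past max_age", {
  cfg <- sort_config(n_init = 1)
  tr <- herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg)
  expect_equal(tr$state, "confirmed")   # N_INIT 1: confirmed immediately
  cfg3 <- sort_config(n_init = 3)
  tr3 <- herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg3)
  expect_equal(tr3$state, "tentative")
  tr3$hits <- 3L
  tr3 <- lifecycle_update(tr3, TRUE, cfg3)
  expect_equal(tr3$state, "confirmed")
  # unmatched tentative dies immediately
  td <- herdtrack:::new_kalman_track(2L, c(0, 0, 10, 10), cfg3)
  expect_equal(lifecycle_update(td, FALSE, cfg3)$state, "deleted")
  # confirmed survives exactly max_age frames without association
  cfg_age <- sort_config(max_age = 1500)
  tc <- herdtrack:::new_kalman_track(3L, c(0, 0, 10, 10), cfg_age)
  tc$time_since_update <- 1500L
  expect_equal(lifecycle_update(tc, FALSE, cfg_age)$state, "confirmed")
  tc$time_since_update <- 1501L
  expect_equal(lifecycle_update(tc, FALSE, cfg_age)$state, "deleted")
  # deleted is terminal
  tc$state <- "deleted"
  expect_error(lifecycle_update(tc, TRUE, cfg_age), "deleted")
})

test_that("the gallery is FIFO-bounded by nn_budget", {
  cfg <- sort_config(nn_budget = 100)
  tr <- herdtrack:::new_kalman_track(1L, c(0, 0, 10, 10), cfg)
  for (i in 1:100)
    tr <- lifecycle_update(tr, TRUE, cfg, embedding = unit_embedding(i))
  expect_length(tr$gallery, 100)
  first <- tr$gallery[[1]]
  tr <- lifecycle_update(tr, TRUE, cfg, embedding = unit_embedding(101))
  expect_length(tr$gallery, 100)       # capacity held
  expect_false(identical(tr$gallery[[1]], first))  # oldest evicted
  expect_identical(tr$gallery[[100]], unit_embedding(101))
})

test_that("run_sort handles empty and single-target sequences", {
  empty <- split_frames(data.frame(frame = integer(0), id = integer(0),
                                   x = numeric(0), y = numeric(0),
                                   w = numeric(0), h = numeric(0),
                                   conf = numeric(0)), 5)
  expect_equal(nrow(run_sort(empty)), 0)
  one <- data.frame(frame = 1:50, id = -1L, x = 10 + (1:50), y = 20,
                    w = 30, h = 30, conf = 1)
  rec <- run_sort(one, n_frames = 50)
  expect_equal(unique(rec$id), 1L)
  expect_equal(nrow(rec), 50)
})

test_that("perfect detections with one-hot embeddings track without switches", {
  cfg <- sim_config(n_cattle = 8, n_frames = 150, miss_rate = 0,
                    fp_rate = 0, jitter_sd = 0, occlusion_merge_iou = 1,
                    seed = 21)
  sc <- simulate_scenario(cfg)
  rec <- run_sort(sc$detections, sort_config(),
                  embed_fn = make_gt_embedder(sc$gt), n_frames = 150)
  rep <- evaluate_tracking(sc$gt, rec)
  expect_equal(rep$mota, 1)
  expect_equal(rep$idsw, 0L)
})

test_that("the SORT tracker is deterministic", {
  cfg <- sim_config(n_cattle = 5, n_frames = 60, seed = 77)
  sc <- simulate_scenario(cfg)
  expect_identical(run_sort(sc$detections, n_frames = 60),
                   run_sort(sc$detections, n_frames = 60))
})
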