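# Connected-component extraction, threshold stability search, cleanup, cap

test_that("component extraction filters by size and computes weighted centroids", {
  dims <- c(40, 40, 40); vox <- 0.4
  aff <- diag(c(vox, vox, vox, 1))
  ct <- array(-1000, dims)
  ct[10:12, 10:12, 10:12] <- 3000          # 27 voxels
  v <- as_volume(ct, aff)
  comp <- extract_components(v, 2500)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$n_voxels, 27L)
  expect_equal(comp$volume_mm3, 27 * vox^3, tolerance = 1e-12)
  ctr <- voxel_to_world(v, c(11, 11, 11))
  expect_equal(c(comp$x, comp$y, comp$z), as.double(ctr), tolerance = 1e-12)

  # 5-voxel blob rejected (needs > 6), 600-voxel blob rejected (>= 33.5 mm3)
  ct2 <- array(-1000, dims)
  ct2[5:9, 5, 5] <- 3000
  ct2[20:29, 20:29, 20:25] <- 3000         # 600 voxels = 38.4 mm3
  comp2 <- extract_components(as_volume(ct2, aff), 2500)
  expect_equal(nrow(comp2), 0L)
  comp2all <- extract_components(as_volume(ct2, aff), 2500, filter = FALSE)
  expect_setequal(comp2all$n_voxels, c(5L, 600L))

  # intensity-weighted centroid: x-indices 0,1,2 with weights 1,2,3
  ct3 <- array(0, dims)
  ct3[1:3, 1, 1] <- 1:3
  comp3 <- extract_components(as_volume(ct3, diag(4)), 0.5, filter = FALSE)
  expect_equal(comp3$x, 8 / 6, tolerance = 1e-12)  # 0-based voxel x = 1.333
})

test_that("optimal-threshold choice follows the stable-segment rule", {
  th <- 1:7
  # one long stable run containing the highest count
  res <- choose_optimal_threshold(c(10, 12, 11, 11, 2, 1, 0), th, 5)
  expect_equal(res$index, 2L)            # centre of run 1..4 (lower middle)
  # a jump splits segments; winner is the segment with the larger max
  res2 <- choose_optimal_threshold(c(3, 3, 20, 19, 18, 2, 2), th, 5)
  expect_equal(res2$index, 4L)           # centre of 3..5
  # tie on max count: longer segment wins, then lower threshold
  res3 <- choose_optimal_threshold(c(9, 9, 0, 9, 9, 9, 0), th, 5)
  expect_equal(res3$index, 5L)           # run 4..6 longer than 1..2
  res4 <- choose_optimal_threshold(c(9, 9, 0, 9, 9, 0, 0), th, 5)
  expect_equal(res4$index, 1L)           # equal length: earlier run
})

test_that("chosen threshold reproduces a brute-force rule implementation", {
  # independent oracle written from the rule text
  brute <- function(counts, delta) {
    n <- length(counts)
    segs <- list(); cur <- c(1)
    for (i in seq_len(n - 1)) {
      if (abs(counts[i + 1] - counts[i]) <= delta) cur <- c(cur, i + 1)
      else { segs[[length(segs) + 1]] <- cur; cur <- c(i + 1) }
    }
    segs[[length(segs) + 1]] <- cur
    maxes <- vapply(segs, function(s) max(counts[s]), double(1))
    lens <- lengths(segs)
    starts <- vapply(segs, `[`, double(1), 1)
    best <- order(-maxes, -lens, starts)[1]
    s <- segs[[best]]
    s[ceiling(length(s) / 2)]
  }
  set.seed(42)
  for (rep in 1:200) {
    counts <- pmax(0, round(cumsum(rnorm(21, 0, 4)) + 20))
    expect_equal(choose_optimal_threshold(counts, seq_len(21), 5)$index,
                 brute(counts, 5))
  }
})

test_that("auto detection recovers every planted contact on the default phantom", {
  ph <- fix_phantom()
  det <- auto_detect(ph$ct, ph$surfaces$projection)
  vox <- ph$spec$voxel_mm
  m <- match_detections(as.matrix(ph$truth[, c("x", "y", "z")]),
                        as.matrix(det$electrodes[, c("x", "y", "z")]),
                        tol_mm = vox)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$false_positives, 0)
  expect_lt(m$max_err, 0.5 * vox)
  expect_equal(nrow(det$curve), 21L)
  expect_true(det$optimal_threshold_hu %in% det$curve$threshold_hu)
})

test_that("an empty CT yields an empty result with a fully populated curve", {
  flat <- as_volume(array(-1000 + runif(20^3), dim = c(20, 20, 20)), diag(4))
  det <- auto_detect(flat, fix_sphere_mesh())
  expect_equal(nrow(det$electrodes), 0L)
  expect_equal(det$curve$n_detected, rep(0L, 21))
  expect_true(is.na(det$optimal_threshold_hu))
})

test_that("cleanup keeps the brighter of two sub-millimetre detections and is idempotent", {
  det <- data.frame(n_voxels = 10, volume_mm3 = 1,
                    mean_intensity = c(3000, 2500, 2800),
                    x = c(0, 0.8, 10), y = 0, z = 0)
  cl <- electrolocate:::cleanup_close(det, 1)
  expect_equal(sort(cl$mean_intensity), c(2800, 3000))
  expect_identical(electrolocate:::cleanup_close(cl, 1), cl)
  # two actual blobs with centres 0.8 mm apart (2 voxels at 0.4 mm),
  # separated by one sub-threshold voxel so they form distinct components
  dims <- c(60, 60, 60); vox <- 0.4
  aff <- diag(c(vox, vox, vox, 1))
  ct <- array(-1000, dims)
  ct[20, 28:32, 28:32] <- 3200         # 25 voxels, centre x-index 20
  ct[22, 28:32, 28:32] <- 2900         # 25 voxels, centre x-index 22
  comp <- extract_components(as_volume(ct, aff), 2000, filter = FALSE)
  expect_equal(nrow(comp), 2L)
  cl2 <- electrolocate:::cleanup_close(comp, 1)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$mean_intensity, 3200)
})

test_that("detections are invariant under positive affine intensity maps", {
  ph <- fix_phantom()
  det1 <- auto_detect(ph$ct, ph$surfaces$projection)
  # pure scaling: voxel sets AND centroids identical (weights proportional)
  det_s <- auto_detect(as_volume(2 * ph$ct$data, ph$ct$affine),
                       ph$surfaces$projection)
  o1 <- order(det1$electrodes$x, det1$electrodes$y)
  os <- order(det_s$electrodes$x, det_s$electrodes$y)
  expect_equal(as.matrix(det_s$electrodes[os, c("x", "y", "z")]),
               as.matrix(det1$electrodes[o1, c("x", "y", "z")]),
               tolerance = 1e-12)
  expect_equal(det_s$optimal_threshold_hu, 2 * det1$optimal_threshold_hu,
               tolerance = 1e-9)
  # affine map with offset: same voxel sets, counts and threshold scale;
  # raw-intensity weighting moves centroids only at the micrometre level
  ct2 <- as_volume(2 * ph$ct$data + 100, ph$ct$affine)
  det2 <- auto_detect(ct2, ph$surfaces$projection)
  expect_equal(det2$curve$n_detected, det1$curve$n_detected)
  expect_equal(nrow(det2$electrodes), nrow(det1$electrodes))
  o2 <- order(det2$electrodes$x, det2$electrodes$y)
  expect_equal(as.matrix(det2$electrodes[o2, c("x", "y", "z")]),
               as.matrix(det1$electrodes[o1, c("x", "y", "z")]),
               tolerance = 1e-3)
  expect_equal(det2$optimal_threshold_hu, 2 * det1$optimal_threshold_hu + 100,
               tolerance = 1e-9)
})

test_that("the electrode cap keeps exactly the brightest contacts", {
  u3 <- electrolocate:::unit3
  leads <- list(
    list(spec = lead_spec("A", 8, 3.5), entry = c(-10, -6, -8),
         direction = u3(c(0.15, 0.2, 0.97)), electrode_hu = 3000),
    list(spec = lead_spec("B", 8, 3.5), entry = c(10, -6, -8),
         direction = u3(c(-0.15, 0.2, 0.97)), electrode_hu = 2700),
    list(spec = lead_spec("C", 8, 3.5), entry = c(0, 10, -8),
         direction = u3(c(0, -0.25, 0.97)), electrode_hu = 2400))
  ph <- make_head_phantom(phantom_spec(voxel_mm = 0.8, leads = leads))
  surf <- build_surfaces(ph$gm, ph$wm)
  det <- auto_detect(ph$ct, surf$projection,
                     detection_config(max_electrodes = 16))
  expect_equal(nrow(det$electrodes), 16L)
  tp <- as.matrix(ph$truth[, c("x", "y", "z")])
  dp <- as.matrix(det$electrodes[, c("x", "y", "z")])
  D <- as.matrix(dist(rbind(tp, dp)))[seq_len(nrow(tp)),
                                      nrow(tp) + seq_len(nrow(dp))]
  matched_names <- ph$truth$name[apply(D, 2, which.min)]
  expect_setequal(unique(matched_names), c("A", "B"))  # two brightest leads
})

test_that("manual detection matches the automatic centroid and respects manual draw", {
  ph <- fix_phantom()
  truth1 <- as.double(ph$truth[1, c("x", "y", "z")])
  e <- manual_detect(ph$ct, truth1 + c(0.9, 0, 0), 1700)
  expect_lt(sqrt(sum((c(e$x, e$y, e$z) - truth1)^2)), 1e-9)
  e2 <- manual_detect(ph$ct, c(10.0, -4.2, 13.1), 1700, manual_draw = TRUE)
  expect_equal(c(e2$x, e2$y, e2$z), c(10.0, -4.2, 13.1))
  expect_error(manual_detect(ph$ct, c(-30, -30, -30), 1700),
               "no component near click")
  expect_error(manual_detect(ph$ct, c(500, 0, 0), 1700), "field of view")
})
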