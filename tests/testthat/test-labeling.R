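# Contact spheres, rank-sum test, gray/white classification, deformation
# fields and atlas labels

test_that("sphere voxels match a brute-force scan and analytic volume", {
  dims <- c(31, 31, 31); vox <- 0.4
  aff <- diag(c(vox, vox, vox, 1)); aff[1:3, 4] <- -(dims - 1) / 2 * vox
  g <- as_volume(array(0, dims), aff)
  ctr <- as.double(voxel_to_world(g, c(16, 16, 16)))   # on a voxel centre
  sv <- sphere_voxels(ctr, 1.3, g)
  # brute force over the full grid
  n_brute <- 0
  for (k in seq_len(dims[3])) {
    w <- slab_world_test(g, k)
    n_brute <- n_brute + sum(rowSums(sweep(w, 2, ctr)^2) <= 1.3^2)
  }
  expect_equal(nrow(sv), n_brute)
  # sub-half-voxel radius captures exactly the central voxel
  expect_equal(nrow(sphere_voxels(ctr, 0.1, g)), 1L)
  # voxelized volume close to analytic at 0.4 mm
  expect_lt(abs(nrow(sv) * vox^3 - 4 / 3 * pi * 1.3^3),
            0.15 * 4 / 3 * pi * 1.3^3)
  # sphere entirely outside the grid
  expect_equal(nrow(sphere_voxels(c(100, 0, 0), 1.3, g)), 0L)
})

test_that("rank-sum p-values are symmetric, exact under identity, and match enumeration", {
  x <- c(0.9, 0.8, 0.85, 0.95)
  expect_equal(rank_sum_p(x, x), 1)
  expect_lt(rank_sum_p(rep(0.9, 20), rep(0.1, 20)), 0.001)
  set.seed(31)
  for (rep in 1:12) {
    a <- round(runif(sample(4:8, 1)), 2)
    b <- round(runif(sample(4:8, 1)) + runif(1, -0.3, 0.3), 2)
    expect_equal(rank_sum_p(a, b), rank_sum_p(b, a))
    expect_equal(rank_sum_p(a, b), enum_rank_sum_p(a, b), tolerance = 1e-12)
  }
  # no-tie case cross-checked against the standard implementation
  set.seed(32)
  a <- rnorm(9); b <- rnorm(8) + 0.4
  expect_equal(rank_sum_p(a, b),
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(rank_sum_p(numeric(0), 1), "non-empty")
})

test_that("gray/white classification follows the unknown/default/test rules", {
  dims <- c(21, 21, 21); vox <- 0.4
  aff <- diag(c(vox, vox, vox, 1)); aff[1:3, 4] <- -(dims - 1) / 2 * vox
  mk <- function(val) as_volume(array(val, dims), aff)
  # both means < 0.1 -> unknown
  expect_equal(classify_gray_white(c(0, 0, 0), mk(0.05), mk(0.05)), "unknown")
  # overlapping samples, p large -> default gray
  set.seed(41)
  g <- as_volume(array(runif(prod(dims), 0.4, 0.6), dims), aff)
  w <- as_volume(array(runif(prod(dims), 0.4, 0.6), dims), aff)
  expect_equal(classify_gray_white(c(0, 0, 0), g, w), "gray")
  # clear white separation
  expect_equal(classify_gray_white(c(0, 0, 0), mk(0.02), mk(0.95)), "white")
  # clear gray separation
  expect_equal(classify_gray_white(c(0, 0, 0), mk(0.95), mk(0.02)), "gray")
  # empty sphere -> unknown with warning
  expect_warning(
    cls <- classify_gray_white(c(100, 100, 100), mk(0.9), mk(0.1)),
    "outside")
  expect_equal(cls, "unknown")
})

test_that("classification recovers planted tissue across 200 random placements", {
  ph <- fix_phantom()
  shell <- ph$spec$gray_shell_mm
  radii <- ph$spec$brain_radii_mm
  set.seed(17)
  n_done <- 0; depths <- c()
  while (n_done < 200) {
    u <- runif(3, -1, 1)
    p <- u * radii
    d <- electrolocate:::ellipsoid_depth(p, radii)[1]
    # keep contacts planted >= 2 mm inside gray or white, or clearly outside
    cls_true <- if (d <= -2) "unknown"
    else if (d >= 2 && d <= shell - 2) "gray"
    else if (d >= shell + 2) "white"
    else next
    if (cls_true == "unknown" && d < -6) next   # stay near the head
    got <- classify_gray_white(p, ph$gm, ph$wm)
    expect_equal(got, cls_true,
                 label = sprintf("class at depth %.2f", d))
    n_done <- n_done + 1; depths <- c(depths, d)
  }
  expect_gt(sum(depths > 0), 50)   # both sides of the boundary exercised
})

test_that("deformation fields warp points exactly for identity, shift and affine", {
  dims <- c(16, 16, 16)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -15
  g <- as_volume(array(0, dims), aff)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  w <- voxel_to_world(g, idx)
  mk_field <- function(target) {
    m <- array(0, dim = c(dims, 3))
    for (c3 in 1:3) m[, , , c3] <- array(target[, c3], dim = dims)
    deformation_field(m, aff, "patient_to_mni")
  }
  set.seed(51)
  pts <- cbind(runif(100, -12, 12), runif(100, -12, 12), runif(100, -12, 12))
  # identity
  expect_equal(warp_points(pts, mk_field(w)), pts, tolerance = 1e-9)
  # constant translation
  sh <- warp_points(pts, mk_field(sweep(w, 2, c(-5, 0, 0))))
  expect_equal(sh, sweep(pts, 2, c(-5, 0, 0)), tolerance = 1e-9)
  # general affine: trilinear interpolation is exact for affine fields
  A <- matrix(c(1.02, 0.05, 0, 0,
                -0.05, 0.98, 0.01, 0,
                0, 0.02, 1.05, 0,
                3, -2, 1, 1), 4, 4)
  fa <- mk_field(cbind(w, 1) %*% t(A))
  wa <- warp_points(pts, fa)
  expect_equal(wa, (cbind(pts, 1) %*% t(A))[, 1:3], tolerance = 1e-6)
  # composing with the inverse-affine field returns the originals
  ginv <- as_volume(array(0, dims), A %*% aff)
  winv <- voxel_to_world(ginv, idx)
  minv <- array(0, dim = c(dims, 3))
  back <- (cbind(winv, 1) %*% t(solve(A)))[, 1:3]
  for (c3 in 1:3) minv[, , , c3] <- array(back[, c3], dim = dims)
  finv <- deformation_field(minv, A %*% aff, "mni_to_patient")
  expect_equal(warp_points(wa, finv), pts, tolerance = 1e-5)
  # out-of-domain points are reported
  expect_error(warp_points(rbind(c(0, 0, 0), c(500, 0, 0)), fa),
               "outside field domain")
})

test_that("atlas labels: modal rule, boundary fractions, exclusion and ties", {
  dims <- c(41, 41, 41); vox <- 1
  aff <- diag(c(vox, vox, vox, 1)); aff[1:3, 4] <- -20
  g <- as_volume(array(0, dims), aff)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  w <- voxel_to_world(g, idx)
  idf <- local({   # identity field on the patient grid
    m <- array(0, dim = c(dims, 3))
    for (c3 in 1:3) m[, , , c3] <- array(w[, c3], dim = dims)
    deformation_field(m, aff, "patient_to_mni")
  })
  # single-label atlas
  one <- atlas_volume(as_volume(array(1, dims), aff, "mni"),
                      data.frame(index = 1, name = "everything"))
  res <- assign_atlas_labels(c(0, 0, 0), one, idf, g)
  expect_equal(res$modal_label, "everything")
  expect_equal(res$prob_labels$fraction, 1)
  # planar boundary placed at the 40% spherical-cap offset of an 8-mm
  # sphere (cap height 6.93 -> plane at x = 1.07): majority label wins and
  # the reported fractions equal a direct voxel count over the sphere
  two_arr <- array(1L, dims)
  two_arr[w[, 1] > 1.07] <- 2L
  two <- atlas_volume(as_volume(two_arr, aff, "mni"),
                      data.frame(index = 1:2, name = c("left", "right")))
  res2 <- assign_atlas_labels(c(0, 0, 0), two, idf, g,
                              label_config(prob_radius_mm = 8))
  expect_equal(res2$modal_label, "left")
  fr <- res2$prob_labels
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  # voxel-count oracle on the constructed geometry
  sv <- sphere_voxels(c(0, 0, 0), 8, g)
  frac_right <- mean(two_arr[attr(sv, "flat")] == 2L)
  expect_equal(fr$fraction[fr$label == "right"], frac_right,
               tolerance = 1e-12)
  expect_equal(fr$fraction[fr$label == "left"], 1 - frac_right,
               tolerance = 1e-12)
  # and the voxelized split itself approximates the analytic 60/40 cap
  expect_lt(abs(frac_right - 0.4), 0.06)
  expect_gt(fr$fraction[fr$label == "left"],
            fr$fraction[fr$label == "right"])
  # a region worth ~4% of the sphere is stored but excluded at 5%
  small_arr <- array(1L, dims)
  small_arr[w[, 1] > 6.05] <- 3L   # spherical cap ~4% of an 8-mm sphere
  sm <- atlas_volume(as_volume(small_arr, aff, "mni"),
                     data.frame(index = c(1, 3), name = c("bulk", "sliver")))
  res3 <- assign_atlas_labels(c(0, 0, 0), sm, idf, g,
                              label_config(prob_radius_mm = 8))
  sliver <- res3$prob_labels[res3$prob_labels$label == "sliver", ]
  expect_equal(nrow(sliver), 1L)
  expect_lt(sliver$fraction, 0.05)
  expect_false("sliver" %in% filter_prob_labels(res3$prob_labels)$label)
  # 50/50 tie breaks to the lower label index
  tie_arr <- array(1L, dims)
  tie_arr[w[, 1] > 0] <- 2L
  tie <- atlas_volume(as_volume(tie_arr, aff, "mni"),
                      data.frame(index = 1:2, name = c("lo", "hi")))
  res4 <- assign_atlas_labels(c(0.5, 0, 0), tie, idf, g)
  expect_equal(res4$modal_index, 1L)
  # background-modal contacts are unlabelled
  bg_arr <- array(0L, dims); bg_arr[1, 1, 1] <- 1L
  bg <- atlas_volume(as_volume(bg_arr, aff, "mni"),
                     data.frame(index = 1, name = "x"))
  expect_equal(assign_atlas_labels(c(0, 0, 0), bg, idf, g)$modal_label,
               "unlabelled")
})

test_that("phantom deformation fields reproduce truth labels and invert cleanly", {
  ph <- fix_phantom()
  p <- as.matrix(ph$truth[, c("x", "y", "z")])
  w <- warp_points(p, ph$field_to_mni)
  want <- (cbind(p, 1) %*% t(ph$mni_affine))[, 1:3]
  expect_lt(max(abs(w - want)), 1e-6)
  # forward then inverse returns the original points
  back <- warp_points(w, ph$field_to_patient)
  expect_lt(max(abs(back - p)), 1e-5)
  # truth labels recovered for interior contacts
  es <- electrode_set(x = p[, 1], y = p[, 2], z = p[, 3])
  es <- label_electrodes(es, ph$atlas, ph$field_to_mni, ph$gm)
  interior <- ph$truth$atlas_margin_mm > 2 & ph$truth$depth_mm > 2
  expect_true(all(es$atlas_octants[interior] ==
                    ph$truth$atlas_true[interior]))
  pl <- attr(es, "prob_labels")$octants
  for (q in which(interior)[1:5]) {
    expect_equal(sum(pl[[q]]$fraction), 1, tolerance = 1e-12)
    expect_false(is.unsorted(rev(pl[[q]]$fraction)))
  }
})

test_that("atlas warped to patient space agrees with per-electrode labels", {
  ph <- fix_phantom()
  lw <- warp_atlas_to_patient(ph$atlas, ph$field_to_mni, ph$gm)
  expect_true(is.integer(lw$data) || all(lw$data == round(lw$data)))
  # identity-check version: field grid = atlas grid, identity mapping
  dims <- c(15, 15, 15)
  aff <- diag(4); aff[1:3, 4] <- -7
  g <- as_volume(array(0, dims), aff)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  w <- voxel_to_world(g, idx)
  m <- array(0, dim = c(dims, 3))
  for (c3 in 1:3) m[, , , c3] <- array(w[, c3], dim = dims)
  idf <- deformation_field(m, aff, "patient_to_mni")
  lab_arr <- array(sample(1:4, prod(dims), replace = TRUE), dims)
  atl <- atlas_volume(as_volume(lab_arr, aff, "mni"),
                      data.frame(index = 1:4, name = letters[1:4]))
  lw_id <- warp_atlas_to_patient(atl, idf, g)
  expect_equal(as.vector(lw_id$data), as.vector(lab_arr))
  # pure translation field shifts labels accordingly
  mt <- m; mt[, , , 1] <- mt[, , , 1] + 1    # sample 1 mm to the right
  ft <- deformation_field(mt, aff, "patient_to_mni")
  lw_sh <- warp_atlas_to_patient(atl, ft, g)
  expect_equal(lw_sh$data[1:(dims[1] - 1), , ], lab_arr[2:dims[1], , ])
  # per-electrode consistency on the phantom: modal label from the sphere
  # equals the modal label read from the warped volume for >= 95% of contacts
  es <- electrode_set(x = ph$truth$x, y = ph$truth$y, z = ph$truth$z)
  es <- label_electrodes(es, ph$atlas, ph$field_to_mni, ph$gm,
                         fill_mni = FALSE)
  agree <- vapply(seq_len(nrow(es)), function(q) {
    sv <- sphere_voxels(c(es$x[q], es$y[q], es$z[q]), 1.3, ph$gm)
    flat <- attr(sv, "flat")
    tt <- table(lw$data[flat])
    cand <- as.integer(names(tt)[tt == max(tt)])
    nm <- if (min(cand) == 0L) "unlabelled" else
      ph$atlas$table$name[match(min(cand), ph$atlas$table$index)]
    nm == es$atlas_octants[q]
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
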