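# Lead spacing correction, grid/strip projection, projection vectors,
# inline rotation

test_that("spacing correction reproduces the stepwise hand trace", {
  out <- correct_lead_spacing(rbind(c(0, 0, 0), c(0, 0, 4.5), c(0, 0, 9.5)),
                              lead_spec("T", 3, 5))
  expect_equal(out, rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("collinear contacts at nominal spacing are a fixed point", {
  spec <- lead_spec("L", 6, 3.5)
  pts <- make_lead_positions(c(1, 2, 3), c(0.6, 0.64, 0.48), spec)
  expect_equal(correct_lead_spacing(pts, spec), pts, tolerance = 1e-12)
})

test_that("grouped-gap leads come out at exactly their nominal gaps", {
  spec <- lead_spec("G", 4, c(3.5, 3.5, 7))
  set.seed(8)
  pts <- make_lead_positions(c(0, 0, 0), c(0, 0, 1), spec)
  pts[2:4, ] <- pts[2:4, ] + matrix(runif(9, -0.4, 0.4), 3, 3)
  out <- correct_lead_spacing(pts, spec)
  gaps <- sqrt(rowSums(diff(out)^2))
  expect_equal(gaps, c(3.5, 3.5, 7), tolerance = 1e-9)
  expect_equal(out[1, ], pts[1, ])     # deepest contact untouched
})

test_that("jittered leads are straightened with sub-millimetre corrections", {
  set.seed(13)
  spec <- lead_spec("L", 10, 3.5)
  chord_dev <- function(p) {
    d <- electrolocate:::unit3(p[nrow(p), ] - p[1, ])
    rel <- sweep(p, 2, p[1, ])
    proj <- rel - outer(as.double(rel %*% d), d)
    max(sqrt(rowSums(proj^2)))
  }
  for (rep in 1:20) {
    dir <- electrolocate:::unit3(rnorm(3))
    true <- make_lead_positions(rnorm(3, sd = 5), dir, spec)
    jit <- true
    jit[2:10, ] <- jit[2:10, ] + matrix(runif(27, -0.5, 0.5), 9, 3)
    corr <- correct_lead_spacing(jit, spec)
    gaps <- sqrt(rowSums(diff(corr)^2))
    expect_lt(max(abs(gaps - 3.5)), 1e-9)
    expect_equal(corr[1, ], jit[1, ])
    expect_lte(chord_dev(corr), chord_dev(jit) + 1e-9)
    expect_lt(median(sqrt(rowSums((corr - jit)^2))), 1)
  }
})

test_that("degenerate two-contact geometry raises an error", {
  expect_error(correct_lead_spacing(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    lead_spec("D", 2, 5)),
               "degenerate")
  # two-contact leads use the single available vector
  out <- correct_lead_spacing(rbind(c(0, 0, 0), c(0, 0, 7)),
                              lead_spec("D", 2, 5))
  expect_equal(out[2, ], c(0, 0, 5))
})

test_that("grid contacts project along the local normal onto the mesh", {
  s <- fix_sphere_mesh()               # radius ~20.6 sphere
  gs <- grid_spec(4, 4, 5)
  gp <- make_grid_positions(gs, c(0, 0, 14), c(0, 0, 1))
  es <- electrode_set(x = gp$x, y = gp$y, z = gp$z,
                      row = gp$row, col = gp$col)
  pr <- project_grid(es, gs, s)
  np <- nearest_point_on_surface(as.matrix(pr[, c("x", "y", "z")]), s)
  expect_lt(max(np$distance), electrolocate:::median_edge_length(s))
  # original positions retained
  expect_equal(pr$orig_z, gp$z)
  # all contacts moved outward (greater radius than before)
  expect_true(all(sqrt(pr$x^2 + pr$y^2 + pr$z^2) >
                  sqrt(gp$x^2 + gp$y^2 + gp$z^2) - 1e-9))
  # normalized intercontact spacing within the expected expansion band
  d_after <- as.matrix(dist(as.matrix(pr[, c("x", "y", "z")])))
  adj <- which(as.matrix(dist(cbind(gp$row, gp$col))) == 1, arr.ind = TRUE)
  ratios <- d_after[adj] / gs$pitch_mm
  expect_true(all(ratios > 0.9 & ratios < 1.2))
  # incomplete topology is rejected
  es_bad <- es; es_bad$row[2] <- 4L
  expect_error(project_grid(es_bad, gs, s), "topology")
})

test_that("strip contacts go to their nearest surface point", {
  s <- fix_sphere_mesh()
  ss <- grid_spec(1, 6, 5, "strip")
  sp <- make_grid_positions(ss, c(0, 0, 14), c(0, 0, 1))
  es <- electrode_set(x = sp$x, y = sp$y, z = sp$z,
                      row = sp$row, col = sp$col)
  pr <- project_grid(es, ss, s)
  np0 <- nearest_point_on_surface(as.matrix(sp[, c("x", "y", "z")]), s)
  expect_equal(as.matrix(pr[, c("x", "y", "z")]), np0$point,
               tolerance = 1e-9, ignore_attr = TRUE)
  disp <- sqrt((pr$x - sp$x)^2 + (pr$y - sp$y)^2 + (pr$z - sp$z)^2)
  expect_equal(disp, np0$distance, tolerance = 1e-9)
})

test_that("projection vectors follow their mode definitions", {
  expect_equal(projection_vector(c(10, 0, 0), "brain_center",
                                 mcp_mm = c(0, 0, 0)), c(1, 0, 0))
  expect_equal(projection_vector(c(1, 2, 3), "view_direction",
                                 view_dir = c(0, -1, 0)), c(0, -1, 0))
  s <- fix_sphere_mesh()
  n <- projection_vector(c(0, 0, 15), "surface_normal", projection = s)
  ang <- acos(sum(n * c(0, 0, 1)))
  expect_lt(ang, 5 * pi / 180)
  expect_error(projection_vector(c(0, 0, 0), "brain_center",
                                 mcp_mm = c(0, 0, 0)), "undefined")
})

test_that("project_along hits the surface or nudges by a signed step", {
  s <- fix_sphere_mesh()
  p <- project_along(c(10, 0, 0), c(1, 0, 0), s)
  r_eff <- mean(sqrt(rowSums(s$vertices^2)))
  expect_lt(abs(p[1] - r_eff), 0.5)
  expect_lt(max(abs(p[2:3])), 1e-9)
  expect_equal(project_along(c(1, 2, 3), c(0, 0, 1), s, step_mm = 0),
               c(1, 2, 3))
  q <- project_along(c(1, 2, 3), c(0, 0, 1), s, step_mm = -2)
  expect_equal(q, c(1, 2, 1))
  expect_equal(project_along(q, c(0, 0, 1), s, step_mm = 2), c(1, 2, 3),
               tolerance = 1e-12)
  expect_error(project_along(c(0, 0, 0), c(1, 0, 0),
                             surface(s$vertices, s$faces[1, , drop = FALSE],
                                     "projection"), step_mm = NULL),
               "misses")
})

test_that("ray intersections equal a brute-force all-triangle scan", {
  s <- fix_sphere_mesh()
  # decimated copy for the O(rays x faces) R-side oracle
  keep <- s$faces[seq(1, nrow(s$faces), by = 40), , drop = FALSE]
  small <- surface(s$vertices, keep, "projection")
  set.seed(21)
  for (q in 1:25) {
    o <- runif(3, -5, 5)
    d <- electrolocate:::unit3(rnorm(3))
    got <- electrolocate:::ray_first_hit(o, d, small)
    want <- brute_ray_hits(small, o, d)
    if (length(want) == 0) {
      expect_null(got)
    } else {
      expect_equal(got$t, want[1], tolerance = 1e-9)
    }
  }
})

test_that("inline rotation brings the lead into the viewing plane", {
  # already in plane -> identity
  t0 <- inline_rotation(c(0, 0, 0), c(0, 0, 10), c(1, 0, 0))
  expect_lt(max(abs(t0$rotation - diag(3))), 1e-12)
  # 45-degree case: rotated lead has zero x-component
  first <- c(0, 0, 0); last <- c(1, 0, 1) / sqrt(2)
  t1 <- inline_rotation(first, last, c(1, 0, 0))
  lead_rot <- rigid_apply_points(t1, rbind(first, last))
  v <- lead_rot[2, ] - lead_rot[1, ]
  expect_lt(abs(v[1]), 1e-12)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  ang <- acos(sum(electrolocate:::unit3(last - first) *
                    electrolocate:::unit3(v)))
  expect_equal(ang, pi / 4, tolerance = 1e-9)
  # the procedure is idempotent: recomputing on the rotated lead gives the
  # identity, so the in-plane condition persists
  t1b <- inline_rotation(lead_rot[1, ], lead_rot[2, ], c(1, 0, 0))
  expect_lt(max(abs(t1b$rotation - diag(3))), 1e-9)
  lead2 <- rigid_apply_points(t1b, lead_rot)
  v2 <- lead2[2, ] - lead2[1, ]
  expect_lt(abs(sum(v2 * c(1, 0, 0))), 1e-9)
  # lead parallel to the normal: deterministic 90-degree rotation
  t2 <- inline_rotation(c(0, 0, 0), c(5, 0, 0), c(1, 0, 0))
  lr <- rigid_apply_points(t2, rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_lt(abs((lr[2, ] - lr[1, ])[1]), 1e-9)
})
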