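# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default phantom at 0.8 mm with its surfaces (the workhorse fixture)
fix_phantom <- function() memo("phantom", function() {
  ph <- make_head_phantom(phantom_spec(voxel_mm = 0.8))
  ph$surfaces <- build_surfaces(ph$gm, ph$wm)
  ph
})

# solid sphere mask, radius 15 mm on a 1-mm grid centred at the origin
fix_sphere_mask <- function(radius = 15, dims = c(48, 48, 48), vox = 1) {
  key <- paste("sphmask", radius, dims[1], vox)
  memo(key, function() {
    aff <- diag(c(vox, vox, vox, 1))
    aff[1:3, 4] <- -(dims - 1) / 2 * vox
    g <- as_volume(array(0, dims), aff)
    m <- array(0, dims)
    for (k in seq_len(dims[3])) {
      w <- voxel_to_world(g, cbind(rep(seq_len(dims[1]), dims[2]),
                                   rep(seq_len(dims[2]), each = dims[1]), k))
      m[, , k] <- as.double(sqrt(rowSums(w^2)) <= radius)
    }
    as_volume(m, aff)
  })
}

# closed sphere mesh of nominal radius 20 mm (effective radius slightly
# larger: iso 0.3 of the 3-mm box-smoothed mask)
fix_sphere_mesh <- function() memo("sphmesh", function() {
  generate_surface(fix_sphere_mask(20, c(56, 56, 56), 1), 3, 0.3, "projection")
})

# world coordinates of every voxel in slab k (test-side copy)
slab_world_test <- function(vol, k) {
  dims <- dim(vol$data)
  voxel_to_world(vol, cbind(rep(seq_len(dims[1]), dims[2]),
                            rep(seq_len(dims[2]), each = dims[1]), k))
}

# brute-force closest point on one triangle via dense barycentric sampling
# (independent of the C++ closest-point routine; used on small meshes only)
brute_closest_on_tri <- function(p, a, b, c, n = 60) {
  s <- seq(0, 1, length.out = n)
  best <- Inf; bp <- a
  for (u in s) for (v in s[s <= 1 - u + 1e-12]) {
    q <- a + u * (b - a) + v * (c - a)
    d <- sum((p - q)^2)
    if (d < best) { best <- d; bp <- q }
  }
  list(point = bp, dist2 = best)
}

# brute-force all-triangle ray intersection oracle (Cramer's rule, R only)
brute_ray_hits <- function(s, origin, dir) {
  ts <- c()
  for (f in seq_len(nrow(s$faces))) {
    a <- s$vertices[s$faces[f, 1], ]
    b <- s$vertices[s$faces[f, 2], ]
    c3 <- s$vertices[s$faces[f, 3], ]
    M <- cbind(b - a, c3 - a, -dir)
    if (abs(det(M)) < 1e-12) next
    sol <- solve(M, origin - a)
    if (sol[1] >= 0 && sol[2] >= 0 && sol[1] + sol[2] <= 1 && sol[3] > 1e-9)
      ts <- c(ts, sol[3])
  }
  sort(ts)
}

# exact two-sided rank-sum p by explicit enumeration over subset choices,
# written independently of the package implementation
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  subsets <- combn(n, n1)
  ws <- apply(subsets, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# greedy matching of detections to ground truth: a truth contact is hit if a
# detection lies within tol_mm; returns sensitivity, false positives, and
# worst matched distance
match_detections <- function(truth_xyz, det_xyz, tol_mm) {
  if (nrow(det_xyz) == 0)
    return(list(sensitivity = 0, false_positives = 0, max_err = Inf))
  D <- as.matrix(dist(rbind(truth_xyz, det_xyz)))
  D <- D[seq_len(nrow(truth_xyz)),
         nrow(truth_xyz) + seq_len(nrow(det_xyz)), drop = FALSE]
  nn_truth <- apply(D, 1, min)
  nn_det <- apply(D, 2, min)
  list(sensitivity = mean(nn_truth <= tol_mm),
       false_positives = sum(nn_det > tol_mm),
       max_err = max(nn_truth))
}
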