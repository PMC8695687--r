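#' Synthetic head phantom specification
#'
#' The phantom emulates the inputs of the localization pipeline on a known
#' geometry: an ellipsoidal brain (gray shell over a white core) inside a
#' bright skull shell on an air background, electrode artifacts as Gaussian
#' blobs along SEEG lead and ECoG grid geometries, smooth gray/white
#' probability maps, a blockwise (octant) toy atlas in a synthetic "MNI"
#' space related to patient space by a known affine, and exact ground truth
#' for every planted quantity.
#'
#' Defaults mirror the pipeline's working conditions: 0.4 mm isotropic
#' voxels, skull at 1500 HU, electrode blobs peaking at 3000 HU (above the
#' CT's 99th percentile by construction), air at -1000 HU, 3.5-mm lead
#' spacing (the tightest spacing in common clinical use) and 10-mm grid
#' pitch.
#'
#' @param grid_shape Integer length-3 voxel counts; `NULL` (default) sizes
#'   the grid to fit the head with a 4-mm air margin.
#' @param voxel_mm Isotropic voxel size.
#' @param brain_radii_mm Ellipsoid semi-axes of the brain.
#' @param gray_shell_mm Thickness of the gray-matter shell.
#' @param skull_hu,electrode_hu,air_hu CT intensities of skull shell,
#'   electrode blob peak and background.
#' @param noise_sigma_hu Additive Gaussian CT noise (0 = noiseless).
#' @param leads List of SEEG leads: each a list with `spec` ([lead_spec()]),
#'   `entry` (deepest contact, mm), `direction` (unit vector, deepest to
#'   superficial) and optional per-lead `electrode_hu`. `NULL` gives three
#'   default leads.
#' @param grids List of ECoG grids: each a list with `spec` ([grid_spec()]),
#'   `center`, `normal`, optional `row_dir` and optional `electrode_hu`.
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return A list of class `eloc_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, voxel_mm = 0.4,
                         brain_radii_mm = c(22, 26, 20), gray_shell_mm = 6,
                         skull_hu = 1500, electrode_hu = 3000,
                         air_hu = -1000, noise_sigma_hu = 0,
                         leads = NULL, grids = list(), seed = 0L) {
  stopifnot(voxel_mm > 0, length(brain_radii_mm) == 3, gray_shell_mm > 0,
            gray_shell_mm < min(brain_radii_mm))
  if (is.null(leads)) leads <- default_phantom_leads()
  if (is.null(grid_shape)) {
    half <- max(brain_radii_mm) + 5 + 4      # skull gap+shell then air margin
    grid_shape <- rep(2L * as.integer(ceiling(half / voxel_mm)) + 1L, 3)
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 brain_radii_mm = as.double(brain_radii_mm),
                 gray_shell_mm = gray_shell_mm, skull_hu = skull_hu,
                 electrode_hu = electrode_hu, air_hu = air_hu,
                 noise_sigma_hu = noise_sigma_hu, leads = leads,
                 grids = grids, seed = as.integer(seed)),
            class = "eloc_phantom_spec")
}

#' Randomized phantom specification
#'
#' Draws a random but geometrically safe implant from a seed: 2-7 SEEG leads
#' with 6-8 contacts each (3.5-mm spacing), entering from below on an
#' azimuthal fan with a slight inward tilt so that trajectories never
#' approach each other, keeping all contacts inside the brain and pairwise
#' at least 2 mm apart. Used to exercise detection across many layouts.
#'
#' @param seed Integer seed (also stored in the spec).
#' @param voxel_mm Voxel size passed through to [phantom_spec()].
#' @param n_leads Number of leads; default drawn from 2-7.
#' @param noise_sigma_hu CT noise passed through.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, voxel_mm = 0.8, n_leads = NULL,
                                noise_sigma_hu = 0) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  radii <- c(22, 26, 20)
  if (is.null(n_leads)) n_leads <- sample(2:7, 1)
  az <- (seq_len(n_leads) - 1) / n_leads * 2 * pi +
    runif(1, 0, 2 * pi / n_leads)
  leads <- lapply(seq_len(n_leads), function(q) {
    nc <- sample(6:8, 1)
    r0 <- 0.55 * c(radii[1] * cos(az[q]), radii[2] * sin(az[q]))
    entry <- c(r0, -9 + runif(1, -1, 1))
    dir <- unit3(c(-0.18 * cos(az[q]), -0.18 * sin(az[q]), 0.98))
    list(spec = lead_spec(sprintf("L%02d", q), nc, 3.5),
         entry = entry, direction = dir)
  })
  phantom_spec(voxel_mm = voxel_mm, brain_radii_mm = radii,
               leads = leads, noise_sigma_hu = noise_sigma_hu, seed = seed)
}

default_phantom_leads <- function() {
  list(
    list(spec = lead_spec("LA", 8, 3.5), entry = c(-10, -6, -8),
         direction = unit3(c(0.15, 0.20, 0.97))),
    list(spec = lead_spec("LB", 8, 3.5), entry = c(10, -6, -8),
         direction = unit3(c(-0.15, 0.20, 0.97))),
    list(spec = lead_spec("LC", 8, 3.5), entry = c(0, 10, -8),
         direction = unit3(c(0, -0.25, 0.97))))
}

#' Contact positions along a lead
#'
#' The deepest contact sits at `entry`; successive contacts follow the gap
#' spacings of `spec` along `direction` (deepest to most superficial).
#'
#' @param entry Deepest contact position (mm).
#' @param direction Unit vector from deepest toward superficial.
#' @param spec An [lead_spec()].
#' @return n x 3 matrix of contact positions, deepest first.
#' @export
make_lead_positions <- function(entry, direction, spec) {
  direction <- unit3(as.double(direction))
  offs <- cumsum(c(0, spec$gap_spacings_mm))
  t(as.double(entry) + outer(direction, offs))
}

#' Contact positions of a planar grid/strip
#'
#' A `rows x cols` lattice at `pitch_mm` in the plane perpendicular to
#' `normal`, centred at `center`, with row/column labels establishing the
#' topology used by [project_grid()].
#'
#' @param spec An [grid_spec()].
#' @param center Grid centre (mm).
#' @param normal Unit plane normal.
#' @param row_dir Optional in-plane direction of increasing row index;
#'   orthogonalized against `normal`.
#' @return data.frame with `x`, `y`, `z`, `row`, `col`, `label`.
#' @export
make_grid_positions <- function(spec, center, normal, row_dir = NULL) {
  n <- unit3(as.double(normal))
  if (is.null(row_dir)) row_dir <- diag(3)[, which.min(abs(n))]
  u <- unit3(as.double(row_dir) - sum(row_dir * n) * n)
  v <- cross3(n, u)
  rows <- rep(seq_len(spec$rows), times = spec$cols)
  cols <- rep(seq_len(spec$cols), each = spec$rows)
  pos <- t(as.double(center) +
             outer(u, (rows - (spec$rows + 1) / 2) * spec$pitch_mm) +
             outer(v, (cols - (spec$cols + 1) / 2) * spec$pitch_mm))
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             row = rows, col = cols,
             label = sprintf("%s_R%dC%d", spec$name, rows, cols),
             stringsAsFactors = FALSE)
}

# Signed depth (mm) inside the brain ellipsoid: positive inside, negative
# outside, first-order distance estimate (1 - rho) / |grad rho|.
ellipsoid_depth <- function(xyz, radii) {
  xyz <- rbind2mat(xyz)
  sx <- sweep(xyz, 2, radii, "/")
  rho <- sqrt(rowSums(sx^2))
  gn <- sqrt(rowSums(sweep(xyz, 2, radii^2, "/")^2))
  d <- ifelse(rho < 1e-9, min(radii), (1 - rho) * rho / pmax(gn, 1e-12))
  d
}

# per-voxel world coordinates of a grid, one z-slab at a time
slab_world <- function(vol, k) {
  dims <- dim(vol$data)
  xy <- cbind(rep(seq_len(dims[1]), times = dims[2]),
              rep(seq_len(dims[2]), each = dims[1]))
  voxel_to_world(vol, cbind(xy, k))
}

#' Generate a synthetic head phantom
#'
#' Builds all pipeline inputs from a [phantom_spec()]: CT with skull and
#' electrode artifacts (plus optional Gaussian noise), gray/white
#' tissue-probability maps (gm + wm <= 1 everywhere), an octant-block toy
#' atlas on the synthetic MNI grid, exact affine deformation fields between
#' patient and MNI space (both directions), and a ground-truth table of every
#' planted contact with its tissue class and atlas label.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `eloc_phantom` with elements `ct`, `gm`, `wm`
#'   (`eloc_volume`s), `atlas` (`eloc_atlas`), `field_to_mni`,
#'   `field_to_patient` (`eloc_defield`s), `mni_affine` (the 4x4 ground-truth
#'   patient-to-MNI affine), `truth` (data.frame) and `spec`.
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  dims <- spec$grid_shape
  vox <- spec$voxel_mm
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- -(dims - 1) / 2 * vox
  template <- as_volume(array(0, dim = dims), affine, "patient")

  # ---- contacts and truth ---------------------------------------------
  truth <- data.frame(kind = character(0), name = character(0),
                      contact = integer(0), row = integer(0),
                      col = integer(0), x = double(0), y = double(0),
                      z = double(0), stringsAsFactors = FALSE)
  truth$peak_hu <- double(0)
  for (ld in spec$leads) {
    pos <- make_lead_positions(ld$entry, ld$direction, ld$spec)
    hu <- if (is.null(ld$electrode_hu)) spec$electrode_hu else ld$electrode_hu
    truth <- rbind(truth, data.frame(
      kind = "lead", name = ld$spec$name,
      contact = seq_len(nrow(pos)), row = NA_integer_, col = NA_integer_,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], peak_hu = hu,
      stringsAsFactors = FALSE))
  }
  for (gd in spec$grids) {
    gp <- make_grid_positions(gd$spec, gd$center, gd$normal, gd$row_dir)
    hu <- if (is.null(gd$electrode_hu)) spec$electrode_hu else gd$electrode_hu
    truth <- rbind(truth, data.frame(
      kind = "grid", name = gd$spec$name, contact = seq_len(nrow(gp)),
      row = gp$row, col = gp$col, x = gp$x, y = gp$y, z = gp$z,
      peak_hu = hu, stringsAsFactors = FALSE))
  }
  if (nrow(truth) > 0) {
    cv <- world_to_voxel(template, as.matrix(truth[, c("x", "y", "z")]))
    bad <- which(apply(cv, 1, function(r) any(r < 1) || any(r > dims)))
    if (length(bad) > 0)
      stop("contacts outside grid: ",
           paste(sprintf("%s#%d", truth$name[bad], truth$contact[bad]),
                 collapse = ", "))
  }

  # ---- tissue maps and CT, slab by slab -------------------------------
  ct <- array(spec$air_hu, dim = dims)
  gm <- array(0, dim = dims)
  wm <- array(0, dim = dims)
  depth_all <- array(0, dim = dims)
  for (k in seq_len(dims[3])) {
    w <- slab_world(template, k)
    d <- ellipsoid_depth(w, spec$brain_radii_mm)
    depth_all[, , k] <- d
    ramp <- pmin(pmax(d, 0), 1)             # 1-mm soft brain edge
    inner <- pmin(pmax(d - spec$gray_shell_mm, 0), 1)
    total <- 0.98 * ramp
    wm[, , k] <- total * inner
    gm[, , k] <- total * (1 - inner)
    skull <- d <= -3 & d > -5                # 2-mm shell, 3 mm off the brain
    slab <- ct[, , k]
    slab[skull] <- spec$skull_hu
    ct[, , k] <- slab
  }

  # ---- electrode blobs (peak electrode_hu, FWHM = 2 x contact radius) --
  sigma <- 2 * 1.3 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / vox)
  for (q in seq_len(nrow(truth))) {
    cv <- world_to_voxel(template, c(truth$x[q], truth$y[q], truth$z[q]))[1, ]
    lo <- pmax(1, floor(cv - half)); hi <- pmin(dims, ceiling(cv + half))
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    wx <- (ii - 1) * vox + affine[1, 4] - truth$x[q]
    wy <- (jj - 1) * vox + affine[2, 4] - truth$y[q]
    wz <- (kk - 1) * vox + affine[3, 4] - truth$z[q]
    d2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
    blob <- truth$peak_hu[q] * exp(-d2 / (2 * sigma^2))
    ct[ii, jj, kk] <- pmax(ct[ii, jj, kk], blob)
  }
  if (spec$noise_sigma_hu > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    ct <- ct + array(rnorm(prod(dims), 0, spec$noise_sigma_hu), dim = dims)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }

  ct <- as_volume(ct, affine, "patient")
  gm <- as_volume(gm, affine, "patient")
  wm <- as_volume(wm, affine, "patient")

  # ---- known affine between patient and synthetic MNI space -----------
  A <- phantom_mni_affine()
  mni_affine_grid <- A %*% affine             # MNI grid shares voxel layout
  mni_template <- as_volume(array(0, dim = dims), mni_affine_grid, "mni")

  map_fwd <- array(0, dim = c(dims, 3))       # patient grid -> MNI coords
  map_inv <- array(0, dim = c(dims, 3))       # MNI grid -> patient coords
  Ainv <- solve(A)
  atlas_arr <- array(0L, dim = dims)
  mni_origin <- (A %*% c(0, 0, 0, 1))[1:3]
  for (k in seq_len(dims[3])) {
    w <- slab_world(template, k)
    fw <- cbind(w, 1) %*% t(A)
    for (c3 in 1:3) map_fwd[, , k, c3] <- fw[, c3]
    wm2 <- slab_world(mni_template, k)
    bw <- cbind(wm2, 1) %*% t(Ainv)
    for (c3 in 1:3) map_inv[, , k, c3] <- bw[, c3]
    # octant atlas on the MNI grid, restricted to the warped brain
    d <- ellipsoid_depth(bw[, 1:3, drop = FALSE], spec$brain_radii_mm)
    oct <- 1L + (wm2[, 1] > mni_origin[1]) + 2L * (wm2[, 2] > mni_origin[2]) +
      4L * (wm2[, 3] > mni_origin[3])
    oct[d <= 0] <- 0L
    atlas_arr[, , k] <- oct
  }
  field_fwd <- deformation_field(map_fwd, affine, "patient_to_mni")
  field_inv <- deformation_field(map_inv, mni_affine_grid, "mni_to_patient")
  atlas <- atlas_volume(
    as_volume(atlas_arr, mni_affine_grid, "mni"),
    data.frame(index = 1:8,
               name = paste0("octant_",
                             c("LPI", "RPI", "LAI", "RAI",
                               "LPS", "RPS", "LAS", "RAS")),
               stringsAsFactors = FALSE),
    name = "octants")

  # ---- per-contact truth annotations -----------------------------------
  if (nrow(truth) > 0) {
    pd <- ellipsoid_depth(as.matrix(truth[, c("x", "y", "z")]),
                          spec$brain_radii_mm)
    truth$depth_mm <- pd
    truth$tissue_true <- ifelse(pd <= 0, "unknown",
                                ifelse(pd < spec$gray_shell_mm, "gray",
                                       "white"))
    truth$tissue_margin_mm <- pmin(abs(pd), abs(pd - spec$gray_shell_mm))
    mni <- as.matrix(truth[, c("x", "y", "z")])
    mni <- cbind(mni, 1) %*% t(A)
    truth$mni_x <- mni[, 1]; truth$mni_y <- mni[, 2]; truth$mni_z <- mni[, 3]
    oct <- 1L + (mni[, 1] > mni_origin[1]) + 2L * (mni[, 2] > mni_origin[2]) +
      4L * (mni[, 3] > mni_origin[3])
    truth$atlas_true <- ifelse(pd > 0, atlas$table$name[oct], "unlabelled")
    # distance to the nearest octant boundary plane, for interior filtering
    truth$atlas_margin_mm <- pmin(abs(mni[, 1] - mni_origin[1]),
                                  abs(mni[, 2] - mni_origin[2]),
                                  abs(mni[, 3] - mni_origin[3]))
  }

  structure(list(ct = ct, gm = gm, wm = wm, atlas = atlas,
                 field_to_mni = field_fwd, field_to_patient = field_inv,
                 mni_affine = A, truth = truth, spec = spec),
            class = "eloc_phantom")
}

# Fixed, exactly invertible patient->MNI affine: 6-degree rotation about z,
# 5% isotropic scale, translation (4, -3, 2) mm.
phantom_mni_affine <- function() {
  th <- 6 * pi / 180
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(c(1.05, 1.05, 1.05, 1))
  A <- S %*% R
  A[1:3, 4] <- c(4, -3, 2)
  A
}

#' @export
print.eloc_phantom <- function(x, ...) {
  cat(sprintf("<eloc_phantom> grid %s at %.2g mm, %d contacts\n",
              paste(dim(x$ct$data), collapse = " x "), x$spec$voxel_mm,
              nrow(x$truth)))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes `CT.nii`, `MRGray.nii`, `MRWhite.nii`, the atlas volume + label
#' table, both deformation fields (`iy_MR.nii`: patient grid storing MNI
#' coordinates; `y_MR.nii`: MNI grid storing patient coordinates), the
#' ground truth as `truth.json`, and a manifest recording the seed and
#' generation parameters.
#'
#' @param phantom An `eloc_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_volume(phantom$ct, file.path(dir, "CT.nii"))
  save_volume(phantom$gm, file.path(dir, "MRGray.nii"))
  save_volume(phantom$wm, file.path(dir, "MRWhite.nii"))
  save_atlas(phantom$atlas, file.path(dir, "octants.nii"))
  save_deformation_field(phantom$field_to_mni, file.path(dir, "iy_MR.nii"))
  save_deformation_field(phantom$field_to_patient, file.path(dir, "y_MR.nii"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(seed = phantom$spec$seed,
                   voxel_mm = phantom$spec$voxel_mm,
                   grid_shape = phantom$spec$grid_shape,
                   brain_radii_mm = phantom$spec$brain_radii_mm,
                   mni_affine = phantom$mni_affine)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA)
  invisible(dir)
}
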