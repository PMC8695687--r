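#' @useDynLib electrolocate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile runif rnorm pnorm setNames
#' @importFrom utils head read.delim write.table combn
NULL

INTERP_CODES <- c(nearest = 0L, linear = 1L, cubic = 3L)

#' Construct a volume
#'
#' A volume couples a 3-D scalar array with a 4x4 affine mapping 0-based voxel
#' indices to world coordinates in millimetres (RAS convention once
#' [reorient_to_ras()] has been applied), plus a tag naming the space the
#' world coordinates live in.
#'
#' @param data 3-D numeric array (Hounsfield units for CT, arbitrary for MRI,
#'   `[0, 1]` for tissue-probability maps).
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @param space `"patient"` or `"mni"`.
#' @return An object of class `eloc_volume`.
#' @export
as_volume <- function(data, affine, space = "patient") {
  if (length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), " dimensions")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular")
  space <- match.arg(space, c("patient", "mni"))
  structure(list(data = data, affine = affine, space = space),
            class = "eloc_volume")
}

#' @export
print.eloc_volume <- function(x, ...) {
  vs <- voxel_size(x)
  cat(sprintf("<eloc_volume> %s  %s space\n",
              paste(dim(x$data), collapse = " x "), x$space))
  cat(sprintf("  voxel size: %s mm\n", paste(signif(vs, 4), collapse = " x ")))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel edge lengths of a volume in mm
#' @param v An `eloc_volume`.
#' @return Numeric length-3 vector of voxel sizes.
#' @export
voxel_size <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param v An `eloc_volume`.
#' @param ijk n x 3 matrix of 1-based (R) voxel indices; may be fractional.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(v, ijk) {
  ijk <- rbind2mat(ijk)
  h <- cbind(ijk - 1, 1) %*% t(v$affine)
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional) voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of 1-based voxel indices (continuous).
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind2mat(xyz)
  h <- cbind(xyz, 1) %*% t(solve(v$affine))
  h[, 1:3, drop = FALSE] + 1
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Sample a volume at world coordinates
#'
#' @param v An `eloc_volume`.
#' @param xyz n x 3 matrix of world mm points.
#' @param interp `"cubic"` (Catmull-Rom convolution), `"linear"` or
#'   `"nearest"`.
#' @param fill Value returned outside the grid.
#' @return Numeric vector of sampled values.
#' @export
sample_volume <- function(v, xyz, interp = c("cubic", "linear", "nearest"),
                          fill = min(v$data)) {
  interp <- match.arg(interp)
  idx0 <- world_to_voxel(v, xyz) - 1
  .sample_volume_cpp(as.double(v$data), dim(v$data), idx0,
                     INTERP_CODES[[interp]], fill)
}

#' Load a NIfTI volume
#'
#' Reads a 3-D NIfTI-1/2 file with its stored affine. No reorientation is
#' applied; use [reorient_to_ras()] afterwards.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param space Space tag for the loaded volume.
#' @return An `eloc_volume`.
#' @export
load_volume <- function(path, space = "patient") {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), " dimensions in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("missing or singular affine in ", path)
  as_volume(array(as.double(img), dim = d), aff, space)
}

#' Save a volume as NIfTI
#'
#' @param v An `eloc_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  write_nifti_affine(v$data, v$affine, path)
  invisible(path)
}

# Shared writer: arbitrary sform affine, pixdim from column norms.
write_nifti_affine <- function(data, affine, path) {
  nd <- length(dim(data))
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  pix <- c(-1, vs, rep(1, 4))
  if (nd == 4L) pix[5] <- 1
  img <- RNifti::asNifti(data, list(pixdim = pix))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Reorient a volume to RAS
#'
#' Permutes and flips the data axes so that the affine's 3x3 block is
#' diagonal-dominant with a positive diagonal (+x right, +y anterior,
#' +z superior). The world coordinate of every voxel is unchanged.
#'
#' @param v An `eloc_volume`.
#' @return The reoriented `eloc_volume`.
#' @export
reorient_to_ras <- function(v) {
  A <- v$affine
  dom <- apply(abs(A[1:3, 1:3]), 2, which.max)
  if (length(unique(dom)) != 3L)
    stop("cannot determine axis permutation from oblique affine")
  ord <- order(dom)                       # data axis feeding world axis 1,2,3
  data <- aperm(v$data, ord)
  B <- diag(4)
  B[1:3, 1:3] <- A[1:3, ord]
  B[1:3, 4] <- A[1:3, 4]
  for (ax in 1:3) {
    if (B[ax, ax] < 0) {
      n <- dim(data)[ax]
      idx <- switch(ax,
                    list(n:1, TRUE, TRUE),
                    list(TRUE, n:1, TRUE),
                    list(TRUE, TRUE, n:1))
      data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
      B[1:3, 4] <- B[1:3, 4] + B[1:3, ax] * (n - 1)
      B[1:3, ax] <- -B[1:3, ax]
    }
  }
  as_volume(data, B, v$space)
}

#' Check whether a volume is in RAS orientation
#' @param v An `eloc_volume`.
#' @return Logical.
#' @export
is_ras <- function(v) {
  A <- v$affine[1:3, 1:3]
  all(apply(abs(A), 2, which.max) == 1:3) && all(diag(A) > 0)
}

# Resample a volume onto an arbitrary output grid. world_map (4x4) maps
# output-world to input-world points before sampling (identity for plain
# regridding). Slab loop keeps the coordinate matrices small.
resample_to_grid <- function(v, out_dims, out_affine, world_map = diag(4),
                             interp = "cubic", fill = min(v$data)) {
  M <- solve(v$affine) %*% world_map %*% out_affine   # out index0 -> in index0
  code <- INTERP_CODES[[match.arg(interp, names(INTERP_CODES))]]
  nx <- out_dims[1]; ny <- out_dims[2]; nz <- out_dims[3]
  out <- array(0, dim = out_dims)
  xy <- cbind(rep(seq_len(nx) - 1, times = ny),
              rep(seq_len(ny) - 1, each = nx))
  for (k in seq_len(nz)) {
    pts <- cbind(xy, k - 1, 1) %*% t(M)
    out[, , k] <- .sample_volume_cpp(as.double(v$data), dim(v$data),
                                     pts[, 1:3, drop = FALSE], code, fill)
  }
  as_volume(out, out_affine, v$space)
}

#' Resample a volume to isotropic resolution
#'
#' Regrids the volume to cubic voxels of the requested edge length (default
#' 0.4 mm, the working resolution of the pipeline), preserving the field of
#' view to within one output voxel. Cubic interpolation by default.
#'
#' @param v An `eloc_volume`, already in RAS orientation.
#' @param resolution_mm Output voxel size in mm.
#' @param interp Interpolation scheme (see [sample_volume()]).
#' @return The resampled `eloc_volume`.
#' @export
resample_isotropic <- function(v, resolution_mm = 0.4, interp = "cubic") {
  if (resolution_mm <= 0) stop("resolution_mm must be positive")
  vs <- voxel_size(v)
  in_dims <- dim(v$data)
  out_dims <- pmax(1L, as.integer(round(in_dims * vs / resolution_mm)))
  A <- v$affine
  B <- diag(4)
  for (ax in 1:3) B[1:3, ax] <- A[1:3, ax] / vs[ax] * resolution_mm
  B[1:3, 4] <- A[1:3, 4]                 # voxel-0 centre fixed
  resample_to_grid(v, out_dims, B, interp = interp)
}

#' ACPC landmarks
#'
#' @param ac,pc,ms World-mm positions of the anterior commissure, posterior
#'   commissure and a midsagittal point well above the AC-PC line.
#' @return An object of class `eloc_acpc_landmarks`.
#' @export
acpc_landmarks <- function(ac, pc, ms) {
  lm <- list(ac = as.double(ac), pc = as.double(pc), ms = as.double(ms))
  if (any(lengths(lm) != 3L)) stop("landmarks must be 3-vectors")
  if (sqrt(sum((lm$ac - lm$pc)^2)) < 1e-9) stop("AC and PC coincide")
  cr <- cross3(lm$pc - lm$ac, lm$ms - lm$ac)
  if (sqrt(sum(cr^2)) < 1e-9)
    stop("midsagittal point collinear with AC-PC")
  structure(lm, class = "eloc_acpc_landmarks")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 translation in mm.
#' @return An object of class `eloc_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.double(translation)),
            class = "eloc_rigid")
}

#' Apply a rigid transform to points
#' @param t An `eloc_rigid`.
#' @param xyz n x 3 matrix of world points.
#' @return n x 3 matrix of transformed points.
#' @export
rigid_apply_points <- function(t, xyz) {
  xyz <- rbind2mat(xyz)
  sweep(xyz %*% t(t$rotation), 2, -t$translation)
}

#' Invert a rigid transform
#' @param t An `eloc_rigid`.
#' @return The inverse `eloc_rigid`.
#' @export
rigid_invert <- function(t) {
  rigid_transform(t(t$rotation), -t(t$rotation) %*% t$translation)
}

#' Compose two rigid transforms
#' @param a,b `eloc_rigid` objects; the result applies `b` first, then `a`.
#' @return An `eloc_rigid`.
#' @export
rigid_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  a$rotation %*% b$translation + a$translation)
}

#' Compute the rigid transform into ACPC space
#'
#' Builds the rigid motion that sends the AC to the origin, puts the PC on
#' the negative y axis (anterior positive), and places the midsagittal point
#' in the x = 0 plane with positive z, completing a right-handed RAS-style
#' frame.
#'
#' @param lm An [acpc_landmarks()] object.
#' @return An `eloc_rigid` mapping world mm to ACPC mm.
#' @export
compute_acpc_transform <- function(lm) {
  stopifnot(inherits(lm, "eloc_acpc_landmarks"))
  yax <- unit3(lm$ac - lm$pc)                 # PC -> AC is +y
  zraw <- lm$ms - lm$ac
  zax <- unit3(zraw - sum(zraw * yax) * yax)  # MS into x = 0, positive z
  xax <- cross3(yax, zax)                     # right-handed
  R <- rbind(xax, yax, zax)
  dimnames(R) <- NULL
  rigid_transform(R, -R %*% lm$ac)
}

#' Reslice a volume through a rigid transform
#'
#' Resamples the volume on its own grid so that the image content is moved by
#' the transform: a feature at world point `p` appears at `t(p)` in the
#' output. Out-of-field voxels take `fill` (default: the input minimum, so CT
#' padding stays at air level and can never masquerade as electrode signal).
#'
#' @param v An `eloc_volume`.
#' @param t An `eloc_rigid`.
#' @param interp Interpolation scheme; use `"nearest"` for label volumes.
#' @param fill Fill value for voxels mapped outside the input field of view.
#' @return The resliced `eloc_volume` on the same grid.
#' @export
apply_rigid <- function(v, t, interp = "cubic", fill = min(v$data)) {
  ti <- rigid_invert(t)
  W <- diag(4)
  W[1:3, 1:3] <- ti$rotation
  W[1:3, 4] <- ti$translation
  resample_to_grid(v, dim(v$data), v$affine, world_map = W,
                   interp = interp, fill = fill)
}
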