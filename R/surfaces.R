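#' Surface generation configuration
#'
#' Defaults follow the pipeline's published recipe: the brain mask is the
#' summed gray+white probability thresholded at > 0.95; the brain surface is
#' the 0.3 isosurface of the mask smoothed with a 3-mm cuboid (uniform box)
#' kernel; the projection surface uses a 10-mm kernel so that it envelopes
#' the brain and fills sulci, giving surface electrodes something to land on.
#'
#' @param mask_threshold Threshold on gray+white summed probability.
#' @param iso_level Isosurface level applied to the smoothed mask.
#' @param brain_smooth_mm Cuboid kernel width for the brain surface.
#' @param projection_smooth_mm Cuboid kernel width for the projection surface.
#' @param dbscan_eps_factor Remnant-removal DBSCAN `eps` as a multiple of the
#'   median mesh edge length.
#' @param dbscan_min_pts Remnant-removal DBSCAN core-point threshold.
#' @return A list of class `eloc_surface_config`.
#' @export
surface_config <- function(mask_threshold = 0.95, iso_level = 0.3,
                           brain_smooth_mm = 3, projection_smooth_mm = 10,
                           dbscan_eps_factor = 3, dbscan_min_pts = 10) {
  stopifnot(mask_threshold > 0, mask_threshold <= 1,
            iso_level > 0, iso_level < 1,
            brain_smooth_mm > 0, projection_smooth_mm > 0)
  structure(list(mask_threshold = mask_threshold, iso_level = iso_level,
                 brain_smooth_mm = brain_smooth_mm,
                 projection_smooth_mm = projection_smooth_mm,
                 dbscan_eps_factor = dbscan_eps_factor,
                 dbscan_min_pts = dbscan_min_pts),
            class = "eloc_surface_config")
}

#' Construct a triangulated surface
#'
#' @param vertices n x 3 matrix of world-mm vertex positions.
#' @param faces m x 3 integer matrix of 1-based vertex indices; winding is
#'   counter-clockwise seen from outside (outward normals).
#' @param kind `"brain"` or `"projection"`.
#' @return An object of class `eloc_surface`.
#' @export
surface <- function(vertices, faces, kind = c("brain", "projection")) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, kind = kind),
            class = "eloc_surface")
}

#' @export
print.eloc_surface <- function(x, ...) {
  cat(sprintf("<eloc_surface> kind=%s  %d vertices, %d faces\n",
              x$kind, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Brain mask from tissue-probability maps
#'
#' Thresholds the summed gray + white probability (strictly greater than
#' `cfg$mask_threshold`) and keeps only the largest 26-connected component,
#' discarding detached satellites.
#'
#' @param gm,wm Gray/white probability `eloc_volume`s on the same grid.
#' @param cfg A [surface_config()].
#' @return Binary `eloc_volume` (0/1).
#' @export
make_brain_mask <- function(gm, wm, cfg = surface_config()) {
  if (!identical(dim(gm$data), dim(wm$data)) ||
      max(abs(gm$affine - wm$affine)) > 1e-6)
    stop("gray and white maps must share a grid")
  mask <- (gm$data + wm$data) > cfg$mask_threshold
  lab <- .label_components_cpp(as.vector(mask), dim(gm$data), 26L)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L) stop("empty brain mask")
  keep <- which.max(tabulate(lab, ncomp))
  out <- array(as.double(lab == keep), dim = dim(gm$data))
  as_volume(out, gm$affine, gm$space)
}

odd_width <- function(smooth_mm, voxel_mm) {
  w <- as.integer(round(smooth_mm / voxel_mm))
  w <- pmax(w, 1L)
  w + (w %% 2L == 0L)   # force odd
}

#' Extract an isosurface from a binary mask
#'
#' The mask is mean-filtered with a cuboid kernel (width `smooth_mm`,
#' rounded to an odd number of voxels per axis) and the `iso_level`
#' isosurface is extracted with linear interpolation along cell edges
#' (marching tetrahedra on the Kuhn cell subdivision). The grid is treated
#' as embedded in zeros, so surfaces always close, and vertices are mapped
#' to world mm through the mask affine.
#'
#' @param mask Binary `eloc_volume`.
#' @param smooth_mm Cuboid kernel width in mm.
#' @param iso_level Isosurface threshold on the smoothed mask.
#' @param kind Surface kind tag.
#' @return An `eloc_surface`.
#' @export
generate_surface <- function(mask, smooth_mm, iso_level = 0.3,
                             kind = c("brain", "projection")) {
  kind <- match.arg(kind)
  if (!any(mask$data > 0)) stop("no surface: mask is empty")
  if (smooth_mm <= 0) stop("smooth_mm must be positive")
  vs <- voxel_size(mask)
  w <- vapply(vs, function(v) odd_width(smooth_mm, v), integer(1))
  sm <- .box_mean_cpp(as.double(mask$data), dim(mask$data), w)
  mt <- .marching_tets_cpp(sm, dim(mask$data), iso_level, 0)
  if (nrow(mt$vertices) == 0L) stop("no surface: isosurface is empty")
  vw <- cbind(mt$vertices, 1) %*% t(mask$affine)
  surface(vw[, 1:3, drop = FALSE], mt$faces + 1L, kind)
}

median_edge_length <- function(s) {
  f <- s$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  d <- s$vertices[e[, 1], , drop = FALSE] - s$vertices[e[, 2], , drop = FALSE]
  stats::median(sqrt(rowSums(d^2)))
}

#' Remove detached surface remnants
#'
#' Clusters mesh vertices with DBSCAN and keeps only the largest cluster
#' (most vertices; ties broken toward the cluster containing the smallest
#' vertex index), dropping faces that reference removed vertices and
#' compacting indices. This strips enclosed remnants (e.g. ventricle
#' surfaces) from the main brain or projection surface.
#'
#' @param s An `eloc_surface`.
#' @param eps_mm DBSCAN radius; default 3 x median edge length.
#' @param min_pts DBSCAN core-point count.
#' @return The cleaned `eloc_surface`.
#' @export
remove_remnants <- function(s, eps_mm = NULL, min_pts = 10) {
  if (nrow(s$vertices) == 0L) stop("empty surface")
  if (is.null(eps_mm)) eps_mm <- 3 * median_edge_length(s)
  cl <- .dbscan_cpp(s$vertices, eps_mm, as.integer(min_pts))
  ncl <- attr(cl, "n_clusters")
  if (ncl == 0L) stop("no dominant cluster: all vertices classified as noise")
  sizes <- tabulate(cl, ncl)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    first_idx <- vapply(best, function(b) min(which(cl == b)), integer(1))
    best <- best[which.min(first_idx)]
  }
  keep <- cl == best
  new_id <- cumsum(keep)
  fk <- s$faces[rowSums(matrix(keep[s$faces], ncol = 3)) == 3L, , drop = FALSE]
  surface(s$vertices[keep, , drop = FALSE],
          matrix(new_id[fk], ncol = 3), s$kind)
}

#' Build brain and projection surfaces from tissue maps
#'
#' Convenience wrapper: mask, smooth, isosurface and remnant removal for both
#' surfaces in one call.
#'
#' @inheritParams make_brain_mask
#' @return List with elements `brain` and `projection` (`eloc_surface`s) and
#'   `mask` (the binary brain mask).
#' @export
build_surfaces <- function(gm, wm, cfg = surface_config()) {
  mask <- make_brain_mask(gm, wm, cfg)
  brain <- remove_remnants(
    generate_surface(mask, cfg$brain_smooth_mm, cfg$iso_level, "brain"),
    min_pts = cfg$dbscan_min_pts)
  proj <- remove_remnants(
    generate_surface(mask, cfg$projection_smooth_mm, cfg$iso_level,
                     "projection"),
    min_pts = cfg$dbscan_min_pts)
  list(brain = brain, projection = proj, mask = mask)
}

#' Is a surface closed?
#'
#' @param s An `eloc_surface`.
#' @return `TRUE` if every undirected edge is shared by exactly two faces.
#' @export
surface_is_closed <- function(s) {
  f <- s$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mark grid voxels interior to a closed surface
#'
#' @param s A closed `eloc_surface`.
#' @param grid An `eloc_volume` defining the target grid.
#' @return Binary `eloc_volume`: 1 where the voxel centre lies inside `s`.
#' @export
interior_mask <- function(s, grid) {
  if (!surface_is_closed(s)) stop("surface not closed")
  vv <- cbind(s$vertices, 1) %*% t(solve(grid$affine))
  inside <- .voxelize_mesh_cpp(vv[, 1:3, drop = FALSE], s$faces - 1L,
                               dim(grid$data))
  as_volume(array(as.double(inside), dim = dim(grid$data)), grid$affine,
            grid$space)
}

#' Test points against a closed surface
#'
#' @param s A closed `eloc_surface`.
#' @param xyz n x 3 matrix of world-mm points.
#' @return Logical vector: `TRUE` for interior points.
#' @export
points_in_surface <- function(s, xyz) {
  .points_in_mesh_cpp(s$vertices, s$faces - 1L, rbind2mat(xyz))
}

#' Nearest point on a surface
#'
#' Exhaustive closest-point query over all triangles, returning the closest
#' surface point, the outward unit normal of the containing triangle, the
#' (1-based) face index and the distance.
#'
#' @param p World-mm point (length 3) or n x 3 matrix.
#' @param s An `eloc_surface`.
#' @return List with `point` (n x 3), `normal` (n x 3), `face`, `distance`.
#' @export
nearest_point_on_surface <- function(p, s) {
  p <- rbind2mat(p)
  res <- .mesh_closest_cpp(s$vertices, s$faces - 1L, p)
  f <- res$face + 1L
  n <- face_normals(s)[f, , drop = FALSE]
  list(point = res$point, normal = n, face = f, distance = res$distance)
}

face_normals <- function(s) {
  a <- s$vertices[s$faces[, 1], , drop = FALSE]
  b <- s$vertices[s$faces[, 2], , drop = FALSE]
  c <- s$vertices[s$faces[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Enclosed volume of a closed surface
#'
#' Signed-tetrahedron (divergence) formula; positive for outward-oriented
#' closed meshes.
#'
#' @param s An `eloc_surface`.
#' @return Volume in mm^3.
#' @export
surface_volume <- function(s) {
  a <- s$vertices[s$faces[, 1], , drop = FALSE]
  b <- s$vertices[s$faces[, 2], , drop = FALSE]
  c <- s$vertices[s$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Write a surface as ASCII PLY
#' @param s An `eloc_surface`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment electrolocate %s surface, units mm", s$kind),
               sprintf("element vertex %d", nrow(s$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(s$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(s$vertices, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
  writeLines(apply(s$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Save brain and projection surfaces with a manifest
#'
#' Writes `brain.ply`, `projection.ply` and a small `surfaces.json` manifest
#' (vertex/face counts, units) to a directory.
#'
#' @param surfaces List with `brain` and `projection` `eloc_surface`s (as
#'   returned by [build_surfaces()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_surfaces <- function(surfaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(surfaces$brain, file.path(dir, "brain.ply"))
  write_ply(surfaces$projection, file.path(dir, "projection.ply"))
  manifest <- list(
    units = "mm",
    brain = list(vertices = nrow(surfaces$brain$vertices),
                 faces = nrow(surfaces$brain$faces)),
    projection = list(vertices = nrow(surfaces$projection$vertices),
                      faces = nrow(surfaces$projection$faces)))
  jsonlite::write_json(manifest, file.path(dir, "surfaces.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read an ASCII PLY surface
#' @param path Path to a `.ply` written by [write_ply()].
#' @param kind Surface kind tag.
#' @return An `eloc_surface`.
#' @export
read_ply <- function(path, kind = c("brain", "projection")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("not a PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)))
  vtx <- matrix(scan(text = lines[hend + seq_len(nv)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  fc <- matrix(scan(text = lines[hend + nv + seq_len(nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  surface(vtx, fc[, 2:4, drop = FALSE] + 1L, kind)
}
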