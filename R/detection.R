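#' Electrode detection configuration
#'
#' Defaults implement the published detection recipe: 21 candidate thresholds
#' evenly spaced between the 99th and 100th intensity percentile of the whole
#' CT; connected components count as electrode candidates when their
#' intensity-weighted centroid falls inside the projection surface, they
#' exceed 6 voxels, and their volume stays below that of a 2-mm-radius sphere
#' (~33.5 mm^3); threshold stability means the per-threshold detection count
#' changes by at most 5 between consecutive thresholds; detections closer
#' than 1 mm are merged (brighter wins); at most 250 electrodes are kept.
#'
#' @param n_thresholds Number of candidate thresholds.
#' @param pct_lo,pct_hi Percentile range (0-100) spanned by the thresholds.
#' @param min_voxels Components must have strictly more voxels than this.
#' @param max_volume_mm3 Components must be strictly smaller than this;
#'   default is the volume of a sphere of radius 2 mm.
#' @param stability_delta Maximum count change between consecutive thresholds
#'   inside a stable segment.
#' @param min_separation_mm Cleanup radius for near-duplicate detections.
#' @param max_electrodes Cap on the number of reported electrodes.
#' @param electrode_radius_mm Nominal contact radius used for label/class
#'   spheres and for the manual-detection cube.
#' @param manual_cube_factor Manual-detection cube side, in electrode radii.
#' @return A list of class `eloc_detection_config`.
#' @export
detection_config <- function(n_thresholds = 21, pct_lo = 99, pct_hi = 100,
                             min_voxels = 6,
                             max_volume_mm3 = 4 / 3 * pi * 2^3,
                             stability_delta = 5, min_separation_mm = 1,
                             max_electrodes = 250, electrode_radius_mm = 1.3,
                             manual_cube_factor = 6) {
  stopifnot(n_thresholds >= 2, pct_lo < pct_hi, min_voxels > 0,
            max_volume_mm3 > 0, stability_delta >= 0,
            min_separation_mm >= 0, max_electrodes > 0,
            electrode_radius_mm > 0, manual_cube_factor > 0)
  structure(list(n_thresholds = as.integer(n_thresholds), pct_lo = pct_lo,
                 pct_hi = pct_hi, min_voxels = as.integer(min_voxels),
                 max_volume_mm3 = max_volume_mm3,
                 stability_delta = stability_delta,
                 min_separation_mm = min_separation_mm,
                 max_electrodes = as.integer(max_electrodes),
                 electrode_radius_mm = electrode_radius_mm,
                 manual_cube_factor = manual_cube_factor),
            class = "eloc_detection_config")
}

#' Supra-threshold connected components of a CT
#'
#' Labels voxels strictly above `threshold_hu` with 26-connectivity and
#' summarizes each component: voxel count, physical volume, mean intensity
#' and the intensity-weighted centroid in world mm. Components are kept only
#' if the voxel containing the weighted centroid lies inside `inside` (when
#' given), the voxel count exceeds `cfg$min_voxels`, and the volume is below
#' `cfg$max_volume_mm3`.
#'
#' @param ct CT `eloc_volume` (Hounsfield units or any monotone scale).
#' @param threshold_hu Intensity threshold.
#' @param inside Optional binary `eloc_volume` on the CT grid (e.g. from
#'   [interior_mask()]); `NULL` disables the inside test.
#' @param cfg A [detection_config()].
#' @param filter If `FALSE`, return all components without the size/inside
#'   filters (used by manual detection).
#' @return data.frame with columns `n_voxels`, `volume_mm3`,
#'   `mean_intensity`, `x`, `y`, `z`.
#' @export
extract_components <- function(ct, threshold_hu, inside = NULL,
                               cfg = detection_config(), filter = TRUE) {
  dims <- dim(ct$data)
  if (!is.null(inside) && !identical(dim(inside$data), dims))
    stop("ct and inside mask must share a grid")
  mask <- ct$data > threshold_hu
  lab <- .label_components_cpp(as.vector(mask), dims, 26L)
  ncomp <- attr(lab, "n_components")
  empty <- data.frame(n_voxels = integer(0), volume_mm3 = double(0),
                      mean_intensity = double(0),
                      x = double(0), y = double(0), z = double(0))
  if (ncomp == 0L) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  vals <- as.double(ct$data[idx])
  i <- (idx - 1L) %% dims[1] + 1L
  j <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  k <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  n <- tabulate(l, ncomp)
  sw <- rowsum(vals, l)[, 1]
  ci <- rowsum(vals * i, l)[, 1] / sw
  cj <- rowsum(vals * j, l)[, 1] / sw
  ck <- rowsum(vals * k, l)[, 1] / sw
  vox_vol <- prod(voxel_size(ct))
  cw <- voxel_to_world(ct, cbind(ci, cj, ck))
  comp <- data.frame(n_voxels = n, volume_mm3 = n * vox_vol,
                     mean_intensity = sw / n,
                     x = cw[, 1], y = cw[, 2], z = cw[, 3])
  if (!filter) return(comp)
  keep <- comp$n_voxels > cfg$min_voxels &
    comp$volume_mm3 < cfg$max_volume_mm3
  if (!is.null(inside)) {
    cv <- round(world_to_voxel(ct, as.matrix(comp[, c("x", "y", "z")])))
    inb <- cv[, 1] >= 1 & cv[, 2] >= 1 & cv[, 3] >= 1 &
      cv[, 1] <= dims[1] & cv[, 2] <= dims[2] & cv[, 3] <= dims[3]
    ins <- rep(FALSE, nrow(comp))
    ins[inb] <- inside$data[cbind(cv[inb, 1], cv[inb, 2], cv[inb, 3])] > 0
    keep <- keep & ins
  }
  comp[keep, , drop = FALSE]
}

#' Optimal threshold from a detection curve
#'
#' Implements the stability rule: stable segments are maximal runs of
#' consecutive thresholds in which the detection count changes by at most
#' `stability_delta` between neighbours; the winning segment is the one whose
#' maximum per-threshold count is largest (ties: longer segment, then lower
#' threshold), and the optimal threshold is its centre element (lower middle
#' for even-length segments).
#'
#' @param counts Integer vector of per-threshold detection counts.
#' @param thresholds Numeric vector of the tested thresholds (ascending).
#' @param stability_delta Maximum allowed step between consecutive counts.
#' @return List with `index`, `threshold`, and a data.frame `segments`
#'   (`start`, `end`, `max_count`).
#' @export
choose_optimal_threshold <- function(counts, thresholds,
                                     stability_delta = 5) {
  n <- length(counts)
  stopifnot(length(thresholds) == n, n >= 1)
  brk <- if (n > 1) which(abs(diff(counts)) > stability_delta) else integer(0)
  start <- c(1L, brk + 1L)
  end <- c(brk, n)
  segs <- data.frame(start = start, end = end,
                     max_count = vapply(seq_along(start), function(s)
                       max(counts[start[s]:end[s]]), double(1)))
  len <- segs$end - segs$start + 1L
  ord <- order(-segs$max_count, -len, segs$start)
  win <- segs[ord[1], ]
  centre <- win$start + ceiling((win$end - win$start + 1L) / 2) - 1L
  list(index = centre, threshold = thresholds[centre], segments = segs)
}

#' Automatic electrode detection
#'
#' Runs the full adaptive-threshold search: candidate thresholds are evenly
#' spaced across the `pct_lo`-`pct_hi` percentile range of all CT voxel
#' intensities (linear interpolation between order statistics); components
#' are extracted and filtered at every threshold; the optimal threshold is
#' chosen by the stability rule ([choose_optimal_threshold()]); detections at
#' that threshold closer together than `min_separation_mm` are merged keeping
#' the brighter one; survivors are sorted by mean intensity (descending) and
#' truncated to `max_electrodes`.
#'
#' @param ct CT `eloc_volume`.
#' @param projection Closed projection `eloc_surface`, or a binary
#'   `eloc_volume` interior mask on the CT grid (accepted to avoid
#'   re-voxelizing when one is already available).
#' @param cfg A [detection_config()].
#' @return An object of class `eloc_detection`: list with `electrodes`
#'   (an [electrode_set()]), `optimal_threshold_hu`, and `curve`
#'   (data.frame `threshold_hu`, `n_detected`).
#' @export
auto_detect <- function(ct, projection, cfg = detection_config()) {
  inside <- if (inherits(projection, "eloc_surface"))
    interior_mask(projection, ct)
  else projection
  qr <- quantile(ct$data, probs = c(cfg$pct_lo, cfg$pct_hi) / 100,
                 names = FALSE, type = 7)
  thresholds <- seq(qr[1], qr[2], length.out = cfg$n_thresholds)
  comps <- lapply(thresholds, function(th)
    extract_components(ct, th, inside, cfg))
  counts <- vapply(comps, nrow, integer(1))
  curve <- data.frame(threshold_hu = thresholds, n_detected = counts)
  if (all(counts == 0L)) {
    return(structure(list(electrodes = electrode_set(),
                          optimal_threshold_hu = NA_real_, curve = curve),
                     class = "eloc_detection"))
  }
  opt <- choose_optimal_threshold(counts, thresholds, cfg$stability_delta)
  det <- cleanup_close(comps[[opt$index]], cfg$min_separation_mm)
  det <- det[order(-det$mean_intensity), , drop = FALSE]
  det <- head(det, cfg$max_electrodes)
  es <- electrode_set(x = det$x, y = det$y, z = det$z,
                      mean_intensity = det$mean_intensity,
                      radius_mm = cfg$electrode_radius_mm)
  structure(list(electrodes = es, optimal_threshold_hu = opt$threshold,
                 curve = curve),
            class = "eloc_detection")
}

#' @export
print.eloc_detection <- function(x, ...) {
  cat(sprintf("<eloc_detection> %d electrodes at threshold %.1f HU\n",
              nrow(x$electrodes), x$optimal_threshold_hu))
  cat(sprintf("  curve: %d thresholds in [%.1f, %.1f] HU\n",
              nrow(x$curve), min(x$curve$threshold_hu),
              max(x$curve$threshold_hu)))
  invisible(x)
}

# Greedy pass in descending mean intensity: a detection within min_sep of an
# already kept (brighter) one is dropped. Idempotent.
cleanup_close <- function(det, min_sep) {
  if (nrow(det) <= 1L || min_sep <= 0) return(det)
  ord <- order(-det$mean_intensity)
  pts <- as.matrix(det[ord, c("x", "y", "z")])
  kept <- logical(nrow(det))
  kept_pts <- matrix(0, 0, 3)
  for (q in seq_len(nrow(det))) {
    if (nrow(kept_pts) == 0L ||
        min(sqrt(rowSums(sweep(kept_pts, 2, pts[q, ])^2))) >= min_sep) {
      kept[ord[q]] <- TRUE
      kept_pts <- rbind(kept_pts, pts[q, ])
    }
  }
  det[kept, , drop = FALSE]
}

#' Manual electrode localization at a click point
#'
#' With `manual_draw = TRUE` the electrode is placed exactly at `click_mm`.
#' Otherwise the CT is thresholded inside a cube of side
#' `manual_cube_factor * electrode_radius_mm` centred at the click, and the
#' weighted centroid of the connected component nearest to the click is
#' returned.
#'
#' @param ct CT `eloc_volume`.
#' @param click_mm World-mm click position (inside the CT field of view).
#' @param threshold_hu Threshold applied within the cube.
#' @param cfg A [detection_config()].
#' @param manual_draw If `TRUE`, bypass detection and place at the click.
#' @return One-row [electrode_set()].
#' @export
manual_detect <- function(ct, click_mm, threshold_hu,
                          cfg = detection_config(), manual_draw = FALSE) {
  click_mm <- as.double(click_mm)
  if (manual_draw)
    return(electrode_set(x = click_mm[1], y = click_mm[2], z = click_mm[3],
                         mean_intensity = NA_real_,
                         radius_mm = cfg$electrode_radius_mm))
  dims <- dim(ct$data)
  half_mm <- cfg$manual_cube_factor * cfg$electrode_radius_mm / 2
  cv <- world_to_voxel(ct, click_mm)
  if (any(cv < 0.5) || any(cv > dims + 0.5))
    stop("click outside the CT field of view")
  half_vox <- ceiling(half_mm / voxel_size(ct))
  lo <- pmax(1, floor(cv - half_vox))
  hi <- pmin(dims, ceiling(cv + half_vox))
  sub <- ct$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_aff <- ct$affine
  sub_aff[1:3, 4] <- voxel_to_world(ct, lo)
  subv <- as_volume(sub, sub_aff, ct$space)
  comp <- extract_components(subv, threshold_hu, inside = NULL, cfg = cfg,
                             filter = FALSE)
  if (nrow(comp) == 0L) stop("no component near click")
  d2 <- (comp$x - click_mm[1])^2 + (comp$y - click_mm[2])^2 +
    (comp$z - click_mm[3])^2
  b <- which.min(d2)
  electrode_set(x = comp$x[b], y = comp$y[b], z = comp$z[b],
                mean_intensity = comp$mean_intensity[b],
                radius_mm = cfg$electrode_radius_mm)
}

#' Electrode set container
#'
#' A data.frame (class `eloc_electrodes`) with one row per contact: patient
#' world coordinates `x`, `y`, `z` (mm), optional MNI coordinates
#' `mni_x/y/z`, detection `mean_intensity`, contact `radius_mm`, user
#' `label` and `channel`, `tissue_class`
#' (`"gray"`/`"white"`/`"unknown"`/`NA`), and any per-atlas modal label
#' columns added by [assign_atlas_labels()].
#'
#' @param x,y,z Patient-space coordinates in mm.
#' @param ... Further equal-length columns.
#' @param mean_intensity Mean CT intensity of the detected component.
#' @param radius_mm Contact radius.
#' @return An `eloc_electrodes` data.frame.
#' @export
electrode_set <- function(x = double(0), y = double(0), z = double(0),
                          mean_intensity = rep(NA_real_, length(x)),
                          radius_mm = 1.3, ...) {
  n <- length(x)
  df <- data.frame(id = seq_len(n), x = x, y = y, z = z,
                   mean_intensity = mean_intensity,
                   radius_mm = rep_len(radius_mm, n),
                   label = rep(NA_character_, n),
                   channel = rep(NA_integer_, n),
                   tissue_class = rep(NA_character_, n),
                   mni_x = rep(NA_real_, n), mni_y = rep(NA_real_, n),
                   mni_z = rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("eloc_electrodes", "data.frame")
  df
}

#' @export
print.eloc_electrodes <- function(x, ...) {
  cat(sprintf("<eloc_electrodes> %d contacts\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
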