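#' Labeling and classification configuration
#'
#' Defaults follow the published rules: tissue class and the modal atlas
#' label are computed over the voxels of a 1.3-mm contact sphere; the
#' probabilistic label list uses a 1-cm sphere; label matching utilities
#' exclude fractions below 5% of the sphere; the gray/white rank-sum test is
#' significant at p < 0.001; a contact whose mean gray AND white probability
#' are both below 0.1 is "unknown".
#'
#' @param sphere_radius_mm Contact sphere radius.
#' @param prob_radius_mm Radius of the probabilistic-label sphere.
#' @param prob_exclude_frac Fraction below which probabilistic labels are
#'   excluded by [filter_prob_labels()].
#' @param p_threshold Significance level of the rank-sum test.
#' @param unknown_mean_threshold Mean-probability floor below which (for both
#'   tissues) a contact is "unknown".
#' @return A list of class `eloc_label_config`.
#' @export
label_config <- function(sphere_radius_mm = 1.3, prob_radius_mm = 10,
                         prob_exclude_frac = 0.05, p_threshold = 0.001,
                         unknown_mean_threshold = 0.1) {
  stopifnot(sphere_radius_mm > 0, prob_radius_mm > 0,
            prob_exclude_frac > 0, prob_exclude_frac < 1,
            p_threshold > 0, p_threshold < 1)
  structure(list(sphere_radius_mm = sphere_radius_mm,
                 prob_radius_mm = prob_radius_mm,
                 prob_exclude_frac = prob_exclude_frac,
                 p_threshold = p_threshold,
                 unknown_mean_threshold = unknown_mean_threshold),
            class = "eloc_label_config")
}

#' Voxels inside a sphere
#'
#' All voxels of `grid` whose centres lie within `radius_mm` (world distance)
#' of `center_mm`.
#'
#' @param center_mm World-mm sphere centre.
#' @param radius_mm Sphere radius in mm.
#' @param grid An `eloc_volume`.
#' @return n x 3 matrix of 1-based voxel indices, with the flat (linear)
#'   indices as attribute `"flat"`. Zero rows when the sphere misses the
#'   grid.
#' @export
sphere_voxels <- function(center_mm, radius_mm, grid) {
  stopifnot(radius_mm > 0)
  dims <- dim(grid$data)
  cv <- world_to_voxel(grid, center_mm)[1, ]
  half <- ceiling(radius_mm / voxel_size(grid)) + 1
  lo <- pmax(1, floor(cv - half))
  hi <- pmin(dims, ceiling(cv + half))
  if (any(lo > hi)) {
    out <- matrix(integer(0), 0, 3)
    attr(out, "flat") <- integer(0)
    return(out)
  }
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  w <- voxel_to_world(grid, ijk)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2
  out <- ijk[keep, , drop = FALSE]
  attr(out, "flat") <- as.integer(out[, 1] + dims[1] * (out[, 2] - 1) +
                                    dims[1] * dims[2] * (out[, 3] - 1))
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration of the permutation distribution of the rank-sum
#' statistic (midranks, so ties are handled exactly) when both samples have
#' at most `exact_max` observations; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Size bound under which both samples trigger the exact
#'   path.
#' @return Two-sided p-value in (0, 1].
#' @export
rank_sum_p <- function(x, y, exact_max = 10) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- colSums(matrix(r[combn(n, n1)], nrow = n1))
    # two-sided: as extreme or more extreme in |W - mu|
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(min(1, p))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- z - sign(z) * min(abs(z), 0.5)  # continuity correction
  min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
}

#' Classify a contact as gray or white matter
#'
#' Takes the gray and white probability values over the contact sphere. If
#' the mean probability is below `cfg$unknown_mean_threshold` for both
#' tissues the contact is `"unknown"` (out of brain). Otherwise a two-sided
#' rank-sum test compares the two samples: when significant
#' (p < `cfg$p_threshold`) the tissue with the higher median wins; when not,
#' the default class is `"gray"`.
#'
#' @param center_mm World-mm contact centre.
#' @param gm,wm Gray/white probability `eloc_volume`s on the patient grid.
#' @param cfg A [label_config()].
#' @return `"gray"`, `"white"` or `"unknown"`.
#' @export
classify_gray_white <- function(center_mm, gm, wm, cfg = label_config()) {
  if (!identical(dim(gm$data), dim(wm$data)))
    stop("gray and white maps must share a grid")
  sv <- sphere_voxels(center_mm, cfg$sphere_radius_mm, gm)
  flat <- attr(sv, "flat")
  if (length(flat) == 0L) {
    warning("contact sphere outside the tissue maps; class unknown")
    return("unknown")
  }
  g <- gm$data[flat]; w <- wm$data[flat]
  if (mean(g) < cfg$unknown_mean_threshold &&
      mean(w) < cfg$unknown_mean_threshold)
    return("unknown")
  p <- rank_sum_p(g, w)
  if (p < cfg$p_threshold) {
    if (median(g) >= median(w)) "gray" else "white"
  } else "gray"
}

#' Classify every contact of an electrode set
#'
#' @param electrodes An [electrode_set()].
#' @inheritParams classify_gray_white
#' @return The electrode set with `tissue_class` filled in.
#' @export
classify_electrodes <- function(electrodes, gm, wm, cfg = label_config()) {
  electrodes$tissue_class <- vapply(seq_len(nrow(electrodes)), function(q)
    classify_gray_white(c(electrodes$x[q], electrodes$y[q],
                          electrodes$z[q]), gm, wm, cfg),
    character(1))
  electrodes
}

#' Non-linear deformation field
#'
#' A deformation field is a 3-vector volume on a definition grid: at each
#' grid voxel it stores the absolute target-space coordinate (mm) that the
#' voxel's world position maps to (SPM-style absolute mapping, not a
#' displacement). `direction` names the mapping: `"patient_to_mni"` fields
#' are defined on the patient grid and store MNI coordinates (the field used
#' to label electrodes and to pull MNI atlases into patient space);
#' `"mni_to_patient"` fields are defined on the MNI grid and store patient
#' coordinates.
#'
#' @param mapping 4-D array `(i, j, k, 3)` of target coordinates in mm.
#' @param affine 4x4 voxel-to-world affine of the definition grid.
#' @param direction `"patient_to_mni"` or `"mni_to_patient"`.
#' @return An object of class `eloc_defield`.
#' @export
deformation_field <- function(mapping,
                              affine,
                              direction = c("patient_to_mni",
                                            "mni_to_patient")) {
  direction <- match.arg(direction)
  if (length(dim(mapping)) != 4L || dim(mapping)[4] != 3L)
    stop("mapping must be a (i, j, k, 3) array")
  structure(list(mapping = mapping, affine = as.matrix(affine),
                 direction = direction),
            class = "eloc_defield")
}

#' @export
print.eloc_defield <- function(x, ...) {
  cat(sprintf("<eloc_defield> %s  grid %s\n", x$direction,
              paste(dim(x$mapping)[1:3], collapse = " x ")))
  invisible(x)
}

#' Warp points through a deformation field
#'
#' Samples the 3-component mapping with trilinear interpolation at each
#' point (points are given in the field's definition space, e.g. patient mm
#' for a `patient_to_mni` field) and returns the target-space coordinates.
#'
#' @param points n x 3 matrix of source-space mm points.
#' @param field An [deformation_field()].
#' @return n x 3 matrix of target-space mm points.
#' @export
warp_points <- function(points, field) {
  points <- rbind2mat(points)
  dims <- dim(field$mapping)[1:3]
  h <- cbind(points, 1) %*% t(solve(field$affine))
  idx0 <- h[, 1:3, drop = FALSE]
  bad <- idx0[, 1] < 0 | idx0[, 2] < 0 | idx0[, 3] < 0 |
    idx0[, 1] > dims[1] - 1 | idx0[, 2] > dims[2] - 1 |
    idx0[, 3] > dims[3] - 1
  if (any(bad))
    stop("points outside field domain (rows ",
         paste(head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) ", ..." else "", ")")
  out <- matrix(0, nrow(points), 3)
  for (c3 in 1:3)
    out[, c3] <- .sample_volume_cpp(
      as.double(field$mapping[, , , c3]), dims, idx0, 1L, NA_real_)
  out
}

#' Integer label atlas in MNI space
#'
#' @param labels `eloc_volume` of integer labels in MNI space (0 =
#'   background/unlabelled).
#' @param table data.frame with columns `index` and `name`; every non-zero
#'   index present in the volume must appear.
#' @param name Atlas name.
#' @return An object of class `eloc_atlas`.
#' @export
atlas_volume <- function(labels, table, name = "atlas") {
  stopifnot(inherits(labels, "eloc_volume"))
  table <- as.data.frame(table)
  if (!all(c("index", "name") %in% names(table)))
    stop("atlas table needs columns 'index' and 'name'")
  present <- setdiff(unique(as.integer(labels$data)), 0L)
  missing <- setdiff(present, table$index)
  if (length(missing) > 0)
    stop("atlas table misses label indices: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, table = table, name = name),
            class = "eloc_atlas")
}

#' @export
print.eloc_atlas <- function(x, ...) {
  cat(sprintf("<eloc_atlas> '%s': %d labels on a %s grid\n", x$name,
              nrow(x$table), paste(dim(x$labels$data), collapse = " x ")))
  invisible(x)
}

#' Load an atlas (NIfTI + tab-delimited label table)
#'
#' The label table is a tab-delimited text file (`index \t name`, no header)
#' with the same base name as the NIfTI volume, following the `atlases/`
#' folder convention.
#'
#' @param nii_path Path to the label NIfTI.
#' @param table_path Path to the label table; default replaces the NIfTI
#'   extension with `.txt`.
#' @return An `eloc_atlas`.
#' @export
load_atlas <- function(nii_path,
                       table_path = sub("\\.nii(\\.gz)?$", ".txt", nii_path)) {
  vol <- load_volume(nii_path, space = "mni")
  tb <- read.delim(table_path, header = FALSE, col.names = c("index", "name"),
                   stringsAsFactors = FALSE)
  atlas_volume(vol, tb, name = sub("\\.nii(\\.gz)?$", "", basename(nii_path)))
}

#' Save an atlas (NIfTI + tab-delimited label table)
#' @param atlas An `eloc_atlas`.
#' @param nii_path Output NIfTI path; the table goes next to it as `.txt`.
#' @return `nii_path`, invisibly.
#' @export
save_atlas <- function(atlas, nii_path) {
  save_volume(atlas$labels, nii_path)
  write.table(atlas$table[, c("index", "name")],
              sub("\\.nii(\\.gz)?$", ".txt", nii_path),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(nii_path)
}

# nearest-neighbour atlas lookup at MNI mm points; 0 outside the atlas grid
atlas_lookup <- function(atlas, mni_mm) {
  dims <- dim(atlas$labels$data)
  cv <- round(world_to_voxel(atlas$labels, mni_mm))
  inb <- cv[, 1] >= 1 & cv[, 2] >= 1 & cv[, 3] >= 1 &
    cv[, 1] <= dims[1] & cv[, 2] <= dims[2] & cv[, 3] <= dims[3]
  out <- integer(nrow(cv))
  out[inb] <- as.integer(atlas$labels$data[cv[inb, , drop = FALSE]])
  out
}

label_name <- function(atlas, index) {
  if (index == 0L) return("unlabelled")
  atlas$table$name[match(index, atlas$table$index)]
}

#' Assign atlas labels to one contact
#'
#' Warps the contact-sphere voxels (radius `cfg$sphere_radius_mm`) to MNI
#' space through the deformation field and takes the most common atlas label
#' (nearest-neighbour lookup; background counts, and a background mode yields
#' `"unlabelled"`; ties break to the lower label index). A probabilistic
#' list is computed the same way over the `cfg$prob_radius_mm` sphere:
#' per-label voxel fractions (summing to 1 over all labels including
#' background), sorted descending.
#'
#' @param center_mm World-mm contact centre (patient space).
#' @param atlas An [atlas_volume()].
#' @param field A `patient_to_mni` [deformation_field()].
#' @param grid Patient-grid `eloc_volume` defining the sphere voxels.
#' @param cfg A [label_config()].
#' @return List with `modal_label` (character), `modal_index` (integer) and
#'   `prob_labels` (data.frame `label`, `index`, `fraction`).
#' @export
assign_atlas_labels <- function(center_mm, atlas, field, grid,
                                cfg = label_config()) {
  modal <- local({
    sv <- sphere_voxels(center_mm, cfg$sphere_radius_mm, grid)
    if (nrow(sv) == 0L) return(list(index = 0L))
    mni <- warp_points(voxel_to_world(grid, sv), field)
    labs <- atlas_lookup(atlas, mni)
    tt <- table(labs)
    cand <- as.integer(names(tt)[tt == max(tt)])
    list(index = min(cand))
  })
  prob <- local({
    sv <- sphere_voxels(center_mm, cfg$prob_radius_mm, grid)
    if (nrow(sv) == 0L)
      return(data.frame(label = character(0), index = integer(0),
                        fraction = double(0)))
    mni <- warp_points(voxel_to_world(grid, sv), field)
    labs <- atlas_lookup(atlas, mni)
    tt <- sort(table(labs) / length(labs), decreasing = TRUE)
    idx <- as.integer(names(tt))
    data.frame(label = vapply(idx, function(i) label_name(atlas, i),
                              character(1)),
               index = idx, fraction = as.double(tt),
               stringsAsFactors = FALSE)
  })
  list(modal_label = label_name(atlas, modal$index),
       modal_index = modal$index, prob_labels = prob)
}

#' Filter a probabilistic label list for matching
#'
#' Drops entries whose sphere fraction is below `min_frac` (default 5%),
#' the rule used when matching against reference labels.
#'
#' @param prob data.frame from [assign_atlas_labels()].
#' @param min_frac Exclusion threshold.
#' @return Filtered data.frame.
#' @export
filter_prob_labels <- function(prob, min_frac = 0.05) {
  prob[prob$fraction >= min_frac, , drop = FALSE]
}

#' Label every contact of an electrode set
#'
#' Adds a modal-label column named after the atlas and (optionally) fills
#' MNI coordinates by warping the contact centres; probabilistic lists are
#' returned as an attribute `"prob_labels"` (a named list, one data.frame
#' per contact).
#'
#' @param electrodes An [electrode_set()].
#' @inheritParams assign_atlas_labels
#' @param fill_mni Also fill `mni_x/y/z` from the warped centres.
#' @return The electrode set with a new `atlas_<name>` column.
#' @export
label_electrodes <- function(electrodes, atlas, field, grid,
                             cfg = label_config(), fill_mni = TRUE) {
  col <- paste0("atlas_", atlas$name)
  probs <- vector("list", nrow(electrodes))
  lab <- character(nrow(electrodes))
  for (q in seq_len(nrow(electrodes))) {
    res <- assign_atlas_labels(c(electrodes$x[q], electrodes$y[q],
                                 electrodes$z[q]), atlas, field, grid, cfg)
    lab[q] <- res$modal_label
    probs[[q]] <- res$prob_labels
  }
  electrodes[[col]] <- lab
  if (fill_mni) {
    mni <- warp_points(as.matrix(electrodes[, c("x", "y", "z")]), field)
    electrodes$mni_x <- mni[, 1]
    electrodes$mni_y <- mni[, 2]
    electrodes$mni_z <- mni[, 3]
  }
  pl <- attr(electrodes, "prob_labels")
  if (is.null(pl)) pl <- list()
  pl[[atlas$name]] <- probs
  attr(electrodes, "prob_labels") <- pl
  electrodes
}

#' Warp an MNI atlas into patient space
#'
#' For each voxel of the patient grid, the deformation field gives the MNI
#' coordinate, and the atlas label there is taken by nearest-neighbour
#' lookup (labels are categorical). The conventional output file name adds
#' an `lw` prefix to the atlas name.
#'
#' @param atlas An [atlas_volume()].
#' @param field A `patient_to_mni` [deformation_field()] (pulls the MNI
#'   atlas onto the patient grid).
#' @param grid Patient-grid `eloc_volume`.
#' @param path Optional output path; when given, the warped volume is saved
#'   there (e.g. `lw<NAME>.nii`).
#' @return Integer-label `eloc_volume` in patient space.
#' @export
warp_atlas_to_patient <- function(atlas, field, grid, path = NULL) {
  dims <- dim(grid$data)
  out <- array(0L, dim = dims)
  xy <- cbind(rep(seq_len(dims[1]), times = dims[2]),
              rep(seq_len(dims[2]), each = dims[1]))
  for (k in seq_len(dims[3])) {
    w <- voxel_to_world(grid, cbind(xy, k))
    mni <- warp_points(w, field)
    out[, , k] <- atlas_lookup(atlas, mni)
  }
  vol <- as_volume(out, grid$affine, "patient")
  if (!is.null(path)) save_volume(vol, path)
  vol
}

#' Save a deformation field as NIfTI
#' @param field An [deformation_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_deformation_field <- function(field, path) {
  write_nifti_affine(field$mapping, field$affine, path)
  invisible(path)
}

#' Load a deformation field from NIfTI
#'
#' Accepts 4-D `(x, y, z, 3)` volumes or SPM-style 5-D `(x, y, z, 1, 3)`.
#'
#' @param path NIfTI path.
#' @param direction Field direction tag.
#' @return An [deformation_field()].
#' @export
load_deformation_field <- function(path, direction = c("patient_to_mni",
                                                       "mni_to_patient")) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  arr <- array(as.double(img), dim = d)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, dim = d[c(1:3, 5)])
    d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 3-component deformation field in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  deformation_field(arr, aff, match.arg(direction))
}
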