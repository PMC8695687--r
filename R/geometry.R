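#' SEEG lead geometry specification
#'
#' Describes a depth lead by its contact count and the center-to-center gap
#' spacings, ordered from the deepest contact outward. Grouped leads (e.g.
#' groups of contacts with 3.5 mm within-group spacing and 7 mm between
#' groups) are expressed by listing each gap explicitly.
#'
#' @param name Lead name.
#' @param n_contacts Number of contacts (>= 2).
#' @param gap_spacings_mm Either a single spacing recycled to all gaps or a
#'   vector of length `n_contacts - 1`, deepest gap first.
#' @return A list of class `eloc_lead_spec`.
#' @export
lead_spec <- function(name, n_contacts, gap_spacings_mm) {
  n_contacts <- as.integer(n_contacts)
  if (n_contacts < 2L) stop("a lead needs at least 2 contacts")
  if (length(gap_spacings_mm) == 1L)
    gap_spacings_mm <- rep(gap_spacings_mm, n_contacts - 1L)
  if (length(gap_spacings_mm) != n_contacts - 1L)
    stop("gap_spacings_mm must have length n_contacts - 1")
  if (any(gap_spacings_mm <= 0)) stop("spacings must be positive")
  structure(list(name = name, n_contacts = n_contacts,
                 gap_spacings_mm = as.double(gap_spacings_mm)),
            class = "eloc_lead_spec")
}

#' ECoG grid/strip geometry specification
#'
#' @param rows,cols Grid dimensions (a strip has `rows = 1` or `cols = 1`).
#' @param pitch_mm Intercontact pitch in mm.
#' @param name Grid name.
#' @return A list of class `eloc_grid_spec`.
#' @export
grid_spec <- function(rows, cols, pitch_mm, name = "grid") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 1L) stop("grid must have at least one contact")
  if (pitch_mm <= 0) stop("pitch_mm must be positive")
  structure(list(rows = rows, cols = cols, pitch_mm = pitch_mm, name = name),
            class = "eloc_grid_spec")
}

#' Correct SEEG lead intercontact spacing
#'
#' Iterative spacing/alignment correction starting at the (trusted) deepest
#' contact: at each step the direction is the mean of the vectors from the
#' corrected previous contact to the original current and next contacts
#' (normalized after averaging); the current contact is then placed at
#' exactly the nominal gap distance along that direction. The most
#' superficial contact uses the single available vector. Every corrected gap
#' therefore equals the manufacturer spacing exactly, and jittered straight
#' leads come out straighter.
#'
#' @param contacts n x 3 matrix of contact positions (mm), deepest first.
#' @param spec An [lead_spec()] with `n_contacts == nrow(contacts)`.
#' @return n x 3 matrix of corrected positions (deepest row unchanged).
#' @export
correct_lead_spacing <- function(contacts, spec) {
  contacts <- rbind2mat(contacts)
  n <- nrow(contacts)
  if (n != spec$n_contacts)
    stop("contacts (", n, ") do not match spec n_contacts (",
         spec$n_contacts, ")")
  gaps <- spec$gap_spacings_mm
  out <- contacts
  for (k in 2:n) {
    v1 <- contacts[k, ] - out[k - 1, ]
    dir <- if (k < n) (v1 + (contacts[k + 1, ] - out[k - 1, ])) / 2 else v1
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) stop("degenerate lead geometry at contact ", k)
    out[k, ] <- out[k - 1, ] + gaps[k - 1] * dir / nrm
  }
  out
}

#' Projection vector for manual brain-shift correction
#'
#' Three vector modes are supported for projecting a surface electrode back
#' onto the smoothed projection surface: `"brain_center"` points from the
#' mid-commissural point through the electrode; `"view_direction"` is a
#' caller-supplied viewing direction (returned verbatim); `"surface_normal"`
#' is the outward normal of the projection surface at the point nearest the
#' electrode.
#'
#' @param e World-mm electrode position (length 3).
#' @param mode One of `"brain_center"`, `"view_direction"`,
#'   `"surface_normal"`.
#' @param projection Projection `eloc_surface` (required for
#'   `surface_normal`).
#' @param view_dir Unit viewing direction (required for `view_direction`).
#' @param mcp_mm Mid-commissural point (required for `brain_center`).
#' @return Unit length-3 vector.
#' @export
projection_vector <- function(e, mode = c("brain_center", "view_direction",
                                          "surface_normal"),
                              projection = NULL, view_dir = NULL,
                              mcp_mm = NULL) {
  mode <- match.arg(mode)
  e <- as.double(e)
  switch(mode,
    brain_center = {
      if (is.null(mcp_mm)) stop("brain_center mode requires mcp_mm")
      d <- e - as.double(mcp_mm)
      if (sqrt(sum(d^2)) < 1e-9)
        stop("undefined direction: electrode coincides with mcp")
      unit3(d)
    },
    view_direction = {
      if (is.null(view_dir)) stop("view_direction mode requires view_dir")
      unit3(as.double(view_dir))
    },
    surface_normal = {
      if (is.null(projection)) stop("surface_normal mode requires projection")
      np <- nearest_point_on_surface(e, projection)
      as.double(np$normal[1, ])
    })
}

# First ray-mesh hit along +v from p; NULL when the ray misses.
ray_first_hit <- function(p, v, s) {
  hits <- .ray_mesh_cpp(s$vertices, s$faces - 1L, as.double(p), as.double(v))
  if (length(hits$t) == 0L) return(NULL)
  list(t = hits$t[1], point = as.double(p) + hits$t[1] * as.double(v),
       face = hits$face[1] + 1L)
}

#' Move an electrode along a projection vector
#'
#' With `step_mm` unset the electrode moves to the first intersection of the
#' ray from its position along `v` with the projection surface. With
#' `step_mm` set the electrode is nudged by `step_mm * v` with no surface
#' constraint (the interactive fine-adjustment; default nudge elsewhere in
#' the package is 0.4 mm, one working voxel).
#'
#' @param e World-mm electrode position (length 3).
#' @param v Unit direction.
#' @param projection Projection `eloc_surface`.
#' @param step_mm Optional signed nudge distance in mm.
#' @return Updated length-3 position.
#' @export
project_along <- function(e, v, projection, step_mm = NULL) {
  e <- as.double(e); v <- unit3(as.double(v))
  if (!is.null(step_mm)) return(e + step_mm * v)
  hit <- ray_first_hit(e, v, projection)
  if (is.null(hit)) stop("ray misses surface")
  hit$point
}

# Outward projection of one contact along +/-n: the orientation whose first
# hit is nearer wins; falls back to nearest-point projection when both miss.
project_ray_outward <- function(p, n, projection) {
  np <- nearest_point_on_surface(p, projection)
  if (np$distance < 1e-7) return(as.double(p))   # already on the surface
  h1 <- ray_first_hit(p, n, projection)
  h2 <- ray_first_hit(p, -n, projection)
  if (is.null(h1) && is.null(h2)) {
    warning("ray misses surface; falling back to nearest-point projection")
    return(as.double(nearest_point_on_surface(p, projection)$point))
  }
  if (is.null(h2) || (!is.null(h1) && h1$t <= h2$t)) h1$point else h2$point
}

#' Project ECoG grid/strip electrodes onto the projection surface
#'
#' Brain-shift correction for surface electrodes: contacts of a grid are
#' moved along the local grid normal (estimated from labelled row/column
#' neighbours, one-sided at edges and corners) to the nearer ray-surface
#' intersection; contacts of a strip (single row or column) are moved to
#' their nearest point on the surface. Original positions are retained in
#' `orig_x/y/z` columns.
#'
#' @param electrodes An [electrode_set()] with integer `row` and `col`
#'   columns establishing grid topology.
#' @param grid A [grid_spec()]; `rows * cols` must match the labelled
#'   contacts.
#' @param projection Projection `eloc_surface`.
#' @return The updated `eloc_electrodes` with projected coordinates.
#' @export
project_grid <- function(electrodes, grid, projection) {
  es <- electrodes
  if (is.null(es$row) || is.null(es$col) ||
      anyNA(es$row) || anyNA(es$col))
    stop("grid topology unresolved: electrodes need row/col labels")
  if (nrow(es) != grid$rows * grid$cols ||
      !setequal(paste(es$row, es$col),
                paste(rep(seq_len(grid$rows), grid$cols),
                      rep(seq_len(grid$cols), each = grid$rows))))
    stop("grid topology unresolved: labels do not form a complete ",
         grid$rows, " x ", grid$cols, " grid")
  pos <- as.matrix(es[, c("x", "y", "z")])
  es$orig_x <- pos[, 1]; es$orig_y <- pos[, 2]; es$orig_z <- pos[, 3]
  is_strip <- grid$rows == 1L || grid$cols == 1L
  if (is_strip) {
    np <- nearest_point_on_surface(pos, projection)
    es$x <- np$point[, 1]; es$y <- np$point[, 2]; es$z <- np$point[, 3]
    return(es)
  }
  at <- function(r, c) pos[which(es$row == r & es$col == c)[1], ]
  for (q in seq_len(nrow(es))) {
    r <- es$row[q]; c <- es$col[q]
    dr <- at(min(r + 1, grid$rows), c) - at(max(r - 1, 1), c)
    dc <- at(r, min(c + 1, grid$cols)) - at(r, max(c - 1, 1))
    nrm <- cross3(dr, dc)
    if (sqrt(sum(nrm^2)) < 1e-9) {
      warning("degenerate local normal; using nearest-point projection")
      p2 <- as.double(nearest_point_on_surface(pos[q, ], projection)$point)
    } else {
      p2 <- project_ray_outward(pos[q, ], unit3(nrm), projection)
    }
    es$x[q] <- p2[1]; es$y[q] <- p2[2]; es$z[q] <- p2[3]
  }
  es
}

#' Rotation bringing a lead into a viewing plane
#'
#' For in-plane ("inline") display of a depth lead, computes the minimal
#' rotation, about the axis `lead x plane_normal` through the lead midpoint,
#' that makes the first-to-last contact vector perpendicular to
#' `plane_normal` (i.e. lying in the viewing plane). When the lead is
#' parallel to the plane normal the rotation is 90 degrees about a
#' deterministic perpendicular axis (the world axis least aligned with the
#' normal, orthogonalized).
#'
#' @param first,last World-mm positions of the first and last lead contacts.
#' @param plane_normal Unit normal of the viewing plane.
#' @return An `eloc_rigid` (rotation about the lead midpoint).
#' @export
inline_rotation <- function(first, last, plane_normal) {
  first <- as.double(first); last <- as.double(last)
  if (sqrt(sum((last - first)^2)) < 1e-12) stop("first and last coincide")
  v <- unit3(last - first)
  n <- unit3(as.double(plane_normal))
  vpar <- v - sum(v * n) * n
  if (sqrt(sum(vpar^2)) < 1e-9) {
    # lead parallel to the normal: rotate 90 degrees about a fixed choice
    basis <- diag(3)[, which.min(abs(n)), drop = TRUE]
    axis <- unit3(cross3(n, basis))
    R <- rodrigues(axis, pi / 2)
  } else {
    u <- unit3(vpar)
    ang <- acos(pmin(1, pmax(-1, sum(v * u))))
    if (ang < 1e-12) {
      R <- diag(3)
    } else {
      R <- rodrigues(unit3(cross3(v, u)), ang)
    }
  }
  m <- (first + last) / 2
  rigid_transform(R, m - R %*% m)
}

# Rodrigues rotation matrix about unit axis by angle (radians)
rodrigues <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
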