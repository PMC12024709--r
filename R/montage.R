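# Spherical 10-20 montage geometry: electrode angles, surface and depth
# positions, reference re-centring, and the 21 x 4 recording grid.

#' Canonical depth levels
#'
#' Recording depths along the insertion line, expressed as a fraction of the
#' sphere diameter: `Z0` (surface), `Z33` (one third), `Z66` (two thirds) and
#' `Z100` (full diameter, i.e. the far surface). The order is part of the
#' output contract of [recording_grid()].
#'
#' @return Character vector of the four depth labels, ordered shallow to deep.
#' @export
depth_levels <- function() c("Z0", "Z33", "Z66", "Z100")

#' The 21 electrode labels of the 10-20 system
#'
#' Label order is fixed (frontal to occipital, left to right within a row)
#' and defines the row ordering of every table the package produces.
#'
#' @return Character vector of 21 electrode labels.
#' @export
electrode_labels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
}

#' Angular positions of the 21 standard 10-20 electrodes on a sphere
#'
#' Angles use an elevation/azimuth convention on the head sphere: elevation is
#' measured upward from the equatorial plane (so the vertex Cz sits at 90
#' degrees) and azimuth from the nasion direction (+y) toward the right
#' preauricular direction (+x), in (-180, 180]. The 12 circumferential
#' electrodes sit at 18 degrees elevation with azimuths at the conventional
#' 10-20 percentage spacings (0, +/-18, +/-54, +/-90, +/-126, +/-162, 180);
#' the parasagittal row (F3/F4/P3/P4) at 36 degrees; the coronal/midline row
#' (Fz, C3, C4, Pz) at 54 degrees; Cz at the pole. The azimuth of the pole is
#' conventional (0) and carries no geometric meaning.
#'
#' @return A data.frame with columns `label`, `elevation_deg`, `azimuth_deg`
#'   and `hemisphere` (`"left"`, `"right"` or `"midline"`), one row per
#'   electrode in [electrode_labels()] order.
#' @export
#' @examples
#' standard_1020_angles()
standard_1020_angles <- function() {
  a <- rbind(
    Fp1 = c(18, -18),  Fpz = c(18, 0),    Fp2 = c(18, 18),
    F7  = c(18, -54),  F3  = c(36, -36),  Fz  = c(54, 0),
    F4  = c(36, 36),   F8  = c(18, 54),   T3  = c(18, -90),
    C3  = c(54, -90),  Cz  = c(90, 0),    C4  = c(54, 90),
    T4  = c(18, 90),   T5  = c(18, -126), P3  = c(36, -144),
    Pz  = c(54, 180),  P4  = c(36, 144),  T6  = c(18, 126),
    O1  = c(18, -162), Oz  = c(18, 180),  O2  = c(18, 162)
  )
  a <- a[electrode_labels(), , drop = FALSE]
  hemi <- ifelse(a[, 2] %in% c(0, 180) | a[, 1] == 90, "midline",
                 ifelse(a[, 2] < 0, "left", "right"))
  data.frame(label = rownames(a), elevation_deg = a[, 1],
             azimuth_deg = a[, 2], hemisphere = hemi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a spherical phantom model
#'
#' @param diameter_mm Maximum phantom diameter in mm (the sphere diameter).
#' @param center Sphere centre in the world frame (mm); the frame is
#'   right-handed with +x toward the right preauricular point, +y toward the
#'   nasion and +z toward the vertex.
#' @return An object of class `sphere_model` with elements `radius`,
#'   `diameter` and `center`.
#' @export
sphere_model <- function(diameter_mm, center = c(0, 0, 0)) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1 ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be a single positive number")
  }
  stopifnot(is.numeric(center), length(center) == 3, all(is.finite(center)))
  structure(list(radius = diameter_mm / 2, diameter = diameter_mm,
                 center = as.numeric(center)),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("Spherical phantom: diameter %.2f mm, centre (%g, %g, %g)\n",
              x$diameter, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Cartesian surface position of electrodes on the sphere
#'
#' Maps elevation/azimuth angles to world-frame Cartesian coordinates:
#' `center + R * (cos(el) sin(az), cos(el) cos(az), sin(el))`.
#'
#' @param angles A data.frame with columns `label`, `elevation_deg`,
#'   `azimuth_deg` (any subset of rows of [standard_1020_angles()]).
#' @param sphere A [sphere_model()].
#' @return Numeric matrix (n x 3, columns x/y/z in mm) with electrode labels
#'   as row names.
#' @export
surface_position <- function(angles, sphere) {
  stopifnot(inherits(sphere, "sphere_model"))
  el <- angles$elevation_deg * pi / 180
  az <- angles$azimuth_deg * pi / 180
  p <- sphere$radius * cbind(x = cos(el) * sin(az),
                             y = cos(el) * cos(az),
                             z = sin(el))
  p <- sweep(p, 2, sphere$center, "+")
  rownames(p) <- angles$label
  p
}

#' Build the full spherical montage layout
#'
#' Combines the sphere model and the standard angle table into a layout
#' carrying every electrode's surface position.
#'
#' @inheritParams sphere_model
#' @param angles Angle table; defaults to [standard_1020_angles()]. Must
#'   contain exactly 21 distinct labels.
#' @return An object of class `montage_layout` with elements `sphere`,
#'   `angles` and `positions` (21 x 3 matrix, mm, world frame).
#' @export
#' @examples
#' lay <- montage_layout(240.80)
#' lay$positions["Cz", ]
montage_layout <- function(diameter_mm = 240.80,
                           angles = standard_1020_angles()) {
  sph <- if (inherits(diameter_mm, "sphere_model")) diameter_mm else
    sphere_model(diameter_mm)
  if (anyDuplicated(angles$label) || nrow(angles) != 21) {
    stop("the layout needs exactly 21 distinct electrode labels")
  }
  if (any(angles$elevation_deg < 0 | angles$elevation_deg > 90) ||
      any(angles$azimuth_deg <= -180 | angles$azimuth_deg > 180)) {
    stop("elevations must lie in [0, 90] and azimuths in (-180, 180] degrees")
  }
  structure(list(sphere = sph, angles = angles,
                 positions = surface_position(angles, sph)),
            class = "montage_layout")
}

#' @export
print.montage_layout <- function(x, ...) {
  cat(sprintf("10-20 montage on a %.2f mm sphere (%d electrodes)\n",
              x$sphere$diameter, nrow(x$angles)))
  invisible(x)
}

# unit radial vector(s) of surface points, checking they sit on the sphere
.radial_unit <- function(points, sphere, tol = 1e-6) {
  points <- rbind(points)
  v <- sweep(points, 2, sphere$center, "-")
  r <- sqrt(rowSums(v^2))
  if (any(abs(r - sphere$radius) > tol * sphere$radius)) {
    stop("point(s) do not lie on the sphere surface")
  }
  v / r
}

#' Project a surface electrode to a recording depth
#'
#' The insertion line enters at the surface point and the four depths are
#' represented on concentric spheres: `Z0` on the surface sphere (radius R),
#' `Z33` and `Z66` on the inner sphere of radius R/3, and `Z100` back on the
#' surface sphere. For depths beyond the half-diameter (`Z66`, `Z100`) the
#' radial direction is transformed by M(x, y, z) = (x, -y, -z), a 180-degree
#' rotation about the left-right axis through the centre, which keeps deep
#' points book-kept on the ipsilateral side (`deep_projection = "mirror"`,
#' the default). `deep_projection = "antipode"` instead uses the physically
#' radial continuation -u, placing `Z100` at the true antipode.
#'
#' @param surface_point Numeric 3-vector (or n x 3 matrix) of world-frame
#'   surface position(s) in mm; must lie on the sphere (relative tolerance
#'   1e-6).
#' @param sphere A [sphere_model()].
#' @param depth One of `"Z0"`, `"Z33"`, `"Z66"`, `"Z100"`.
#' @param deep_projection `"mirror"` (default) or `"antipode"`.
#' @return World-frame position(s) at the requested depth, same shape as the
#'   input.
#' @export
depth_position <- function(surface_point, sphere,
                           depth = depth_levels(),
                           deep_projection = c("mirror", "antipode")) {
  depth <- match.arg(depth)
  deep_projection <- match.arg(deep_projection)
  u <- .radial_unit(surface_point, sphere)
  M <- if (deep_projection == "mirror") {
    sweep(u, 2, c(1, -1, -1), "*")
  } else {
    -u
  }
  R <- sphere$radius
  d <- switch(depth,
              Z0   = R * u,
              Z33  = (R / 3) * u,
              Z66  = (R / 3) * M,
              Z100 = R * M)
  out <- sweep(d, 2, sphere$center, "+")
  if (is.null(dim(surface_point))) out <- drop(out)
  out
}

#' Define the recording reference frame
#'
#' The recording reference rides on a stimulating pad at one of the 10-20
#' positions; its surface position becomes the coordinate origin after
#' translation.
#'
#' @param layout A [montage_layout()].
#' @param reference Electrode label of the recording reference.
#' @return An object of class `reference_frame` with elements `reference`
#'   (label) and `origin` (world-frame surface position, mm).
#' @export
reference_frame <- function(layout, reference) {
  stopifnot(inherits(layout, "montage_layout"))
  if (!reference %in% rownames(layout$positions)) {
    stop(sprintf("unknown reference electrode '%s'", reference))
  }
  structure(list(reference = reference,
                 origin = layout$positions[reference, ]),
            class = "reference_frame")
}

#' Translate world-frame points into the recording reference frame
#'
#' Subtracts the reference electrode's surface position from every point, so
#' that the reference surface point maps exactly to (0, 0, 0).
#'
#' @param points Numeric 3-vector or n x 3 matrix of world-frame points (mm).
#' @param reference A [reference_frame()].
#' @return Points in the reference frame, same shape as the input.
#' @export
translate_to_reference <- function(points, reference) {
  stopifnot(inherits(reference, "reference_frame"))
  out <- sweep(rbind(points), 2, reference$origin, "-")
  if (is.null(dim(points))) out <- drop(out)
  out
}

#' The 84-site recording grid
#'
#' Positions every electrode at the four recording depths, re-centres on the
#' recording reference, and computes each site's straight-line distance to
#' the reference origin (the denominator of the field estimate).
#'
#' @param layout A [montage_layout()].
#' @param reference A [reference_frame()] or an electrode label.
#' @inheritParams depth_position
#' @return A data.frame of 84 rows (21 electrodes x 4 depths, electrode-major
#'   in [electrode_labels()] order) with columns `electrode`, `depth`,
#'   `x_mm`, `y_mm`, `z_mm` (reference frame) and `distance_mm`. The sphere
#'   radius and reference origin are attached as attributes `radius_mm` and
#'   `origin`.
#' @export
#' @examples
#' g <- recording_grid(montage_layout(240.80), "C3")
#' subset(g, electrode == "Cz" & depth == "Z0")
recording_grid <- function(layout, reference,
                           deep_projection = c("mirror", "antipode")) {
  stopifnot(inherits(layout, "montage_layout"))
  deep_projection <- match.arg(deep_projection)
  if (!inherits(reference, "reference_frame")) {
    reference <- reference_frame(layout, reference)
  }
  labs <- layout$angles$label
  depths <- depth_levels()
  rows <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    sp <- layout$positions[labs[i], ]
    pts <- t(vapply(depths, function(d) {
      depth_position(sp, layout$sphere, d, deep_projection)
    }, numeric(3)))
    rel <- translate_to_reference(pts, reference)
    rows[[i]] <- data.frame(electrode = labs[i], depth = depths,
                            x_mm = rel[, 1], y_mm = rel[, 2], z_mm = rel[, 3],
                            distance_mm = sqrt(rowSums(rel^2)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "radius_mm") <- layout$sphere$radius
  attr(out, "origin") <- reference$origin
  attr(out, "center") <- layout$sphere$center
  attr(out, "reference") <- reference$reference
  out
}
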