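# Topographic rendering of dV / EF on the four concentric recording
# spheres: orthographic projections and inverse-distance-weighted shading.

#' Orthographic projection of recording points for a given view
#'
#' Projects sphere-centred 3-D points onto the viewing plane. The anterior
#' view looks along -y (viewer at the nasion), the posterior view along +y,
#' and the superior view along -z (viewer above the vertex). Points on the
#' hemisphere facing away from the viewer are flagged hidden. By default the
#' phantom's left (x < 0) appears on the viewer's left in the anterior and
#' superior views (`flip_x = FALSE`); `flip_x = TRUE` mirrors the horizontal
#' axis.
#'
#' @param points n x 3 matrix (or data.frame with columns `x_mm`, `y_mm`,
#'   `z_mm`) of sphere-centred coordinates, mm.
#' @param view `"anterior"`, `"posterior"` or `"superior"`.
#' @param flip_x Logical handedness flag for the horizontal axis.
#' @return A data.frame with columns `u`, `v` (mm, viewing plane) and
#'   `hidden` (logical).
#' @export
project_view <- function(points, view = c("anterior", "posterior", "superior"),
                         flip_x = FALSE) {
  view <- match.arg(view)
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  }
  points <- rbind(points)
  out <- switch(view,
    anterior  = data.frame(u = points[, 1], v = points[, 3],
                           hidden = points[, 2] < 0),
    posterior = data.frame(u = -points[, 1], v = points[, 3],
                           hidden = points[, 2] > 0),
    superior  = data.frame(u = points[, 1], v = points[, 2],
                           hidden = points[, 3] < 0))
  if (flip_x) out$u <- -out$u
  out
}

# warm = high, cool = low
.field_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#313695", "#4575b4", "#abd9e9", "#ffffbf",
                                "#fdae61", "#f46d43", "#a50026"))(n)
}

.value_colors <- function(values, bounds, pal = .field_palette()) {
  idx <- findInterval(values, seq(bounds[1], bounds[2],
                                  length.out = length(pal) + 1),
                      all.inside = TRUE)
  pal[idx]
}

# inverse-distance-weighted (power 2) interpolation of scattered values on a
# grid, masked to the disc of the given radius
.idw_disc <- function(u, v, values, radius, ngrid = 120, power = 2) {
  gx <- seq(-radius, radius, length.out = ngrid)
  gy <- seq(-radius, radius, length.out = ngrid)
  zz <- matrix(NA_real_, ngrid, ngrid)
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      if (gx[i]^2 + gy[j]^2 > radius^2) next
      d2 <- (gx[i] - u)^2 + (gy[j] - v)^2
      if (any(d2 == 0)) {
        zz[i, j] <- values[which(d2 == 0)[1]]
      } else {
        w <- 1 / d2^(power / 2)
        zz[i, j] <- sum(w * values) / sum(w)
      }
    }
  }
  list(x = gx, y = gy, z = zz)
}

#' Render a topographic map of a field table on the recording spheres
#'
#' Draws the chosen quantity at one depth (or all four as panels A-D,
#' ordered Z0, Z33, Z66, Z100) as a shaded disc: electrode markers coloured
#' by value, with inverse-distance-weighted shading over the projected disc
#' of the depth's sphere (radius R for Z0/Z100, R/3 for Z33/Z66). Warm
#' colours are high values, cool colours low. Electrodes on the hidden
#' hemisphere are drawn hollow and excluded from the shading.
#'
#' @param table A `field_table` from [build_field_table()].
#' @param quantity `"dv"` (voltage difference, mV) or `"ef"` (field
#'   estimate, mV/mm).
#' @param depth A depth label or `"all"` for a four-panel figure.
#' @param view Passed to [project_view()].
#' @param scale `"global"` (one colour scale across the four depths, the
#'   default, so depths are comparable) or `"per-depth"`; or a numeric
#'   `c(low, high)` for explicit bounds.
#' @param out Output PNG path.
#' @param width,height Device size in pixels.
#' @return Invisibly, the output path.
#' @export
render_map <- function(table, quantity = c("dv", "ef"), depth = "all",
                       view = c("anterior", "posterior", "superior"),
                       scale = "global", out, width = 900, height = 900) {
  quantity <- match.arg(quantity)
  view <- match.arg(view)
  stopifnot(inherits(table, "field_table"))
  depths <- if (identical(depth, "all")) depth_levels() else
    match.arg(depth, depth_levels())
  col <- if (quantity == "dv") "delta_v_mV" else "ef_mV_per_mm"
  unit <- if (quantity == "dv") "mV" else "mV/mm"
  vals_all <- table[[col]][table$depth %in% depths]
  if (is.numeric(scale) && length(scale) == 2) {
    if (scale[1] >= scale[2]) stop("explicit scale bounds need low < high")
    bounds_global <- scale
    per_depth <- FALSE
  } else {
    scale <- match.arg(scale, c("global", "per-depth"))
    per_depth <- scale == "per-depth"
    bounds_global <- range(vals_all)
  }
  # positions in the table are reference-translated; recover sphere-centred
  shift <- attr(table, "origin") - attr(table, "center")
  R <- attr(table, "radius_mm")
  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  np <- length(depths)
  if (np > 1) graphics::par(mfrow = c(2, 2))
  graphics::par(mar = c(2, 2, 3, 5))
  for (k in seq_along(depths)) {
    d <- depths[k]
    sub <- table[table$depth == d, ]
    ctr3 <- sweep(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]), 2, shift, "+")
    prj <- project_view(ctr3, view)
    rad <- if (d %in% c("Z33", "Z66")) R / 3 else R
    vals <- sub[[col]]
    bounds <- if (per_depth) range(vals) else bounds_global
    if (bounds[1] == bounds[2]) bounds <- bounds + c(-0.5, 0.5)
    vis <- !prj$hidden
    graphics::plot(NA, xlim = c(-R, R) * 1.15, ylim = c(-R, R) * 1.15,
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s%s  %s  (%s view)",
                                  if (np > 1) paste0("(", LETTERS[k], ") ") else "",
                                  d, toupper(quantity), view))
    if (any(vis)) {
      fld <- .idw_disc(prj$u[vis], prj$v[vis], vals[vis], rad)
      graphics::image(fld$x, fld$y, t(fld$z), add = TRUE,
                      col = .field_palette(),
                      zlim = bounds, useRaster = TRUE)
    }
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(rad * cos(th), rad * sin(th), col = "grey30")
    graphics::points(prj$u[vis], prj$v[vis], pch = 21, cex = 1.4,
                     bg = .value_colors(vals[vis], bounds), col = "black")
    graphics::points(prj$u[!vis], prj$v[!vis], pch = 21, cex = 1.1,
                     bg = NA, col = "grey50")
    graphics::text(prj$u, prj$v, sub$electrode, pos = 3, cex = 0.7,
                   col = ifelse(prj$hidden, "grey60", "black"))
    # colour bar
    ny <- 50
    ys <- seq(-R, R, length.out = ny + 1)
    graphics::rect(R * 1.08, ys[-(ny + 1)], R * 1.14, ys[-1],
                   col = .field_palette(ny), border = NA, xpd = NA)
    graphics::text(R * 1.14, c(-R, R),
                   sprintf("%.3g", bounds), pos = 4, cex = 0.7, xpd = NA)
    graphics::text(R * 1.11, R * 1.08, unit, cex = 0.7, xpd = NA)
  }
  invisible(out)
}
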