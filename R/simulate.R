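# Quasi-static point-source forward model on a homogeneous conducting
# sphere: montage presets, pad discretisation, superposed monopole
# potentials, and synthetic recording sets for pipeline testing.

#' Stimulation montage presets
#'
#' Three validated montages are built in. Condition A is monopolar: two
#' anodes over the simulated motor cortices (7 x 5 cm over C3 and C4, 1 mA
#' each, 2 mA total) with an extracephalic return (8 x 6 cm in the water
#' bath) and the recording reference riding on the C3 pad. Condition B is
#' bicephalic fronto-occipital: anodes over Fp1/Fp2, returns over O1/O2
#' (5 x 5 cm, 0.7 mA per pad, two 1.4 mA circuits), reference on O1.
#' Condition C is bicephalic latero-lateral: anodes over F7/T5, returns over
#' F8/T6 (5 x 5 cm, 0.7 mA per pad), reference on T6.
#'
#' @param condition `"A"`, `"B"`, `"C"` or `"custom"`.
#' @param pads For `"custom"`: a data.frame with columns `location`
#'   (electrode label or `"bath"` for an extracephalic return), `polarity`
#'   (`"anode"`/`"cathode"`), `width_cm`, `height_cm`, `current_mA`
#'   (signed: positive into the phantom). Currents must sum to zero.
#' @param reference For `"custom"`: recording reference label; must be one
#'   of the pad locations.
#' @return An object of class `stimulus_montage` with elements `condition`,
#'   `pads` and `reference`.
#' @export
#' @examples
#' stimulus_montage("A")
stimulus_montage <- function(condition = c("A", "B", "C", "custom"),
                             pads = NULL, reference = NULL) {
  condition <- match.arg(condition)
  preset <- function(loc, pol, w, h, i) {
    data.frame(location = loc, polarity = pol, width_cm = w, height_cm = h,
               current_mA = i, stringsAsFactors = FALSE)
  }
  if (condition == "A") {
    pads <- preset(c("C3", "C4", "bath"), c("anode", "anode", "cathode"),
                   c(7, 7, 8), c(5, 5, 6), c(1, 1, -2))
    reference <- "C3"
  } else if (condition == "B") {
    pads <- preset(c("Fp1", "Fp2", "O1", "O2"),
                   c("anode", "anode", "cathode", "cathode"),
                   5, 5, c(0.7, 0.7, -0.7, -0.7))
    reference <- "O1"
  } else if (condition == "C") {
    pads <- preset(c("F7", "T5", "F8", "T6"),
                   c("anode", "anode", "cathode", "cathode"),
                   5, 5, c(0.7, 0.7, -0.7, -0.7))
    reference <- "T6"
  } else {
    if (is.null(pads) || is.null(reference)) {
      stop("custom montages need `pads` and `reference`")
    }
  }
  if (abs(sum(pads$current_mA)) > 1e-12) {
    stop("pad currents must sum to zero (charge conservation)")
  }
  if (!reference %in% pads$location) {
    stop("the recording reference must ride on one of the stimulating pads")
  }
  structure(list(condition = condition, pads = pads, reference = reference),
            class = "stimulus_montage")
}

#' @export
print.stimulus_montage <- function(x, ...) {
  cat(sprintf("Stimulus montage %s: %s; reference %s\n", x$condition,
              paste(sprintf("%s %+g mA", x$pads$location, x$pads$current_mA),
                    collapse = ", "), x$reference))
  invisible(x)
}

#' Forward-model parameters
#'
#' @param sigma Medium conductivity, S/m (homogeneous; default 0.5).
#' @param pad_grid Integer vector `c(n, m)`: point sources per pad
#'   (default 3 x 3).
#' @param inset_mm Radial inset of the point sources below the surface, mm
#'   (default 2; avoids singularities at surface recording sites).
#' @param noise_cv Coefficient of variation of the multiplicative readout
#'   noise (default 0.05; 0 for noiseless).
#' @param seed Optional integer seed for the noise generator.
#' @param round_mV Optional readout rounding step in mV (e.g. 400 to mimic a
#'   coarse oscilloscope readout); `NULL` for no rounding.
#' @return An object of class `forward_model_params`.
#' @export
forward_model_params <- function(sigma = 0.5, pad_grid = c(3, 3),
                                 inset_mm = 2, noise_cv = 0.05,
                                 seed = NULL, round_mV = NULL) {
  stopifnot(sigma > 0, inset_mm >= 0, noise_cv >= 0,
            length(pad_grid) %in% c(1, 2), all(pad_grid >= 1))
  if (length(pad_grid) == 1) pad_grid <- rep(pad_grid, 2)
  structure(list(sigma = sigma, pad_grid = as.integer(pad_grid),
                 inset_mm = inset_mm, noise_cv = noise_cv, seed = seed,
                 round_mV = round_mV),
            class = "forward_model_params")
}

# orthonormal tangent basis at unit radial vector u
.tangent_basis <- function(u) {
  helper <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  t1 <- helper - sum(helper * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Discretise stimulating pads into point current sources
#'
#' Each cephalic pad becomes an n x m grid of point sources sharing the pad
#' current equally: grid offsets span the pad's physical extent in the
#' tangent plane at the pad centre and are then projected radially onto the
#' sphere of radius R - inset. An extracephalic (`"bath"`) return is a single
#' point at the bottom pole, offset 20 mm outward into the bath.
#'
#' @param montage A [stimulus_montage()].
#' @param layout A [montage_layout()].
#' @param params A [forward_model_params()].
#' @return A data.frame with columns `pad`, `x`, `y`, `z` (mm, world frame)
#'   and `current_mA`; currents sum to zero.
#' @export
pad_source_points <- function(montage, layout,
                              params = forward_model_params()) {
  stopifnot(inherits(montage, "stimulus_montage"),
            inherits(layout, "montage_layout"))
  R <- layout$sphere$radius
  ctr <- layout$sphere$center
  n <- params$pad_grid[1]
  m <- params$pad_grid[2]
  out <- list()
  for (i in seq_len(nrow(montage$pads))) {
    p <- montage$pads[i, ]
    if (p$location == "bath") {
      pt <- ctr + c(0, 0, -(R + 20))
      out[[i]] <- data.frame(pad = "bath", x = pt[1], y = pt[2], z = pt[3],
                             current_mA = p$current_mA)
      next
    }
    if (!p$location %in% rownames(layout$positions)) {
      stop(sprintf("unknown pad location '%s'", p$location))
    }
    w_mm <- p$width_cm * 10
    h_mm <- p$height_cm * 10
    if (max(w_mm, h_mm) > pi * R) {
      stop(sprintf("pad at %s (%g x %g cm) exceeds the hemisphere circumference",
                   p$location, p$width_cm, p$height_cm))
    }
    u <- (layout$positions[p$location, ] - ctr) / R
    tb <- .tangent_basis(u)
    a <- if (n == 1) 0 else seq(-w_mm / 2, w_mm / 2, length.out = n)
    b <- if (m == 1) 0 else seq(-h_mm / 2, h_mm / 2, length.out = m)
    g <- expand.grid(a = a, b = b)
    pts <- t(apply(g, 1, function(r) {
      v <- R * u + r[["a"]] * tb$t1 + r[["b"]] * tb$t2
      ctr + (R - params$inset_mm) * v / sqrt(sum(v^2))
    }))
    out[[i]] <- data.frame(pad = p$location, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3], current_mA = p$current_mA / (n * m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quasi-static potential of superposed point current sources
#'
#' In an unbounded homogeneous medium of conductivity sigma, a point source
#' injecting current I produces the potential V(r) = I / (4 pi sigma r).
#' The potential of a source set is the superposition over all sources,
#' returned in mV.
#'
#' @param points n x 3 matrix (or 3-vector) of field points, mm.
#' @param sources Data.frame with columns `x`, `y`, `z` (mm) and
#'   `current_mA`, as from [pad_source_points()].
#' @param sigma Conductivity, S/m.
#' @return Potential(s) in mV, length n.
#' @export
#' @examples
#' # 1 mA at 50 mm in 0.5 S/m: ~3.183 mV
#' potential_at(c(50, 0, 0), data.frame(x = 0, y = 0, z = 0, current_mA = 1), 0.5)
potential_at <- function(points, sources, sigma) {
  stopifnot(sigma > 0)
  points <- unname(rbind(points))
  sp <- unname(as.matrix(sources[, c("x", "y", "z")]))
  v <- numeric(nrow(points))
  for (k in seq_len(nrow(sp))) {
    d2 <- (points[, 1] - sp[k, 1])^2 + (points[, 2] - sp[k, 2])^2 +
      (points[, 3] - sp[k, 3])^2
    if (any(d2 == 0)) stop("field point coincides with a source (singular)")
    # I [A] / (4 pi sigma r [m]) -> volts; *1e3 -> mV
    v <- v + (sources$current_mA[k] * 1e-3) / (4 * pi * sigma * sqrt(d2) * 1e-3)
  }
  v * 1e3
}

#' Simulate a phantom voltage recording set
#'
#' Produces an 84-site recording set for a montage by evaluating the forward
#' model at every (electrode, depth) site and differencing against the
#' reference pickup (the centre point of the reference pad's source grid,
#' mirroring a reference electrode taped to the stimulating pad surface):
#' dV = |V(site) - V(reference)|. Pad electrodes are marked not recordable.
#' Multiplicative Gaussian noise (1 + eps), eps ~ N(0, cv), is applied per
#' site, and the readout can optionally be rounded to a step.
#'
#' @param montage A [stimulus_montage()].
#' @param layout A [montage_layout()].
#' @param params A [forward_model_params()].
#' @param reference Recording reference label; defaults to the montage's
#'   built-in reference. Must be one of the montage's pad locations.
#' @return A [voltage_recordings()] set (pads `NA`, metadata carrying the
#'   sphere diameter and the simulation parameters).
#' @export
#' @examples
#' lay <- montage_layout(240.80)
#' rec <- simulate_recordings(stimulus_montage("A"), lay,
#'                            forward_model_params(noise_cv = 0, seed = 1))
simulate_recordings <- function(montage, layout,
                                params = forward_model_params(),
                                reference = montage$reference) {
  stopifnot(inherits(montage, "stimulus_montage"),
            inherits(layout, "montage_layout"),
            inherits(params, "forward_model_params"))
  cephalic <- setdiff(montage$pads$location, "bath")
  if (!reference %in% cephalic) {
    stop("the recording reference must be one of the montage's cephalic pads")
  }
  sources <- pad_source_points(montage, layout, params)
  ref_src <- sources[sources$pad == reference, , drop = FALSE]
  pickup <- colMeans(ref_src[, c("x", "y", "z")])
  grid <- recording_grid(layout, reference)
  world <- as.matrix(grid[, c("x_mm", "y_mm", "z_mm")])
  world <- sweep(world, 2, attr(grid, "origin"), "+")
  v_ref <- potential_at(pickup, sources, params$sigma)
  dv <- abs(potential_at(world, sources, params$sigma) - v_ref)
  if (params$noise_cv > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    dv <- dv * (1 + stats::rnorm(length(dv), 0, params$noise_cv))
    dv <- pmax(dv, 0)
  }
  if (!is.null(params$round_mV)) {
    dv <- round(dv / params$round_mV) * params$round_mV
  }
  is_pad <- grid$electrode %in% cephalic
  tab <- data.frame(electrode = grid$electrode, depth = grid$depth,
                    delta_v_mV = ifelse(is_pad, NA_real_, dv),
                    stringsAsFactors = FALSE)
  voltage_recordings(
    tab, condition = montage$condition, reference = reference,
    pads = cephalic,
    meta = list(diameter_mm = layout$sphere$diameter, simulated = TRUE,
                sigma_S_per_m = params$sigma, noise_cv = params$noise_cv,
                seed = params$seed))
}
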