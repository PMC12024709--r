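# Voltage-difference -> electric-field pipeline: recording-set container,
# pad imputation, the field table (the machine twin of the study's results
# table) and per-depth summaries.

#' Assemble and validate a voltage recording set
#'
#' A recording set holds one stimulation condition's voltage differences
#' (mV) at all 84 (electrode, depth) sites. Sites under stimulating pads are
#' not recordable and carry `NA`; every other site must have a finite,
#' non-negative value.
#'
#' @param delta_v A data.frame with columns `electrode`, `depth`,
#'   `delta_v_mV` covering every (electrode, depth) pair exactly once.
#' @param condition Condition label (free text, e.g. `"A"`).
#' @param reference Recording reference electrode label (must be a pad:
#'   the reference electrode rides on a stimulating pad).
#' @param pads Character vector of pad electrode labels (not recordable).
#' @param meta Optional named list of phantom metadata (`diameter_mm`,
#'   `weight_kg`, `temperature_C`, `resistance_kohm`, ...).
#' @return An object of class `voltage_recordings`.
#' @export
voltage_recordings <- function(delta_v, condition, reference, pads,
                               meta = list()) {
  problems <- character()
  need <- c("electrode", "depth", "delta_v_mV")
  if (!all(need %in% names(delta_v))) {
    stop("`delta_v` needs columns electrode, depth, delta_v_mV")
  }
  labs <- electrode_labels()
  bad <- setdiff(unique(delta_v$electrode), labs)
  if (length(bad)) {
    problems <- c(problems, paste("unknown electrode label(s):",
                                  paste(bad, collapse = ", ")))
  }
  badd <- setdiff(unique(delta_v$depth), depth_levels())
  if (length(badd)) {
    problems <- c(problems, paste("unknown depth level(s):",
                                  paste(badd, collapse = ", ")))
  }
  key <- paste(delta_v$electrode, delta_v$depth)
  full <- paste(rep(labs, each = 4), rep(depth_levels(), 21))
  if (nrow(delta_v) == 0) problems <- c(problems, "recording table has zero rows")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    problems <- c(problems, paste("duplicated (electrode, depth):",
                                  paste(dup, collapse = "; ")))
  }
  miss <- setdiff(full, key)
  if (length(miss) && nrow(delta_v) > 0) {
    problems <- c(problems, paste("missing (electrode, depth):",
                                  paste(miss, collapse = "; ")))
  }
  if (!reference %in% labs) {
    problems <- c(problems, sprintf("unknown reference electrode '%s'", reference))
  }
  is_pad <- delta_v$electrode %in% pads
  v <- delta_v$delta_v_mV
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    problems <- c(problems, paste("negative voltage difference at:",
                                  paste(key[neg], collapse = "; ")))
  }
  na_nonpad <- is.na(v) & !is_pad
  if (any(na_nonpad)) {
    problems <- c(problems, paste("missing voltage at non-pad site(s):",
                                  paste(key[na_nonpad], collapse = "; ")))
  }
  if (any(!is.na(v) & is_pad)) {
    problems <- c(problems, paste("pad electrode carries a measured value at:",
                                  paste(key[!is.na(v) & is_pad], collapse = "; ")))
  }
  if (length(problems)) {
    stop("invalid recording set:\n  - ", paste(problems, collapse = "\n  - "))
  }
  ord <- order(match(delta_v$electrode, labs), match(delta_v$depth, depth_levels()))
  delta_v <- delta_v[ord, need]
  rownames(delta_v) <- NULL
  structure(list(delta_v = delta_v, condition = condition,
                 reference = reference, pads = pads, meta = meta),
            class = "voltage_recordings")
}

#' @export
print.voltage_recordings <- function(x, ...) {
  cat(sprintf(
    "Voltage recording set, condition %s: %d sites, reference %s, pads {%s}\n",
    x$condition, nrow(x$delta_v), x$reference, paste(x$pads, collapse = ", ")))
  invisible(x)
}

#' Electric-field estimate from a voltage difference
#'
#' The field estimate is the scalar ratio EF = dV / ds, the measured voltage
#' difference divided by the straight-line distance between the recording
#' site and the reference origin. It is an average-magnitude estimate, not a
#' vector field.
#'
#' @param delta_v Voltage difference(s), mV; must be non-negative.
#' @param distance Distance(s) to the reference origin, mm; must be
#'   non-negative. A zero distance (the reference's own surface site) yields
#'   `NaN` — undefined at the origin — which [build_field_table()] resolves
#'   by neighbour averaging.
#' @return EF in mV/mm, same length as the inputs.
#' @export
#' @examples
#' compute_ef(15800, 129.37)
compute_ef <- function(delta_v, distance) {
  if (any(delta_v < 0, na.rm = TRUE)) stop("`delta_v` must be non-negative")
  if (any(distance < 0, na.rm = TRUE)) stop("`distance` must be non-negative")
  ifelse(distance == 0, NaN, delta_v / distance)
}

#' Neighbour sets used to impute pad-covered electrodes
#'
#' Sites under a stimulating pad cannot be recorded; their voltage is imputed
#' as the arithmetic mean of surrounding electrodes at the same depth. For
#' the central pads C3 and C4 the rule ships the five same-hemisphere
#' adjacent electrodes (midline excluded): C3 -> {F7, F3, T3, P3, T5} and
#' C4 -> {F8, F4, T4, P4, T6}. Any other pad gets its `k` nearest recordable
#' electrodes by great-circle distance on the surface sphere.
#'
#' @param pads Character vector of pad electrode labels.
#' @param layout A [montage_layout()] (used for the nearest-neighbour
#'   fallback).
#' @param k Number of nearest neighbours for non-canonical pads.
#' @return Named list mapping each pad label to a character vector of
#'   neighbour labels (never containing a pad).
#' @export
default_neighbor_rule <- function(pads, layout = montage_layout(), k = 5) {
  canonical <- list(C3 = c("F7", "F3", "T3", "P3", "T5"),
                    C4 = c("F8", "F4", "T4", "P4", "T6"))
  pos <- layout$positions
  ctr <- layout$sphere$center
  R <- layout$sphere$radius
  u <- sweep(pos, 2, ctr, "-") / R
  rule <- lapply(pads, function(p) {
    cand <- canonical[[p]]
    if (!is.null(cand) && !any(cand %in% pads)) return(cand)
    others <- setdiff(rownames(pos), pads)
    ang <- acos(pmin(1, pmax(-1, u[others, , drop = FALSE] %*% u[p, ])))
    others[order(ang)][seq_len(min(k, length(others)))]
  })
  names(rule) <- pads
  rule
}

.check_rule <- function(rule, pads) {
  if (!all(pads %in% names(rule))) {
    stop("imputation rule is missing pad(s): ",
         paste(setdiff(pads, names(rule)), collapse = ", "))
  }
  for (p in pads) {
    nb <- rule[[p]]
    if (length(nb) == 0) stop(sprintf("empty neighbour set for pad %s", p))
    if (any(nb %in% pads)) {
      stop(sprintf("neighbour set for pad %s contains pad electrode(s): %s",
                   p, paste(intersect(nb, pads), collapse = ", ")))
    }
  }
  invisible(rule)
}

#' Impute pad-covered voltages by neighbour averaging
#'
#' Replaces each pad electrode's `NA` voltage at every depth with the
#' arithmetic mean of its neighbours' voltages at the same depth. Measured
#' values pass through unchanged.
#'
#' @param recordings A [voltage_recordings()] set.
#' @param rule Named list pad -> neighbour labels; defaults to
#'   [default_neighbor_rule()] on the standard layout.
#' @return The recording set with a logical `imputed` column added to
#'   `delta_v` and no remaining `NA` voltages.
#' @export
impute_pad_voltages <- function(recordings,
                                rule = default_neighbor_rule(recordings$pads)) {
  stopifnot(inherits(recordings, "voltage_recordings"))
  .check_rule(rule, recordings$pads)
  dv <- recordings$delta_v
  dv$imputed <- is.na(dv$delta_v_mV)
  for (p in recordings$pads) {
    for (d in depth_levels()) {
      nb <- rule[[p]]
      vals <- dv$delta_v_mV[dv$electrode %in% nb & dv$depth == d]
      if (anyNA(vals)) {
        stop(sprintf("cannot impute %s at %s: neighbour voltage missing", p, d))
      }
      dv$delta_v_mV[dv$electrode == p & dv$depth == d] <- mean(vals)
    }
  }
  recordings$delta_v <- dv
  recordings$imputation_rule <- rule
  recordings
}

#' Field estimate at the reference's own surface site
#'
#' The reference electrode's surface site is the coordinate origin, so its
#' distance is zero and dV/ds is undefined there. Following the study's
#' convention, the field at that site is imputed as the arithmetic mean of
#' the neighbours' surface field estimates.
#'
#' @param field_table A (possibly partial) field table containing `electrode`,
#'   `depth` and `ef_mV_per_mm` for the neighbours' surface rows.
#' @param pad The pad electrode whose surface field is undefined.
#' @param rule Named list pad -> neighbour labels.
#' @return The imputed surface field estimate (mV/mm).
#' @export
impute_reference_surface <- function(field_table, pad, rule) {
  nb <- rule[[pad]]
  if (is.null(nb) || length(nb) == 0) {
    stop(sprintf("empty neighbour set for pad %s", pad))
  }
  efs <- field_table$ef_mV_per_mm[field_table$electrode %in% nb &
                                    field_table$depth == "Z0"]
  if (length(efs) != length(nb) || anyNA(efs)) {
    stop(sprintf("surface field missing for some neighbours of %s", pad))
  }
  mean(efs)
}

#' Build the field table for one condition
#'
#' Joins the recording grid with the (imputed) voltages and computes the
#' field estimate EF = dV / distance at every site. Sites where the distance
#' is zero (the reference pad's own surface position) get their field imputed
#' as the mean of the neighbours' surface fields and are flagged
#' `"imputed_ef"`; pad voltages imputed by neighbour averaging are flagged
#' `"imputed_dv"`; everything else is `"measured"`.
#'
#' @param recordings A [voltage_recordings()] set.
#' @param layout A [montage_layout()]; its diameter must match the
#'   recording metadata's `diameter_mm` within 0.1 mm when both are present.
#' @param rule Imputation rule; defaults to [default_neighbor_rule()] for the
#'   set's pads on `layout`.
#' @param deep_projection Passed to [recording_grid()].
#' @param strict Logical; if `TRUE`, surface field estimates at non-reference
#'   pad sites are set to 0 rather than recomputed (some published tables
#'   print a 0 placeholder there). Default `FALSE`.
#' @return A data.frame of class `field_table` with 84 rows and columns
#'   `electrode`, `depth`, `x_mm`, `y_mm`, `z_mm`, `distance_mm`,
#'   `delta_v_mV`, `status`, `ef_mV_per_mm`; condition, reference, pads and
#'   sphere radius are carried as attributes.
#' @export
build_field_table <- function(recordings, layout = NULL,
                              rule = NULL,
                              deep_projection = c("mirror", "antipode"),
                              strict = FALSE) {
  stopifnot(inherits(recordings, "voltage_recordings"))
  deep_projection <- match.arg(deep_projection)
  if (is.null(layout)) {
    dia <- recordings$meta$diameter_mm
    if (is.null(dia)) stop("no layout given and no diameter_mm in metadata")
    layout <- montage_layout(dia)
  }
  dia_meta <- recordings$meta$diameter_mm
  if (!is.null(dia_meta) && abs(dia_meta - layout$sphere$diameter) > 0.1) {
    stop(sprintf("metadata diameter (%.2f mm) does not match layout (%.2f mm)",
                 dia_meta, layout$sphere$diameter))
  }
  if (!setequal(unique(recordings$delta_v$electrode), layout$angles$label)) {
    stop("recordings and layout do not share the same electrode labels")
  }
  if (is.null(rule)) rule <- default_neighbor_rule(recordings$pads, layout)
  imp <- impute_pad_voltages(recordings, rule)
  grid <- recording_grid(layout, recordings$reference, deep_projection)
  stopifnot(identical(grid$electrode, imp$delta_v$electrode),
            identical(grid$depth, imp$delta_v$depth))
  tab <- grid
  tab$delta_v_mV <- imp$delta_v$delta_v_mV
  tab$status <- ifelse(imp$delta_v$imputed, "imputed_dv", "measured")
  tab$ef_mV_per_mm <- compute_ef(tab$delta_v_mV, tab$distance_mm)

  at_origin <- which(tab$distance_mm == 0)
  for (i in at_origin) {
    tab$ef_mV_per_mm[i] <- impute_reference_surface(tab, tab$electrode[i], rule)
    tab$status[i] <- "imputed_ef"
  }
  if (strict) {
    zero_out <- tab$electrode %in% setdiff(recordings$pads, recordings$reference) &
      tab$depth == "Z0"
    tab$ef_mV_per_mm[zero_out] <- 0
  }
  class(tab) <- c("field_table", "data.frame")
  attr(tab, "condition") <- recordings$condition
  attr(tab, "reference") <- recordings$reference
  attr(tab, "pads") <- recordings$pads
  attr(tab, "hemisphere") <- stats::setNames(layout$angles$hemisphere,
                                             layout$angles$label)
  tab
}

#' @export
print.field_table <- function(x, digits = 2, ...) {
  cat(sprintf("Field table, condition %s (reference %s, pads {%s})\n",
              attr(x, "condition"), attr(x, "reference"),
              paste(attr(x, "pads"), collapse = ", ")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(utils::head(y, 8))
  cat(sprintf("... %d rows total\n", nrow(y)))
  invisible(x)
}

#' Per-depth summary of a field table
#'
#' For each depth and quantity (voltage difference and field estimate)
#' reports the extreme values with the electrodes attaining them, the mean,
#' and hemispheric means (left/right of the mid-sagittal plane, midline
#' electrodes excluded).
#'
#' @param field_table A [build_field_table()] result.
#' @param include_imputed Logical; if `FALSE`, extremes and means are taken
#'   over measured sites only.
#' @return A data.frame with one row per (depth, quantity) and columns
#'   `depth`, `quantity`, `min`, `argmin`, `max`, `argmax`, `mean`,
#'   `mean_left`, `mean_right`.
#' @export
summarize_field_table <- function(field_table, include_imputed = TRUE) {
  stopifnot(inherits(field_table, "field_table"))
  hemi <- attr(field_table, "hemisphere")
  out <- list()
  for (d in depth_levels()) {
    sub <- field_table[field_table$depth == d, ]
    if (!include_imputed) sub <- sub[sub$status == "measured", ]
    for (q in c("delta_v_mV", "ef_mV_per_mm")) {
      v <- sub[[q]]
      h <- hemi[sub$electrode]
      out[[length(out) + 1]] <- data.frame(
        depth = d,
        quantity = if (q == "delta_v_mV") "delta_v" else "ef",
        min = min(v), argmin = sub$electrode[which.min(v)],
        max = max(v), argmax = sub$electrode[which.max(v)],
        mean = mean(v),
        mean_left = mean(v[h == "left"]),
        mean_right = mean(v[h == "right"]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
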