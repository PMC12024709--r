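# Reading and writing recording sets and field tables, bundled fixtures,
# and the end-to-end pipeline runner.

#' Path to a bundled example file
#'
#' The package ships the published Condition A recording set (the measured
#' voltage-difference column only; coordinates, distances and fields are
#' always recomputed) together with its metadata sidecar.
#'
#' @param file `"condition_a_recordings.csv"` or `"condition_a_meta.json"`;
#'   with no argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
#' @examples
#' phantom_example()
phantom_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "phantomEF")))
  }
  path <- system.file("extdata", file, package = "phantomEF")
  if (path == "") stop(sprintf("no bundled file '%s'", file))
  path
}

#' Load a voltage recording set from CSV + metadata JSON
#'
#' The CSV has columns `electrode,depth,delta_v_mV` with the literal token
#' `NR` (not recordable) at pad-covered sites; the JSON sidecar carries
#' `condition`, `reference`, `pads`, `diameter_mm` and optional phantom
#' metadata (`weight_kg`, `temperature_C`, `resistance_kohm`). All
#' validation failures are reported together.
#'
#' @param csv Path to the recordings CSV.
#' @param meta Path to the metadata JSON.
#' @return A [voltage_recordings()] set.
#' @export
#' @examples
#' rec <- load_recordings(phantom_example("condition_a_recordings.csv"),
#'                        phantom_example("condition_a_meta.json"))
load_recordings <- function(csv, meta) {
  if (!file.exists(csv)) stop(sprintf("recordings file not found: %s", csv))
  if (!file.exists(meta)) stop(sprintf("metadata file not found: %s", meta))
  raw <- utils::read.csv(csv, colClasses = "character")
  need <- c("electrode", "depth", "delta_v_mV")
  if (!all(need %in% names(raw))) {
    stop("recordings CSV needs columns electrode, depth, delta_v_mV")
  }
  md <- jsonlite::read_json(meta, simplifyVector = TRUE)
  for (f in c("condition", "reference", "pads", "diameter_mm")) {
    if (is.null(md[[f]])) stop(sprintf("metadata is missing field '%s'", f))
  }
  v <- trimws(raw$delta_v_mV)
  is_nr <- toupper(v) %in% c("NR", "N.R.", "NA", "")
  num <- suppressWarnings(as.numeric(v))
  if (any(!is_nr & is.na(num))) {
    stop("non-numeric voltage value(s): ",
         paste(unique(v[!is_nr & is.na(num)]), collapse = ", "))
  }
  tab <- data.frame(electrode = trimws(raw$electrode),
                    depth = trimws(raw$depth),
                    delta_v_mV = ifelse(is_nr, NA_real_, num),
                    stringsAsFactors = FALSE)
  nr_electrodes <- unique(tab$electrode[is_nr])
  extra_nr <- setdiff(nr_electrodes, md$pads)
  if (length(extra_nr)) {
    stop("NR marker at electrode(s) not declared as pads in the metadata: ",
         paste(extra_nr, collapse = ", "))
  }
  voltage_recordings(tab, condition = md$condition, reference = md$reference,
                     pads = md$pads,
                     meta = md[setdiff(names(md),
                                       c("condition", "reference", "pads"))])
}

#' Write a recording set to CSV + metadata JSON
#'
#' Inverse of [load_recordings()]: pad sites are written as `NR`.
#'
#' @param recordings A [voltage_recordings()] set.
#' @param csv,meta Output paths.
#' @return Invisibly, the CSV path.
#' @export
write_recordings <- function(recordings, csv, meta) {
  stopifnot(inherits(recordings, "voltage_recordings"))
  dv <- recordings$delta_v[, c("electrode", "depth", "delta_v_mV")]
  out <- data.frame(electrode = dv$electrode, depth = dv$depth,
                    delta_v_mV = ifelse(is.na(dv$delta_v_mV), "NR",
                                        format(dv$delta_v_mV, trim = TRUE,
                                               scientific = FALSE)))
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  md <- c(list(condition = recordings$condition,
               reference = recordings$reference,
               pads = recordings$pads), recordings$meta)
  jsonlite::write_json(md, meta, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(csv)
}

#' Write a field table to CSV
#'
#' Numeric columns are rounded to two decimals on export (presentation
#' style); keep the in-memory table for exact downstream arithmetic.
#'
#' @param table A `field_table`.
#' @param path Output CSV path.
#' @param digits Decimal places for export.
#' @return Invisibly, the path.
#' @export
write_field_table <- function(table, path, digits = 2) {
  stopifnot(inherits(table, "field_table"))
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a recording set, imputes pad sites, builds the field
#' table, summarises it, and writes the results bundle: `field_table.csv`,
#' `summary.json` and optionally topographic maps.
#'
#' @param recordings_csv,meta_json Paths to a measured recording set; omit
#'   (leave `NULL`) to simulate instead.
#' @param condition Montage preset (`"A"`, `"B"`, `"C"`) used when
#'   simulating.
#' @param diameter_mm Sphere diameter used when simulating (mm).
#' @param seed,noise_cv Simulation noise controls.
#' @param neighbors Optional named list overriding the pad imputation rule.
#' @param deep_projection `"mirror"` or `"antipode"` (see
#'   [depth_position()]).
#' @param strict Passed to [build_field_table()].
#' @param out_dir Output directory (created if needed).
#' @param plots Logical: also render dV and EF superior-view maps.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `recordings`, `field_table`, `summary` and
#'   `files` (paths written).
#' @export
run_pipeline <- function(recordings_csv = NULL, meta_json = NULL,
                         condition = NULL, diameter_mm = 240.80,
                         seed = 1L, noise_cv = 0.05,
                         neighbors = NULL,
                         deep_projection = c("mirror", "antipode"),
                         strict = FALSE, out_dir = tempfile("phantomEF-"),
                         plots = FALSE, quiet = FALSE) {
  deep_projection <- match.arg(deep_projection)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(recordings_csv)) {
    say("loading recordings from %s", recordings_csv)
    rec <- stage("load", load_recordings(recordings_csv, meta_json))
    layout <- stage("load", montage_layout(rec$meta$diameter_mm))
  } else {
    if (is.null(condition) || !condition %in% c("A", "B", "C")) {
      stop("[config] simulation needs `condition` of \"A\", \"B\" or \"C\"")
    }
    say("simulating condition %s (diameter %.2f mm, seed %s)",
        condition, diameter_mm, as.character(seed))
    layout <- montage_layout(diameter_mm)
    rec <- stage("simulate", simulate_recordings(
      stimulus_montage(condition), layout,
      forward_model_params(noise_cv = noise_cv, seed = seed)))
  }
  rule <- if (is.null(neighbors)) default_neighbor_rule(rec$pads, layout)
          else neighbors
  say("building field table (reference %s, pads {%s})",
      rec$reference, paste(rec$pads, collapse = ", "))
  tab <- stage("field_table",
               build_field_table(rec, layout, rule,
                                 deep_projection = deep_projection,
                                 strict = strict))
  summ <- stage("summary", summarize_field_table(tab))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(field_table = file.path(out_dir, "field_table.csv"),
             summary = file.path(out_dir, "summary.json"))
  write_field_table(tab, files[["field_table"]])
  jsonlite::write_json(summ, files[["summary"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) {
    for (q in c("dv", "ef")) {
      f <- file.path(out_dir, sprintf("map_%s_superior.png", q))
      stage("plot", render_map(tab, q, "all", "superior", out = f))
      files[paste0("map_", q)] <- f
    }
  }
  say("wrote %d file(s) to %s", length(files), out_dir)
  invisible(list(recordings = rec, field_table = tab, summary = summ,
                 files = files))
}
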