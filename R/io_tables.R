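#' @keywords internal
"_PACKAGE"

#' Names of the eleven odorant series
#'
#' Canonical order of the odorant series used throughout the package:
#' chemical, fruity/ripe fruit, green fruit, green, floral, creamy, citrus,
#' herbaceous, toasty/smoky, honey, waxy. Series are addressed by their
#' integer id (1--11) in threshold maps and by these names in outputs.
#'
#' @return Character vector of length 11.
#' @export
odorant_series_names <- function() {
  c("chemical", "fruity/ripe fruit", "green fruit", "green", "floral",
    "creamy", "citrus", "herbaceous", "toasty/smoky", "honey", "waxy")
}

#' Number of odorant series
#' @keywords internal
N_SERIES <- 11L

# internal: stop with a classed condition so callers/tests can discriminate
vs_stop <- function(msg, class) {
  stop(structure(class = c(class, "vinosense_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a volatile-compound quantification table
#'
#' Reads a compound-by-sample concentration table from CSV. Two layouts are
#' supported: `wide` (first column `compound`, remaining columns one per
#' sample) and `long` (columns `compound`, `sample`, `value`). Concentrations
#' must be non-negative finite numbers; non-numeric cells are reported with
#' their row/column coordinates.
#'
#' @param path Path to a CSV file (comma separated, header row, `.` decimal).
#' @param layout Either `"wide"` or `"long"`.
#' @param units Unit string recorded on the returned table (default `"mg/L"`).
#' @return A `volatile_table`: list with `compounds` (character),
#'   `samples` (character), `conc` (compound x sample numeric matrix) and
#'   `units`.
#' @export
load_volatile_table <- function(path, layout = c("wide", "long"),
                                units = "mg/L") {
  layout <- match.arg(layout)
  if (!file.exists(path))
    vs_stop(sprintf("file not found: %s", path), "vinosense_io_error")
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L || is.null(names(raw)) || any(!nzchar(names(raw))))
    vs_stop("missing or incomplete header row", "vinosense_format_error")

  if (layout == "wide") {
    if (names(raw)[1L] != "compound")
      vs_stop("wide layout requires first column 'compound'",
              "vinosense_format_error")
    compounds <- raw[[1L]]
    samples <- names(raw)[-1L]
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    conc <- parse_numeric_cells(cells, compounds, samples)
  } else {
    need <- c("compound", "sample", "value")
    if (!all(need %in% names(raw)))
      vs_stop("long layout requires columns compound, sample, value",
              "vinosense_format_error")
    compounds <- unique(raw$compound)
    samples <- unique(raw$sample)
    cells <- matrix(NA_character_, length(compounds), length(samples),
                    dimnames = list(compounds, samples))
    cells[cbind(match(raw$compound, compounds),
                match(raw$sample, samples))] <- raw$value
    if (anyNA(cells))
      vs_stop("long table does not cover every compound x sample pair",
              "vinosense_validation_error")
    conc <- parse_numeric_cells(cells, compounds, samples)
  }

  new_volatile_table(compounds, samples, conc, units)
}

# parse a character matrix of cells, reporting bad coordinates
parse_numeric_cells <- function(cells, compounds, samples) {
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    coords <- apply(bad, 1L, function(ij)
      sprintf("(%s, %s) = '%s'", compounds[ij[1L]], samples[ij[2L]],
              cells[ij[1L], ij[2L]]))
    vs_stop(paste0("unparseable numeric cells: ",
                   paste(coords, collapse = "; ")),
            "vinosense_format_error")
  }
  dimnames(num) <- list(compounds, samples)
  num
}

new_volatile_table <- function(compounds, samples, conc, units) {
  if (anyDuplicated(compounds))
    vs_stop("duplicate compound identifiers", "vinosense_validation_error")
  if (any(conc < 0))
    vs_stop("negative concentrations", "vinosense_validation_error")
  structure(list(compounds = compounds, samples = samples,
                 conc = conc, units = units),
            class = "volatile_table")
}

#' @export
print.volatile_table <- function(x, ...) {
  cat(sprintf("volatile_table: %d compounds x %d samples [%s]\n",
              length(x$compounds), length(x$samples), x$units))
  invisible(x)
}

#' Read an odor-perception-threshold / odorant-series map
#'
#' The CSV must have columns `compound`, `opt` (odor perception threshold,
#' same units as the concentration table), `series_ids` (semicolon- or
#' comma-separated integers in 1..11) and `descriptor`.
#'
#' @param path Path to a CSV file.
#' @param units Unit string of the thresholds (default `"mg/L"`).
#' @return A `threshold_map`: data frame with columns `compound`, `opt`,
#'   `descriptor` and a list-column `series_ids` of integer vectors.
#' @export
load_threshold_map <- function(path, units = "mg/L") {
  if (!file.exists(path))
    vs_stop(sprintf("file not found: %s", path), "vinosense_io_error")
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  need <- c("compound", "opt", "series_ids", "descriptor")
  if (!all(need %in% names(raw)))
    vs_stop("threshold map requires columns compound, opt, series_ids, descriptor",
            "vinosense_format_error")
  opt <- suppressWarnings(as.numeric(raw$opt))
  if (anyNA(opt) || any(opt <= 0))
    vs_stop("every OPT must be a number > 0", "vinosense_validation_error")
  series_ids <- parse_series_ids(raw$series_ids, raw$compound)
  out <- data.frame(compound = raw$compound, opt = opt,
                    descriptor = raw$descriptor,
                    stringsAsFactors = FALSE)
  out$series_ids <- series_ids
  attr(out, "units") <- units
  class(out) <- c("threshold_map", "data.frame")
  out
}

parse_series_ids <- function(txt, compounds) {
  ids <- lapply(strsplit(txt, "[;,]"), function(x) {
    v <- suppressWarnings(as.integer(trimws(x)))
    v[!is.na(v)]
  })
  for (i in seq_along(ids)) {
    v <- ids[[i]]
    if (length(v) == 0L)
      vs_stop(sprintf("compound '%s' has no series id", compounds[i]),
              "vinosense_validation_error")
    if (any(v < 1L | v > N_SERIES))
      vs_stop(sprintf("compound '%s': series id outside 1..%d",
                      compounds[i], N_SERIES),
              "vinosense_validation_error")
  }
  ids
}

#' Load the packaged five-wine OAV fixture
#'
#' Returns the packaged reference dataset of mean odor activity values for
#' 57 volatile compounds across five young white wines produced from the
#' same grape must with different fermentation strategies: spontaneous
#' fermentation (WY), *Saccharomyces cerevisiae* (SC), *Metschnikowia
#' pulcherrima* (MP), and *Lachancea thermotolerans* free (LT) and
#' immobilized in biocapsules (BC). Each compound carries its odorant-series
#' assignment (ids 1..11, see [odorant_series_names()]).
#'
#' @return An `oav_table` (see [oav_table()]): 57 compounds x 5 wines of
#'   OAV means, with per-compound `series_ids`.
#' @export
load_fivewine_fixture <- function() {
  path <- system.file("extdata", "table2_oav.csv", package = "vinosense",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  wines <- c("WY", "SC", "MP", "LT", "BC")
  oav <- parse_numeric_cells(as.matrix(raw[, wines]), raw$compound, wines)
  oav_table(oav, parse_series_ids(raw$series_ids, raw$compound))
}

#' Load the packaged synthetic-OPT threshold map
#'
#' Series assignments and descriptors are those of the packaged five-wine
#' dataset; the OPT column holds synthetic placeholder values (real
#' perception thresholds for this matrix are not redistributable), so the
#' fixture is suitable for exercising parsing and series mapping, not for
#' computing real OAVs.
#'
#' @return A `threshold_map` with 57 entries.
#' @export
load_threshold_fixture <- function() {
  load_threshold_map(system.file("extdata", "threshold_map_synthetic_opt.csv",
                                 package = "vinosense", mustWork = TRUE))
}

#' Extract steady-state frequency shifts from raw sensor traces
#'
#' A quartz-microbalance e-nose feature is the resonant frequency shift
#' between two steady states: clean-air baseline and headspace exposure.
#' For each sensor trace, `steady_state_shift` computes
#' \deqn{\Delta f = \mathrm{mean}(f, \mathrm{response\ window}) -
#'       \mathrm{mean}(f, \mathrm{baseline\ window})}
#' Sign is preserved: mass adsorption lowers the resonant frequency, so
#' adsorption yields a negative shift.
#'
#' @param traces A list, one element per sensor, each a data frame with
#'   columns `time` (seconds) and `freq` (Hz).
#' @param baseline_window Numeric length-2 vector, `[start, end]` seconds.
#' @param response_window Numeric length-2 vector, `[start, end]` seconds;
#'   must not overlap the baseline window.
#' @return Named numeric vector of per-sensor shifts (Hz).
#' @export
steady_state_shift <- function(traces, baseline_window, response_window) {
  check_window <- function(w, name) {
    if (length(w) != 2L || !all(is.finite(w)) || w[2L] <= w[1L])
      vs_stop(sprintf("invalid %s window", name), "vinosense_validation_error")
  }
  check_window(baseline_window, "baseline")
  check_window(response_window, "response")
  if (max(baseline_window[1L], response_window[1L]) <
      min(baseline_window[2L], response_window[2L]))
    vs_stop("baseline and response windows overlap",
            "vinosense_validation_error")
  win_mean <- function(tr, w, sensor, name) {
    sel <- tr$time >= w[1L] & tr$time <= w[2L]
    if (sum(sel) < 2L)
      vs_stop(sprintf("sensor %s: fewer than 2 points in %s window",
                      sensor, name), "vinosense_validation_error")
    f <- tr$freq[sel]
    if (any(!is.finite(f)))
      vs_stop(sprintf("sensor %s: non-finite frequency samples", sensor),
              "vinosense_validation_error")
    mean(f)
  }
  if (is.null(names(traces)))
    names(traces) <- sprintf("QMB%d", seq_along(traces))
  vapply(names(traces), function(s) {
    win_mean(traces[[s]], response_window, s, "response") -
      win_mean(traces[[s]], baseline_window, s, "baseline")
  }, numeric(1L))
}

#' Read an e-nose sensor matrix
#'
#' CSV with columns `sample`, `class`, then one column per sensor
#' (`QMB1`..`QMB12` by default).
#'
#' @param path Path to a CSV file.
#' @param n_sensors Expected number of sensor columns (default 12).
#' @return A `sensor_matrix`: list with `samples`, `classes` (factor) and
#'   `delta_f` (sample x sensor numeric matrix).
#' @export
load_sensor_matrix <- function(path, n_sensors = 12L) {
  if (!file.exists(path))
    vs_stop(sprintf("file not found: %s", path), "vinosense_io_error")
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (!all(c("sample", "class") %in% names(raw)))
    vs_stop("sensor matrix requires columns sample, class",
            "vinosense_format_error")
  sensor_cols <- setdiff(names(raw), c("sample", "class"))
  if (length(sensor_cols) != n_sensors)
    vs_stop(sprintf("expected %d sensor columns, found %d",
                    n_sensors, length(sensor_cols)),
            "vinosense_validation_error")
  delta_f <- parse_numeric_cells(as.matrix(raw[, sensor_cols, drop = FALSE]),
                                 raw$sample, sensor_cols)
  sensor_matrix(delta_f, raw$class, samples = raw$sample)
}

#' Construct a sensor matrix object
#'
#' @param delta_f Sample x sensor numeric matrix of frequency shifts (Hz).
#' @param classes Class label per sample.
#' @param samples Optional sample identifiers.
#' @return A `sensor_matrix`.
#' @export
sensor_matrix <- function(delta_f, classes, samples = NULL) {
  delta_f <- as.matrix(delta_f)
  if (any(!is.finite(delta_f)))
    vs_stop("non-finite sensor values", "vinosense_validation_error")
  if (length(classes) != nrow(delta_f))
    vs_stop("one class label per sample required",
            "vinosense_validation_error")
  if (is.null(samples)) samples <- rownames(delta_f)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(delta_f)))
  rownames(delta_f) <- samples
  if (is.null(colnames(delta_f)))
    colnames(delta_f) <- sprintf("QMB%d", seq_len(ncol(delta_f)))
  structure(list(samples = samples,
                 classes = factor(classes, levels = unique(classes)),
                 delta_f = delta_f),
            class = "sensor_matrix")
}

#' @export
print.sensor_matrix <- function(x, ...) {
  cat(sprintf("sensor_matrix: %d samples x %d sensors, %d classes\n",
              nrow(x$delta_f), ncol(x$delta_f), nlevels(x$classes)))
  invisible(x)
}

#' Write the standard report tables for a result bundle
#'
#' Writes deterministic CSV files (series profile, series summary, VIP
#' vector, confusion matrices, per-response regression metrics, correlation
#' map -- whichever are present in `results`) plus a JSON run-log recording
#' the configuration, seed and package version. Rerunning with identical
#' results produces byte-identical files.
#'
#' @param results Named list of result tables; at least one element required.
#'   Recognised names: `series_profile`, `series_summary`, `active_compounds`,
#'   `vip`, `confusion_cal`, `confusion_cv`, `metrics`, `correlation`.
#' @param out_dir Output directory (created if needed).
#' @param config List echoed into the run-log.
#' @param seed Seed echoed into the run-log.
#' @return Invisibly, character vector of files written.
#' @export
write_report_tables <- function(results, out_dir, config = list(),
                                seed = NA_integer_) {
  if (length(results) == 0L)
    vs_stop("empty result set: nothing to write", "vinosense_validation_error")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    vs_stop(sprintf("cannot create output directory: %s", out_dir),
            "vinosense_io_error")
  written <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    df <- as_report_df(obj, nm)
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    written <- c(written, f)
  }
  log_file <- file.path(out_dir, "run_log.json")
  log <- list(package = "vinosense",
              version = as.character(utils::packageVersion("vinosense")),
              seed = seed, config = config,
              outputs = basename(written))
  jsonlite::write_json(log, log_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, log_file)
  invisible(written)
}

# coerce result objects to plain data frames with stable column order
as_report_df <- function(obj, name) {
  if (is.data.frame(obj)) return(obj)
  if (is.matrix(obj))
    return(data.frame(id = rownames(obj) %||% seq_len(nrow(obj)),
                      as.data.frame(obj, check.names = FALSE),
                      check.names = FALSE))
  if (is.atomic(obj))
    return(data.frame(id = names(obj) %||% seq_along(obj),
                      value = as.vector(obj), check.names = FALSE))
  vs_stop(sprintf("cannot serialise result '%s'", name),
          "vinosense_validation_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# render doubles with enough digits to round-trip exactly through CSV
fmt_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write a sensor matrix to CSV in the standard layout
#' @param x A `sensor_matrix`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sensor_matrix <- function(x, path) {
  df <- data.frame(sample = x$samples, class = as.character(x$classes),
                   as.data.frame(x$delta_f, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(fmt_full(df), path, row.names = FALSE)
  invisible(path)
}

#' Write a volatile table to CSV (wide layout)
#' @param x A `volatile_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_volatile_table <- function(x, path) {
  df <- data.frame(compound = x$compounds,
                   as.data.frame(x$conc, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(fmt_full(df), path, row.names = FALSE)
  invisible(path)
}
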