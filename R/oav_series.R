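#' Compute odor activity values
#'
#' The odor activity value (OAV) of a compound is its concentration divided
#' by its odor perception threshold (OPT); a dimensionless measure of how
#' far a volatile stands above (OAV > 1) or below its detectability limit.
#'
#' @param conc Non-negative concentration(s).
#' @param opt Positive odor perception threshold(s), same units as `conc`.
#' @param conc_units,opt_units Optional unit strings; if both are given they
#'   must match.
#' @return `conc / opt`, dimensionless.
#' @export
compute_oav <- function(conc, opt, conc_units = NULL, opt_units = NULL) {
  if (!is.null(conc_units) && !is.null(opt_units) &&
      !identical(conc_units, opt_units))
    vs_stop(sprintf("unit mismatch: concentrations in %s, thresholds in %s",
                    conc_units, opt_units), "vinosense_validation_error")
  if (any(!is.finite(opt)) || any(opt <= 0))
    vs_stop("every OPT must be finite and > 0", "vinosense_validation_error")
  if (any(!is.finite(conc)) || any(conc < 0))
    vs_stop("concentrations must be finite and >= 0",
            "vinosense_validation_error")
  conc / opt
}

#' Construct an OAV table
#'
#' @param oav Compound x sample numeric matrix of odor activity values
#'   (dimnames required or supplied via `compounds`/`samples`).
#' @param series_ids List (one per compound) of integer odorant-series ids
#'   in 1..11.
#' @param compounds,samples Optional identifier vectors overriding dimnames.
#' @return An `oav_table` object.
#' @export
oav_table <- function(oav, series_ids, compounds = NULL, samples = NULL) {
  oav <- as.matrix(oav)
  if (!is.null(compounds)) rownames(oav) <- compounds
  if (!is.null(samples)) colnames(oav) <- samples
  if (is.null(rownames(oav)) || is.null(colnames(oav)))
    vs_stop("oav matrix needs compound and sample identifiers",
            "vinosense_validation_error")
  if (any(!is.finite(oav)) || any(oav < 0))
    vs_stop("OAVs must be finite and >= 0", "vinosense_validation_error")
  if (anyDuplicated(rownames(oav)))
    vs_stop("duplicate compound identifiers", "vinosense_validation_error")
  if (length(series_ids) != nrow(oav))
    vs_stop("one series_ids entry per compound required",
            "vinosense_validation_error")
  series_ids <- lapply(series_ids, function(v) {
    v <- as.integer(v)
    if (length(v) == 0L || any(v < 1L | v > N_SERIES))
      vs_stop("series ids must be a non-empty subset of 1..11",
              "vinosense_validation_error")
    sort(unique(v))
  })
  names(series_ids) <- rownames(oav)
  structure(list(oav = oav, series_ids = series_ids),
            class = "oav_table")
}

#' Build an OAV table from concentrations and a threshold map
#'
#' @param volatiles A `volatile_table` from [load_volatile_table()].
#' @param map A `threshold_map` from [load_threshold_map()].
#' @param exclude_unmapped Compounds in `volatiles` but not in `map` abort
#'   by default; list them here to drop them instead (a warning names each
#'   exclusion).
#' @return An `oav_table`.
#' @export
oav_from_concentrations <- function(volatiles, map,
                                    exclude_unmapped = character(0)) {
  missing <- setdiff(volatiles$compounds, map$compound)
  to_drop <- intersect(missing, exclude_unmapped)
  hard_missing <- setdiff(missing, exclude_unmapped)
  if (length(hard_missing) > 0L)
    vs_stop(paste0("compounds without threshold-map entry: ",
                   paste(hard_missing, collapse = ", ")),
            "vinosense_validation_error")
  if (length(to_drop) > 0L)
    warning(sprintf("excluding unmapped compounds: %s",
                    paste(to_drop, collapse = ", ")))
  keep <- setdiff(volatiles$compounds, to_drop)
  conc <- volatiles$conc[keep, , drop = FALSE]
  idx <- match(keep, map$compound)
  oav <- compute_oav(conc, matrix(map$opt[idx], nrow(conc), ncol(conc)),
                     conc_units = volatiles$units,
                     opt_units = attr(map, "units"))
  oav_table(oav, map$series_ids[idx])
}

#' @export
print.oav_table <- function(x, ...) {
  cat(sprintf("oav_table: %d compounds x %d samples\n",
              nrow(x$oav), ncol(x$oav)))
  invisible(x)
}

#' Flag aroma-active compounds
#'
#' A cell is aroma-active when its OAV strictly exceeds the activity
#' threshold (default 0.2). Returns both the per-cell flags and the set of
#' compounds active in at least one sample.
#'
#' @param table An `oav_table`.
#' @param threshold Activity threshold, strict inequality (default 0.2).
#' @return List with `flags` (logical compound x sample matrix),
#'   `active_compounds` (character) and `n_active` (integer count).
#' @export
flag_active <- function(table, threshold = 0.2) {
  stopifnot(inherits(table, "oav_table"))
  if (!is.finite(threshold) || threshold <= 0)
    vs_stop("activity threshold must be > 0", "vinosense_validation_error")
  flags <- table$oav > threshold
  active <- rownames(table$oav)[apply(flags, 1L, any)]
  list(flags = flags, active_compounds = active,
       n_active = length(active), threshold = threshold)
}

#' Aggregate OAVs into odorant-series scores
#'
#' The score of odorant series *k* in sample *s* is the sum of the OAVs of
#' all compounds whose series set contains *k*. A compound assigned to
#' several series contributes its full OAV to each of them (no splitting).
#'
#' @param table An `oav_table` whose compounds already carry series ids, or
#'   a `volatile_table` (then `map` is required).
#' @param map A `threshold_map`; required when `table` is a
#'   `volatile_table`, optional override otherwise.
#' @param exclude_unmapped Passed to [oav_from_concentrations()].
#' @return A sample x 11 numeric matrix of class `series_profile`, columns
#'   named after [odorant_series_names()].
#' @export
series_profile <- function(table, map = NULL,
                           exclude_unmapped = character(0)) {
  if (inherits(table, "volatile_table")) {
    if (is.null(map))
      vs_stop("a threshold map is required to score a volatile_table",
              "vinosense_validation_error")
    table <- oav_from_concentrations(table, map, exclude_unmapped)
  }
  stopifnot(inherits(table, "oav_table"))
  # membership matrix: compound x series, 1 where the compound belongs
  memb <- matrix(0, nrow(table$oav), N_SERIES)
  for (i in seq_len(nrow(table$oav)))
    memb[i, table$series_ids[[i]]] <- 1
  prof <- t(table$oav) %*% memb
  colnames(prof) <- odorant_series_names()
  rownames(prof) <- colnames(table$oav)
  class(prof) <- c("series_profile", class(prof))
  prof
}

#' Summarise a series profile across samples
#'
#' Per-series mean, minimum, maximum and sample standard deviation
#' (denominator n - 1) over samples.
#'
#' @param profile A `series_profile` (sample x series matrix).
#' @return Data frame with columns `series`, `mean`, `min`, `max`, `sd`.
#' @export
series_summary <- function(profile) {
  profile <- unclass(profile)
  if (nrow(profile) < 2L)
    vs_stop("at least 2 samples required for a series summary (SD undefined)",
            "vinosense_validation_error")
  data.frame(series = colnames(profile),
             mean = apply(profile, 2L, mean),
             min = apply(profile, 2L, min),
             max = apply(profile, 2L, max),
             sd = apply(profile, 2L, stats::sd),
             row.names = NULL)
}
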