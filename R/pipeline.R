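#' Build a pipeline run configuration
#'
#' Exactly one input source must be chosen: CSV paths (`volatiles` +
#' `thresholds` and/or `sensors`), the packaged five-wine OAV dataset
#' (`packaged = TRUE`), or the synthetic generator (`synthetic = TRUE` with
#' a [sim_config()]). `replicate_paper = TRUE` pins the replication
#' profile: 3 PLS-DA latent variables, 5 PCR components, venetian blind
#' thickness 1, five classes of six replicates.
#'
#' @param volatiles,thresholds,sensors Input CSV paths (or `NULL`).
#' @param packaged Use the packaged five-wine OAV dataset for scoring.
#' @param synthetic Use the synthetic generator.
#' @param sim A [sim_config()] when `synthetic = TRUE`.
#' @param activity_threshold OAV activity threshold (strict `>`, default 0.2).
#' @param plsda_lvs PLS-DA latent variables; `NULL` = choose from the
#'   cross-validated error curve.
#' @param pcr_pcs PCR principal components; `NULL` = choose from the curve.
#' @param cv_splits Venetian splits; `NULL` = `min(n, 10)`.
#' @param blind_thickness Venetian blind thickness (default 1).
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Integer seed for all stochastic stages.
#' @param replicate_paper Pin the replication profile described above.
#' @return A `run_config` list.
#' @export
run_config <- function(volatiles = NULL, thresholds = NULL, sensors = NULL,
                       packaged = FALSE, synthetic = FALSE, sim = NULL,
                       activity_threshold = 0.2,
                       plsda_lvs = NULL, pcr_pcs = NULL,
                       cv_splits = NULL, blind_thickness = 1L,
                       out_dir = NULL, seed = NULL,
                       replicate_paper = FALSE) {
  n_sources <- (!is.null(volatiles) || !is.null(sensors)) + packaged + synthetic
  if (n_sources != 1L)
    vs_stop("exactly one input source required: files, packaged, or synthetic",
            "vinosense_validation_error")
  if (synthetic && is.null(sim)) sim <- sim_config(seed = seed)
  if (replicate_paper) {
    plsda_lvs <- 3L
    pcr_pcs <- 5L
    blind_thickness <- 1L
  }
  structure(list(volatiles = volatiles, thresholds = thresholds,
                 sensors = sensors, packaged = packaged,
                 synthetic = synthetic, sim = sim,
                 activity_threshold = activity_threshold,
                 plsda_lvs = plsda_lvs, pcr_pcs = pcr_pcs,
                 cv_splits = cv_splits,
                 blind_thickness = as.integer(blind_thickness),
                 out_dir = out_dir, seed = seed,
                 replicate_paper = replicate_paper),
            class = "run_config")
}

# resolve the input data for a config (memoised per call chain)
resolve_inputs <- function(cfg) {
  if (cfg$synthetic) {
    ds <- generate_dataset(cfg$sim)
    list(oav = NULL, profile = ds$profile, classes = ds$classes,
         sensors = ds$sensors, dataset = ds)
  } else if (cfg$packaged) {
    oav <- load_fivewine_fixture()
    list(oav = oav, profile = series_profile(oav), classes = NULL,
         sensors = NULL, dataset = NULL)
  } else {
    oav <- NULL; profile <- NULL; sensors <- NULL
    if (!is.null(cfg$volatiles)) {
      vol <- load_volatile_table(cfg$volatiles)
      map <- load_threshold_map(cfg$thresholds)
      oav <- oav_from_concentrations(vol, map)
      profile <- series_profile(oav)
    }
    if (!is.null(cfg$sensors)) sensors <- load_sensor_matrix(cfg$sensors)
    list(oav = oav, profile = profile,
         classes = if (!is.null(sensors)) sensors$classes else NULL,
         sensors = sensors, dataset = NULL)
  }
}

cfg_splits <- function(cfg, n) {
  if (!is.null(cfg$cv_splits)) cfg$cv_splits else min(n, 10L)
}

#' Run the aroma-scoring stage
#'
#' Computes the odorant-series profile, its per-series summary (mean, min,
#' max, SD over samples) and, when compound-level OAVs are available, the
#' aroma-active compound report (strict OAV > threshold).
#'
#' @param cfg A [run_config()].
#' @return List with `profile`, `summary`, `active` (or `NULL` for
#'   synthetic input) and `files` (written outputs, if `out_dir` set).
#' @export
run_scoring <- function(cfg) {
  inp <- resolve_inputs(cfg)
  if (is.null(inp$profile) || nrow(inp$profile) == 0L)
    vs_stop("scoring stage: no compound/profile input available",
            "vinosense_validation_error")
  summary <- series_summary(inp$profile)
  active <- if (!is.null(inp$oav))
    flag_active(inp$oav, cfg$activity_threshold) else NULL
  res <- list(series_profile = profile_df(inp$profile, inp$classes),
              series_summary = summary)
  if (!is.null(active))
    res$active_compounds <- data.frame(compound = active$active_compounds)
  files <- maybe_write(res, cfg)
  list(profile = inp$profile, summary = summary, active = active,
       files = files)
}

profile_df <- function(profile, classes = NULL) {
  df <- data.frame(sample = rownames(profile),
                   as.data.frame(unclass(profile), check.names = FALSE),
                   check.names = FALSE)
  if (!is.null(classes)) df <- cbind(df[1L], class = as.character(classes),
                                     df[-1L])
  df
}

maybe_write <- function(res, cfg) {
  if (is.null(cfg$out_dir)) return(invisible(character(0)))
  write_report_tables(res, cfg$out_dir,
                      config = cfg[!vapply(cfg, is.function, TRUE)],
                      seed = cfg$seed %||% NA_integer_)
}

#' Run the e-nose classification stage
#'
#' Auto-scales the sensor matrix and fits a PLS-DA model; reports per-LV
#' explained variance of both blocks, VIP scores with the conventional
#' VIP > 1 influence flag, and calibration plus venetian-blind
#' cross-validation confusion matrices.
#'
#' @param cfg A [run_config()].
#' @return List with `model`, `vip` (data frame with `influential` flag),
#'   `confusion_cal`, `confusion_cv`, `explained`, `files`.
#' @export
run_classification <- function(cfg) {
  inp <- resolve_inputs(cfg)
  if (is.null(inp$sensors))
    vs_stop("classification stage: no sensor matrix available",
            "vinosense_validation_error")
  X <- inp$sensors$delta_f
  labels <- inp$sensors$classes
  if (nlevels(labels) < 2L)
    vs_stop("classification requires at least 2 classes",
            "vinosense_validation_error")
  counts <- table(labels)
  if (any(counts < 2L))
    vs_stop(paste0("classes with fewer than 2 samples: ",
                   paste(names(counts)[counts < 2L], collapse = ", "),
                   "; add replicates or merge classes"),
            "vinosense_validation_error")
  s <- cfg_splits(cfg, nrow(X))
  A <- cfg$plsda_lvs
  if (is.null(A)) {
    curve <- plsda_rmsecv_curve(X, labels, max_a = min(qr(X)$rank, 8L),
                                s = s, w = cfg$blind_thickness)
    A <- select_components(rmsecv = curve)
  }
  model <- plsda_fit(X, labels, A)
  cal_cm <- confusion_matrix(labels, model$fitted, levels = model$levels)
  cv <- plsda_cv(X, labels, A, s = s, w = cfg$blind_thickness)
  vip_df <- data.frame(sensor = names(model$vip), vip = unname(model$vip),
                       influential = unname(model$vip) > 1)
  res <- list(vip = vip_df,
              confusion_cal = cm_df(cal_cm), confusion_cv = cm_df(cv$confusion),
              plsda_explained = data.frame(
                lv = seq_len(A),
                explained_x = model$core$explained_x,
                explained_y = model$core$explained_y))
  files <- maybe_write(res, cfg)
  list(model = model, vip = vip_df, confusion_cal = cal_cm,
       confusion_cv = cv$confusion,
       explained = res$plsda_explained, files = files)
}

cm_df <- function(cm) {
  data.frame(actual = rownames(cm$counts),
             as.data.frame.matrix(cm$counts, check.names = FALSE),
             accuracy = cm$accuracy, check.names = FALSE)
}

# cross-validated root mean squared error on the one-hot class responses,
# by number of LVs
plsda_rmsecv_curve <- function(X, labels, max_a, s, w = 1L) {
  labels <- factor(labels, levels = unique(as.character(labels)))
  Y <- stats::model.matrix(~ labels - 1)
  folds <- venetian_folds(nrow(X), s, w)
  vapply(seq_len(max_a), function(a) {
    yhat <- cross_validate(X, Y, folds,
      function(Xt, Yt) {
        lt <- factor(levels(labels)[max.col(Yt)], levels = levels(labels))
        plsda_fit(Xt, lt, a)
      },
      function(m, Xn) plsda_predict(m, Xn, scores = TRUE)$Yhat)
    sqrt(mean((Y - yhat)^2))
  }, numeric(1L))
}

#' Run the odorant-series prediction stage (PCR)
#'
#' Regresses the odorant-series profile on principal components of the
#' auto-scaled sensor matrix and reports, per series, the reference
#' descriptives and calibration/cross-validation performance
#' (RMSEC, RMSECV, R2 cal, R2 cv, RPD = SD/RMSECV).
#'
#' @param cfg A [run_config()].
#' @param reverse Predict sensors from series scores instead (off by
#'   default; the forward direction treats QMB responses as predictors).
#' @return List with `model`, `metrics` (one row per response), `files`.
#' @export
run_prediction <- function(cfg, reverse = FALSE) {
  inp <- resolve_inputs(cfg)
  if (is.null(inp$sensors) || is.null(inp$profile))
    vs_stop("prediction stage needs paired sensor and series data",
            "vinosense_validation_error")
  X <- inp$sensors$delta_f
  Y <- unclass(inp$profile)
  mism <- c(setdiff(rownames(X), rownames(Y)), setdiff(rownames(Y), rownames(X)))
  if (length(mism) > 0L)
    vs_stop(paste0("sample mismatch between sensors and series profile: ",
                   paste(unique(mism), collapse = ", ")),
            "vinosense_validation_error")
  Y <- Y[rownames(X), , drop = FALSE]
  if (reverse) { tmp <- X; X <- Y; Y <- tmp }
  s <- cfg_splits(cfg, nrow(X))
  k <- cfg$pcr_pcs
  if (is.null(k)) {
    rk <- qr(scale(X))$rank
    curve <- vapply(seq_len(min(rk, 8L)), function(kk) {
      cv <- pcr_cv(X, Y, kk, s = s, w = cfg$blind_thickness)
      sqrt(mean((Y - cv)^2))
    }, numeric(1L))
    k <- select_components(rmsecv = curve)
  }
  model <- pcr_fit(X, Y, k)
  metrics <- pcr_metrics_table(X, Y, k, s = s, w = cfg$blind_thickness)
  res <- list(metrics = metrics,
              pcr_explained = data.frame(pc = seq_len(k),
                                         explained = model$pca$explained))
  files <- maybe_write(res, cfg)
  list(model = model, metrics = metrics, files = files)
}

#' Run the full analysis pipeline
#'
#' Executes scoring, classification, the Pearson correlation map between
#' series scores and sensor responses, and PCR prediction; validates the
#' core output invariants (series non-negativity, confusion-matrix row
#' sums, the RPD = SD/RMSECV identity) and, when `out_dir` is set, writes
#' every table plus a manifest with MD5 checksums. Reruns with an identical
#' config and seed are byte-identical.
#'
#' @param cfg A [run_config()] with both series and sensor data available
#'   (synthetic input always qualifies).
#' @return List with `scoring`, `classification`, `correlation`,
#'   `prediction`, `manifest`.
#' @export
run_all <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      vs_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "vinosense_pipeline_error"))
  }
  inner <- cfg; inner$out_dir <- NULL   # write once, at the end
  scoring <- stage("scoring", run_scoring(inner))
  classification <- stage("classification", run_classification(inner))
  inp <- resolve_inputs(inner)
  correlation <- stage("correlation",
                       pearson_map(unclass(inp$profile), inp$sensors$delta_f))
  prediction <- stage("prediction", run_prediction(inner))

  stage("validation", {
    stopifnot(all(unclass(scoring$profile) >= 0))
    stopifnot(all(rowSums(classification$confusion_cal$counts) ==
                    as.vector(table(inp$sensors$classes))))
    with(prediction$metrics,
         stopifnot(all(ifelse(is.finite(rpd), abs(rpd - sd / rmsecv) < 1e-12,
                              rmsecv == 0))))
    TRUE
  })

  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    res <- list(series_profile = profile_df(scoring$profile, inp$classes),
                series_summary = scoring$summary,
                vip = classification$vip,
                confusion_cal = cm_df(classification$confusion_cal),
                confusion_cv = cm_df(classification$confusion_cv),
                plsda_explained = classification$explained,
                correlation_map = correlation,
                metrics = prediction$metrics)
    if (!is.null(scoring$active))
      res$active_compounds <-
        data.frame(compound = scoring$active$active_compounds)
    files <- write_report_tables(res, cfg$out_dir,
                                 config = list(replicate_paper = cfg$replicate_paper,
                                               plsda_lvs = cfg$plsda_lvs,
                                               pcr_pcs = cfg$pcr_pcs,
                                               cv_splits = cfg$cv_splits,
                                               blind_thickness = cfg$blind_thickness,
                                               activity_threshold = cfg$activity_threshold),
                                 seed = cfg$seed %||% NA_integer_)
    sums <- tools::md5sum(files)
    manifest <- data.frame(file = basename(names(sums)), md5 = unname(sums),
                           row.names = NULL)
    utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(scoring = scoring, classification = classification,
       correlation = correlation, prediction = prediction,
       manifest = manifest)
}
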