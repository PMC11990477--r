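#' Default QMB sensitivity matrix (11 series x 12 sensors)
#'
#' A fixed, deterministic sensitivity pattern mapping odorant-series scores
#' to sensor frequency shifts (Hz per unit OAV). Entries are negative
#' (mass adsorption on a quartz microbalance lowers its resonant frequency)
#' and their magnitudes span about 2.5 orders of magnitude (~0.01 to ~3
#' Hz per unit OAV): molecular films deposited on QMBs genuinely differ
#' that much in affinity across odorant classes, and the spread lets the
#' array resolve low-scoring series next to the dominant ones. The pattern
#' is full rank (11) so that, noise-free, the linear sensor model is
#' exactly invertible on the series space.
#'
#' @param n_series Number of odorant series (default 11).
#' @param n_sensors Number of sensors (default 12).
#' @return `n_series` x `n_sensors` numeric matrix.
#' @export
default_sensitivity_matrix <- function(n_series = N_SERIES, n_sensors = 12L) {
  K <- outer(seq_len(n_series), seq_len(n_sensors), function(i, j) {
    u <- 0.5 + 0.5 * sin(2.3 * i + 1.7 * j + 0.5 * i * j)
    -10^(0.5 - 2.5 * (1 - u))
  })
  dimnames(K) <- list(odorant_series_names()[seq_len(n_series)],
                      sprintf("QMB%d", seq_len(n_sensors)))
  K
}

#' Configuration for the synthetic wine-aroma generator
#'
#' The generator emulates the study design the package targets: five wine
#' classes (spontaneous fermentation plus four inoculation strategies) with
#' replicated measurements, an 11-series aroma profile per sample, and a
#' 12-sensor QMB array responding linearly to the profile.
#'
#' @param classes Class labels (default `WY, SC, MP, LT, BC`).
#' @param replicates Replicates per class (default 6, giving n = 30).
#' @param class_means Class x series matrix of mean odorant-series scores;
#'   default: the five per-wine series vectors of the packaged five-wine
#'   dataset, so synthetic data inherit realistic inter-class geometry.
#' @param cv Within-class coefficient of variation (default 0.08);
#'   multiplicative noise, appropriate since series scores span three
#'   orders of magnitude.
#' @param K Sensitivity matrix, series x sensors (Hz per unit OAV);
#'   default [default_sensitivity_matrix()].
#' @param baseline Per-sensor baseline offsets b (Hz), default 0 (frequency
#'   shifts are already differential).
#' @param sigma Per-sensor additive noise SD (Hz), default 1 (the QMB
#'   frequency resolution is 0.1 Hz; 1 Hz is a realistic noise floor).
#' @param drift Optional linear-in-time drift (Hz per sample index), default
#'   0 (off).
#' @param seed Integer seed; mandatory for any stochastic call.
#' @return A `sim_config` list.
#' @export
sim_config <- function(classes = c("WY", "SC", "MP", "LT", "BC"),
                       replicates = 6L,
                       class_means = NULL,
                       cv = 0.08,
                       K = default_sensitivity_matrix(),
                       baseline = rep(0, ncol(K)),
                       sigma = 1,
                       drift = 0,
                       seed = NULL) {
  if (is.null(class_means)) {
    fixture_profile <- series_profile(load_fivewine_fixture())
    if (!all(classes %in% rownames(fixture_profile)))
      vs_stop("default class means only exist for classes WY, SC, MP, LT, BC",
              "vinosense_validation_error")
    class_means <- unclass(fixture_profile)[classes, , drop = FALSE]
  }
  class_means <- as.matrix(class_means)
  if (replicates < 2L)
    vs_stop("replicates must be >= 2", "vinosense_validation_error")
  if (cv < 0) vs_stop("cv must be >= 0", "vinosense_validation_error")
  if (sigma < 0) vs_stop("sigma must be >= 0", "vinosense_validation_error")
  if (nrow(class_means) != length(classes))
    vs_stop("class_means needs one row per class", "vinosense_validation_error")
  if (ncol(class_means) != nrow(K))
    vs_stop("class_means columns must match K rows",
            "vinosense_validation_error")
  if (length(baseline) != ncol(K))
    vs_stop("baseline needs one entry per sensor", "vinosense_validation_error")
  structure(list(classes = classes, replicates = as.integer(replicates),
                 class_means = class_means, cv = cv, K = K,
                 baseline = baseline, sigma = sigma, drift = drift,
                 seed = seed),
            class = "sim_config")
}

check_seed <- function(cfg, stochastic) {
  if (stochastic && (is.null(cfg$seed) || !is.finite(cfg$seed)))
    vs_stop("a seed is mandatory for stochastic simulation",
            "vinosense_validation_error")
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fn()
}

#' Simulate replicated odorant-series profiles
#'
#' Each sample of class *c* observes `M[c, k] * (1 + delta)` per series *k*,
#' with `delta ~ N(0, cv^2)` i.i.d. and values truncated at 0. Fully
#' deterministic under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `true` and `observed` sample x series matrices (both of
#'   class `series_profile`) and `classes` (factor, one label per sample).
#' @export
simulate_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_seed(cfg, stochastic = cfg$cv > 0)
  n_class <- length(cfg$classes)
  n <- n_class * cfg$replicates
  classes <- factor(rep(cfg$classes, each = cfg$replicates),
                    levels = cfg$classes)
  true <- cfg$class_means[as.integer(classes), , drop = FALSE]
  rownames(true) <- sprintf("%s_%d", classes,
                            rep(seq_len(cfg$replicates), times = n_class))
  observed <- if (cfg$cv > 0) {
    with_local_seed(cfg$seed, function() {
      delta <- matrix(stats::rnorm(n * ncol(true), sd = cfg$cv),
                      n, ncol(true))
      pmax(true * (1 + delta), 0)
    })
  } else true
  dimnames(observed) <- dimnames(true)
  class(true) <- c("series_profile", class(true))
  class(observed) <- c("series_profile", class(observed))
  list(true = true, observed = observed, classes = classes)
}

#' Simulate QMB sensor responses from series profiles
#'
#' Linear sensor model: each sample's frequency-shift row is
#' `profile %*% K + b + eps`, with `eps ~ N(0, sigma^2)` i.i.d. per sensor,
#' plus an optional linear drift term. With `sigma = 0` (and no drift) the
#' map is exact.
#'
#' @param profiles Sample x series matrix (e.g. `observed` from
#'   [simulate_profiles()]).
#' @param cfg A [sim_config()].
#' @param classes Class label per sample (for the returned
#'   [sensor_matrix()]); defaults to the sample-name prefix.
#' @return A `sensor_matrix`.
#' @export
simulate_sensors <- function(profiles, cfg, classes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  profiles <- unclass(as.matrix(profiles))
  if (ncol(profiles) != nrow(cfg$K))
    vs_stop("profile columns must match sensitivity-matrix rows",
            "vinosense_validation_error")
  check_seed(cfg, stochastic = cfg$sigma > 0)
  n <- nrow(profiles)
  delta_f <- profiles %*% cfg$K +
    matrix(cfg$baseline, n, ncol(cfg$K), byrow = TRUE)
  if (cfg$drift != 0)
    delta_f <- delta_f + cfg$drift * seq_len(n)
  if (cfg$sigma > 0) {
    # derive a distinct stream from the config seed so profile and sensor
    # noise stay independent yet jointly reproducible
    delta_f <- delta_f + with_local_seed(cfg$seed + 1L, function()
      matrix(stats::rnorm(n * ncol(cfg$K), sd = cfg$sigma), n, ncol(cfg$K)))
  }
  if (is.null(classes))
    classes <- sub("_[0-9]+$", "", rownames(profiles) %||% rep("S", n))
  sensor_matrix(delta_f, classes, samples = rownames(profiles))
}

#' Generate a complete synthetic wine-aroma dataset
#'
#' Bundles replicated odorant-series profiles (true and observed) with the
#' linearly coupled sensor matrix and the generating ground truth.
#' Optionally writes the observed profile and sensor matrix as CSVs in the
#' exact layouts the package readers accept.
#'
#' @param cfg A [sim_config()] (seed required unless `cv = 0` and
#'   `sigma = 0`).
#' @param out_dir If non-`NULL`, write `series_profile.csv` and
#'   `sensor_matrix.csv` here.
#' @return A `synthetic_dataset`: list with `true_profile`, `profile`
#'   (observed), `sensors` (a `sensor_matrix`), `classes`, `K`, `baseline`,
#'   `seed`, `config`.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  prof <- simulate_profiles(cfg)
  sens <- simulate_sensors(prof$observed, cfg, classes = prof$classes)
  ds <- structure(list(true_profile = prof$true, profile = prof$observed,
                       sensors = sens, classes = prof$classes,
                       K = cfg$K, baseline = cfg$baseline,
                       seed = cfg$seed, config = cfg),
                  class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prof_df <- data.frame(sample = rownames(prof$observed),
                          class = as.character(prof$classes),
                          as.data.frame(unclass(prof$observed),
                                        check.names = FALSE),
                          check.names = FALSE)
    utils::write.csv(prof_df, file.path(out_dir, "series_profile.csv"),
                     row.names = FALSE)
    write_sensor_matrix(sens, file.path(out_dir, "sensor_matrix.csv"))
  }
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples (%d classes x %d replicates), %d series, %d sensors\n",
              nrow(x$profile), length(x$config$classes),
              x$config$replicates, ncol(x$profile), ncol(x$sensors$delta_f)))
  invisible(x)
}
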