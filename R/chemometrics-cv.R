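#' Venetian-blind cross-validation folds
#'
#' Deterministic interleaved partition: with blind thickness `w = 1`,
#' fold *i* holds samples `i, i + s, i + 2s, ...`; general thickness groups
#' `w` consecutive samples per blind. Folds partition `1..n` exactly.
#'
#' @param n Number of samples.
#' @param s Number of splits, `2 <= s <= n`.
#' @param w Blind thickness (default 1).
#' @return List of `s` integer index vectors (in original order), of class
#'   `cv_folds` with attributes `s` and `w`.
#' @export
venetian_folds <- function(n, s, w = 1L) {
  if (s < 2L || s > n)
    vs_stop(sprintf("splits s must satisfy 2 <= s <= n = %d", n),
            "vinosense_validation_error")
  if (w < 1L)
    vs_stop("blind thickness w must be >= 1", "vinosense_validation_error")
  idx0 <- seq_len(n) - 1L
  fold_of <- (idx0 %/% w) %% s
  folds <- lapply(seq_len(s) - 1L, function(i) which(fold_of == i))
  structure(folds, s = s, w = w, class = "cv_folds")
}

#' Cross-validate an arbitrary fit/predict pair
#'
#' For each fold the model (including any internal scaling) is refitted on
#' the training samples only and the held-out samples are predicted; the
#' cross-validated predictions are assembled in original sample order. No
#' randomness is involved: venetian-blind folds make the whole procedure
#' bit-for-bit reproducible.
#'
#' @param X Predictor matrix.
#' @param Y Response matrix (or vector), same row count.
#' @param folds A `cv_folds` partition of `1..nrow(X)`.
#' @param fit_fun `function(Xtrain, Ytrain)` returning a model; must do its
#'   own scaling (so no information leaks from held-out samples).
#' @param predict_fun `function(model, Xtest)` returning predictions.
#' @return Matrix (or vector) of cross-validated predictions in original
#'   sample order.
#' @export
cross_validate <- function(X, Y, folds, fit_fun, predict_fun) {
  X <- as.matrix(X)
  Y <- if (is.matrix(Y) || is.data.frame(Y)) as.matrix(Y) else matrix(Y)
  n <- nrow(X)
  if (!setequal(unlist(folds), seq_len(n)))
    vs_stop("folds must partition the sample indices",
            "vinosense_validation_error")
  out <- NULL
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    if (length(train) < 2L)
      vs_stop("a fold leaves fewer than 2 training samples",
              "vinosense_validation_error")
    model <- fit_fun(X[train, , drop = FALSE], Y[train, , drop = FALSE])
    pred <- predict_fun(model, X[fold, , drop = FALSE])
    pred <- if (is.factor(pred) || is.vector(pred)) matrix(as.character(pred))
            else as.matrix(pred)
    if (is.null(out))
      out <- matrix(if (is.character(pred)) NA_character_ else NA_real_,
                    n, ncol(pred))
    out[fold, ] <- pred
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Cross-validated PLS-DA class predictions
#'
#' Convenience wrapper: refits scaling + PLS-DA inside each venetian-blind
#' fold and returns held-out class predictions plus the CV confusion matrix.
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param A Number of latent variables.
#' @param s Number of venetian splits (default `min(n, 10)`).
#' @param w Blind thickness (default 1).
#' @return List with `predicted` (factor, original order), `confusion`
#'   (a [confusion_matrix()]) and `accuracy`.
#' @export
plsda_cv <- function(X, labels, A, s = min(nrow(as.matrix(X)), 10L), w = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels, levels = unique(as.character(labels)))
  folds <- venetian_folds(nrow(X), s, w)
  pred <- cross_validate(X, as.character(labels), folds,
                         function(Xt, Yt) plsda_fit(Xt, drop(Yt), A),
                         function(m, Xn) plsda_predict(m, Xn))
  pred <- factor(pred, levels = levels(labels))
  cm <- confusion_matrix(labels, pred, levels = levels(labels))
  list(predicted = pred, confusion = cm, accuracy = cm$accuracy)
}

#' Select a model dimension from an RMSECV curve or a scree curve
#'
#' With an RMSECV curve the default is the smallest dimension at the first
#' local minimum; a curve with no interior minimum yields its global
#' minimum (the last point for a monotone decreasing curve) with a warning.
#' With eigenvalue scree input the elbow is taken as the point of largest
#' second difference. An explicit `k` always wins.
#'
#' @param rmsecv Numeric RMSECV-by-dimension curve (optional).
#' @param scree Numeric eigenvalue curve (optional, used when `rmsecv` is
#'   absent).
#' @param k Explicit override.
#' @return Integer number of components.
#' @export
select_components <- function(rmsecv = NULL, scree = NULL, k = NULL) {
  if (!is.null(k)) return(as.integer(k))
  if (!is.null(rmsecv)) {
    v <- as.numeric(rmsecv)
    if (length(v) < 2L)
      vs_stop("RMSECV curve needs at least 2 points",
              "vinosense_validation_error")
    m <- length(v)
    for (i in 2:m) {
      if (v[i] < v[i - 1L] && (i == m || v[i] <= v[i + 1L])) {
        if (i == m) warning("no interior RMSECV minimum; using the last point")
        return(i)
      }
    }
    warning("no interior RMSECV minimum; using the global minimum")
    return(which.min(v))
  }
  if (!is.null(scree)) {
    v <- as.numeric(scree)
    if (length(v) < 2L)
      vs_stop("scree curve needs at least 2 points",
              "vinosense_validation_error")
    if (length(v) == 2L) {
      warning("scree curve too short for an elbow; using 1 component")
      return(1L)
    }
    d2 <- v[1:(length(v) - 2L)] - 2 * v[2:(length(v) - 1L)] + v[3:length(v)]
    return(which.max(d2) + 1L)
  }
  vs_stop("supply an RMSECV curve, a scree curve, or an explicit k",
          "vinosense_validation_error")
}
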