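#' Principal component regression
#'
#' Auto-scales the predictors, extracts `k` principal components, and
#' regresses each mean-centered response column on the PC scores by
#' ordinary least squares (QR). Responses are centered but not
#' variance-scaled, so errors are reported in original response units.
#'
#' @param X Sample x predictor matrix (e.g. sensor frequency shifts).
#' @param Y Sample x response matrix (e.g. odorant-series scores).
#' @param k Number of principal components, `1 <= k <= rank(scaled X)`.
#' @param mode Predictor scaling mode (default `"autoscale"`).
#' @return A `pcr_model`: list with `scaling`, `pca`, `B` (k x m score
#'   coefficients), `y_means`, `fitted` (calibration predictions, original
#'   units), `k`.
#' @export
pcr_fit <- function(X, Y, k, mode = "autoscale") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    vs_stop("X and Y must have the same number of samples",
            "vinosense_validation_error")
  sc <- autoscale_fit(X, mode = mode)
  rk <- qr(scale(sc$scaled, center = TRUE, scale = FALSE))$rank
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > rk)
    vs_stop(sprintf("k must be in 1..rank(X) = 1..%d", rk),
            "vinosense_validation_error")
  pca <- pca_fit(sc$scaled, k, center = TRUE, scale. = FALSE)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means, "-")
  B <- qr.solve(pca$scores, Yc)            # OLS of responses on PC scores
  fitted <- sweep(pca$scores %*% B, 2L, y_means, "+")
  dimnames(fitted) <- dimnames(Y)
  structure(list(scaling = sc$model, pca = pca, B = B,
                 y_means = y_means, fitted = fitted, k = k),
            class = "pcr_model")
}

#' Predict responses from a fitted PCR model
#' @param model A `pcr_model`.
#' @param Xnew Matrix with the training predictor columns.
#' @return Predicted response matrix in original units.
#' @export
pcr_predict <- function(model, Xnew) {
  Xs <- scaling_apply(model$scaling, as.matrix(Xnew))
  Tn <- pca_project(model$pca, Xs)
  sweep(Tn %*% model$B, 2L, model$y_means, "+")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("pcr_model: %d PCs (%.2f%% of predictor variance), %d responses\n",
              x$k, 100 * sum(x$pca$explained), length(x$y_means)))
  invisible(x)
}

#' Cross-validated PCR predictions
#'
#' Scaling, PCA and regression are all refitted inside each venetian-blind
#' fold; held-out predictions are assembled in original order.
#'
#' @inheritParams pcr_fit
#' @param s Number of venetian splits (default `min(n, 10)`).
#' @param w Blind thickness (default 1).
#' @return Matrix of cross-validated predictions.
#' @export
pcr_cv <- function(X, Y, k, s = min(nrow(as.matrix(X)), 10L), w = 1L,
                   mode = "autoscale") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  folds <- venetian_folds(nrow(X), s, w)
  out <- cross_validate(X, Y, folds,
                        function(Xt, Yt) pcr_fit(Xt, Yt, k, mode = mode),
                        function(m, Xn) pcr_predict(m, Xn))
  out <- as.matrix(out)
  dimnames(out) <- dimnames(Y)
  out
}

#' Calibration / cross-validation metrics for one response
#'
#' Computes the standard multivariate-calibration diagnostics:
#' \itemize{
#'   \item RMSEC: root mean square error of calibration,
#'     `sqrt(mean((y - y_cal)^2))`;
#'   \item RMSECV: the analogue with cross-validated predictions;
#'   \item R2 cal / R2 cv: `1 - SS_res / SS_tot`, with `SS_tot` about the
#'     global reference mean (for CV this is `1 - PRESS / SS_tot`);
#'   \item RPD: residual prediction deviation, `SD(y) / RMSECV`, with the
#'     sample SD (n - 1). RPD > 3 indicates strong, < 2 weak predictive
#'     ability.
#' }
#' Descriptive statistics (mean, min, max, SD) of the reference values are
#' included.
#'
#' @param y_ref Reference values.
#' @param y_cal Calibration (fitted) predictions.
#' @param y_cv Cross-validated predictions.
#' @return One-row data frame with columns `mean`, `min`, `max`, `sd`,
#'   `rmsec`, `rmsecv`, `r2_cal`, `r2_cv`, `rpd`.
#' @export
regression_metrics <- function(y_ref, y_cal, y_cv) {
  n <- length(y_ref)
  if (length(y_cal) != n || length(y_cv) != n || n < 2L)
    vs_stop("y_ref, y_cal, y_cv must have equal length >= 2",
            "vinosense_validation_error")
  ss_tot <- sum((y_ref - mean(y_ref))^2)
  if (ss_tot == 0)
    vs_stop("zero total variance in the reference values: R2 undefined",
            "vinosense_validation_error")
  rmsec <- sqrt(mean((y_ref - y_cal)^2))
  rmsecv <- sqrt(mean((y_ref - y_cv)^2))
  sdv <- stats::sd(y_ref)
  data.frame(mean = mean(y_ref), min = min(y_ref), max = max(y_ref),
             sd = sdv, rmsec = rmsec, rmsecv = rmsecv,
             r2_cal = 1 - sum((y_ref - y_cal)^2) / ss_tot,
             r2_cv = 1 - sum((y_ref - y_cv)^2) / ss_tot,
             rpd = sdv / rmsecv)
}

#' Per-response PCR performance table
#'
#' Fits a PCR model, cross-validates it, and assembles one metrics row per
#' response column (mean, min, max, SD, RMSEC, RMSECV, R2 cal, R2 cv, RPD).
#'
#' @inheritParams pcr_cv
#' @return Data frame, one row per response, first column `response`.
#' @export
pcr_metrics_table <- function(X, Y, k, s = min(nrow(as.matrix(X)), 10L),
                              w = 1L, mode = "autoscale") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fit <- pcr_fit(X, Y, k, mode = mode)
  cv <- pcr_cv(X, Y, k, s = s, w = w, mode = mode)
  rows <- lapply(seq_len(ncol(Y)), function(j)
    regression_metrics(Y[, j], fit$fitted[, j], cv[, j]))
  out <- do.call(rbind, rows)
  cbind(data.frame(response = colnames(Y) %||% sprintf("Y%d", seq_len(ncol(Y)))),
        out)
}

#' Pearson correlation map between two column sets
#'
#' Column-by-column Pearson correlations between the columns of `A` and of
#' `B` (e.g. odorant-series scores vs sensor responses). Zero-variance
#' columns yield `NA` entries (undefined correlation), never 0.
#'
#' @param A Sample x p matrix.
#' @param B Sample x q matrix.
#' @return p x q correlation matrix.
#' @export
pearson_map <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || nrow(A) < 3L)
    vs_stop("pearson_map needs matched matrices with >= 3 samples",
            "vinosense_validation_error")
  if (any(!is.finite(A)) || any(!is.finite(B)))
    vs_stop("non-finite values", "vinosense_validation_error")
  suppressWarnings(r <- stats::cor(A, B, method = "pearson"))
  r
}
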