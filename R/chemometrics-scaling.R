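#' Fit a column scaling model (auto-scale or center-only)
#'
#' Auto-scaling (unit-variance scaling) subtracts each column's mean and
#' divides by its sample standard deviation (denominator n - 1), putting
#' sensors with very different raw shift magnitudes on a common footing
#' before multivariate modelling.
#'
#' @param X Sample x variable numeric matrix, >= 2 rows.
#' @param mode `"autoscale"` (default) or `"center"`.
#' @return List with `scaled` (transformed matrix) and `model` (a
#'   `scaling_model` holding per-column `mean`, `sd`, `mode`).
#' @export
autoscale_fit <- function(X, mode = c("autoscale", "center")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    vs_stop("at least 2 samples required to fit scaling",
            "vinosense_validation_error")
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  if (mode == "autoscale" && any(sdev == 0)) {
    bad <- colnames(X)[sdev == 0] %||% which(sdev == 0)
    vs_stop(paste0("zero-variance column(s) in autoscale mode: ",
                   paste(bad, collapse = ", ")),
            "vinosense_validation_error")
  }
  model <- structure(list(mean = mu,
                          sd = if (mode == "autoscale") sdev
                               else rep(1, length(mu)),
                          mode = mode),
                     class = "scaling_model")
  list(scaled = scaling_apply(model, X), model = model)
}

#' Apply a fitted scaling model to new data
#' @param model A `scaling_model`.
#' @param X Matrix with the same columns as the training data.
#' @return Scaled matrix.
#' @export
scaling_apply <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    vs_stop("column count does not match the fitted scaling model",
            "vinosense_validation_error")
  sweep(sweep(X, 2L, model$mean, "-"), 2L, model$sd, "/")
}

#' Invert a scaling transform
#' @param model A `scaling_model`.
#' @param Xs Scaled matrix.
#' @return Matrix on the original scale.
#' @export
scaling_invert <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  sweep(sweep(Xs, 2L, model$sd, "*"), 2L, model$mean, "+")
}
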