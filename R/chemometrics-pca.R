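#' Principal component analysis
#'
#' Thin wrapper around the singular value decomposition (via
#' [stats::prcomp()]) returning loadings, scores and explained-variance
#' fractions, with a deterministic sign convention: each component is
#' flipped so its largest-magnitude loading entry is positive.
#'
#' @param X Sample x variable matrix, already scaled as desired (set
#'   `center`/`scale.` to have the transform applied here).
#' @param k Number of components to keep, `k <= min(n - 1, p)`.
#' @param center,scale. Passed to [stats::prcomp()]; defaults center only.
#' @return A `pca_model`: list with `loadings` (p x k), `scores` (n x k),
#'   `explained` (length-k fractions of total variance), `eigenvalues`
#'   (all `min(n-1, p)` of them), `center`, `scale`.
#' @export
pca_fit <- function(X, k, center = TRUE, scale. = FALSE) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k < 1L || k > kmax)
    vs_stop(sprintf("k must be in 1..%d", kmax), "vinosense_validation_error")
  pc <- stats::prcomp(X, center = center, scale. = scale.)
  eig <- pc$sdev^2
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {       # deterministic component sign
    j <- which.max(abs(load[, a]))
    if (load[j, a] < 0) {
      load[, a] <- -load[, a]
      sco[, a] <- -sco[, a]
    }
  }
  structure(list(loadings = load, scores = sco,
                 explained = eig[seq_len(k)] / sum(eig),
                 eigenvalues = eig,
                 center = pc$center, scale = pc$scale),
            class = "pca_model")
}

#' Project new samples onto a fitted PCA model
#' @param model A `pca_model`.
#' @param Xnew Matrix with the training columns, on the training (pre-model)
#'   scale.
#' @return Score matrix (n_new x k).
#' @export
pca_project <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (!isFALSE(model$center)) Xnew <- sweep(Xnew, 2L, model$center, "-")
  if (!isFALSE(model$scale)) Xnew <- sweep(Xnew, 2L, model$scale, "/")
  Xnew %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, cumulative variance %.2f%%\n",
              ncol(x$loadings), 100 * sum(x$explained)))
  invisible(x)
}
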