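#' NIPALS partial least squares (PLS2) core fit
#'
#' Extracts `A` latent variables from pre-scaled `X` (n x p) and centered
#' `Y` (n x m) by the NIPALS algorithm with deflation of both blocks.
#' Convergence is declared when successive X-score vectors change by less
#' than `tol` (relative L2 norm); each component's sign is fixed so its
#' largest-magnitude X-loading entry is positive, making fits reproducible
#' across platforms.
#'
#' Per-LV explained variance of each block is the fraction of the block's
#' initial sum of squares removed by that LV's deflation step.
#'
#' @param X Pre-scaled predictor matrix (column means 0 expected).
#' @param Y Centered response matrix (one column allowed).
#' @param A Number of latent variables, `A <= rank(X)`.
#' @param tol Convergence tolerance on the score vector (default 1e-10).
#' @param max_iter Maximum NIPALS iterations per LV (default 5000).
#' @return A `pls_model`: list with `W` (p x A X-weights, unit norm),
#'   `P` (p x A X-loadings), `Q` (m x A Y-loadings), `T` (n x A X-scores),
#'   `B` (p x m regression coefficients for scaled X, centered Y),
#'   `explained_x`, `explained_y` (per-LV fractions), `A`.
#' @export
pls2_fit <- function(X, Y, A, tol = 1e-10, max_iter = 5000L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n)
    vs_stop("X and Y must have the same number of samples",
            "vinosense_validation_error")
  rk <- qr(X)$rank
  if (A < 1L || A > rk)
    vs_stop(sprintf("A must be in 1..rank(X) = 1..%d", rk),
            "vinosense_validation_error")
  ssx_tot <- sum(X^2); ssy_tot <- sum(Y^2)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, m, A); Tm <- matrix(0, n, A)
  ex <- numeric(A); ey <- numeric(A)
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2)), drop = TRUE]
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) {
        # zero cross-covariance: fall back to an arbitrary unit direction;
        # the LV then explains (numerically) none of Y
        w <- c(1, rep(0, p - 1L))
      } else w <- w / nw
      t_vec <- drop(X %*% w)
      q <- drop(crossprod(Y, t_vec)) / sum(t_vec^2)
      nq <- sum(q^2)
      u <- if (nq == 0) t_vec else drop(Y %*% q) / nq
      if (sqrt(sum((t_vec - t_old)^2)) < tol * max(sqrt(sum(t_vec^2)), 1e-300)) {
        converged <- TRUE; break
      }
      t_old <- t_vec
    }
    if (!converged)
      vs_stop(sprintf("NIPALS did not converge for LV %d within %d iterations",
                      a, max_iter), "vinosense_convergence_error")
    p_vec <- drop(crossprod(X, t_vec)) / sum(t_vec^2)
    j <- which.max(abs(p_vec))
    if (p_vec[j] < 0) {         # deterministic sign
      w <- -w; t_vec <- -t_vec; p_vec <- -p_vec; q <- -q
    }
    X <- X - tcrossprod(t_vec, p_vec)
    Y <- Y - tcrossprod(t_vec, q)
    W[, a] <- w; P[, a] <- p_vec; Q[, a] <- q; Tm[, a] <- t_vec
    ex[a] <- sum(t_vec^2) * sum(p_vec^2) / ssx_tot
    ey[a] <- sum(t_vec^2) * sum(q^2) / if (ssy_tot > 0) ssy_tot else 1
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(W = W, P = P, Q = Q, T = Tm, B = B,
                 explained_x = ex, explained_y = ey, A = A),
            class = "pls_model")
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a \, w_{ja}^2 / \sum_a SSY_a}}
#' where `SSY_a` is the Y-block variance explained by LV `a` and the
#' weight vectors have unit norm, so the squared VIPs average to 1.
#' Predictors with VIP > 1 are conventionally deemed influential.
#'
#' @param model A `pls_model` (or `plsda_model`).
#' @return Numeric VIP vector, one entry per predictor.
#' @export
vip_scores <- function(model) {
  if (inherits(model, "plsda_model")) model <- model$core
  stopifnot(inherits(model, "pls_model"))
  if (model$A < 1L)
    vs_stop("VIP requires at least one fitted LV", "vinosense_validation_error")
  ssy <- model$explained_y
  if (sum(ssy) == 0) ssy <- rep(1, length(ssy))  # no Y signal: weights only
  p <- nrow(model$W)
  vip <- sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(model$W) %||% sprintf("X%d", seq_len(p))
  vip
}

#' Fit a PLS discriminant analysis model
#'
#' Predictors are auto-scaled; class membership is coded as a one-hot
#' {0,1} matrix (class order = first appearance) and column-centered, then
#' a NIPALS PLS2 model with `A` latent variables is fitted. Classification
#' is by the largest predicted class response.
#'
#' @param X Sample x predictor matrix (e.g. e-nose frequency shifts).
#' @param labels Class label per sample (>= 2 classes).
#' @param A Number of latent variables.
#' @param mode Scaling mode, `"autoscale"` (default) or `"center"`.
#' @return A `plsda_model`: list with the `core` [pls2_fit()] model, the
#'   X `scaling` model, `y_means`, `levels` (class order), `vip`, and
#'   calibration `fitted` labels.
#' @export
plsda_fit <- function(X, labels, A, mode = "autoscale") {
  X <- as.matrix(X)
  labels <- factor(labels, levels = unique(as.character(labels)))
  if (nlevels(labels) < 2L)
    vs_stop("PLS-DA requires at least 2 classes", "vinosense_validation_error")
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  y_means <- colMeans(Y)
  sc <- autoscale_fit(X, mode = mode)
  core <- pls2_fit(sc$scaled, sweep(Y, 2L, y_means, "-"), A)
  rownames(core$W) <- colnames(X)
  model <- structure(list(core = core, scaling = sc$model,
                          y_means = y_means, levels = levels(labels),
                          vip = NULL, labels = labels),
                     class = "plsda_model")
  model$vip <- vip_scores(core)
  model$fitted <- plsda_predict(model, X)
  model
}

#' Predict class labels from a fitted PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param Xnew Matrix with the training predictor columns.
#' @param scores If `TRUE`, also return the predicted class-response matrix.
#' @return Factor of predicted labels (levels = training class order), or a
#'   list with `labels` and `Yhat` when `scores = TRUE`.
#' @export
plsda_predict <- function(model, Xnew, scores = FALSE) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(model$scaling$mean))
    vs_stop("predictor dimension differs from the training data",
            "vinosense_validation_error")
  Xs <- scaling_apply(model$scaling, Xnew)
  Yhat <- sweep(Xs %*% model$core$B, 2L, model$y_means, "+")
  colnames(Yhat) <- model$levels
  idx <- apply(Yhat, 1L, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1L)
      warning("tie in predicted class responses; choosing the lowest class index")
    top[1L]
  })
  lab <- factor(model$levels[idx], levels = model$levels)
  if (scores) list(labels = lab, Yhat = Yhat) else lab
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d LVs, %d classes (%s)\n", x$core$A,
              length(x$levels), paste(x$levels, collapse = ", ")))
  cat(sprintf("  X variance explained: %.2f%%; Y: %.2f%%\n",
              100 * sum(x$core$explained_x), 100 * sum(x$core$explained_y)))
  invisible(x)
}

#' Confusion matrix and accuracy
#'
#' @param actual Actual class labels.
#' @param predicted Predicted class labels.
#' @param levels Optional class order; defaults to first appearance in
#'   `actual`.
#' @return A `confusion_matrix`: list with `counts` (rows = actual,
#'   columns = predicted) and `accuracy` (trace / total).
#' @export
confusion_matrix <- function(actual, predicted, levels = NULL) {
  if (is.null(levels)) levels <- unique(as.character(actual))
  a <- factor(as.character(actual), levels = levels)
  p <- factor(as.character(predicted), levels = levels)
  if (length(a) != length(p) || anyNA(a) || anyNA(p))
    vs_stop("actual and predicted labels must align on one label set",
            "vinosense_validation_error")
  counts <- table(actual = a, predicted = p)
  structure(list(counts = unclass(counts),
                 accuracy = sum(diag(counts)) / length(a)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}
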