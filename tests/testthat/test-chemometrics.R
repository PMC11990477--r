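test_that("auto-scaling standardizes columns and round-trips exactly", {
  two <- matrix(c(1, 3), 2, 1)
  sc <- autoscale_fit(two)
  expect_equal(sc$model$mean, 2)
  expect_equal(sc$model$sd, sqrt(2))
  expect_equal(drop(sc$scaled), c(-1, 1) / sqrt(2))

  # idempotence on already-standardized data
  z <- sc$scaled
  expect_equal(autoscale_fit(z)$scaled, z, tolerance = 1e-12)

  X <- rmat(20, 5, seed = 3)
  fit <- autoscale_fit(X)
  expect_true(all(abs(colMeans(fit$scaled)) < 1e-12))
  expect_true(all(abs(apply(fit$scaled, 2, sd) - 1) < 1e-12))
  expect_equal(scaling_invert(fit$model, fit$scaled), X, tolerance = 1e-12)

  Xz <- cbind(X, zero = 7)
  err <- expect_error(autoscale_fit(Xz), class = "vinosense_validation_error")
  expect_match(conditionMessage(err), "zero")
  expect_silent(autoscale_fit(Xz, mode = "center"))
})

test_that("PCA matches an independent eigendecomposition and behaves at edges", {
  collinear <- cbind(c(1, -1, 2, -2), c(1, -1, 2, -2))
  expect_equal(pca_fit(collinear, 1)$explained, 1)

  X <- rmat(10, 4, seed = 5)
  rk <- qr(scale(X, scale = FALSE))$rank
  expect_equal(sum(pca_fit(X, rk)$explained), 1)
  expect_error(pca_fit(X, 10), class = "vinosense_validation_error")

  # eigendecomposition oracle on the covariance matrix
  fit <- pca_fit(X, 4)
  eig <- eigen(cov(X), symmetric = TRUE)
  expect_equal(fit$eigenvalues, eig$values, tolerance = 1e-8)
  for (a in 1:4) {
    v <- eig$vectors[, a]
    expect_lt(min(sum((fit$loadings[, a] - v)^2),
                  sum((fit$loadings[, a] + v)^2)), 1e-16)
  }
  # scores are uncorrelated
  cc <- crossprod(fit$scores)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-8))
})

test_that("NIPALS PLS recovers exact linear structure and the closed-form first LV", {
  # single response exactly linear in one predictor
  set.seed(2); x <- matrix(scale(rnorm(20), scale = FALSE))
  y <- 3 * x
  fit <- pls2_fit(x, y, 1)
  yhat <- x %*% fit$B
  expect_equal(yhat, y, tolerance = 1e-10)

  # response orthogonal to every predictor column: no Y variance explained
  X <- matrix(c(1, 1, -1, -1), 4, 1)
  yo <- matrix(c(1, -1, 1, -1))
  fo <- pls2_fit(X, yo, 1)
  expect_lt(fo$explained_y[1], 1e-12)

  # first weight vector is proportional to X'y (closed form, single response)
  Xm <- scale(rmat(15, 6, seed = 9), scale = FALSE)
  yv <- matrix(scale(rnorm(15), scale = FALSE))
  f1 <- pls2_fit(Xm, yv, 1)
  w_ref <- drop(crossprod(Xm, yv)); w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(min(sum((f1$W[, 1] - w_ref)^2), sum((f1$W[, 1] + w_ref)^2)),
            1e-16)

  # X-score orthogonality across several random problems
  for (seed in 1:5) {
    Xr <- scale(rmat(12, 7, seed = seed), scale = FALSE)
    Yr <- scale(rmat(12, 3, seed = seed + 100), scale = FALSE)
    fr <- pls2_fit(Xr, Yr, 4)
    G <- crossprod(fr$T)
    nrm <- sqrt(diag(G))
    off <- abs(G[upper.tri(G)]) / outer(nrm, nrm)[upper.tri(G)]
    expect_true(all(off < 1e-8))
  }
})

test_that("PLS-DA separates well-separated classes and reports honest CV", {
  d <- separated_classes()
  m <- plsda_fit(d$X, d$labels, 2)
  cm <- confusion_matrix(d$labels, m$fitted)
  expect_equal(cm$accuracy, 1)
  expect_true(all(cm$counts[upper.tri(cm$counts) | lower.tri(cm$counts)] == 0))

  expect_error(plsda_fit(d$X, rep("A", 20), 2),
               class = "vinosense_validation_error")
  expect_error(plsda_predict(m, d$X[, 1, drop = FALSE]),
               class = "vinosense_validation_error")

  # calibration accuracy >= cross-validated accuracy on the 5-class generator
  ds <- generate_dataset(sim_config(seed = 1))
  fit <- plsda_fit(ds$sensors$delta_f, ds$classes, 3)
  cal <- confusion_matrix(ds$classes, fit$fitted)$accuracy
  cv <- plsda_cv(ds$sensors$delta_f, ds$classes, 3)$accuracy
  expect_gte(cal, cv)
})

test_that("VIP scores are normalized and respect symmetry", {
  x <- matrix(scale(rnorm(10), scale = FALSE))
  y <- 2 * x
  expect_equal(unname(vip_scores(pls2_fit(x, y, 1))), 1)

  # duplicated informative predictor: identical VIPs
  set.seed(4)
  base <- scale(rnorm(20), scale = FALSE)
  X <- cbind(a = base, b = base)
  y <- matrix(3 * base)
  v <- vip_scores(pls2_fit(X, y, 1))
  expect_equal(unname(v[1]), unname(v[2]))

  for (seed in 1:5) {
    X <- scale(rmat(15, 8, seed = seed), scale = FALSE)
    Y <- scale(rmat(15, 2, seed = seed + 50), scale = FALSE)
    v <- vip_scores(pls2_fit(X, Y, 3))
    expect_equal(sum(v^2), 8, tolerance = 1e-8)
  }
})

test_that("venetian-blind folds are the deterministic interleaved partition", {
  expect_equal(unclass(venetian_folds(6, 3)), list(c(1L, 4L), c(2L, 5L), c(3L, 6L)),
               ignore_attr = TRUE)
  loo <- venetian_folds(6, 6)
  expect_equal(lengths(loo), rep(1L, 6))

  f73 <- venetian_folds(7, 3)
  expect_equal(lengths(f73), c(3L, 2L, 2L))
  expect_identical(sort(unlist(f73)), 1:7)
  expect_equal(length(unlist(f73)), length(unique(unlist(f73))))

  expect_error(venetian_folds(5, 6), class = "vinosense_validation_error")
  expect_error(venetian_folds(5, 1), class = "vinosense_validation_error")

  # thickness-2 blinds group consecutive pairs
  f <- venetian_folds(8, 2, w = 2)
  expect_equal(unclass(f), list(c(1L, 2L, 5L, 6L), c(3L, 4L, 7L, 8L)),
               ignore_attr = TRUE)
})

test_that("cross-validation refits per fold, is deterministic, and nulls out under permutation", {
  # noiseless linear response: RMSECV ~ 0
  X <- rmat(18, 3, seed = 8)
  B <- matrix(c(1, -2, 0.5), 3, 1)
  Y <- X %*% B
  folds <- venetian_folds(18, 6)
  fit_fun <- function(Xt, Yt) pcr_fit(Xt, Yt, 3)
  pred_fun <- function(m, Xn) pcr_predict(m, Xn)
  yhat <- cross_validate(X, Y, folds, fit_fun, pred_fun)
  expect_lt(sqrt(mean((Y - yhat)^2)), 1e-8)

  # bit-for-bit reproducible
  expect_identical(yhat, cross_validate(X, Y, folds, fit_fun, pred_fun))

  expect_error(cross_validate(X, Y, venetian_folds(18, 6)[1:2], fit_fun, pred_fun),
               class = "vinosense_validation_error")  # not a partition

  # permuted labels on informative data: CV accuracy at or below chance
  ds <- generate_dataset(sim_config(seed = 1))
  set.seed(99)
  accs <- replicate(200, {
    lab <- sample(as.character(ds$classes))
    plsda_cv(ds$sensors$delta_f, lab, 3)$accuracy
  })
  chance <- 1 / 5
  ci <- 1.96 * sqrt(chance * (1 - chance) / 30)
  expect_lt(mean(accs), chance + ci)
  informative <- plsda_cv(ds$sensors$delta_f, ds$classes, 3)$accuracy
  expect_gt(informative, mean(accs) + 4 * sd(accs))
})

test_that("PCR matches the normal-equations solution and flags bad k", {
  # noiseless linear map at full rank: perfect calibration
  ds0 <- generate_dataset(sim_config(cv = 0, sigma = 0))
  X0 <- ds0$sensors$delta_f; Y0 <- unclass(ds0$profile)
  rk <- qr(scale(X0))$rank
  fit0 <- pcr_fit(X0, Y0, rk)
  expect_equal(fit0$fitted, Y0, tolerance = 1e-8)

  expect_error(pcr_fit(X0, Y0, 0), class = "vinosense_validation_error")
  expect_error(pcr_fit(X0, Y0, 99), class = "vinosense_validation_error")

  # coefficients solve the normal equations on the PC scores
  ds <- generate_dataset(sim_config(seed = 1))
  X <- ds$sensors$delta_f; Y <- unclass(ds$profile)
  fit <- pcr_fit(X, Y, 5)
  T5 <- fit$pca$scores
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  B_ref <- solve(crossprod(T5), crossprod(T5, Yc))
  expect_equal(fit$B, B_ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("regression metrics reproduce definitions, including RPD = SD/RMSECV", {
  # printed-precision check: SD 1.25, RMSECV 0.38 gives RPD 3.29 (2 dp)
  expect_equal(round(1.25 / 0.38, 2), 3.29)

  y <- c(1, 2, 3, 4, 10)
  perfect <- regression_metrics(y, y, y + 0.1)
  expect_equal(perfect$rmsec, 0)
  expect_equal(perfect$r2_cal, 1)

  # CV prediction = reference mean: R2cv exactly 0, RPD from first principles
  ycv <- rep(mean(y), 5)
  ycal <- y + c(0.1, -0.1, 0.2, -0.2, 0)
  m <- regression_metrics(y, ycal, ycv)
  expect_equal(m$r2_cv, 0)
  rmsecv_ref <- sqrt(mean((y - mean(y))^2))
  expect_equal(m$rmsecv, rmsecv_ref)
  expect_equal(m$rpd, sd(y) / rmsecv_ref)
  expect_equal(m$mean, 4); expect_equal(m$min, 1); expect_equal(m$max, 10)

  expect_error(regression_metrics(rep(1, 5), rnorm(5), rnorm(5)),
               class = "vinosense_validation_error")

  # identity holds on every emitted metrics row
  ds <- generate_dataset(sim_config(seed = 2))
  tab <- pcr_metrics_table(ds$sensors$delta_f, unclass(ds$profile), 5)
  expect_equal(tab$rpd, tab$sd / tab$rmsecv)
  expect_true(all(tab$r2_cal <= 1))
})

test_that("Pearson maps follow the textbook formula and flag degenerate columns", {
  A <- rmat(10, 3, seed = 21)
  expect_equal(diag(pearson_map(A, 2 * A + 7)), rep(1, 3))
  expect_equal(diag(pearson_map(A, -A)), rep(-1, 3))

  B <- rmat(10, 2, seed = 22)
  r <- pearson_map(A, B)
  n <- 10
  ref <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    a <- A[, i]; b <- B[, j]
    ref[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      ((n - 1) * sd(a) * sd(b))
  }
  expect_equal(unname(r), ref, tolerance = 1e-12)

  Bz <- cbind(B, 5)
  rz <- pearson_map(A, Bz)
  expect_true(all(is.na(rz[, 3])))

  expect_error(pearson_map(A[1:2, ], B[1:2, ]),
               class = "vinosense_validation_error")
})

test_that("component selection finds the first RMSECV minimum or the scree elbow", {
  expect_equal(select_components(rmsecv = c(5, 3, 2, 2.5, 2.4)), 3L)
  expect_warning(k <- select_components(rmsecv = c(5, 4, 3, 2)),
                 "minimum")
  expect_equal(k, 4L)
  expect_equal(select_components(rmsecv = c(5, 3, 2), k = 7), 7L)
  expect_error(select_components(rmsecv = numeric(0)),
               class = "vinosense_validation_error")
  # scree elbow: sharp drop then flat
  expect_equal(select_components(scree = c(10, 5, 1, 0.9, 0.8)), 3L)

  # the replication profile pins the dimensions used throughout
  cfg <- run_config(packaged = TRUE, replicate_paper = TRUE)
  expect_equal(cfg$plsda_lvs, 3L)
  expect_equal(cfg$pcr_pcs, 5L)
  expect_equal(cfg$blind_thickness, 1L)
})
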