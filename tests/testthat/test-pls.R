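test_that("first weight vector is proportional to X'y for one response", {
  set.seed(31)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- rnorm(25)
  m <- fit_pls(X, y, ncomp = 3)
  w_ref <- crossprod(scale(X), scale(y))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  cosine <- abs(sum(m$weights[, 1] * w_ref))
  expect_gte(cosine, 1 - 1e-10)
})

test_that("full-component PLS predictions equal OLS on full-rank data", {
  set.seed(32)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n)
  m <- fit_pls(X, y, ncomp = p)
  expect_lt(max(abs(predict(m) - fitted(lm(y ~ X)))), 1e-8)
})

test_that("noiseless low-rank data are fit exactly at the latent rank", {
  dat <- make_latent_data(n = 30, p = 8, L = 3, seed = 33)
  m <- fit_pls(dat$X, dat$Y, ncomp = 3)
  expect_gte(m$r2y_cum[3], 1 - 1e-10)
  sc <- rmse_scree(m)
  expect_lt(sc$rmse[3], 1e-8)
})

test_that("scores are orthogonal and weights orthonormal", {
  set.seed(34)
  X <- matrix(rnorm(40 * 10), 40, 10)
  Y <- cbind(rnorm(40), rnorm(40))
  m <- fit_pls(X, Y, ncomp = 6, max_iter = 10000)
  G <- crossprod(m$scores)
  norms <- sqrt(diag(G))
  off <- abs(G[upper.tri(G)]) / outer(norms, norms)[upper.tri(G)]
  expect_lt(max(off), 1e-8)
  WW <- crossprod(m$weights)
  expect_equal(diag(WW), rep(1, 6), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("prediction respects the training interpolation limits", {
  dat <- make_latent_data(n = 24, p = 6, L = 2, seed = 35)
  # fit on the first 18 rows, predict the held-out 6 exactly (rank-2 truth)
  m <- fit_pls(dat$X[1:18, ], dat$Y[1:18, ], ncomp = 2)
  pred <- predict(m, dat$X[19:24, ], h = 2)
  expect_lt(max(abs(pred - dat$Y[19:24, ])), 1e-8)
  # h = 0 predicts the training means
  p0 <- predict(m, dat$X[1:3, ], h = 0)
  expect_equal(unname(p0[1, ]), unname(colMeans(dat$Y[1:18, ])))
  expect_error(predict(m, dat$X[, 1:3], h = 2), "lacks descriptor")
})

test_that("rmse curve is nonincreasing and self-consistent with predict", {
  set.seed(36)
  X <- matrix(rnorm(30 * 7), 30, 7)
  Y <- X[, 1:3] %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(60, sd = 0.3), 30, 2)
  m <- fit_pls(X, Y, ncomp = 5, max_iter = 10000)
  sc <- rmse_scree(m)
  expect_true(all(diff(sc$rmse) <= 1e-10))
  # independent recomputation from predict()
  Ys <- scale(Y)
  manual <- sapply(1:5, function(h) {
    pred <- predict(m, X, h = h)
    preds <- sweep(sweep(pred, 2, m$y_means, "-"), 2, m$y_sds, "/")
    sqrt(mean((Ys - preds)^2))
  })
  expect_equal(sc$rmse, manual, tolerance = 1e-10)
  # LOO mode exists and is no lower than in-sample at the same h on average
  loo <- rmse_scree(m, cv = "loo")
  expect_equal(nrow(loo), 5L)
  expect_gt(mean(loo$rmse - sc$rmse), 0)
})

test_that("variance bookkeeping is exact", {
  set.seed(37)
  dat <- make_latent_data(n = 25, p = 9, L = 4, seed = 37, noise = 0.1)
  m <- fit_pls(dat$X, dat$Y, ncomp = 6, max_iter = 10000)
  vt <- variance_tables(m)
  expect_equal(vt$x_r2_cum, cumsum(vt$x_r2), tolerance = 1e-12)
  expect_equal(vt$y_r2_cum, cumsum(vt$y_r2), tolerance = 1e-12)
  expect_true(all(diff(vt$x_r2_cum) >= -1e-12))
  expect_true(all(vt$x_r2_cum <= 1 + 1e-12))
  expect_true(all(vt$y_r2_cum <= 1 + 1e-12))
  # per-component shares match a direct Frobenius recomputation
  manual_x <- sapply(1:6, function(h) {
    sum((m$scores[, h] %*% t(m$x_loadings[, h]))^2) / sum(m$X0^2)
  })
  expect_equal(vt$x_r2, manual_x, tolerance = 1e-12)
  # noiseless rank-2 X reaches X-R2 cum = 1 at h = 2
  d2 <- make_latent_data(n = 20, p = 6, L = 2, seed = 38)
  m2 <- fit_pls(d2$X, d2$Y, ncomp = 2)
  expect_equal(m2$r2x_cum[2], 1, tolerance = 1e-10)
})

test_that("component selection applies both criteria", {
  # cumulative X variance series with the 80% threshold first met at h = 6
  r2x_cum <- c(0.27, 0.45, 0.51, 0.67, 0.77, 0.82, 0.84, 0.87, 0.90, 0.93)
  scree <- structure(data.frame(h = 1:10, rmse = seq(1, 0.1, length.out = 10)),
                     class = c("scree_curve", "data.frame"))
  sel <- suppressWarnings(select_components(scree, r2x_cum, threshold = 0.80))
  expect_equal(sel$h_variance, 6L)

  # constructed single knee in a decreasing curve
  expect_equal(scree_elbow(c(10, 5, 4.5, 4.4, 4.35, 4.3)), 2L)
  expect_error(select_components(
    structure(data.frame(h = 1:2, rmse = c(1, 0.5)),
              class = c("scree_curve", "data.frame")), c(0.5, 0.9)),
    "H >= 3")
})

test_that("selection recovers the planted latent dimension at low noise", {
  hits <- sapply(1:25, function(s) {
    g <- generate_library(library_sim_config(
      block_correlation = 0.95, noise_sd_y = 0.01,
      loadings_seed = s, noise_seed = s + 500))
    std <- standardize_descriptors(g$descriptors)
    m <- fit_pls(std$z_values, log(as.matrix(g$responses[, c("e1", "e2")])),
                 ncomp = 10, max_iter = 20000)
    sel <- suppressWarnings(select_components(rmse_scree(m), m$r2x_cum))
    sel$h_selected == 5
  })
  expect_gte(mean(hits), 0.8)  # full-scale check (100 seeds) in acceptance
})

test_that("loading map coordinates are correlations", {
  dat <- make_latent_data(n = 30, p = 8, L = 3, seed = 39, noise = 0.2)
  m <- fit_pls(dat$X, dat$Y, ncomp = 3, max_iter = 10000)
  map <- loading_map(m)
  expect_true(all(abs(c(map$comp1, map$comp2)) <= 1 + 1e-10))
  # a descriptor column equal to t1 itself maps to (1, 0)
  X2 <- cbind(dat$X, t1copy = m$scores[, 1])
  m2 <- fit_pls(X2, dat$Y, ncomp = 2, max_iter = 10000)
  map2 <- loading_map(m2)
  row <- map2[map2$name == "t1copy", ]
  manual <- cor(m2$X0[, "t1copy"], m2$scores[, 1:2])
  expect_equal(c(row$comp1, row$comp2), as.numeric(manual), tolerance = 1e-12)
  # direct recomputation for every descriptor
  manual_all <- cor(m$X0, m$scores[, 1:2])
  desc <- map[map$role == "descriptor", ]
  expect_equal(desc$comp1, unname(manual_all[, 1]), tolerance = 1e-12)
})

test_that("descriptor-response correlations recover planted signs", {
  ok <- sapply(1:20, function(s) {
    g <- generate_library(library_sim_config(
      block_correlation = 0.9, noise_sd_y = 0.01,
      loadings_seed = s, noise_seed = s + 900))
    std <- standardize_descriptors(g$descriptors)
    # response driven purely by latent 1, positively
    y <- 2 * g$truth$latent_scores[, 1]
    m <- fit_pls(std$z_values, y, ncomp = 3)
    vrc <- variable_response_correlations(m, h = 3)
    blk1 <- g$truth$descriptor_block == 1
    signs_truth <- sign(g$truth$x_loadings[blk1, 1])
    signs_est <- sign(vrc$correlation[blk1])
    mean(signs_est == signs_truth)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("permuting responses destroys the h = 1 fit", {
  set.seed(40)
  g <- generate_library(library_sim_config())
  std <- standardize_descriptors(g$descriptors)
  y <- log(as.matrix(g$responses[, c("e1", "e2")]))
  n <- nrow(y)
  observed <- fit_pls(std$z_values, y, ncomp = 1, max_iter = 10000)$r2y[1]
  r2 <- replicate(200, {
    fit_pls(std$z_values, y[sample(n), ], ncomp = 1, max_iter = 10000)$r2y[1]
  })
  # the null scale: a handful of strong descriptor directions to overfit,
  # each worth ~1/(n-1) of response variance by chance
  expect_lt(mean(r2), 8 / (n - 1))
  expect_lt(mean(r2), observed / 4)
  expect_gt(observed, max(r2))
})
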