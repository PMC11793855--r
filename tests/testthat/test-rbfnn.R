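# exhaustive-partition k-means oracle for tiny instances
brute_kmeans_objective <- function(x, k) {
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    obj <- 0
    for (j in unique(a)) {
      pts <- x[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      obj <- obj + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, obj)
  }
  best
}

test_that("k-means centers reproduce trivial and brute-force optima", {
  withr::with_seed(1, x <- matrix(rnorm(8), ncol = 2))
  # k = n: every point is its own center, objective zero
  km <- rbf_kmeans(x, k = nrow(x), seed = 1)
  expect_equal(km$objective, 0, tolerance = 1e-12)

  # two well-separated blobs: centers at the blob means
  blobs <- rbind(matrix(c(0, 0, 0.2, 0.2), ncol = 2, byrow = TRUE),
                 matrix(c(10, 10, 10.2, 10.2), ncol = 2, byrow = TRUE))
  km2 <- rbf_kmeans(blobs, k = 2, seed = 1)
  ctrs <- km2$centers[order(km2$centers[, 1]), ]
  expect_equal(unname(ctrs), rbind(c(0.1, 0.1), c(10.1, 10.1)))

  # small random instances: objective equals the exhaustive optimum,
  # and agrees with the stock Lloyd implementation as an independent check
  for (s in 1:3) {
    withr::with_seed(s, x <- matrix(rnorm(14), ncol = 2))
    for (k in 2:3) {
      km <- rbf_kmeans(x, k, seed = s)
      expect_equal(km$objective, brute_kmeans_objective(x, k),
                   tolerance = 1e-8)
      ref <- withr::with_seed(s, stats::kmeans(x, k, nstart = 20))
      expect_equal(km$objective, ref$tot.withinss, tolerance = 1e-8)
    }
  }
})

test_that("requesting more centers than points pads with a warning", {
  x <- matrix(rnorm(6), ncol = 2)
  expect_warning(km <- rbf_kmeans(x, k = 5, seed = 1), "padding")
  expect_equal(nrow(km$centers), 5L)
})

test_that("activations match the Gaussian basis formula", {
  model <- list(centers = matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE),
                sigma2 = 0.5)
  phi <- rbf_activations(model, c(0, 0))
  expect_equal(phi[1, 1], 1)                       # at its center
  # squared distance 2 * sigma^2 gives exp(-1)
  expect_equal(rbf_activations(model, c(1, 0))[1, 1], exp(-1))

  withr::with_seed(4, {
    ctrs <- matrix(rnorm(12), ncol = 3)
    xs <- matrix(rnorm(15), ncol = 3)
  })
  m <- list(centers = ctrs, sigma2 = 1.7)
  phi <- rbf_activations(m, xs)
  oracle <- matrix(0, nrow(xs), nrow(ctrs))
  for (i in seq_len(nrow(xs))) for (k in seq_len(nrow(ctrs))) {
    oracle[i, k] <- exp(-sum((xs[i, ] - ctrs[k, ])^2) / (2 * 1.7))
  }
  expect_equal(phi, oracle)
  expect_true(all(phi > 0 & phi <= 1))
  expect_error(rbf_activations(m, c(1, 2)), "dimensions")
})

test_that("normalized LMS interpolates a single point and is inert at zero error", {
  phi <- matrix(c(0.8, 0.3), nrow = 1)
  tr <- nlms_train(phi, targets = 1, mu = 0.5, epochs = 100, seed = 1)
  expect_equal(sum(phi * tr$weights), 1, tolerance = 1e-3)

  # all-zero targets with zero-initialized weights never move
  phi2 <- matrix(runif(12), nrow = 4)
  tr2 <- nlms_train(phi2, targets = rep(0, 4), epochs = 10, seed = 1)
  expect_identical(tr2$weights, rep(0, 3))
  expect_error(nlms_train(phi2, targets = c(0, 1, 2, 0)), "binary")
})

test_that("prediction follows the linear output layer and the threshold rule", {
  model <- structure(
    list(centers = matrix(0, 1, 1), sigma2 = 1, weights = 0,
         feature_names = "x", feature_mean = c(x = 0), feature_sd = c(x = 1),
         threshold = 0.5, n_input = 1L, n_hidden = 1L),
    class = "rbfnn")
  # zero weights -> output 0 everywhere
  expect_equal(predict(model, matrix(c(-3, 0, 5), ncol = 1)), c(0, 0, 0))
  # single neuron, unit weight, input at the center -> 1
  model$weights <- 1
  expect_equal(predict(model, matrix(0, 1, 1)), 1)

  # scalar-loop oracle on a random model
  withr::with_seed(6, {
    ctrs <- matrix(rnorm(10), ncol = 2)
    w <- rnorm(5)
    xs <- matrix(rnorm(8), ncol = 2)
  })
  m <- structure(
    list(centers = ctrs, sigma2 = 0.9, weights = w,
         feature_names = c("a", "b"), feature_mean = c(a = 0, b = 0),
         feature_sd = c(a = 1, b = 1), threshold = 0.5,
         n_input = 2L, n_hidden = 5L),
    class = "rbfnn")
  oracle <- apply(xs, 1, function(v) {
    sum(w * exp(-colSums((t(ctrs) - v)^2) / (2 * 0.9)))
  })
  expect_equal(predict(m, xs), oracle)

  # threshold rule: above or at threshold -> poor, below -> good
  m1 <- m; m1$weights <- w * 0; m1$threshold <- 0
  expect_equal(unique(predict(m1, xs, type = "class")), "poor")  # tie -> poor
  m1$threshold <- 0.5
  expect_equal(unique(predict(m1, xs, type = "class")), "good")
})

test_that("with one center per point the network interpolates its targets", {
  withr::with_seed(7, {
    x <- matrix(rnorm(20), ncol = 2)
    y <- rep(c(0, 1), 5)
  })
  df <- tibble::tibble(a = x[, 1], b = x[, 2], label = y)
  # narrow basis width: near-orthogonal responses, so normalized LMS can
  # drive the training error to zero on distinct points
  fit <- rbf_fit(df, outcome = "label", features = c("a", "b"),
                 n_hidden = 10, epochs = 2000, mu = 0.5, sigma2 = 0.2,
                 seed = 1)
  expect_lt(fit$error_trace[length(fit$error_trace)], 1e-3)
})

test_that("a separable two-blob problem trains to high accuracy", {
  withr::with_seed(8, {
    good <- matrix(rnorm(60, mean = 0), ncol = 2)
    poor <- matrix(rnorm(60, mean = 4), ncol = 2)
  })
  df <- tibble::tibble(a = c(good[, 1], poor[, 1]),
                       b = c(good[, 2], poor[, 2]),
                       label = rep(c("good", "poor"), each = 30))
  fit <- rbf_fit(df, outcome = "label", features = c("a", "b"),
                 n_hidden = 8, seed = 2)
  acc <- mean(predict(fit, df, type = "class") == df$label)
  expect_gte(acc, 0.95)

  # tidy/glance expose one row per hidden neuron and the model summary
  expect_equal(nrow(tidy(fit)), 8L)
  expect_equal(glance(fit)$n_hidden, 8L)
})

test_that("JSON round-trip preserves the model's predictions", {
  withr::with_seed(9, {
    df <- tibble::tibble(a = rnorm(20), b = rnorm(20),
                         label = rep(0:1, 10))
  })
  fit <- rbf_fit(df, outcome = "label", features = c("a", "b"),
                 n_hidden = 5, epochs = 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  rbf_save(fit, path)
  back <- rbf_load(path)
  expect_equal(predict(back, df), predict(fit, df), tolerance = 1e-12)
})
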