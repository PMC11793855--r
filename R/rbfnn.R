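#' Seeded Lloyd k-means for radial-basis center selection
#'
#' Plain Lloyd iteration with deterministic, seeded initialization
#' (k points sampled without replacement), run from `nstart` restarts and
#' keeping the best objective. A cluster that empties during iteration is
#' re-seeded at the point farthest from its assigned center, which keeps
#' training deterministic given the seed even when the number of hidden
#' neurons exceeds the number of distinct training points. Requesting more
#' centers than points pads the sample with replacement (with a warning), so
#' a 64-neuron network can be trained on 70 trials.
#'
#' @param x Numeric matrix, one row per point.
#' @param k Number of centers.
#' @param seed Integer seed; all randomness is local to the call.
#' @param nstart Number of random restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return List with `centers` (k x ncol(x) matrix), `cluster` (assignment
#'   of each point), and `objective` (total within-cluster sum of squared
#'   distances).
#' @export
rbf_kmeans <- function(x, k, seed = 1, nstart = 10, max_iter = 300) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) abort("k must be at least 1")
  if (k > n) {
    warn(sprintf("k = %d exceeds the %d available points; padding centers by sampling with replacement", k, n))
  }
  withr::with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      init <- if (k <= n) sample.int(n, k) else c(sample.int(n), sample.int(n, k - n, replace = TRUE))
      fit <- lloyd_once(x, x[init, , drop = FALSE], max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  })
}

lloyd_once <- function(x, centers, max_iter) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_old <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters at the farthest point from its current center
    empty <- setdiff(seq_len(k), unique(assign_new))
    for (j in empty) {
      far <- which.max(d2[cbind(seq_len(n), assign_new)])
      centers[j, ] <- x[far, ]
      d2 <- sq_dist(x, centers)
      assign_new <- max.col(-d2, ties.method = "first")
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      mem <- assign_new == j
      if (any(mem)) centers[j, ] <- colMeans(x[mem, , drop = FALSE])
    }
  }
  d2 <- sq_dist(x, centers)
  assign_new <- max.col(-d2, ties.method = "first")
  list(centers = centers, cluster = assign_new,
       objective = sum(d2[cbind(seq_len(n), assign_new)]))
}

# squared Euclidean distances, n x k
sq_dist <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

#' Hidden-layer activations of a radial-basis network
#'
#' Gaussian basis responses `phi_k = exp(-||x - c_k||^2 / (2 sigma^2))` for
#' one or more input vectors; each activation lies in (0, 1] and decreases
#' monotonically with distance to its center.
#'
#' @param model A fitted `rbfnn` (or any list with `centers` and `sigma2`).
#' @param x A numeric vector (one input) or matrix (one input per row),
#'   already on the model's feature scale.
#' @return A matrix of activations, one row per input, one column per
#'   hidden neuron.
#' @export
rbf_activations <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$centers)) {
    abort(sprintf("input has %d dimensions but the model expects %d",
                  ncol(x), ncol(model$centers)))
  }
  exp(-sq_dist(x, model$centers) / (2 * model$sigma2))
}

#' Normalized least-mean-squares training of the output weights
#'
#' One output neuron: `y(n) = Phi(n)' w`. For each presentation the error
#' `e(n) = d(n) - y(n)` updates the weights by
#' `w <- w + mu / (||Phi(n)||^2 + eps) * e(n) * Phi(n)`; presentations are
#' shuffled each epoch with the run seed. Targets must be binary 0/1 (0 =
#' good perfusion, 1 = poor perfusion).
#'
#' @param phi Activation matrix (presentations x hidden neurons).
#' @param targets Binary 0/1 vector, one per presentation.
#' @param mu Step size.
#' @param epochs Number of passes over the data.
#' @param eps Regularizer in the normalization denominator.
#' @param seed Integer seed for the per-epoch shuffles.
#' @param w0 Initial weights (default all zero).
#' @return List with `weights` and `error_trace` (per-epoch mean squared
#'   error).
#' @export
nlms_train <- function(phi, targets, mu = 0.05, epochs = 200, eps = 1e-8,
                       seed = 1, w0 = NULL) {
  phi <- as.matrix(phi)
  if (!all(targets %in% c(0, 1))) {
    abort("training targets must be binary 0/1")
  }
  n <- nrow(phi)
  w <- w0 %||% rep(0, ncol(phi))
  err <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      se <- 0
      for (i in ord) {
        ph <- phi[i, ]
        e <- targets[i] - sum(ph * w)
        w <- w + (mu / (sum(ph^2) + eps)) * e * ph
        se <- se + e^2
      }
      err[ep] <- se / n
    }
  })
  list(weights = w, error_trace = err)
}

#' Fit the radial-basis-function perfusion classifier
#'
#' Trains the three-layer RBF network used to discriminate good from poor
#' blood perfusion: hidden centers by seeded k-means over the training
#' features, a shared Gaussian width set to the estimated variation of the
#' input dataset (mean squared distance of the training points from their
#' centroid), and output weights by
#' normalized LMS against binary targets (0 = good perfusion, 1 = poor
#' perfusion). Features are z-scored with training-set statistics by
#' default, since the raw indexes live on scales an order of magnitude
#' apart and would otherwise dominate the Euclidean distances in the basis
#' functions. The operating point of the published system is 64 hidden
#' neurons with decision threshold 0.5.
#'
#' @param data Data frame holding the feature columns.
#' @param outcome Name of the binary outcome column (0/1 or a factor /
#'   character with levels "good"/"poor").
#' @param features Character vector of feature column names (default the
#'   canonical five-index set, [feature_names()]).
#' @param n_hidden Number of hidden neurons.
#' @param threshold Decision threshold on the fuzzy output; outputs greater
#'   than or equal to it are classified "poor" (ties break toward flagging
#'   poor perfusion).
#' @param mu,epochs,eps Normalized-LMS hyperparameters, see [nlms_train()].
#' @param scale Z-score the features with training statistics.
#' @param sigma2 Shared Gaussian width (squared, on the scaled feature
#'   space). `NULL` uses the data-variance estimate described above; a
#'   small explicit value gives near-orthogonal basis responses and exact
#'   interpolation when `n_hidden` equals the number of training points.
#' @param seed Integer seed covering center initialization and the LMS
#'   shuffles.
#' @return An object of class `rbfnn`.
#' @export
rbf_fit <- function(data, outcome = "label", features = feature_names(),
                    n_hidden = 64, threshold = 0.5,
                    mu = 0.05, epochs = 200, eps = 1e-8,
                    scale = TRUE, sigma2 = NULL, seed = 1) {
  if (!all(features %in% names(data))) {
    abort("missing feature columns in data")
  }
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("good", "poor"))) {
      abort("outcome labels must be 'good'/'poor' (or binary 0/1)")
    }
    y <- as.numeric(y == "poor")
  }
  if (!all(y %in% c(0, 1))) abort("outcome must be binary 0/1")
  x <- as.matrix(data[features])
  if (scale) {
    mu_f <- colMeans(x)
    sd_f <- apply(x, 2, sd)
    sd_f[sd_f == 0] <- 1
  } else {
    mu_f <- rep(0, ncol(x)); sd_f <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, mu_f), 2, sd_f, "/")

  km <- rbf_kmeans(xs, n_hidden, seed = seed)
  # shared width = estimated variation of the input dataset: mean squared
  # distance of the training points from their centroid. (A width tied to
  # the distance-to-assigned-center collapses toward zero when the hidden
  # layer is nearly as large as the training set, as it is at the 64-neuron
  # / 70-trial operating point, and the network then cannot generalize.)
  if (is.null(sigma2)) {
    sigma2 <- mean(sq_dist(xs, matrix(colMeans(xs), nrow = 1)))
    if (sigma2 <= 0) sigma2 <- 1
  }

  model <- list(centers = km$centers, sigma2 = sigma2,
                feature_names = features, feature_mean = mu_f,
                feature_sd = sd_f, threshold = threshold,
                n_input = ncol(xs), n_hidden = n_hidden)
  phi <- rbf_activations(model, xs)
  tr <- nlms_train(phi, y, mu = mu, epochs = epochs, eps = eps, seed = seed)
  model$weights <- tr$weights
  model$error_trace <- tr$error_trace
  model$n_train <- nrow(xs)
  class(model) <- "rbfnn"
  model
}

scale_features <- function(model, data) {
  x <- if (is.data.frame(data)) as.matrix(data[model$feature_names]) else {
    if (is.null(dim(data))) data <- matrix(data, nrow = 1)
    as.matrix(data)
  }
  sweep(sweep(x, 2, model$feature_mean), 2, model$feature_sd, "/")
}

#' Predict from a fitted RBF perfusion classifier
#'
#' @param object A fitted `rbfnn`.
#' @param newdata Data frame with the model's feature columns, or a numeric
#'   matrix/vector already in feature order.
#' @param type `"response"` for the fuzzy output (a real number, usually in
#'   \[0, 1\] but not clamped) or `"class"` for `"good"`/`"poor"` labels.
#' @param ... Unused.
#' @return Numeric vector (`"response"`) or character vector (`"class"`).
#' @export
predict.rbfnn <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(object$weights)) abort("model has no trained weights")
  xs <- scale_features(object, newdata)
  y <- drop(rbf_activations(object, xs) %*% object$weights)
  if (type == "response") return(y)
  ifelse(y >= object$threshold, "poor", "good")
}

#' @export
print.rbfnn <- function(x, ...) {
  cat(sprintf(
    "<rbfnn> %d -> %d -> 1, sigma^2 = %.4g, threshold = %.2f, trained on %d trials\n",
    x$n_input, x$n_hidden, x$sigma2, x$threshold, x$n_train))
  invisible(x)
}

#' @rdname rbf_fit
#' @param x A fitted `rbfnn`.
#' @param ... Unused.
#' @method tidy rbfnn
#' @export
tidy.rbfnn <- function(x, ...) {
  centers <- as_tibble(x$centers, .name_repair = ~ x$feature_names)
  dplyr::bind_cols(
    tibble(hidden_neuron = seq_len(x$n_hidden), weight = x$weights),
    centers
  )
}

#' @rdname rbf_fit
#' @method glance rbfnn
#' @export
glance.rbfnn <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_hidden = x$n_hidden,
    sigma2 = x$sigma2,
    threshold = x$threshold,
    n_train = x$n_train,
    final_train_mse = x$error_trace[length(x$error_trace)]
  )
}

#' @rdname rbf_fit
#' @param object A fitted `rbfnn`.
#' @method autoplot rbfnn
#' @export
autoplot.rbfnn <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$error_trace),
               mse = object$error_trace)
  ggplot(df, aes(x = .data$epoch, y = .data$mse)) +
    geom_line(color = "steelblue") +
    labs(x = "Epoch", y = "Training MSE",
         title = "Normalized-LMS training error") +
    theme_minimal()
}

#' Serialize / restore an RBF model as JSON
#'
#' Stores centers, shared width, weights, threshold, and the feature order
#' and z-score parameters needed to apply the model to new trials.
#'
#' @param model A fitted `rbfnn`.
#' @param path Output (or input) file path.
#' @return `rbf_save` returns `path` invisibly; `rbf_load` returns the
#'   restored `rbfnn`.
#' @export
rbf_save <- function(model, path) {
  payload <- list(
    centers = unclass(model$centers), sigma2 = model$sigma2,
    weights = model$weights, threshold = model$threshold,
    feature_names = model$feature_names,
    feature_mean = model$feature_mean, feature_sd = model$feature_sd,
    n_input = model$n_input, n_hidden = model$n_hidden,
    n_train = model$n_train, error_trace = model$error_trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rbf_save
#' @export
rbf_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.matrix(p$centers)) {
    p$centers <- matrix(unlist(p$centers), nrow = p$n_hidden, byrow = TRUE)
  }
  p$feature_mean <- stats::setNames(p$feature_mean, p$feature_names)
  p$feature_sd <- stats::setNames(p$feature_sd, p$feature_names)
  class(p) <- "rbfnn"
  p
}
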