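#' Training configuration for the feedforward classifier
#'
#' Hyperparameters of full-batch gradient descent on the three-layer sigmoid
#' network.  The cost is the per-example mean of the summed per-output-unit
#' binary cross-entropy against one-hot targets (the sigmoid-consistent form
#' of a cross-entropy cost); a softmax output variant is available behind
#' `loss = "softmax"`.
#'
#' By default the feature columns are standardized (centered and scaled by
#' the training-set statistics, which are stored in the model and re-applied
#' at prediction time).  The envelope-derived inputs span several orders of
#' magnitude, which conditions plain gradient descent so badly that training
#' stalls for thousands of epochs; standardization removes that obstacle
#' without changing the classifier family.  Set `standardize = FALSE` for the
#' raw-input behavior.
#'
#' @param learning_rate step size of gradient descent.
#' @param max_epochs maximum number of full-batch epochs.
#' @param tolerance early-stopping threshold on the absolute change of the
#'   cost between consecutive epochs.
#' @param seed integer seed for weight initialization.
#' @param init_scale weights are drawn uniformly from
#'   `[-init_scale, init_scale]`; biases start at zero.
#' @param loss `"bce"` (independent sigmoid outputs, default) or `"softmax"`.
#' @param standardize store and apply per-feature standardization?
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, max_epochs = 2000,
                         tolerance = 1e-6, seed = 1L, init_scale = 0.05,
                         loss = c("bce", "softmax"), standardize = TRUE) {
  loss <- match.arg(loss)
  if (!is.numeric(learning_rate) || learning_rate < 0) {
    stop("`learning_rate` must be nonnegative", call. = FALSE)
  }
  stop_if_not_count(max_epochs, "max_epochs")
  structure(
    list(
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      tolerance = tolerance, seed = as.integer(seed), init_scale = init_scale,
      loss = loss, standardize = isTRUE(standardize)
    ),
    class = "train_config"
  )
}

#' Initialize the three-layer network
#'
#' One hidden layer with `floor(input_dim / 2)` sigmoid units (half the
#' length of the feature vector) and `n_classes` output units (five gestures
#' plus "No-Gesture" by default).  Weights are drawn uniformly in
#' `[-init_scale, init_scale]` from the seeded generator; biases are zero.
#'
#' @param input_dim length of the flattened feature vector, e.g.
#'   `8 * (80 + 7) = 696` for the default window.
#' @param n_classes number of output units (gestures plus rest).
#' @param config a [train_config()].
#' @return an object of class `mlp_model`.
#' @export
#' @examples
#' m <- init_mlp(696, 6)
#' m$hidden_dim # 348
init_mlp <- function(input_dim, n_classes = 6, config = train_config()) {
  stop_if_not_count(input_dim, "input_dim", min = 2)
  if (!is_count(n_classes, min = 2)) {
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  }
  hidden_dim <- input_dim %/% 2
  s <- config$init_scale
  model <- withr::with_seed(config$seed, {
    list(
      weights_ih = matrix(stats::runif(hidden_dim * input_dim, -s, s), hidden_dim, input_dim),
      bias_h = rep(0, hidden_dim),
      weights_ho = matrix(stats::runif(n_classes * hidden_dim, -s, s), n_classes, hidden_dim),
      bias_o = rep(0, n_classes)
    )
  })
  structure(
    c(model, list(
      input_dim = as.integer(input_dim),
      hidden_dim = as.integer(hidden_dim),
      output_dim = as.integer(n_classes),
      loss = config$loss,
      standardization = NULL,
      training_meta = NULL
    )),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  trained <- if (is.null(x$training_meta)) "untrained" else
    sprintf("trained %d epochs, final cost %.4g",
            x$training_meta$epochs_run, x$training_meta$final_cost)
  cat(sprintf("<mlp_model> %d-%d-%d sigmoid network (%s loss), %s\n",
              x$input_dim, x$hidden_dim, x$output_dim, x$loss, trained))
  invisible(x)
}

apply_standardization <- function(model, X) {
  st <- model$standardization
  if (is.null(st)) return(X)
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

# forward pass on an already-standardized matrix; returns hidden and output
mlp_forward_core <- function(model, Xs) {
  H <- sigmoid(sweep(Xs %*% t(model$weights_ih), 2, model$bias_h, "+"))
  Z <- sweep(H %*% t(model$weights_ho), 2, model$bias_o, "+")
  P <- if (model$loss == "softmax") {
    E <- exp(Z - apply(Z, 1, max))
    E / rowSums(E)
  } else {
    sigmoid(Z)
  }
  list(H = H, P = P)
}

# cost and gradients on an already-standardized matrix with one-hot targets
mlp_cost_grad <- function(model, Xs, Y) {
  n <- nrow(Xs)
  f <- mlp_forward_core(model, Xs)
  # no clamping inside the logs: an exactly-saturated *wrong* output makes
  # the cost non-finite, which train_mlp() reports as divergence.  Terms are
  # indexed by the target so a saturated correct output contributes 0.
  on <- Y == 1
  cost <- if (model$loss == "softmax") {
    -sum(log(f$P[on])) / n
  } else {
    -(sum(log(f$P[on])) + sum(log1p(-f$P[!on]))) / n
  }
  dZ2 <- (f$P - Y) / n # gradient of both losses wrt the output pre-activation
  gW2 <- t(dZ2) %*% f$H
  gb2 <- colSums(dZ2)
  dH <- (dZ2 %*% model$weights_ho) * f$H * (1 - f$H)
  gW1 <- t(dH) %*% Xs
  gb1 <- colSums(dH)
  list(cost = cost, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2, P = f$P)
}

#' Forward pass of the network
#'
#' Computes the per-class scores for one flattened feature vector or a matrix
#' of them (one per row).  With the default per-unit sigmoid output the
#' scores each lie in `(0, 1)` but are not constrained to sum to 1; with the
#' softmax variant they form a probability vector.
#'
#' @param model an `mlp_model`.
#' @param x numeric vector of length `input_dim`, or a matrix with
#'   `input_dim` columns.
#' @return a numeric `n x output_dim` matrix of scores.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim) {
    stop(sprintf("input has %d columns but the model expects %d",
                 ncol(x), model$input_dim), call. = FALSE)
  }
  mlp_forward_core(model, apply_standardization(model, x))$P
}

one_hot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y + 1)] <- 1
  Y
}

#' Train the network by full-batch gradient descent
#'
#' Minimizes the cross-entropy cost over the whole training set with a fixed
#' learning rate, stopping early when the cost change falls below the
#' configured tolerance.  Labels are integers in `0..n_classes-1`, with 0 the
#' rest / "No-Gesture" class.  Training is deterministic given the seed.
#'
#' @param model an `mlp_model` from [init_mlp()].
#' @param X numeric matrix of flattened feature vectors (rows) or a
#'   `training_set` from [build_training_set()] (in which case `y` is taken
#'   from it).
#' @param y integer labels in `0..output_dim-1`.
#' @param config a [train_config()].
#' @return the trained `mlp_model`, with `training_meta` filled
#'   (learning rate, epochs run, seed, initial/final cost, cost history).
#' @export
train_mlp <- function(model, X, y = NULL, config = train_config()) {
  stopifnot(inherits(model, "mlp_model"))
  if (inherits(X, "training_set")) {
    y <- X$y
    X <- X$X
  }
  if (!nrow(X)) stop("empty training set", call. = FALSE)
  if (length(y) != nrow(X)) stop("`y` must have one label per row of `X`", call. = FALSE)
  if (any(y < 0) || any(y >= model$output_dim)) {
    stop(sprintf("labels must lie in 0..%d", model$output_dim - 1), call. = FALSE)
  }
  present <- sort(unique(y))
  if (ncol(X) != model$input_dim) {
    stop(sprintf("training matrix has %d columns but the model expects %d",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  if (config$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale < 1e-12] <- 1
    model$standardization <- list(center = center, scale = scale)
  } else {
    model$standardization <- NULL
  }
  Xs <- apply_standardization(model, X)
  Y <- one_hot(y, model$output_dim)
  lr <- config$learning_rate
  costs <- numeric(config$max_epochs)
  epochs_run <- 0L
  for (e in seq_len(config$max_epochs)) {
    g <- mlp_cost_grad(model, Xs, Y)
    if (!is.finite(g$cost)) {
      stop("training diverged (non-finite cost); use a smaller learning rate",
           call. = FALSE)
    }
    costs[e] <- g$cost
    epochs_run <- e
    model$weights_ih <- model$weights_ih - lr * g$gW1
    model$bias_h <- model$bias_h - lr * g$gb1
    model$weights_ho <- model$weights_ho - lr * g$gW2
    model$bias_o <- model$bias_o - lr * g$gb2
    if (!all(is.finite(model$weights_ih)) || !all(is.finite(model$weights_ho))) {
      stop("training diverged (non-finite weights); use a smaller learning rate",
           call. = FALSE)
    }
    if (e > 1 && abs(costs[e - 1] - costs[e]) < config$tolerance) break
  }
  costs <- costs[seq_len(epochs_run)]
  model$training_meta <- list(
    learning_rate = lr,
    epochs_run = epochs_run,
    max_epochs = config$max_epochs,
    seed = config$seed,
    initial_cost = costs[1],
    final_cost = mlp_cost_grad(model, Xs, Y)$cost,
    cost_history = costs,
    n_examples = nrow(X),
    classes_present = present,
    loss = config$loss,
    standardized = config$standardize
  )
  model
}

#' Predict window labels
#'
#' The predicted label of each row is the index of its maximal class score,
#' with exact ties broken toward the lowest label index.
#'
#' @param object a trained `mlp_model`.
#' @param newdata numeric vector or matrix of flattened feature vectors, or a
#'   `feature_matrix` from [extract_features()].
#' @param type `"class"` for integer labels in `0..output_dim-1`,
#'   `"score"` for the raw score matrix.
#' @param ... unused.
#' @return an integer vector of labels, or a score matrix.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  P <- forward(object, newdata)
  if (type == "score") return(P)
  as.integer(max.col(P, ties.method = "first") - 1L)
}

# numbers are serialized as %.17g strings so that save/load round-trips are
# exact at the bit level
fmt_num <- function(x) sprintf("%.17g", as.numeric(x))

mlp_format_version <- "1.0"

#' Save / load a model as a versioned JSON container
#'
#' Weights are stored row-major as decimal strings with 17 significant
#' digits, which round-trips IEEE doubles exactly: a saved-and-reloaded model
#' produces bit-identical forward outputs.  Loading validates the format
#' version and the consistency of all shapes.
#'
#' @param model a trained or untrained `mlp_model`.
#' @param path file path of the JSON container.
#' @return `save_mlp()` returns `path` invisibly; `load_mlp()` returns the
#'   `mlp_model`.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(
    format_version = mlp_format_version,
    input_dim = model$input_dim,
    hidden_dim = model$hidden_dim,
    output_dim = model$output_dim,
    loss = model$loss,
    weights_ih = fmt_num(t(model$weights_ih)), # row-major
    bias_h = fmt_num(model$bias_h),
    weights_ho = fmt_num(t(model$weights_ho)),
    bias_o = fmt_num(model$bias_o),
    standardization = if (!is.null(model$standardization)) {
      list(center = fmt_num(model$standardization$center),
           scale = fmt_num(model$standardization$scale))
    },
    training_meta = if (!is.null(model$training_meta)) {
      meta <- model$training_meta
      meta$cost_history <- NULL # keep the container small
      meta
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop(sprintf("cannot parse model file '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (is.null(obj$format_version)) {
    stop("model file has no format_version field", call. = FALSE)
  }
  if (!identical(as.character(obj$format_version), mlp_format_version)) {
    stop(sprintf("unsupported model format version '%s' (expected '%s')",
                 obj$format_version, mlp_format_version), call. = FALSE)
  }
  nin <- as.integer(obj$input_dim)
  nh <- as.integer(obj$hidden_dim)
  nout <- as.integer(obj$output_dim)
  if (length(obj$weights_ih) != nh * nin || length(obj$weights_ho) != nout * nh ||
      length(obj$bias_h) != nh || length(obj$bias_o) != nout) {
    stop("model file shapes are inconsistent with its declared dimensions",
         call. = FALSE)
  }
  model <- list(
    weights_ih = t(matrix(as.numeric(obj$weights_ih), nin, nh)),
    bias_h = as.numeric(obj$bias_h),
    weights_ho = t(matrix(as.numeric(obj$weights_ho), nh, nout)),
    bias_o = as.numeric(obj$bias_o),
    input_dim = nin, hidden_dim = nh, output_dim = nout,
    loss = obj$loss %||% "bce",
    standardization = if (!is.null(obj$standardization)) {
      st <- list(center = as.numeric(obj$standardization$center),
                 scale = as.numeric(obj$standardization$scale))
      if (length(st$center) != nin || length(st$scale) != nin) {
        stop("model file standardization length is inconsistent", call. = FALSE)
      }
      st
    },
    training_meta = obj$training_meta
  )
  structure(model, class = "mlp_model")
}

#' @importFrom generics tidy
#' @export
tidy.mlp_model <- function(x, ...) {
  layer_row <- function(name, W, b) {
    tibble::tibble(
      layer = name,
      n_weights = length(W), n_biases = length(b),
      weight_mean = mean(W), weight_sd = stats::sd(as.vector(W)),
      weight_min = min(W), weight_max = max(W)
    )
  }
  dplyr::bind_rows(
    layer_row("input->hidden", x$weights_ih, x$bias_h),
    layer_row("hidden->output", x$weights_ho, x$bias_o)
  )
}

#' @importFrom generics glance
#' @export
glance.mlp_model <- function(x, ...) {
  meta <- x$training_meta
  tibble::tibble(
    input_dim = x$input_dim, hidden_dim = x$hidden_dim, output_dim = x$output_dim,
    loss = x$loss,
    standardized = !is.null(x$standardization),
    epochs_run = meta$epochs_run %||% NA_integer_,
    learning_rate = meta$learning_rate %||% NA_real_,
    initial_cost = meta$initial_cost %||% NA_real_,
    final_cost = meta$final_cost %||% NA_real_,
    n_examples = meta$n_examples %||% NA_integer_
  )
}
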