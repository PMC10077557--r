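#' Gradient-descent-with-momentum training configuration
#'
#' Batch gradient descent with a momentum term on the training-set mean
#' squared error. The learning rate, momentum and epoch budget are
#' package defaults (the goal matches the optimiser's 1e-6 objective
#' precision); all are configurable.
#'
#' @param learning_rate Positive step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param max_epochs Maximum number of epochs.
#' @param goal Stop once training MSE drops to or below this value.
#' @return An object of class `gdm_config`.
#' @export
gdm_config <- function(learning_rate = 0.05, momentum = 0.9,
                       max_epochs = 2000L, goal = 1e-6) {
  check_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  check_scalar_number(momentum, "momentum")
  if (momentum < 0 || momentum >= 1) abort("`momentum` must lie in [0, 1).")
  max_epochs <- check_count(max_epochs, "max_epochs", min = 1L)
  check_scalar_number(goal, "goal")
  structure(
    list(
      learning_rate = learning_rate, momentum = momentum,
      max_epochs = max_epochs, goal = goal
    ),
    class = "gdm_config"
  )
}

# one-hot target matrix for integer class codes 1..k
one_hot <- function(codes, k) {
  t_mat <- matrix(0, length(codes), k)
  t_mat[cbind(seq_along(codes), codes)] <- 1
  t_mat
}

train_gdm_engine <- function(arch, features, targets, config) {
  params <- init_network_params(arch)
  velocity <- list(
    weights = purrr::map(params$weights, ~ .x * 0),
    thresholds = purrr::map(params$thresholds, ~ .x * 0)
  )
  mse <- nn_mse(params, features, targets, arch)
  history <- numeric(config$max_epochs + 1L)
  history[1L] <- mse
  epochs <- 0L
  while (epochs < config$max_epochs && mse > config$goal) {
    g <- nn_gradient(params, features, targets, arch)
    velocity$weights <- purrr::map2(
      velocity$weights, g$weights,
      ~ config$momentum * .x - config$learning_rate * .y
    )
    velocity$thresholds <- purrr::map2(
      velocity$thresholds, g$thresholds,
      ~ config$momentum * .x - config$learning_rate * .y
    )
    params$weights <- purrr::map2(params$weights, velocity$weights, `+`)
    params$thresholds <- purrr::map2(params$thresholds, velocity$thresholds, `+`)
    mse <- nn_mse(params, features, targets, arch)
    if (!is.finite(mse)) {
      abort("training diverged (non-finite MSE); try a smaller learning_rate.")
    }
    epochs <- epochs + 1L
    history[epochs + 1L] <- mse
  }
  list(
    params = params, train_mse = mse, iterations = epochs,
    history = tibble::tibble(
      iteration = 0:epochs,
      mse = history[seq_len(epochs + 1L)]
    )
  )
}

train_colony_engine <- function(arch, features, targets, config, bounds, variant) {
  p_total <- n_params(arch)
  space <- search_space(rep(bounds[1L], p_total), rep(bounds[2L], p_total))
  objective <- function(theta) {
    nn_mse(unflatten_params(theta, arch), features, targets, arch)
  }
  res <- abc_optimize(objective, space, config, variant = variant)
  list(
    params = unflatten_params(res$best_position, arch),
    train_mse = res$best_objective,
    iterations = res$cycles_run,
    history = dplyr::rename(res$trace, iteration = "cycle", mse = "best_objective"),
    opt_result = res
  )
}

#' Train the spectra classifier network
#'
#' Fits the feed-forward network on a table of features (typically
#' principal-component scores) and class labels. Features are
#' standardised (zero mean, unit variance per column, estimated on the
#' training data) before entering the network, and labels are encoded as
#' one-hot targets for the logsig output layer. Three trainers are
#' available: `"iaabc"` and `"abc"` search the flattened weight/threshold
#' vector with the bee colony over a `[-5, 5]` box per parameter;
#' `"gdm"` is back-propagation by batch gradient descent with momentum.
#'
#' @param data A data frame with one numeric column per feature plus a
#'   label column.
#' @param label_col Name of the label column (default `"label"`).
#' @param trainer `"iaabc"`, `"abc"` or `"gdm"`.
#' @param arch A [network_arch()]; defaults to one hidden layer of 8
#'   neurons between the feature count and the class count.
#' @param colony [colony_config()] used by the colony trainers.
#' @param gdm [gdm_config()] used by the gradient trainer.
#' @param bounds Length-2 search bounds per network parameter for the
#'   colony trainers.
#' @param seed Optional seed; overrides `colony$seed` when supplied.
#'
#' @return An object of class `bpann_fit` with the fitted parameters,
#'   feature scaler, class levels and an `iteration`/`mse` history.
#' @examples
#' d <- data.frame(
#'   x = c(rnorm(10, -2), rnorm(10, 2)),
#'   y = c(rnorm(10, 2), rnorm(10, -2)),
#'   label = rep(c("a", "b"), each = 10)
#' )
#' fit <- bpann_train(d, trainer = "gdm", seed = 1,
#'   gdm = gdm_config(max_epochs = 50))
#' predict(fit, d)
#' @export
bpann_train <- function(data, label_col = "label",
                        trainer = c("iaabc", "abc", "gdm"),
                        arch = NULL, colony = colony_config(),
                        gdm = gdm_config(), bounds = c(-5, 5), seed = NULL) {
  trainer <- match.arg(trainer)
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("`data` has no column named '%s'.", label_col))
  }
  if (nrow(data) == 0L) abort("`data` must have at least one row.")
  labels <- factor(data[[label_col]])
  feature_cols <- setdiff(names(data), label_col)
  features <- as.matrix(data[feature_cols])
  if (!is.numeric(features)) abort("all feature columns must be numeric.")

  classes <- levels(labels)
  k <- length(classes)
  targets <- one_hot(as.integer(labels), k)

  center <- colMeans(features)
  scale_ <- apply(features, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  x <- sweep(sweep(features, 2L, center), 2L, scale_, "/")

  arch <- arch %||% network_arch(c(ncol(x), 8L, k))
  if (arch$layer_sizes[1L] != ncol(x)) {
    abort("input layer size must equal the number of feature columns.")
  }
  if (arch$layer_sizes[length(arch$layer_sizes)] != k) {
    abort("output layer size must equal the number of classes.")
  }

  if (!is.null(seed)) {
    colony$seed <- check_count(seed, "seed", min = 0L)
    set.seed(colony$seed)
  }
  fit <- switch(trainer,
    gdm = train_gdm_engine(arch, x, targets, gdm),
    abc = train_colony_engine(arch, x, targets, colony, bounds, "abc"),
    iaabc = train_colony_engine(arch, x, targets, colony, bounds, "iaabc")
  )

  structure(
    list(
      arch = arch, params = fit$params, center = center, scale = scale_,
      feature_cols = feature_cols, classes = classes, trainer = trainer,
      train_mse = fit$train_mse, iterations = fit$iterations,
      history = fit$history
    ),
    class = "bpann_fit"
  )
}

# standardise new feature rows with the training-set scaler
scale_features <- function(object, data) {
  data <- as.data.frame(data)
  missing <- setdiff(object$feature_cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("missing feature column(s): %s.", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[object$feature_cols])
  sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
}

#' Predict classes or class scores from a fitted network
#'
#' @param object A `bpann_fit`.
#' @param new_data Data frame containing the fit's feature columns.
#' @param type `"class"` for predicted labels, `"prob"` for the raw
#'   logsig outputs (one column per class; not normalised).
#' @param ... Unused.
#' @return A tibble with a `.pred` factor column, or one numeric column
#'   per class when `type = "prob"`.
#' @export
predict.bpann_fit <- function(object, new_data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- scale_features(object, new_data)
  out <- nn_forward(object$params, x, object$arch)
  if (type == "prob") {
    colnames(out) <- object$classes
    return(tibble::as_tibble(out))
  }
  idx <- predict_classes(out)
  tibble::tibble(.pred = factor(object$classes[idx], levels = object$classes))
}

#' @export
print.bpann_fit <- function(x, ...) {
  cat(sprintf(
    "<bpann_fit> %s network, trainer = %s, %d iterations, train MSE = %.4g\n",
    paste(x$arch$layer_sizes, collapse = "-"), x$trainer, x$iterations, x$train_mse
  ))
  invisible(x)
}

#' @describeIn bpann_train Per-parameter tibble (layer, kind, indices,
#'   value) of the fitted weights and thresholds.
#' @param x A `bpann_fit`.
#' @param ... Unused.
#' @export
tidy.bpann_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$params$weights), function(l) {
    w <- x$params$weights[[l]]
    b <- x$params$thresholds[[l]]
    dplyr::bind_rows(
      tibble::tibble(
        layer = l, kind = "weight",
        from = rep(seq_len(nrow(w)), ncol(w)),
        to = rep(seq_len(ncol(w)), each = nrow(w)),
        value = as.double(w)
      ),
      tibble::tibble(layer = l, kind = "threshold", from = NA_integer_,
                     to = seq_along(b), value = b)
    )
  })
}

#' @describeIn bpann_train One-row fit summary.
#' @export
glance.bpann_fit <- function(x, ...) {
  tibble::tibble(
    trainer = x$trainer,
    architecture = paste(x$arch$layer_sizes, collapse = "-"),
    n_parameters = n_params(x$arch),
    iterations = x$iterations,
    train_mse = x$train_mse
  )
}

#' @describeIn bpann_train Training-history plot (MSE per iteration).
#' @param object A `bpann_fit`.
#' @export
autoplot.bpann_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$iteration, .data$mse)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "training MSE") +
    ggplot2::theme_minimal()
}
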