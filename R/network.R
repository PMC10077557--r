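#' Feed-forward network architecture
#'
#' Layered architecture of the classifier network. The default, 3 input
#' neurons (three principal-component scores), 8 hidden neurons and 3
#' output neurons, uses the hyperbolic tangent (`"tansig"`) in the hidden
#' layer and the logistic function (`"logsig"`) in the output layer.
#'
#' @param layer_sizes Integer vector of at least two layer sizes, all >= 1.
#' @param hidden_transfer Transfer function of hidden layers, `"tansig"`
#'   or `"logsig"`.
#' @param output_transfer Transfer function of the output layer.
#' @return An object of class `network_arch`.
#' @examples
#' network_arch(c(3, 8, 3))
#' @export
network_arch <- function(layer_sizes = c(3L, 8L, 3L),
                         hidden_transfer = "tansig",
                         output_transfer = "logsig") {
  if (!is.numeric(layer_sizes) || length(layer_sizes) < 2L ||
      any(layer_sizes < 1) || any(layer_sizes != round(layer_sizes))) {
    abort("`layer_sizes` must be >= 2 integer sizes, all >= 1.")
  }
  transfers <- c("tansig", "logsig")
  if (!hidden_transfer %in% transfers || !output_transfer %in% transfers) {
    abort('transfer functions must be "tansig" or "logsig".')
  }
  structure(
    list(
      layer_sizes = as.integer(layer_sizes),
      hidden_transfer = hidden_transfer,
      output_transfer = output_transfer
    ),
    class = "network_arch"
  )
}

transfer_fun <- function(name) {
  switch(name, tansig = tanh, logsig = plogis, abort("unknown transfer"))
}

# derivative of the transfer expressed through the activation value a
transfer_deriv <- function(name) {
  switch(name,
    tansig = function(a) 1 - a^2,
    logsig = function(a) a * (1 - a),
    abort("unknown transfer")
  )
}

#' Total number of free parameters of an architecture
#'
#' Counts all weights and thresholds; e.g. the 3-8-3 network has
#' `3*8 + 8 + 8*3 + 3 = 67` parameters.
#'
#' @param arch A [network_arch()].
#' @return Integer parameter count.
#' @examples
#' n_params(network_arch(c(3, 8, 3)))
#' @export
n_params <- function(arch) {
  s <- arch$layer_sizes
  sum(s[-length(s)] * s[-1L] + s[-1L])
}

#' Flatten network parameters to a vector and back
#'
#' Bridges the layered weight matrices and threshold vectors to the flat
#' position vector a honey source carries. The round trip
#' `unflatten_params(flatten_params(p), arch)` is exact.
#'
#' @param params A list with elements `weights` (list of input-by-output
#'   matrices per layer) and `thresholds` (list of per-layer bias vectors).
#' @return `flatten_params()`: a numeric vector; `unflatten_params()`: a
#'   parameter list.
#' @export
flatten_params <- function(params) {
  unlist(
    purrr::map2(params$weights, params$thresholds, function(w, b) c(as.double(w), b)),
    use.names = FALSE
  )
}

#' @rdname flatten_params
#' @param theta Numeric vector of length [n_params()].
#' @param arch A [network_arch()].
#' @export
unflatten_params <- function(theta, arch) {
  if (!is.numeric(theta) || length(theta) != n_params(arch)) {
    abort(sprintf(
      "`theta` must have length %d for this architecture, not %d.",
      n_params(arch), length(theta)
    ))
  }
  s <- arch$layer_sizes
  weights <- vector("list", length(s) - 1L)
  thresholds <- vector("list", length(s) - 1L)
  offset <- 0L
  for (l in seq_len(length(s) - 1L)) {
    nw <- s[l] * s[l + 1L]
    weights[[l]] <- matrix(theta[offset + seq_len(nw)], nrow = s[l])
    offset <- offset + nw
    thresholds[[l]] <- theta[offset + seq_len(s[l + 1L])]
    offset <- offset + s[l + 1L]
  }
  list(weights = weights, thresholds = thresholds)
}

# random initial parameters, uniform in [-range, range]
init_network_params <- function(arch, range = 0.5) {
  theta <- runif(n_params(arch), -range, range)
  unflatten_params(theta, arch)
}

#' Forward pass of the network
#'
#' Propagates feature rows through the layers: tansig activations in the
#' hidden layers and logsig in the output layer, so every output lies
#' strictly in (0, 1).
#'
#' @param params Parameter list as produced by [unflatten_params()].
#' @param features Numeric matrix (or data frame) with one row per sample
#'   and as many columns as input neurons.
#' @param arch A [network_arch()] supplying the transfer names.
#' @return Matrix of network outputs, one row per sample.
#' @export
nn_forward <- function(params, features, arch = network_arch()) {
  a <- as.matrix(features)
  if (!is.numeric(a)) abort("`features` must be numeric.")
  if (ncol(a) != nrow(params$weights[[1L]])) {
    abort(sprintf(
      "feature width %d does not match input layer size %d.",
      ncol(a), nrow(params$weights[[1L]])
    ))
  }
  n_layers <- length(params$weights)
  for (l in seq_len(n_layers)) {
    z <- a %*% params$weights[[l]] +
      matrix(params$thresholds[[l]], nrow(a), length(params$thresholds[[l]]), byrow = TRUE)
    f <- if (l < n_layers) transfer_fun(arch$hidden_transfer) else transfer_fun(arch$output_transfer)
    a <- f(z)
  }
  a
}

# forward pass retaining all layer activations (for backprop)
nn_forward_full <- function(params, a, arch) {
  n_layers <- length(params$weights)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- a
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params$weights[[l]] +
      matrix(params$thresholds[[l]], nrow(a), length(params$thresholds[[l]]), byrow = TRUE)
    f <- if (l < n_layers) transfer_fun(arch$hidden_transfer) else transfer_fun(arch$output_transfer)
    acts[[l + 1L]] <- f(z)
  }
  acts
}

# mean squared error of network outputs against one-hot targets
nn_mse <- function(params, features, targets, arch) {
  out <- nn_forward(params, features, arch)
  mean((out - targets)^2)
}

# gradient of nn_mse w.r.t. all parameters, by backpropagation
nn_gradient <- function(params, features, targets, arch) {
  n_layers <- length(params$weights)
  acts <- nn_forward_full(params, as.matrix(features), arch)
  n <- nrow(targets)
  k <- ncol(targets)
  out <- acts[[n_layers + 1L]]
  d_out <- transfer_deriv(arch$output_transfer)
  delta <- 2 * (out - targets) * d_out(out) / (n * k)
  g_w <- vector("list", n_layers)
  g_b <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    g_w[[l]] <- t(acts[[l]]) %*% delta
    g_b[[l]] <- colSums(delta)
    if (l > 1L) {
      d_hid <- transfer_deriv(arch$hidden_transfer)
      delta <- (delta %*% t(params$weights[[l]])) * d_hid(acts[[l]])
    }
  }
  list(weights = g_w, thresholds = g_b)
}

#' Decode network outputs to class labels
#'
#' The predicted class is the index of the maximal output neuron
#' (1-based); ties go to the lowest index.
#'
#' @param outputs Numeric matrix of network outputs, one row per sample.
#' @return Integer vector of class indices in `1..k`.
#' @examples
#' predict_classes(rbind(c(0, 1, 0), c(0.1, 0.2, 0.9)))
#' @export
predict_classes <- function(outputs) {
  outputs <- as.matrix(outputs)
  if (length(outputs) == 0L) abort("`outputs` must be a non-empty matrix.")
  max.col(outputs, ties.method = "first")
}
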