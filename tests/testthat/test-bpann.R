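test_that("architectures validate and count their parameters", {
  arch <- network_arch(c(3, 8, 3))
  expect_equal(n_params(arch), 3 * 8 + 8 + 8 * 3 + 3)
  expect_equal(n_params(network_arch(c(2, 4, 4, 2))), 2 * 4 + 4 + 4 * 4 + 4 + 4 * 2 + 2)
  expect_error(network_arch(c(3)), ">= 2")
  expect_error(network_arch(c(3, 0, 2)), ">= 1")
  expect_error(network_arch(c(3, 8, 3), hidden_transfer = "relu"), "tansig")
})

test_that("parameter flattening round-trips exactly", {
  arch <- network_arch(c(3, 8, 3))
  withr::with_seed(31, {
    params <- uvabc:::init_network_params(arch)
  })
  theta <- flatten_params(params)
  expect_length(theta, n_params(arch))
  back <- unflatten_params(theta, arch)
  expect_identical(back$weights, params$weights)
  expect_identical(back$thresholds, params$thresholds)

  zero <- unflatten_params(rep(0, n_params(arch)), arch)
  expect_true(all(vapply(zero$weights, function(w) all(w == 0), logical(1))))
  expect_error(unflatten_params(rep(0, 10), arch), "length")
})

test_that("the forward pass honours the transfer functions", {
  arch <- network_arch(c(3, 8, 3))
  zero <- unflatten_params(rep(0, n_params(arch)), arch)
  x <- matrix(rnorm(15), 5, 3)
  out <- nn_forward(zero, x, arch)
  expect_true(all(out == 0.5)) # logsig(0)

  withr::with_seed(7, {
    params <- uvabc:::init_network_params(arch)
    out2 <- nn_forward(params, matrix(rnorm(30), 10, 3), arch)
  })
  expect_true(all(out2 > 0 & out2 < 1))

  # 1-1-1 network with only an output threshold: closed form logsig(t)
  arch1 <- network_arch(c(1, 1, 1))
  t_out <- 0.8
  p1 <- unflatten_params(c(0, 0, 0, t_out), arch1)
  expect_equal(as.numeric(nn_forward(p1, matrix(0), arch1)),
               1 / (1 + exp(-t_out)))

  expect_error(nn_forward(zero, matrix(0, 2, 4), arch), "width")
})

test_that("backpropagation matches a finite-difference oracle", {
  arch <- network_arch(c(2, 4, 2))
  withr::with_seed(3, {
    params <- uvabc:::init_network_params(arch)
    x <- matrix(rnorm(10), 5, 2)
    targets <- uvabc:::one_hot(sample(1:2, 5, replace = TRUE), 2)
  })
  grad <- flatten_params(uvabc:::nn_gradient(params, x, targets, arch))
  theta <- flatten_params(params)
  eps <- 1e-6
  numeric_grad <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (uvabc:::nn_mse(unflatten_params(up, arch), x, targets, arch) -
      uvabc:::nn_mse(unflatten_params(dn, arch), x, targets, arch)) / (2 * eps)
  }, double(1))
  expect_equal(grad, numeric_grad, tolerance = 1e-6)
})

test_that("gradient training reduces the error and stops at the goal", {
  d <- separable_scores(n_per_class = 15, seed = 2)
  fit <- bpann_train(d, trainer = "gdm", seed = 1,
                     gdm = gdm_config(max_epochs = 800))
  expect_lt(fit$train_mse, 0.5 * fit$history$mse[1])
  expect_gte(mean(predict(fit, d)$.pred == d$label), 0.95)

  # an immediately satisfied goal returns with zero epochs run
  fit0 <- bpann_train(d, trainer = "gdm", seed = 1,
                      gdm = gdm_config(goal = 10, max_epochs = 500))
  expect_equal(fit0$iterations, 0)

  # an extreme learning rate saturates the transfers but stays finite and
  # is returned rather than silently corrupting the parameters
  fit_big <- bpann_train(d, trainer = "gdm", seed = 1,
                         gdm = gdm_config(learning_rate = 1e4, max_epochs = 20))
  expect_true(is.finite(fit_big$train_mse))
})

test_that("colony training beats its own initial colony and separates classes", {
  d <- separable_scores(n_per_class = 15, seed = 8)
  cfg <- colony_config(max_cycles = 150, seed = 4)
  fit <- bpann_train(d, trainer = "iaabc", colony = cfg)
  # greedy selection: final MSE never exceeds the best initial member
  expect_lte(fit$train_mse, fit$history$mse[1])
  expect_gte(mean(predict(fit, d)$.pred == d$label), 0.95)

  fit2 <- bpann_train(d, trainer = "iaabc", colony = cfg)
  expect_identical(fit$params, fit2$params)

  # the plain colony variant trains through the same interface
  fit3 <- bpann_train(d, trainer = "abc",
                      colony = colony_config(max_cycles = 60, seed = 9))
  expect_lte(fit3$train_mse, fit3$history$mse[1])
})

test_that("class decoding takes the first maximal output", {
  expect_equal(predict_classes(rbind(c(0, 1, 0))), 2)
  expect_equal(predict_classes(rbind(c(0.5, 0.5, 0.5))), 1)
  expect_equal(predict_classes(rbind(c(0.1, 0.2, 0.9), c(0.9, 0.1, 0))), c(3, 1))
  expect_error(predict_classes(matrix(numeric(), 0, 0)), "non-empty")
})

test_that("fit accessors report architecture and parameters consistently", {
  d <- separable_scores(n_per_class = 10, seed = 3)
  fit <- bpann_train(d, trainer = "gdm", seed = 2,
                     gdm = gdm_config(max_epochs = 50))
  gl <- glance(fit)
  expect_equal(gl$architecture, "3-8-3")
  expect_equal(gl$n_parameters, 59)
  td <- tidy(fit)
  expect_equal(nrow(td), 59)
  expect_equal(sum(td$kind == "threshold"), 8 + 3)
  # probabilities come back one column per class, inside (0, 1)
  pr <- predict(fit, d, type = "prob")
  expect_equal(names(pr), c("a", "b", "c"))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(predict(fit, d[, c("PC1", "label")]), "missing feature")
})
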