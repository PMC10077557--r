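# shared fixtures built in code

# the three mixture-classification outcomes narrated for the test set of
# 140 samples (7 classes x 20): lists of (actual class, predicted class,
# count) for the misclassified samples; everything else is on the diagonal
narrated_misclassifications <- list(
  bpann = list(c(2, 1, 6), c(3, 4, 6), c(5, 4, 2), c(5, 6, 2), c(7, 6, 4)),
  abc = list(c(2, 1, 4), c(3, 4, 4), c(5, 4, 2), c(5, 6, 2), c(7, 6, 2)),
  iaabc = list(c(2, 1, 2), c(3, 4, 2), c(5, 4, 2), c(7, 6, 2))
)

# build actual/predicted label vectors from a narrated outcome
narrated_labels <- function(model, n_per_class = 20L, k = 7L) {
  actual <- rep(seq_len(k), each = n_per_class)
  predicted <- actual
  for (mis in narrated_misclassifications[[model]]) {
    idx <- which(actual == mis[1L] & predicted == mis[1L])[seq_len(mis[3L])]
    predicted[idx] <- mis[2L]
  }
  list(actual = actual, predicted = predicted)
}

# published per-class metric table for the three mixture models
# (recall %, precision %, F-score, accuracy %), classes 0..60 % m/m
published_mixture_metrics <- function() {
  tibble::tibble(
    class = rep(c("1", "2", "3", "4", "5", "6", "7"), times = 3),
    model = rep(c("bpann", "abc", "iaabc"), each = 7),
    recall = c(
      100, 70, 70, 100, 80, 100, 80,
      100, 80, 80, 100, 80, 100, 90,
      100, 90, 90, 100, 90, 100, 90
    ),
    precision = c(
      76.9, 100, 100, 71.4, 100, 76.9, 100,
      83.3, 100, 100, 76.9, 100, 83.3, 100,
      90.9, 100, 100, 83.3, 100, 90.9, 100
    ),
    f_score = c(
      0.869, 0.824, 0.824, 0.833, 0.889, 0.869, 0.889,
      0.909, 0.889, 0.889, 0.869, 0.889, 0.909, 0.947,
      0.952, 0.947, 0.947, 0.909, 0.947, 0.952, 0.947
    ),
    accuracy = rep(c(85.7, 90.0, 94.3), each = 7)
  )
}

# a small well-separated three-class score dataset
separable_scores <- function(n_per_class = 20L, seed = 42L, sdev = 0.3) {
  withr::with_seed(seed, {
    centers <- list(a = c(-3, 0, 1), b = c(3, 0, -1), c = c(0, 3, 0))
    purrr::map_dfr(names(centers), function(nm) {
      m <- matrix(rnorm(3L * n_per_class, sd = sdev), ncol = 3L, byrow = TRUE)
      m <- sweep(m, 2L, centers[[nm]], "+")
      tibble::tibble(PC1 = m[, 1L], PC2 = m[, 2L], PC3 = m[, 3L], label = nm)
    })
  })
}

# tiny spectra set on the default grid, deterministic
toy_spectra <- function(n = 3L) {
  grid <- default_grid()
  comps <- default_components()
  specs <- purrr::map_dfr(seq_len(n), function(i) {
    comp <- comps[[((i - 1L) %% 3L) + 1L]]
    tibble::as_tibble(component_spectrum(comp, 1e-5 * i, grid,
                                         sample = sprintf("t%02d", i)))
  })
  uv_spectra(specs)
}
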