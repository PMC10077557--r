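#' Principal component analysis of a spectra set
#'
#' Fits PCA on the mean-centred (un-scaled) absorbance matrix, the usual
#' convention for absorption spectra where the measurement scale is
#' shared by all wavelengths. The first `k` loading vectors, the sample
#' score vectors and the variance contribution rate of each component
#' (as a percentage of the total variance over *all* components) are
#' retained. Loading signs are fixed deterministically by making each
#' component's largest-magnitude element positive.
#'
#' @param spectra A [uv_spectra] object with at least two samples.
#' @param k Number of components to keep; must satisfy
#'   `k <= min(n - 1, p)`.
#' @return An object of class `spectra_pca` with elements
#'   `mean_spectrum`, `wavelengths`, `loadings` (p x k), `scores`
#'   (tibble with metadata and `PC1..PCk`), `variance_contribution`
#'   (percentages) and `all_variances` (every eigenvalue).
#' @examples
#' set.seed(1)
#' spec <- generate_dataset(classes = "components", n_per_class = 5,
#'   noise = noise_model(sigma = 0), seed = 1)
#' fit_pca(spec$train, k = 3)
#' @export
fit_pca <- function(spectra, k = 3L) {
  spectra <- uv_spectra(spectra)
  x <- spectra_matrix(spectra)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) abort("PCA needs at least two spectra.")
  k <- check_count(k, "k", min = 1L)
  if (k > min(n - 1L, p)) {
    abort(sprintf("`k` must be <= min(n - 1, p) = %d.", min(n - 1L, p)))
  }
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) { # deterministic sign convention
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  meta <- spectra_meta(spectra)
  score_tbl <- tibble::as_tibble(scores)
  names(score_tbl) <- paste0("PC", seq_len(k))
  score_tbl <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(x)), score_tbl
  )
  score_tbl <- dplyr::left_join(meta, score_tbl, by = "sample")
  structure(
    list(
      mean_spectrum = pr$center,
      wavelengths = as.numeric(colnames(x)),
      loadings = loadings,
      scores = score_tbl,
      variance_contribution = 100 * ev[seq_len(k)] / sum(ev),
      all_variances = ev,
      n = n, k = k
    ),
    class = "spectra_pca"
  )
}

#' Project spectra onto a fitted PCA model
#'
#' Centres new spectra with the model's mean spectrum and projects them
#' onto the stored loading vectors. Test spectra must lie on the model's
#' wavelength grid; the model is never refitted.
#'
#' @param model A `spectra_pca` model.
#' @param spectra A [uv_spectra] object on the model grid.
#' @return Tibble with `sample`, `label`, `concentration` and one score
#'   column per component.
#' @export
project <- function(model, spectra) {
  if (!inherits(model, "spectra_pca")) abort("`model` must be a spectra_pca.")
  spectra <- uv_spectra(spectra)
  x <- spectra_matrix(spectra)
  if (ncol(x) != length(model$wavelengths) ||
      !isTRUE(all.equal(as.numeric(colnames(x)), model$wavelengths))) {
    abort("spectra are not on the model's wavelength grid.")
  }
  scores <- sweep(x, 2L, model$mean_spectrum) %*% model$loadings
  out <- tibble::as_tibble(scores)
  names(out) <- paste0("PC", seq_len(ncol(scores)))
  meta <- spectra_meta(spectra)
  dplyr::left_join(meta, dplyr::bind_cols(tibble::tibble(sample = rownames(x)), out),
                   by = "sample")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf(
    "<spectra_pca> %d components of %d spectra; variance contribution: %s\n",
    x$k, x$n, paste(sprintf("%.2f%%", x$variance_contribution), collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn fit_pca Per-component variance-contribution table.
#' @param x A `spectra_pca`.
#' @param ... Unused.
#' @export
tidy.spectra_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    variance_percent = x$variance_contribution,
    cumulative_percent = cumsum(x$variance_contribution)
  )
}

#' @describeIn fit_pca One-row model summary.
#' @export
glance.spectra_pca <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = length(x$wavelengths), k = x$k,
    cumulative_variance_percent = sum(x$variance_contribution)
  )
}

#' @describeIn fit_pca Score scatter plot in two chosen components.
#' @param object A `spectra_pca`.
#' @param dims Length-2 integer vector of components to plot.
#' @export
autoplot.spectra_pca <- function(object, dims = c(1L, 2L), ...) {
  cols <- paste0("PC", dims)
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data[[cols[1L]]], .data[[cols[2L]]], colour = .data$label)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cols[1L], object$variance_contribution[dims[1L]]),
      y = sprintf("%s (%.1f%%)", cols[2L], object$variance_contribution[dims[2L]]),
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Loading-vector profiles across wavelength
#'
#' Line plot of each retained loading vector against wavelength, the
#' usual way to read which spectral regions drive each component.
#'
#' @param model A `spectra_pca`.
#' @return A ggplot object.
#' @export
plot_loadings <- function(model) {
  long <- tibble::as_tibble(model$loadings)
  names(long) <- paste0("PC", seq_len(ncol(model$loadings)))
  long$wavelength <- model$wavelengths
  long <- tidyr::pivot_longer(long, -"wavelength",
                              names_to = "component", values_to = "loading")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$loading,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "loading") +
    ggplot2::theme_minimal()
}
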