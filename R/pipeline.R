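#' Simulate a spectra dataset and write it to disk
#'
#' Generates a synthetic train/test dataset with [generate_dataset()],
#' writes `train.csv` and `test.csv` in the wide spectra format plus a
#' `manifest.json` recording the seed, the generator settings and the
#' MD5 checksums of the written files. Reruns with the same seed are
#' byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param classes `"mixtures"` or `"components"`.
#' @param n_per_class Samples per class.
#' @param noise A [noise_model()].
#' @param train_fraction Fraction of each class used for training.
#' @param seed Master seed.
#' @return Invisibly, the manifest as a list.
#' @export
simulate_spectra <- function(out_dir, classes = c("mixtures", "components"),
                             n_per_class = 30L, noise = noise_model(),
                             train_fraction = 2 / 3, seed = 1L) {
  classes <- match.arg(classes)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  ds <- generate_dataset(
    classes = classes, n_per_class = n_per_class, noise = noise,
    train_fraction = train_fraction, seed = seed
  )
  train_path <- file.path(out_dir, "train.csv")
  test_path <- file.path(out_dir, "test.csv")
  write_spectra_csv(ds$train, train_path)
  write_spectra_csv(ds$test, test_path)
  manifest <- list(
    classes = classes, n_per_class = n_per_class, seed = seed,
    train_fraction = train_fraction,
    noise = list(sigma = noise$sigma, baseline_amplitude = noise$baseline_amplitude),
    files = list(
      train = list(path = "train.csv", md5 = unname(tools::md5sum(train_path))),
      test = list(path = "test.csv", md5 = unname(tools::md5sum(test_path)))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

as_uv_input <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("cannot read spectra file '%s'.", x))
    read_spectra_csv(x)
  } else {
    uv_spectra(x)
  }
}

#' Train the full PCA + network classifier
#'
#' Fits PCA on the training spectra only, projects them to `pca_k` score
#' vectors and trains the classifier network on the scores with
#' [bpann_train()]. Optionally serialises the combined model to JSON.
#'
#' @param train Training spectra: a [uv_spectra] object or a path to a
#'   wide spectra CSV.
#' @param trainer `"iaabc"`, `"abc"` or `"gdm"`.
#' @param pca_k Number of principal components used as network inputs.
#' @param arch Optional [network_arch()] override.
#' @param colony,gdm Trainer configurations.
#' @param seed Master seed for the run.
#' @param out_model Optional path for the serialised model JSON.
#' @return An object of class `uvabc_model` holding the `spectra_pca`
#'   model and the `bpann_fit`.
#' @export
train_classifier <- function(train, trainer = c("iaabc", "abc", "gdm"),
                             pca_k = 3L, arch = NULL,
                             colony = colony_config(), gdm = gdm_config(),
                             seed = 1L, out_model = NULL) {
  trainer <- match.arg(trainer)
  train <- as_uv_input(train)
  pca <- fit_pca(train, k = pca_k)
  scores <- dplyr::select(pca$scores, -"sample", -"concentration")
  fit <- bpann_train(scores, label_col = "label", trainer = trainer,
                     arch = arch, colony = colony, gdm = gdm, seed = seed)
  model <- structure(
    list(pca = pca, fit = fit, pca_k = pca_k, trainer = trainer, seed = seed),
    class = "uvabc_model"
  )
  if (!is.null(out_model)) write_model(model, out_model)
  model
}

#' @export
print.uvabc_model <- function(x, ...) {
  cat(sprintf(
    "<uvabc_model> %d PCs -> %s network (trainer = %s), classes: %s\n",
    x$pca_k, paste(x$fit$arch$layer_sizes, collapse = "-"), x$trainer,
    paste(x$fit$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Serialise and restore a trained classifier
#'
#' The model is written as a single JSON document carrying the network
#' architecture and flattened parameter vector, the feature scaler, the
#' class levels and the PCA model (mean spectrum, loadings, variance
#' contributions). Numbers are written at full precision so the restored
#' model predicts identically.
#'
#' @param model A `uvabc_model`.
#' @param path File path.
#' @return `read_model()`: the restored `uvabc_model`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "uvabc_model")) abort("`model` must be a uvabc_model.")
  doc <- list(
    package = "uvabc",
    trainer = model$trainer,
    seed = model$seed,
    network = list(
      layer_sizes = model$fit$arch$layer_sizes,
      hidden_transfer = model$fit$arch$hidden_transfer,
      output_transfer = model$fit$arch$output_transfer,
      theta = flatten_params(model$fit$params),
      center = model$fit$center,
      scale = model$fit$scale,
      feature_cols = model$fit$feature_cols,
      classes = model$fit$classes,
      train_mse = model$fit$train_mse,
      iterations = model$fit$iterations
    ),
    pca = list(
      k = model$pca_k,
      wavelengths = model$pca$wavelengths,
      mean_spectrum = unname(model$pca$mean_spectrum),
      loadings = unname(model$pca$loadings),
      variance_contribution = model$pca$variance_contribution
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file '%s' does not exist.", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- network_arch(doc$network$layer_sizes, doc$network$hidden_transfer,
                       doc$network$output_transfer)
  fit <- structure(
    list(
      arch = arch,
      params = unflatten_params(doc$network$theta, arch),
      center = doc$network$center, scale = doc$network$scale,
      feature_cols = doc$network$feature_cols, classes = doc$network$classes,
      trainer = doc$trainer, train_mse = doc$network$train_mse,
      iterations = doc$network$iterations, history = NULL
    ),
    class = "bpann_fit"
  )
  loadings <- doc$pca$loadings
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  mean_spectrum <- doc$pca$mean_spectrum
  names(mean_spectrum) <- as.character(doc$pca$wavelengths)
  pca <- structure(
    list(
      mean_spectrum = mean_spectrum,
      wavelengths = doc$pca$wavelengths,
      loadings = loadings,
      scores = NULL,
      variance_contribution = doc$pca$variance_contribution,
      all_variances = NULL, n = NA_integer_, k = doc$pca$k
    ),
    class = "spectra_pca"
  )
  structure(
    list(pca = pca, fit = fit, pca_k = doc$pca$k, trainer = doc$trainer,
         seed = doc$seed),
    class = "uvabc_model"
  )
}

#' Classify spectra with a trained model
#'
#' Projects spectra onto the model's PCA loadings and runs the network.
#'
#' @param model A `uvabc_model` or a path to a model JSON.
#' @param spectra A [uv_spectra] object or a spectra CSV path.
#' @return Tibble with `sample`, `label` (if present), `actual` and
#'   `predicted` class columns.
#' @export
classify_spectra <- function(model, spectra) {
  if (is.character(model)) model <- read_model(model)
  spectra <- as_uv_input(spectra)
  scores <- project(model$pca, spectra)
  pred <- predict(model$fit, dplyr::select(scores, dplyr::starts_with("PC")))
  tibble::tibble(
    sample = scores$sample,
    actual = factor(scores$label, levels = model$fit$classes),
    predicted = pred$.pred
  )
}

#' Evaluate a trained model on a test set
#'
#' Runs [classify_spectra()] and assembles the full evaluation report:
#' the confusion matrix (rows = actual), per-class recall/precision/
#' F-score with overall accuracy, and the regression-style RMSEP, REP
#' and R-squared computed on the integer class codes.
#'
#' @inheritParams classify_spectra
#' @param out_json Optional path for a JSON report.
#' @return An object of class `uvabc_evaluation`: a list with
#'   `predictions`, `confusion`, `class_metrics` and
#'   `regression_metrics`.
#' @export
evaluate_classifier <- function(model, spectra, out_json = NULL) {
  preds <- classify_spectra(model, spectra)
  if (anyNA(preds$actual)) {
    abort("test spectra carry labels outside the model's class set.")
  }
  cm <- build_confusion(preds$actual, preds$predicted,
                        labels = levels(preds$actual))
  cls <- class_metrics(cm)
  reg <- regression_metrics(as.integer(preds$actual), as.integer(preds$predicted))
  out <- structure(
    list(predictions = preds, confusion = cm, class_metrics = cls,
         regression_metrics = reg),
    class = "uvabc_evaluation"
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(
        confusion = list(labels = rownames(cm), counts = unclass(cm)),
        class_metrics = cls, regression_metrics = reg
      ),
      out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' @export
print.uvabc_evaluation <- function(x, ...) {
  print(x$confusion)
  cat("\nPer-class metrics (Recall %, Precision %, F-Score, Accuracy %):\n")
  print(as.data.frame(x$class_metrics), digits = 4)
  cat("\nRegression metrics on class codes:\n")
  print(as.data.frame(x$regression_metrics), digits = 4)
  invisible(x)
}

#' Read and write pipeline configuration as YAML
#'
#' A flat YAML file with optional `colony`, `gdm`, `noise` and `pipeline`
#' sections mirroring the configuration constructors' field names.
#'
#' @param path YAML file path.
#' @return A list with `colony` ([colony_config()]), `gdm`
#'   ([gdm_config()]), `noise` ([noise_model()]) and `pipeline` (plain
#'   list of remaining settings).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path) %||% list()
  list(
    colony = do.call(colony_config, raw$colony %||% list()),
    gdm = do.call(gdm_config, raw$gdm %||% list()),
    noise = do.call(noise_model, raw$noise %||% list()),
    pipeline = raw$pipeline %||% list()
  )
}
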