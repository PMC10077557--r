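#' The default measurement grid
#'
#' Wavelengths 190 to 400 nm at 1 nm spacing (211 points), matching the
#' spectrophotometer acquisition settings the package emulates.
#'
#' @return Numeric vector of 211 wavelengths in nm.
#' @export
default_grid <- function() {
  seq(190, 400, by = 1)
}

#' Tidy container for UV absorption spectra
#'
#' A `uv_spectra` object is a long-format tibble with one row per
#' (sample, wavelength) pair and columns `sample`, `label`,
#' `concentration`, `wavelength` and `absorbance`. All samples must share
#' one strictly increasing wavelength grid and carry finite absorbances.
#'
#' @param x A data frame with the five columns above.
#' @return `x` validated and classed as `uv_spectra`.
#' @export
uv_spectra <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("sample", "label", "concentration", "wavelength", "absorbance")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort("a uv_spectra object needs at least one spectrum.")
  if (!all(is.finite(x$absorbance))) abort("absorbance values must be finite.")
  grids <- split(x$wavelength, x$sample)
  if (any(!vapply(grids, function(g) all(diff(g) > 0), logical(1)))) {
    abort("each spectrum's wavelength grid must be strictly increasing.")
  }
  if (length(unique(vapply(grids, length, integer(1)))) != 1L ||
      length(unique(lapply(grids, identity))) != 1L) {
    abort("all spectra must share one common wavelength grid.")
  }
  class(x) <- unique(c("uv_spectra", class(x)))
  x
}

# long tibble for one spectrum
new_spectrum <- function(sample, label, concentration, wavelength, absorbance) {
  tibble::tibble(
    sample = sample, label = label, concentration = concentration,
    wavelength = wavelength, absorbance = absorbance
  )
}

#' Sample-by-wavelength absorbance matrix of a spectra set
#'
#' @param spectra A [uv_spectra] object.
#' @return Numeric matrix with one row per sample (rownames = sample ids,
#'   colnames = wavelengths).
#' @export
spectra_matrix <- function(spectra) {
  wide <- tidyr::pivot_wider(
    dplyr::arrange(tibble::as_tibble(spectra), .data$sample, .data$wavelength),
    id_cols = "sample", names_from = "wavelength", values_from = "absorbance"
  )
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$sample
  m
}

#' Per-sample metadata of a spectra set
#'
#' @param spectra A [uv_spectra] object.
#' @return Tibble with columns `sample`, `label`, `concentration`.
#' @export
spectra_meta <- function(spectra) {
  dplyr::distinct(
    tibble::as_tibble(spectra), .data$sample, .data$label, .data$concentration
  )
}

spectra_grid <- function(spectra) {
  sort(unique(spectra$wavelength))
}

#' Read and write spectra as wide CSV
#'
#' The file format has a first `wavelength` column (nm) and one column
#' per sample whose header is `"label;concentration"`. Values round-trip
#' through write/read at full double precision.
#'
#' @param path File path.
#' @return `read_spectra_csv()`: a [uv_spectra] object.
#' @export
read_spectra_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  n_fields <- utils::count.fields(path, sep = ",")
  ragged <- which(n_fields != length(header))
  if (length(ragged) > 0L) {
    abort(sprintf("malformed spectra CSV: line %d of '%s' has %d fields, expected %d.",
                  ragged[1L], path, n_fields[ragged[1L]], length(header)))
  }
  body <- tryCatch(
    utils::read.csv(path, header = FALSE, skip = 1L, colClasses = "numeric"),
    error = function(e) abort(sprintf("malformed spectra CSV '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (ncol(body) < 2L) abort("spectra CSV needs at least one sample column.")
  wl <- body[[1L]]
  bad <- which(diff(wl) <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "wavelength column must be strictly increasing; violated at line %d (%g nm).",
      bad[1L] + 2L, wl[bad[1L] + 1L]
    ))
  }
  meta <- strsplit(header[-1L], ";", fixed = TRUE)
  labels <- vapply(meta, `[`, character(1), 1L)
  conc <- vapply(meta, function(f) {
    if (length(f) >= 2L) suppressWarnings(as.numeric(f[2L])) else NA_real_
  }, double(1))
  n <- length(labels)
  uv_spectra(purrr::map_dfr(seq_len(n), function(i) {
    new_spectrum(sprintf("s%03d", i), labels[i], conc[i], wl, body[[i + 1L]])
  }))
}

#' @rdname read_spectra_csv
#' @param spectra A [uv_spectra] object.
#' @export
write_spectra_csv <- function(spectra, path) {
  spectra <- uv_spectra(spectra)
  meta <- spectra_meta(spectra)
  m <- spectra_matrix(spectra)
  m <- m[meta$sample, , drop = FALSE]
  header <- c("wavelength", paste(meta$label, meta$concentration, sep = ";"))
  wide <- cbind(spectra_grid(spectra), t(m))
  lines <- c(
    paste(header, collapse = ","),
    apply(wide, 1L, function(row) {
      paste(vapply(row, format_full, character(1)), collapse = ",")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

# decimal representation that round-trips a double exactly
format_full <- function(x) {
  s <- sprintf("%.15g", x)
  if (as.numeric(s) == x) s else sprintf("%.17g", x)
}

#' Average replicate scans into one spectrum
#'
#' Instrument acquisition scans each sample several times; this takes the
#' pointwise arithmetic mean of the replicates. Metadata (label,
#' concentration) is inherited from the first replicate.
#'
#' @param replicates A [uv_spectra] object whose samples are replicate
#'   scans of one solution, all on a common grid.
#' @param sample Sample id of the averaged spectrum.
#' @return A single-sample [uv_spectra] object.
#' @export
average_scans <- function(replicates, sample = "mean") {
  replicates <- uv_spectra(replicates)
  meta <- spectra_meta(replicates)
  avg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(replicates), .data$wavelength),
    absorbance = mean(.data$absorbance), .groups = "drop"
  )
  uv_spectra(new_spectrum(
    sample, meta$label[1L], meta$concentration[1L], avg$wavelength, avg$absorbance
  ))
}

#' @describeIn uv_spectra Spectra overlay plot coloured by class label.
#' @param object A `uv_spectra` object.
#' @param ... Unused.
#' @export
autoplot.uv_spectra <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$wavelength, .data$absorbance,
                 group = .data$sample, colour = .data$label)
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance", colour = "class") +
    ggplot2::theme_minimal()
}
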