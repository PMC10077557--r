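#' Gaussian absorption band
#'
#' One absorption band of a chromophore, modelled as a Gaussian in
#' wavelength with peak molar absorptivity `epsilon` (absorbance L/mol
#' for a unit path length) at `center`.
#'
#' @param center Peak position in nm, inside the measurement grid.
#' @param width Gaussian sigma in nm.
#' @param epsilon Peak molar absorptivity scale (> 0).
#' @return An object of class `uv_band`.
#' @export
uv_band <- function(center, width = 6, epsilon = 1e4) {
  check_scalar_number(center, "center")
  check_scalar_number(width, "width")
  check_scalar_number(epsilon, "epsilon")
  grid <- default_grid()
  if (center < min(grid) || center > max(grid)) {
    abort("band `center` must lie within the 190-400 nm grid.")
  }
  if (width <= 0) abort("band `width` must be > 0.")
  if (epsilon <= 0) abort("band `epsilon` must be > 0.")
  structure(list(center = center, width = width, epsilon = epsilon),
            class = "uv_band")
}

#' Component band model
#'
#' A named solute with one or more Gaussian absorption bands.
#'
#' @param name Component name.
#' @param bands List of [uv_band()] objects (at least one).
#' @return An object of class `uv_component`.
#' @export
uv_component <- function(name, bands) {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a string.")
  if (!is.list(bands) || length(bands) == 0L ||
      !all(vapply(bands, inherits, logical(1), "uv_band"))) {
    abort("`bands` must be a non-empty list of uv_band objects.")
  }
  structure(list(name = name, bands = bands), class = "uv_component")
}

#' Default band models for NaCl, NaOH and PEA
#'
#' Characteristic peaks: PEA at 210 and 258 nm, NaOH at 202 nm, NaCl at
#' 197 nm, with Gaussian widths of 6 nm. Peak absorptivities are chosen
#' once so that, at equal molar concentration, PEA absorbs most strongly
#' and NaCl most weakly, and so that the secondary 258 nm PEA band of a
#' mixture vanishes when the PEA mole fraction falls below 10 % m/m.
#'
#' @return Named list of three [uv_component()] models.
#' @export
default_components <- function() {
  list(
    NaCl = uv_component("NaCl", list(uv_band(197, 6, 2e4))),
    NaOH = uv_component("NaOH", list(uv_band(202, 6, 4e4))),
    PEA = uv_component("PEA", list(uv_band(210, 6, 6e4), uv_band(258, 6, 1.5e4)))
  )
}

# stated preparation ranges of the single-component solutions, mol/L
component_conc_ranges <- function() {
  list(
    NaCl = c(3.52e-6, 0.5),
    NaOH = c(7.62e-6, 0.5),
    PEA = c(3.06e-6, 8.91e-3)
  )
}

#' The seven-mixture design
#'
#' Component concentrations of the seven NaCl/NaOH/PEA mixtures, one row
#' per PEA mole-fraction class from 0 to 60 % m/m.
#'
#' @return Tibble with columns `fraction` (% m/m), `NaCl`, `NaOH`, `PEA`
#'   (mol/L).
#' @export
mixture_design <- function() {
  tibble::tibble(
    fraction = c(0, 10, 20, 30, 40, 50, 60),
    NaCl = c(1.24e-5, 1.54e-5, 2.67e-5, 3.24e-5, 4.45e-5, 3.15e-5, 1.95e-5),
    NaOH = c(3.92e-5, 4.09e-5, 1.07e-5, 7.7e-6, 4.7e-6, 1.5e-5, 1.46e-5),
    PEA = c(0, 6.25e-6, 9.36e-6, 1.72e-5, 3.28e-5, 4.65e-5, 5.12e-5)
  )
}

#' Instrument noise surrogate
#'
#' Additive Gaussian absorbance noise plus a slow non-negative baseline
#' drift (half-sine of random phase), emulating benchtop
#' spectrophotometer behaviour. The default sigma of 0.002 absorbance
#' units is typical of such instruments.
#'
#' @param sigma Standard deviation of the additive Gaussian noise (>= 0).
#' @param baseline_amplitude Amplitude of the slow drift (>= 0).
#' @param seed Optional seed used when noise is applied outside
#'   [generate_dataset()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.002, baseline_amplitude = 0.001, seed = NULL) {
  check_scalar_number(sigma, "sigma")
  check_scalar_number(baseline_amplitude, "baseline_amplitude")
  if (sigma < 0 || baseline_amplitude < 0) {
    abort("`sigma` and `baseline_amplitude` must be >= 0.")
  }
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(sigma = sigma, baseline_amplitude = baseline_amplitude, seed = seed),
    class = "noise_model"
  )
}

# noiseless Beer-Lambert absorbance of one component on a grid
component_absorbance <- function(component, concentration, grid) {
  a <- numeric(length(grid))
  for (band in component$bands) {
    a <- a + concentration * band$epsilon *
      exp(-(grid - band$center)^2 / (2 * band$width^2))
  }
  a
}

#' Noiseless single-component spectrum
#'
#' Beer-Lambert absorbance of one component at a given concentration:
#' the sum over its Gaussian bands of
#' `concentration * epsilon * exp(-(lambda - center)^2 / (2 width^2))`.
#'
#' @param component A [uv_component()].
#' @param concentration Molar concentration (>= 0).
#' @param grid Wavelength grid (default [default_grid()]).
#' @param sample Sample id for the returned spectrum.
#' @return A single-sample [uv_spectra] object.
#' @export
component_spectrum <- function(component, concentration, grid = default_grid(),
                               sample = component$name) {
  check_scalar_number(concentration, "concentration")
  if (concentration < 0) abort("`concentration` must be >= 0.")
  uv_spectra(new_spectrum(
    sample, component$name, concentration, grid,
    component_absorbance(component, concentration, grid)
  ))
}

#' Noiseless mixture spectrum by Beer-Lambert additivity
#'
#' Pointwise sum of the component spectra at the given concentrations.
#'
#' @param components List of [uv_component()] models.
#' @param concentrations Numeric vector of concentrations, one per
#'   component.
#' @param grid Wavelength grid.
#' @param label Class label of the mixture spectrum.
#' @param sample Sample id.
#' @param concentration Concentration metadata stored with the spectrum
#'   (defaults to the total molar concentration).
#' @return A single-sample [uv_spectra] object.
#' @export
mixture_spectrum <- function(components, concentrations, grid = default_grid(),
                             label = "mixture", sample = label,
                             concentration = sum(concentrations)) {
  if (length(components) != length(concentrations)) {
    abort("`components` and `concentrations` must have equal length.")
  }
  a <- numeric(length(grid))
  for (i in seq_along(components)) {
    a <- a + component_absorbance(components[[i]], concentrations[i], grid)
  }
  uv_spectra(new_spectrum(sample, label, concentration, grid, a))
}

# add seeded instrument noise to an absorbance matrix (rows = samples)
apply_noise <- function(m, noise, grid) {
  if (noise$sigma == 0 && noise$baseline_amplitude == 0) return(m)
  for (i in seq_len(nrow(m))) {
    drift <- 0
    if (noise$baseline_amplitude > 0) {
      phase <- runif(1L, 0, 2 * pi)
      drift <- noise$baseline_amplitude *
        (1 + sin(2 * pi * (grid - grid[1L]) / diff(range(grid)) + phase)) / 2
    }
    m[i, ] <- m[i, ] + drift + rnorm(ncol(m), sd = noise$sigma)
  }
  m
}

#' Generate a synthetic train/test spectra dataset
#'
#' Emulates the study's sample plan. For `classes = "components"`, each
#' of NaCl, NaOH and PEA gets `n_per_class` solutions with
#' concentrations drawn log-uniformly within the stated preparation
#' ranges (0.00000352-0.5, 0.00000762-0.5 and 0.00000306-0.00891 mol/L
#' respectively). For `classes = "mixtures"`, each of the seven
#' mole-fraction classes gets `n_per_class` solutions whose component
#' concentrations jitter the design row by +/-20 % (log-uniform).
#' Instrument noise is added and a stratified seeded split assigns
#' `round(n_per_class * train_fraction)` samples per class to the
#' training set (20/10 with the defaults).
#'
#' @param classes `"components"` or `"mixtures"`.
#' @param n_per_class Samples per class (>= 2); default 30.
#' @param noise A [noise_model()].
#' @param train_fraction Fraction of each class used for training.
#' @param seed Seed controlling concentrations, noise and the split.
#' @param components Band models (default [default_components()]).
#' @param design Mixture design table (default [mixture_design()]).
#' @param grid Wavelength grid.
#' @return List with `train` and `test` [uv_spectra] objects.
#' @examples
#' d <- generate_dataset(classes = "components", n_per_class = 4, seed = 1)
#' dplyr::count(spectra_meta(d$train), label)
#' @export
generate_dataset <- function(classes = c("mixtures", "components"),
                             n_per_class = 30L, noise = noise_model(),
                             train_fraction = 2 / 3, seed = NULL,
                             components = default_components(),
                             design = mixture_design(), grid = default_grid()) {
  classes <- match.arg(classes)
  n_per_class <- check_count(n_per_class, "n_per_class", min = 2L)
  if (length(components) == 0L) abort("`components` must be non-empty.")
  if (classes == "mixtures" && nrow(design) == 0L) {
    abort("`design` must have at least one mixture row.")
  }
  seed <- seed %||% noise$seed
  if (!is.null(seed)) set.seed(seed)

  if (classes == "components") {
    ranges <- component_conc_ranges()[names(components)]
    specs <- purrr::imap(components, function(comp, nm) {
      rg <- ranges[[nm]] %||% abort(sprintf("no concentration range for '%s'.", nm))
      conc <- exp(runif(n_per_class, log(rg[1L]), log(rg[2L])))
      a <- t(vapply(conc, function(cc) component_absorbance(comp, cc, grid),
                    numeric(length(grid))))
      list(label = nm, conc = conc, absorbance = a)
    })
  } else {
    comp_list <- components[c("NaCl", "NaOH", "PEA")]
    specs <- purrr::pmap(design, function(fraction, NaCl, NaOH, PEA) {
      base <- c(NaCl, NaOH, PEA)
      conc_mat <- t(vapply(seq_len(n_per_class), function(i) {
        base * exp(runif(3L, log(0.8), log(1.2))) * (base > 0)
      }, numeric(3L)))
      a <- t(vapply(seq_len(n_per_class), function(i) {
        Reduce(`+`, purrr::map2(comp_list, conc_mat[i, ], function(comp, cc) {
          component_absorbance(comp, cc, grid)
        }))
      }, numeric(length(grid))))
      list(label = sprintf("%g", fraction), conc = rowSums(conc_mat), absorbance = a)
    })
  }

  n_train <- round(n_per_class * train_fraction)
  if (n_train < 1L || n_train >= n_per_class) {
    abort("`train_fraction` must leave at least one sample in each split.")
  }

  rows <- purrr::imap(specs, function(sp, idx) {
    a <- apply_noise(sp$absorbance, noise, grid)
    in_train <- seq_len(n_per_class) %in% sample.int(n_per_class, n_train)
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      dplyr::mutate(
        new_spectrum(
          sprintf("%s_%02d", sp$label, i), sp$label, sp$conc[i], grid, a[i, ]
        ),
        .split = in_train[i]
      )
    })
  })
  all_rows <- dplyr::bind_rows(rows)
  train <- uv_spectra(dplyr::select(dplyr::filter(all_rows, .data$.split), -".split"))
  test <- uv_spectra(dplyr::select(dplyr::filter(all_rows, !.data$.split), -".split"))
  list(train = train, test = test)
}
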