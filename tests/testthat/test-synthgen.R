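test_that("component spectra follow Beer-Lambert linearity", {
  pea <- default_components()$PEA
  zero <- component_spectrum(pea, 0)
  expect_true(all(zero$absorbance == 0))

  one <- component_spectrum(pea, 1e-5)
  two <- component_spectrum(pea, 2e-5)
  expect_equal(two$absorbance, 2 * one$absorbance)
})

test_that("characteristic peaks sit at the published positions", {
  grid <- default_grid()
  comps <- default_components()
  local_maxima <- function(a) {
    which(diff(sign(diff(a))) == -2) + 1L
  }
  pea <- component_spectrum(comps$PEA, 1.67e-5, grid)
  peaks <- grid[local_maxima(pea$absorbance)]
  expect_true(210 %in% peaks)
  expect_true(258 %in% peaks)
  naoh <- component_spectrum(comps$NaOH, 1.67e-5, grid)
  expect_equal(grid[which.max(naoh$absorbance)], 202)
  nacl <- component_spectrum(comps$NaCl, 1.67e-5, grid)
  expect_equal(grid[which.max(nacl$absorbance)], 197)

  # at equal concentration PEA absorbs most strongly, NaCl most weakly
  expect_gt(max(pea$absorbance), max(naoh$absorbance))
  expect_gt(max(naoh$absorbance), max(nacl$absorbance))
})

test_that("mixture spectra are additive and lose the 258 nm peak at low PEA", {
  comps <- default_components()
  grid <- default_grid()
  design <- mixture_design()

  a <- mixture_spectrum(comps[c("NaCl", "NaOH")], c(1e-5, 2e-5), grid)
  b <- mixture_spectrum(comps["PEA"], 3e-5, grid)
  ab <- mixture_spectrum(comps[c("NaCl", "NaOH", "PEA")], c(1e-5, 2e-5, 3e-5), grid)
  expect_equal(ab$absorbance, a$absorbance + b$absorbance)
  single <- mixture_spectrum(comps["PEA"], 3e-5, grid)
  expect_equal(single$absorbance, component_spectrum(comps$PEA, 3e-5, grid)$absorbance)

  has_258_peak <- function(fraction) {
    row <- design[design$fraction == fraction, ]
    mx <- mixture_spectrum(comps[c("NaCl", "NaOH", "PEA")],
                           c(row$NaCl, row$NaOH, row$PEA), grid)
    win <- mx$absorbance[grid >= 250 & grid <= 266]
    i <- which.max(win)
    i > 1 && i < length(win) && (max(win) - min(win)) > 0.002
  }
  # the secondary PEA band is visible at 10 % m/m and above, gone below
  expect_false(has_258_peak(0))
  expect_true(has_258_peak(10))
  expect_true(has_258_peak(60))
})

test_that("generated datasets honour the sample plan and the seed", {
  d <- generate_dataset(classes = "mixtures", n_per_class = 30, seed = 7)
  meta_tr <- spectra_meta(d$train)
  meta_te <- spectra_meta(d$test)
  expect_equal(nrow(meta_tr), 7 * 20)
  expect_equal(nrow(meta_te), 7 * 10)
  expect_true(all(table(meta_tr$label) == 20))
  expect_true(all(table(meta_te$label) == 10))

  d2 <- generate_dataset(classes = "mixtures", n_per_class = 30, seed = 7)
  expect_identical(d, d2)

  d3 <- generate_dataset(classes = "mixtures", n_per_class = 30, seed = 8)
  expect_false(identical(d$train$absorbance, d3$train$absorbance))

  expect_error(generate_dataset(n_per_class = 1), ">= 2")
})

test_that("noiseless generation is exact and non-negative", {
  quiet <- noise_model(sigma = 0, baseline_amplitude = 0)
  d <- generate_dataset(classes = "components", n_per_class = 4,
                        noise = quiet, seed = 12)
  all_spec <- dplyr::bind_rows(d$train, d$test)
  expect_true(all(all_spec$absorbance >= 0))

  # each sample equals its noiseless band model at the recorded concentration
  comps <- default_components()
  meta <- spectra_meta(all_spec)
  for (i in seq_len(nrow(meta))) {
    want <- component_spectrum(comps[[meta$label[i]]], meta$concentration[i])
    got <- dplyr::filter(tibble::as_tibble(all_spec), .data$sample == meta$sample[i])
    expect_equal(got$absorbance, want$absorbance)
  }

  # mixture concentrations jitter the design by at most 20 percent
  dm <- generate_dataset(classes = "mixtures", n_per_class = 5,
                         noise = quiet, seed = 3)
  design <- mixture_design()
  total <- design$NaCl + design$NaOH + design$PEA
  meta_m <- spectra_meta(dm$train)
  for (i in seq_len(nrow(meta_m))) {
    base <- total[design$fraction == as.numeric(meta_m$label[i])]
    expect_gt(meta_m$concentration[i], 0.8 * base)
    expect_lt(meta_m$concentration[i], 1.2 * base)
  }
})

test_that("class shapes separate perfectly once amplitude is factored out", {
  # noiseless single-component spectra lie on one ray per class; after
  # normalising each spectrum to unit norm the classes collapse to three
  # points, and a nearest-centroid rule on 3 principal-component scores
  # classifies every sample correctly
  quiet <- noise_model(sigma = 0, baseline_amplitude = 0)
  d <- generate_dataset(classes = "components", n_per_class = 10,
                        noise = quiet, seed = 5)
  x <- spectra_matrix(d$train)
  xn <- x / sqrt(rowSums(x^2))
  labs <- spectra_meta(d$train)$label
  norm_spec <- uv_spectra(purrr::map_dfr(seq_len(nrow(xn)), function(i) {
    tibble::tibble(sample = rownames(xn)[i], label = labs[i],
                   concentration = NA_real_,
                   wavelength = default_grid(), absorbance = xn[i, ])
  }))
  m <- fit_pca(norm_spec, k = 3)
  sc <- as.matrix(m$scores[paste0("PC", 1:3)])
  cen <- rowsum(sc, m$scores$label) / as.vector(table(m$scores$label))
  pred <- rownames(cen)[apply(sc, 1L, function(v) {
    which.min(colSums((t(cen) - v)^2))
  })]
  expect_equal(mean(pred == m$scores$label), 1)
})
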