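test_that("constructors enforce band and chemistry invariants", {
  expect_error(lorentz_band(-10, 60, 0.1), "center")
  expect_error(lorentz_band(1500, 0, 0.1), "width")
  expect_error(lorentz_band(1500, 60, -0.1), "amplitude")
  expect_error(chemistry_model(list(lorentz_band(1500, 60, 0.1)),
                               n_offset = 0.9), "n_offset")
  expect_error(chemistry_model(list(lorentz_band(1500, 60, 0.1),
                                    lorentz_band(1500, 30, 0.2))),
               "distinct")
  # bands come back sorted by center
  chem <- chemistry_model(list(lorentz_band(3000, 60, 0.1),
                               lorentz_band(1500, 60, 0.1)))
  expect_equal(band_centers(chem), c(1500, 3000))
})

test_that("imaginary index is the Lorentzian band sum", {
  grid <- default_grid()
  # empty chemistry: zero everywhere
  expect_equal(synth_imag_index(chemistry_model(), grid),
               numeric(length(grid)))
  # single band: amplitude at center, half amplitude at center +/- width/2
  chem <- chemistry_model(list(lorentz_band(3000, 60, 0.08)))
  k <- synth_imag_index(chem, grid)
  expect_equal(k[grid == 3000], 0.08)
  expect_equal(k[grid == 3030], 0.04)
  expect_equal(k[grid == 2970], 0.04)
  # default chemistry: local maxima at the grid-nearest band positions
  kd <- synth_imag_index(default_chemistry(), grid)
  n <- length(kd)
  locmax <- which(kd[2:(n - 1)] > kd[1:(n - 2)] & kd[2:(n - 1)] > kd[3:n]) + 1L
  expect_equal(grid[locmax], c(1500, 2010, 3000, 5400))
})

test_that("grid preconditions are enforced and out-of-grid bands warn", {
  chem <- chemistry_model(list(lorentz_band(8000, 60, 0.1)))
  expect_error(synth_imag_index(chem, numeric(0)), "empty")
  expect_error(synth_imag_index(chem, c(2000, 1000)), "increasing")
  expect_warning(k <- synth_imag_index(chem, default_grid()), "outside")
  expect_true(all(k > 0))   # tails still evaluated
})

test_that("analytic Lorentz oscillator agrees with the band sum and stays physical", {
  grid <- default_grid()
  # zero bands: constant offset
  m0 <- lorentz_complex_analytic(chemistry_model(n_offset = 1.4), grid)
  expect_equal(m0$n, rep(1.4, length(grid)))
  expect_equal(m0$k, numeric(length(grid)))
  # imaginary part identical to synth_imag_index to machine precision
  chem <- default_chemistry()
  ma <- lorentz_complex_analytic(chem, grid)
  expect_rel_equal(ma$k, synth_imag_index(chem, grid), 1e-12)
  # property: k >= 0 and n > 0 over randomized band sets
  set.seed(7)
  for (rep in 1:20) {
    nb <- sample(1:6, 1)
    bands <- lapply(seq_len(nb), function(i)
      lorentz_band(stats::runif(1, 1200, 5800), stats::runif(1, 20, 200),
                   stats::runif(1, 0, 0.3)))
    centers <- vapply(bands, `[[`, numeric(1), "center")
    if (anyDuplicated(centers)) next
    chem_r <- chemistry_model(bands, n_offset = stats::runif(1, 1.2, 1.8))
    mr <- lorentz_complex_analytic(chem_r, grid)
    expect_true(all(mr$k >= 0))
    expect_true(all(mr$n > 0))
  }
})

test_that("shift_bands moves only the listed centers and is invertible", {
  chem <- default_chemistry()
  mapping <- c("1500" = 1520, "2010" = 1950, "3000" = 3500, "5400" = 5350)
  shifted <- shift_bands(chem, mapping)
  expect_equal(band_centers(shifted), c(1520, 1950, 3500, 5350))
  # widths and amplitudes preserved
  expect_equal(vapply(shifted$bands, `[[`, numeric(1), "width"),
               vapply(chem$bands, `[[`, numeric(1), "width"))
  expect_equal(vapply(shifted$bands, `[[`, numeric(1), "amplitude"),
               vapply(chem$bands, `[[`, numeric(1), "amplitude"))
  # empty mapping: identity
  expect_identical(shift_bands(chem, numeric(0)), chem)
  # applying the inverse mapping restores the original
  inverse <- stats::setNames(as.numeric(names(mapping)),
                             as.character(unname(mapping)))
  expect_equal(shift_bands(shifted, inverse), chem)
  # unknown center is reported by value
  expect_error(shift_bands(chem, c("1501" = 1520)), "1501")
})
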