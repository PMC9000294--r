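test_that("tdm_total reproduces the printed 'tot' column from components", {
  expect_equal(tdm_total(c(-20.635, 1.344, 0)), 20.679, tolerance = 0.002 / 20.679)
  expect_equal(tdm_total(c(-19.844, 0.109, -0.003)), 19.845,
               tolerance = 0.002 / 19.845)
  expect_equal(tdm_total(c(0, 0, 0)), 0)
  expect_error(tdm_total(transition(2, 1)), "no transition-dipole")
})

test_that("the oscillator-strength relation matches the tabulated f values", {
  expect_equal(oscillator_strength_from_tdm(2.249, 19.845), 3.363,
               tolerance = 0.002)   # within 0.2% of the printed value
  expect_equal(oscillator_strength_from_tdm(2.599, 20.057), 3.970,
               tolerance = 0.002)
  expect_equal(oscillator_strength_from_tdm(2.5, 0), 0)
  expect_error(oscillator_strength_from_tdm(-1, 5), "positive")
})

test_that("every tabulated transition row is internally consistent at 1%", {
  trn <- load_reference_table("transitions")
  for (i in seq_len(nrow(trn))) {
    t <- transition(trn$e01[i], trn$f[i],
                    tdm = c(trn$mu01_x[i], trn$mu01_y[i], trn$mu01_z[i]),
                    wavelength = trn$lambda01[i])
    v <- validate_transition(t, rel_tol = 0.01)
    expect_true(v$pass, label = sprintf("row %d (%s/%s/%s)", i, trn$molecule[i],
                                        trn$functional[i], trn$medium[i]))
  }
})

test_that("validation fails loudly on corrupted fields and tightly on synthetic ones", {
  trn <- load_reference_table("transitions")
  bad <- transition(trn$e01[1], trn$f[1] * 2,
                    tdm = c(trn$mu01_x[1], trn$mu01_y[1], trn$mu01_z[1]),
                    wavelength = trn$lambda01[1])
  v <- validate_transition(bad, rel_tol = 0.01)
  expect_false(v$pass)
  expect_identical(v$failed_fields, "osc_strength")

  synth <- gen_transition(2.317, c(0.2, -1, 0.4), 19.665)
  expect_true(validate_transition(synth, rel_tol = 1e-9)$pass)
  expect_error(validate_transition(synth, rel_tol = 0), "rel_tol")
})

test_that("a single broadened transition peaks at its tabulated wavelength", {
  tr <- transition(2.317, 3.403)
  s <- suppressWarnings(broaden_spectrum(tr, from = 300, to = 800, n = 5001))
  expect_equal(peak_wavelength(s), 535.1, tolerance = 0.2 / 535.1)
  expect_equal(max(s$intensity), 1)  # normalized by default

  # energy-axis peak sits at the transition energy for assorted widths
  for (fwhm in c(0.1, 0.37, 0.8)) {
    se <- broaden_spectrum(tr, fwhm = fwhm, from = 2.317 - 3 * fwhm,
                           to = 2.317 + 3 * fwhm, n = 2001, axis = "energy")
    expect_equal(peak_wavelength(se), 2.317, tolerance = (6 * fwhm / 2000) / 2.317)
  }
})

test_that("broadening resolves, merges and scales transitions as expected", {
  # two equal-f transitions much closer than the width: one merged peak
  close_pair <- list(transition(2.45, 1), transition(2.55, 1))
  s1 <- broaden_spectrum(close_pair, from = 1.3, to = 3.7, n = 4001, axis = "energy")
  dens <- s1$intensity
  n_peaks <- sum(diff(sign(diff(dens))) == -2)
  expect_equal(n_peaks, 1L)
  expect_equal(peak_wavelength(s1), 2.5, tolerance = 1e-3)

  # separation of 5*FWHM: two resolved peaks at the energies, ratio 1
  e1 <- 2.0; e2 <- 2.0 + 5 * 0.37
  far_pair <- list(transition(e1, 1), transition(e2, 1))
  s2 <- broaden_spectrum(far_pair, from = 0.8, to = 5.1, n = 8001,
                         axis = "energy", normalize = FALSE)
  peaks <- which(diff(sign(diff(s2$intensity))) == -2) + 1L
  expect_length(peaks, 2L)
  step <- diff(s2$axis[1:2])
  expect_equal(s2$axis[peaks], c(e1, e2), tolerance = step / e1)
  expect_equal(s2$intensity[peaks[1]] / s2$intensity[peaks[2]], 1.0,
               tolerance = 1e-6)

  # linearity in f before normalization
  s3 <- broaden_spectrum(list(transition(2.0, 0.8), transition(2.3, 1.7)),
                         from = 0.8, to = 3.5, n = 501, axis = "energy",
                         normalize = FALSE)
  s4 <- broaden_spectrum(list(transition(2.0, 1.6), transition(2.3, 3.4)),
                         from = 0.8, to = 3.5, n = 501, axis = "energy",
                         normalize = FALSE)
  expect_equal(s4$intensity, 2 * s3$intensity, tolerance = 1e-12)
})

test_that("the integrated single-transition band matches f * sigma * sqrt(2*pi)", {
  f_osc <- 3.403; fwhm <- 0.37
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  s <- suppressWarnings(
    broaden_spectrum(transition(2.317, f_osc), fwhm = fwhm,
                     from = 2.317 - 6 * sigma, to = 2.317 + 6 * sigma,
                     n = 20001, axis = "energy", normalize = FALSE))
  integral <- sum((s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2) *
    diff(s$axis[1:2])
  expect_equal(integral, f_osc * sigma * sqrt(2 * pi), tolerance = 1e-3)
})

test_that("grid coverage and degenerate spectra are policed", {
  expect_error(broaden_spectrum(list(), axis = "energy"), "non-empty")
  expect_error(broaden_spectrum(transition(5.0, 1), from = 1, to = 4,
                                axis = "energy"), "does not cover")
  expect_warning(broaden_spectrum(transition(2.0, 1), from = 1.9, to = 2.1,
                                  n = 101, axis = "energy"), "truncates")

  flat <- spectrum_curve(1:10, rep(0, 10), "energy")
  expect_error(peak_wavelength(flat), "flat zero")

  # exact tie: resolved toward lower energy / longer wavelength, with warning
  twin_e <- spectrum_curve(c(1, 2, 3, 4), c(0.1, 5, 5, 0.1), "energy")
  expect_warning(pk <- peak_wavelength(twin_e), "tie")
  expect_equal(pk, 2)
  twin_l <- spectrum_curve(c(400, 500, 600, 700), c(0.1, 5, 5, 0.1), "wavelength")
  expect_warning(pk2 <- peak_wavelength(twin_l), "tie")
  expect_equal(pk2, 600)
})

test_that("the wavelength axis maps pointwise, with the Jacobian opt-in", {
  tr <- transition(2.5, 1)
  plain <- suppressWarnings(broaden_spectrum(tr, from = 350, to = 700, n = 7001))
  expect_equal(peak_wavelength(plain), ev_to_nm(2.5), tolerance = 0.1 / 496)
  jac <- suppressWarnings(broaden_spectrum(tr, from = 350, to = 700, n = 7001,
                                           jacobian = TRUE))
  # Jacobian weighting drags the band maximum to a shorter wavelength
  expect_lt(peak_wavelength(jac), peak_wavelength(plain))
})

test_that("solvent shift is the wavelength difference under matching contexts", {
  ctx_gas <- calc_context("CAM-B3LYP", "6-31+G(d,p)", "gas")
  ctx_sol <- calc_context("CAM-B3LYP", "6-31+G(d,p)", "chloroform")
  gas <- transition(2.831, 3.642, wavelength = 437.99, context = ctx_gas)
  sol <- transition(2.624, 3.802, wavelength = 472.53, context = ctx_sol)
  expect_equal(solvent_shift(gas, sol), 34.54, tolerance = 1e-9)

  t0 <- transition(2.5, 1)
  expect_equal(solvent_shift(t0, t0), 0)

  ctx_other <- calc_context("B3LYP", "6-31+G(d,p)", "chloroform")
  expect_error(solvent_shift(gas, transition(2.6, 3.8, context = ctx_other)),
               "context mismatch")
  expect_error(solvent_shift(sol, sol), "not tagged with the gas medium")

  # every tabulated molecule/functional pair red-shifts in chloroform
  trn <- load_reference_table("transitions")
  for (m in unique(trn$molecule)) for (fn in unique(trn$functional)) {
    g <- trn[trn$molecule == m & trn$functional == fn & trn$medium == "gas", ]
    s <- trn[trn$molecule == m & trn$functional == fn & trn$medium == "chloroform", ]
    shift <- solvent_shift(
      transition(g$e01, g$f, wavelength = g$lambda01,
                 context = calc_context(fn, g$basis, "gas")),
      transition(s$e01, s$f, wavelength = s$lambda01,
                 context = calc_context(fn, s$basis, "chloroform")))
    expect_gt(shift, 0)
  }
})
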