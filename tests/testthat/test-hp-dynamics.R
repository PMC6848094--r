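hp_model <- function(...) {
  exchange_model(k_pyr_lac = 0.02, k_pyr_ala = 0.01, k_pyr_bic = 0.004,
                 k_pyr_mal1 = 0.0012, k_pyr_asp1 = 0.0008,
                 k_mal1_mal4 = 0.02, k_asp1_asp4 = 0.02,
                 bolus = list(dose = 1, duration = 5, hydrate_fraction = 0.08),
                 ...)
}

test_that("with no exchange the pyruvate signal obeys the pulsed decay law", {
  m <- exchange_model(t1 = 30, bolus = list(dose = 1, duration = 0,
                                            hydrate_fraction = 0))
  s <- simulate_hp_timeseries(m, acquisition_scheme(n_spectra = 12),
                              render_spectra = FALSE)
  n <- 0:11
  expected <- sin(20 * pi / 180) * (cos(20 * pi / 180) * exp(-2 / 30))^n
  expect_equal(unname(s$areas[, "pyruvate"]), expected, tolerance = 1e-12)
  expect_true(all(s$areas[, setdiff(colnames(s$areas), "pyruvate")] == 0))
})

test_that("conversion rates populate the product resonances", {
  m <- hp_model()
  s <- simulate_hp_timeseries(m, acquisition_scheme(n_spectra = 30))
  expect_gt(sum(s$areas[, "bicarbonate"]), 0)
  # bicarbonate appears at its 160.9 ppm window in the summed spectrum
  ss <- sum_spectra(s)
  a <- integrate_peaks(ss, list(bicarbonate = c(160.4, 161.4)))
  expect_gt(a[["bicarbonate"]], 0.01 * sum(s$areas[, "bicarbonate"]))
  # slow fumarase scrambling keeps summed malate C1 above malate C4
  tot <- colSums(s$areas)
  expect_gt(tot[["malate_C1"]], tot[["malate_C4"]])
  # total longitudinal magnetization never grows after the bolus ends
  tot_t <- rowSums(s$areas)
  after <- tot_t[s$time >= 5]
  expect_true(all(diff(after) <= 1e-12))
})

test_that("spectral summation is pointwise and consistent with area sums", {
  m <- hp_model()
  s <- simulate_hp_timeseries(m, acquisition_scheme(n_spectra = 10))
  one <- sum_spectra(s$spectra[3, , drop = FALSE], s$ppm)
  expect_equal(one$intensity, unname(s$spectra[3, ]))
  rep50 <- sum_spectra(s$spectra[rep(3, 50), ], s$ppm)
  expect_equal(rep50$intensity, 50 * unname(s$spectra[3, ]), tolerance = 1e-12)
  # summed-spectrum window areas match the time-summed per-acquisition areas
  areas <- integrate_peaks(sum_spectra(s), default_peak_windows(m))
  tot <- colSums(s$areas)
  for (met in c("pyruvate", "lactate", "alanine", "bicarbonate")) {
    expect_equal(areas[[met]], tot[[met]], tolerance = 0.02)
  }
})

test_that("peak integration matches the analytic Lorentzian area", {
  ppm <- seq(155, 190, length.out = 16384)
  hw <- 0.75 / 100.6
  spec <- data.frame(ppm = ppm,
                     intensity = (hw / pi) / ((ppm - 183.1)^2 + hw^2))
  a <- integrate_peaks(spec, list(lactate = c(182.6, 183.6)))
  expect_equal(a[["lactate"]], 1, tolerance = 0.02)
  # empty spectrum integrates to zero everywhere
  spec0 <- data.frame(ppm = ppm, intensity = 0)
  expect_true(all(integrate_peaks(spec0, list(a = c(160, 161), b = c(170, 171))) == 0))
  # disjoint windows are additive
  spec2 <- spec
  spec2$intensity <- spec2$intensity + (hw / pi) / ((ppm - 160.9)^2 + hw^2)
  a2 <- integrate_peaks(spec2, list(bic = c(160.4, 161.4),
                                    lac = c(182.6, 183.6)))
  expect_equal(sum(a2), pracma::trapz(ppm, spec2$intensity), tolerance = 0.03)
  expect_error(integrate_peaks(spec, list(a = c(160, 161), b = c(160.5, 162))),
               "overlap")
})

test_that("normalized fractions exclude the hydrate impurity", {
  areas <- c(pyruvate = 8, pyruvate_hydrate = 2, lactate = 2, bicarbonate = 0)
  nf <- normalize_fractions(areas)
  expect_equal(nf$fractions[["lactate"]], 0.2)
  expect_equal(sum(nf$fractions), 1)
  expect_equal(nf$bicarbonate_lactate_ratio, 0)
  only_lac <- c(pyruvate = 0, pyruvate_hydrate = 5, lactate = 3, bicarbonate = 0)
  nf2 <- normalize_fractions(only_lac)
  expect_equal(nf2$fractions[["lactate"]], 1)
  expect_error(normalize_fractions(c(pyruvate = 0, lactate = 0,
                                     bicarbonate = 0)))
})

test_that("quantifier round trip recovers the simulated area fractions", {
  m <- hp_model()
  s <- simulate_hp_timeseries(m, acquisition_scheme(), noise_sd = 0)
  got <- normalize_fractions(integrate_peaks(sum_spectra(s),
                                             default_peak_windows(m)))
  want <- normalize_fractions(colSums(s$areas))
  expect_equal(got$fractions, want$fractions, tolerance = 0.02)
  major <- want$fractions >= 0.02
  expect_lt(max(abs(got$fractions[major] - want$fractions[major]) /
                  want$fractions[major]), 0.02)
  expect_equal(got$bicarbonate_lactate_ratio, want$bicarbonate_lactate_ratio,
               tolerance = 0.02 * want$bicarbonate_lactate_ratio)
})
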