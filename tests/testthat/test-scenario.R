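table6 <- data.frame(
  total = c(6, 7.5, 8, 5.5, 6, 3.5, 4, 8, 9),
  outer = c(2.82, 3.53, 3.76, 2.59, 2.82, 1.65, 1.88, 3.76, 4.23),
  trab  = c(1.5, 1.88, 2, 1.38, 1.5, 0.88, 1, 2, 2.25),
  inner = c(1.68, 2.10, 2.24, 1.54, 1.68, 0.98, 1.12, 2.24, 2.52))

test_that("skull decomposition reproduces every tabulated geometry row", {
  for (i in seq_len(nrow(table6))) {
    lay <- decompose_skull(table6$total[i])
    expect_equal(round(unname(lay), 2),
                 c(table6$outer[i], table6$trab[i], table6$inner[i]),
                 label = sprintf("total %.1f mm", table6$total[i]))
    expect_equal(sum(lay), table6$total[i])  # components sum exactly
  }
  expect_equal(unname(decompose_skull(7.5)["outer"] /
                        decompose_skull(7.5)["inner"]), 1.68)
  expect_error(decompose_skull(0), "thickness")
  expect_error(decompose_skull(-3), "thickness")
})

test_that("scenario construction validates its geometric invariants", {
  sc <- head_scenario(skull_thickness = 6, roc = 65)
  expect_s3_class(sc, "head_scenario")
  expect_equal(sc$outer_cortical + sc$trabecular + sc$inner_cortical, 6)
  # inconsistent explicit layers rejected
  expect_error(head_scenario(skull_thickness = 6, roc = 65,
                             outer_cortical = 3, trabecular = 1,
                             inner_cortical = 1.5), "sum")
  # curvature must clear the aperture
  expect_error(head_scenario(skull_thickness = 6, roc = 30), "curvature")
  expect_error(head_scenario(skull_thickness = -1, roc = 65), "> 0")
})

test_that("regional presets populate layers and warn off-menu", {
  sc <- region_preset("temporal", 3.5, 65)
  expect_equal(round(c(sc$outer_cortical, sc$trabecular, sc$inner_cortical), 2),
               c(1.65, 0.88, 0.98))
  expect_equal(sc$aperture_diameter, 74)
  sc9 <- region_preset("occipital", 9, 75)
  expect_equal(sc9$trabecular, 2.25)
  expect_warning(region_preset("frontal", 6, 40), "44-97")
  expect_warning(region_preset("parietal", 7, 65), "menu")
  expect_error(region_preset("sphenoid", 4, 65), "unknown region")
})

test_that("tone bursts peak at the set amplitude with the spectrum at f0", {
  for (env in c("gaussian", "tukey")) {
    p <- synth_pulse(2e6, 1e6, n_cycles = 3, sample_rate = 80e6,
                     envelope = env)
    expect_equal(max(abs(p$pressures)), 1e6)
    expect_lt(abs(p$pressures[1]), 1e-2 * 1e6)
    expect_lt(abs(p$pressures[length(p$pressures)]), 1e-2 * 1e6)
    # discrete spectrum peak at f0: a short burst quantizes the padded-
    # transform peak to within a couple of fine bins, far inside the
    # burst's own single-bin width (sample_rate / n_samples)
    x <- c(p$pressures, numeric(2^14 - length(p$pressures)))
    sp <- Mod(stats::fft(x))[1:2^13]
    fr <- (seq_along(sp) - 1) * p$sample_rate / 2^14
    expect_lt(abs(fr[which.max(sp)] - 2e6),
              p$sample_rate / length(p$pressures))
  }
  expect_identical(max(abs(synth_pulse(2e6, 0, 3, 80e6)$pressures)), 0)
  expect_error(synth_pulse(2e6, 1e6, 3, sample_rate = 10e6), "undersample")
  expect_error(synth_pulse(2e6, 1e6, n_cycles = 0), "n_cycles")
})

test_that("pulse spectrum location agrees with the analytic burst spectrum", {
  # Gaussian burst: spectrum is a Gaussian centred at f0 with width ~ 1/sigma
  f0 <- 1e6; n <- 6; rate <- 60e6
  p <- synth_pulse(f0, 2e5, n_cycles = n, sample_rate = rate)
  probe_f <- seq(0.5e6, 1.5e6, by = 2.5e4)
  amp <- vapply(probe_f, function(ff)
    Mod(sum(p$pressures * exp(-2i * pi * ff * p$sample_times))), 0)
  sigma <- (n / f0) / 6
  oracle <- vapply(probe_f, function(ff)
    abs(sum(sin(2 * pi * f0 * p$sample_times) *
              exp(-0.5 * ((p$sample_times - n / f0 / 2) / sigma)^2) *
              exp(-2i * pi * ff * p$sample_times))), 0)
  expect_equal(probe_f[which.max(amp)], probe_f[which.max(oracle)])
})

test_that("scenarios and pulses round-trip through their file formats", {
  sc <- region_preset("parietal", 5.5, 75, source_frequency = 1e6)
  f <- tempfile(fileext = ".yaml")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(unclass(sc2), unclass(sc), tolerance = 1e-10)
  p <- synth_pulse(1e6, 1e6, 3)
  fc <- tempfile(fileext = ".csv")
  write_pulse_csv(p, fc)
  back <- utils::read.csv(fc)
  expect_equal(back$pressure_pa, p$pressures, tolerance = 1e-12)
})
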