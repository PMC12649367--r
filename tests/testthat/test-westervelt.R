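test_that("the stable step takes the per-class Courant minimum", {
  g <- grid_homogeneous("gel", 4, 6, 5e-4, 1e6)
  expect_equal(stable_timestep(g), 0.2 * 5e-4 / 1580)
  gb <- grid_homogeneous("cortical_bone", 4, 6, 5e-4, 1e6)
  expect_equal(stable_timestep(gb), 0.1 * 5e-4 / 3194)
  # refining dx by 2 halves dt
  g2 <- grid_homogeneous("gel", 4, 6, 2.5e-4, 1e6)
  expect_equal(stable_timestep(g2), stable_timestep(g) / 2)
  # mixed grid: the bone class bound dominates where bone is present
  sc <- region_preset("temporal", 4, 65, source_frequency = 0.5e6)
  gm <- rasterize(sc, N0 = 1)
  dt <- stable_timestep(gm)
  expect_lte(dt, 0.1 * gm$dx / 3194)
  cn <- cfl_numbers(gm, dt)
  expect_lte(cn[["soft"]], 0.2 + 1e-12)
  expect_lte(cn[["bone"]], 0.1 + 1e-12)
})

test_that("a quiescent state with a silent source stays quiescent", {
  g <- grid_homogeneous("brain", 10, 12, 5e-4, 1e6)
  g$source_mask <- plane_source_mask(g, 2)
  run <- westervelt_run(g, synth_pulse(1e6, 0, 3), duration = 2e-6)
  expect_identical(max(abs(run$envelope)), 0)
  expect_identical(max(abs(run$state$p)), 0)
})

test_that("lossless linear energy is conserved within 0.5%", {
  dx <- 2e-4
  g <- grid_homogeneous("brain", 60, 90, dx, 1e6, delta = 0, beta = 1)
  st <- time_state(g)
  st$p <- 1e5 * exp(-(outer((g$r - g$r[20])^2, rep(1, g$nz)) +
                       outer(rep(1, g$nr), (g$z - g$z[45])^2)) / (2 * (8 * dx)^2))
  dt <- stable_timestep(g)
  e0 <- acoustic_energy(st, g)
  for (i in 1:8) {
    st <- westervelt_step(st, g, dt, nsteps = 25, linear = TRUE)
    expect_lt(abs(acoustic_energy(st, g) / e0 - 1), 0.005)
  }
})

test_that("plane-wave decay matches the diffusivity attenuation within 2%", {
  f <- 1e6
  tab <- material_table()$gel
  g <- column_grid("gel", f, ppw = 24, length_m = 0.055, absorber_zhi = 48)
  pulse <- synth_pulse(f, 1e5, n_cycles = 25, sample_rate = 60 * f)
  k1 <- 200L; k2 <- 500L
  pr <- data.frame(label = c("a", "b"), i = 2L, k = c(k1, k2))
  run <- westervelt_run(g, pulse, probes = pr, linear = TRUE,
                        duration = 0.055 / tab$sos * 1.2 + 25 / f)
  ratio <- max(abs(run$probes$b$pressure)) / max(abs(run$probes$a$pressure))
  alpha <- attenuation_from_diffusivity(tissue_diffusivity("gel", f),
                                        tab$sos, f)
  expect_equal(ratio, exp(-alpha * (k2 - k1) * g$dx), tolerance = 0.02)
})

test_that("runs are deterministic and respect the stability guard", {
  g <- column_grid("brain", 1e6, ppw = 12, length_m = 0.01, absorber_zhi = 24)
  pulse <- synth_pulse(1e6, 1e6, 3)
  r1 <- westervelt_run(g, pulse, duration = 4e-6)
  r2 <- westervelt_run(g, pulse, duration = 4e-6)
  expect_identical(r1$envelope, r2$envelope)
  expect_identical(r1$state$p, r2$state$p)
  st <- time_state(g)
  expect_error(westervelt_step(st, g, stable_timestep(g) * 2), "stable")
})

test_that("the soft source radiates the pulse amplitude both ways", {
  # absorbers on both z ends: the sheet radiates amplitude A to each side
  f <- 1e6
  t <- material_table()$gel
  dx <- t$sos / f / 24
  nz <- round(0.03 / dx) + 96
  g <- grid_homogeneous("gel", 3, nz, dx, f,
                        absorber_cells = c(r = 0, zlo = 48, zhi = 48))
  ksrc <- 60L
  g$source_mask <- plane_source_mask(g, ksrc)
  pulse <- synth_pulse(f, 1e5, n_cycles = 12, envelope = "tukey")
  kp <- ksrc + 200L
  pr <- data.frame(label = "x", i = 2L, k = kp)
  run <- westervelt_run(g, pulse, probes = pr, linear = TRUE,
                        duration = 0.03 / t$sos + 13 / f,
                        source_model = "soft")
  alpha <- attenuation_from_diffusivity(tissue_diffusivity("gel", f),
                                        t$sos, f)
  expected <- 1e5 * exp(-alpha * 200 * dx)
  expect_equal(max(abs(run$probes$x$pressure)), expected, tolerance = 0.03)
})

test_that("local sound speed diagnostic is c0 + (beta - 1) u", {
  expect_identical(local_sos(1550, 1, 12), 1550)
  expect_identical(local_sos(1550, 4.65, 0), 1550)
  expect_equal(local_sos(1550, 4.65, 1), 1553.65)
})

test_that("probe placement outside the domain is refused", {
  g <- column_grid("gel", 1e6, ppw = 12, length_m = 0.01, absorber_zhi = 24)
  bad <- data.frame(label = "x", i = 2L, k = g$nz + 5L)
  expect_error(westervelt_run(g, synth_pulse(1e6, 1e6, 3), probes = bad),
               "outside")
})
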