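test_that("gel diffusivity follows 2 c^3 alpha / omega^2 with 1/f^2 scaling", {
  expect_equal(gel_diffusivity(7, 1580, 1e6), 0.001399, tolerance = 1e-3)
  expect_equal(gel_diffusivity(7, 1580, 0.5e6), 0.005595, tolerance = 1e-3)
  expect_identical(gel_diffusivity(0, 1580, 1e6), 0)
  # exact 1/f^2 scaling at fixed alpha
  d1 <- gel_diffusivity(7, 1580, 1e6)
  expect_equal(gel_diffusivity(7, 1580, 0.5e6), 4 * d1)
  expect_equal(gel_diffusivity(7, 1580, 5e6), d1 / 25)
  expect_error(gel_diffusivity(7, -1, 1e6), "c0")
  expect_error(gel_diffusivity(7, 1580, 0), "f")
  expect_error(gel_diffusivity(-1, 1580, 1e6), "alpha")
})

test_that("attenuation_from_diffusivity inverts the gel relation", {
  expect_equal(attenuation_from_diffusivity(0, 1580, 1e6), 0)
  expect_equal(attenuation_from_diffusivity(0.001399, 1580, 1e6), 7,
               tolerance = 1e-2 / 7)
  # algebraic round trip at machine precision over assorted parameters
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.1, 200); c0 <- runif(1, 500, 4000); f <- runif(1, 2e5, 6e6)
    expect_equal(
      attenuation_from_diffusivity(gel_diffusivity(a, c0, f), c0, f), a)
  }
})

test_that("material table carries the five tissues with printed constants", {
  tab <- material_table()
  expect_named(tab, c("gel", "skin", "cortical_bone", "trabecular_bone",
                      "brain"))
  tb <- tab$trabecular_bone
  expect_equal(tb$density, 572)
  expect_equal(tb$sos, 2325)
  expect_equal(tb$b_over_a, 80.6)
  expect_equal(unname(tab$brain$diffusivity["5MHz"]), 0.0003635)
  expect_error(tissue_diffusivity("bone_marrow", 1e6), "unknown tissue")
  # diffusivity strictly decreasing in frequency for every tissue
  for (t in tab) expect_true(all(diff(t$diffusivity) < 0), label = t$name)
})

test_that("tissue diffusivity interpolates log-log between tabulated points", {
  expect_identical(tissue_diffusivity("cortical_bone", 2e6), 0.043824)
  expect_identical(tissue_diffusivity("skin", 1e6), 0.0026709)
  # closed-form power law through the bracketing (1, 2) MHz pair
  d1 <- 0.0026709; d2 <- 0.001542
  n <- log(d2 / d1) / log(2)
  expect_equal(tissue_diffusivity("skin", 1.5e6), d1 * 1.5^n,
               tolerance = 1e-12)
  expect_error(tissue_diffusivity("skin", 0.4e6), "range")
  expect_error(tissue_diffusivity("skin", 6e6), "range")
})

test_that("nonlinearity coefficient is 1 + B/2A, affine and order-preserving", {
  expect_identical(nonlinearity_coefficient(0), 1)
  expect_identical(nonlinearity_coefficient(7), 4.5)
  expect_identical(nonlinearity_coefficient(80.6), 41.3)
  x <- seq(0, 100, by = 7.3)
  expect_true(all(diff(nonlinearity_coefficient(x)) > 0))
  # affine: second differences vanish
  expect_equal(diff(diff(nonlinearity_coefficient(x))), rep(0, length(x) - 2))
  expect_error(nonlinearity_coefficient(-1), "b_over_a")
})

test_that("equivalent fluid reduces to (rho, c) without loss and recovers
          the diffusivity attenuation in the small-loss regime", {
  tab <- material_table()
  ef0 <- equivalent_fluid("gel", 1e6, delta = 0)
  expect_identical(ef0$rho_c, complex(real = 1020))
  expect_identical(ef0$c_c, complex(real = 1580))
  # gel at 1 MHz: |Im(omega/cc)| recovers alpha = 7 1/m within 2%
  ef <- equivalent_fluid("gel", 1e6)
  alpha <- abs(Im(2 * pi * 1e6 / ef$c_c))
  expect_equal(alpha, 7, tolerance = 0.02)
  # cortical bone at 0.5 MHz: real part of cc within 5% of c, no speed-up
  efc <- equivalent_fluid("cortical_bone", 0.5e6)
  expect_lt(abs(Re(efc$c_c) - 3194) / 3194, 0.05)
  # all tissues, all tabulated frequencies: small-loss attenuation matches
  # delta omega^2 / (2 c^3) within 2% wherever eps <= 0.1
  for (nm in names(tab)) {
    for (fmhz in c(0.5, 1, 2, 4, 5)) {
      f <- fmhz * 1e6
      ef <- equivalent_fluid(nm, f)
      if (ef$eps > 0.1) next
      a_ef <- abs(Im(2 * pi * f / ef$c_c))
      a_ref <- attenuation_from_diffusivity(
        tissue_diffusivity(nm, f), tab[[nm]]$sos, f)
      expect_equal(a_ef, a_ref, tolerance = 0.02,
                   label = sprintf("%s at %g MHz", nm, fmhz))
    }
  }
})
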