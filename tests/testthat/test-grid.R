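test_that("mesh spacing follows c_min / (6 N0 f0)", {
  expect_equal(mesh_spacing(1550, 2, 0.5e6), 1550 / (6 * 2 * 0.5e6))
  expect_equal(mesh_spacing(1550, 1, 2e6), 1550 / 12e6)
})

test_that("rasterized axis column is ordered gel-skin-cortical-trabecular-
          cortical-brain with layer counts matching the thicknesses", {
  sc <- region_preset("frontal", 8, 65, source_frequency = 0.5e6)
  g <- rasterize(sc, N0 = 1)
  ax <- rle(g$material_index[1, ])
  expect_identical(ax$values, c(1L, 2L, 3L, 4L, 5L, 6L))
  # signed-distance oracle on the axis: material from the arc radii directly
  mm <- 1e-3
  zcen <- (sc$gel_thickness + sc$skin_thickness + sc$roc) * mm
  d <- zcen - g$z   # axis distance to the arc centre
  roc <- sc$roc * mm
  expected <- ifelse(d > roc + sc$skin_thickness * mm, 1L,
              ifelse(d > roc, 2L,
              ifelse(d > roc - sc$outer_cortical * mm, 3L,
              ifelse(d > roc - (sc$outer_cortical + sc$trabecular) * mm, 4L,
              ifelse(d > roc - sc$skull_thickness * mm, 5L, 6L)))))
  expect_identical(g$material_index[1, ], expected)
  # per-layer axial cell counts reproduce thicknesses within one cell
  th_mm <- c(sc$skin_thickness, sc$outer_cortical, sc$trabecular,
             sc$inner_cortical)
  for (j in seq_along(th_mm))
    expect_lt(abs(ax$lengths[j + 1] * g$dx * 1e3 - th_mm[j]), g$dx * 1e3)
})

test_that("material fields are consistent with the tissue table at f0", {
  sc <- region_preset("temporal", 4, 75, source_frequency = 1e6)
  g <- rasterize(sc, N0 = 1)
  tab <- material_table()
  i <- which(g$material_index == 4L)[1]  # a trabecular cell
  expect_equal(g$rho[i], tab$trabecular_bone$density)
  expect_equal(g$c0[i], tab$trabecular_bone$sos)
  expect_equal(g$delta[i], tissue_diffusivity("trabecular_bone", 1e6))
  expect_equal(g$beta[i], nonlinearity_coefficient(80.6))
  # every cell maps to exactly one material; absorber is a mask, not a medium
  expect_true(all(g$material_index %in% 1:6))
  expect_true(all(g$absorber$dnorm >= 0 & g$absorber$dnorm <= 1))
})

test_that("cell budget violations report the required spacing", {
  sc <- region_preset("frontal", 8, 65, source_frequency = 4e6)
  expect_error(rasterize(sc, N0 = 2, cell_budget = 1e4), "required dx")
})

test_that("rasterized layer areas converge to the fine-lattice area", {
  sc <- region_preset("temporal", 4, 65, source_frequency = 0.5e6)
  area_of <- function(dx) {
    g <- rasterize(sc, N0 = 1, dx = dx)
    sum(g$material_index %in% 3:5) * g$dx^2   # skull cross-section, m^2
  }
  a1 <- area_of(8e-4); a2 <- area_of(4e-4); a0 <- area_of(1.5e-4)
  expect_lt(abs(a2 - a0), abs(a1 - a0))          # refinement improves
  expect_lt(abs(a2 - a0) / a0, 0.05)
})

test_that("cap source marks one cell per column with sub-cell delays", {
  sc <- region_preset("temporal", 4, 65, source_frequency = 0.5e6)
  g <- rasterize(sc, N0 = 1)
  counts <- rowSums(g$source_mask)
  inside <- g$r <= sc$aperture_diameter / 2 * 1e-3
  expect_true(all(counts[inside] == 1))
  expect_true(all(counts[!inside] == 0))
  # the cap curves toward the head: z of the source cell increases with r
  kcap <- apply(g$source_mask[inside, ], 1, which)
  expect_true(all(diff(kcap) >= 0))
  # staircase-compensation delays are below one cell of travel time
  tau <- g$source_delay[g$source_mask]
  expect_true(all(abs(tau) <= g$dx / min(g$c0) + 1e-15))
})

test_that("scenario grids expose the four standard probes on the axis", {
  g <- rasterize(region_preset("temporal", 4, 65, source_frequency = 0.5e6),
                 N0 = 1)
  pr <- standard_probes(g)
  expect_identical(pr$label, c("source", "skin_skull", "skull_brain", "focus"))
  expect_true(all(pr$i == 1L))
  # interface probes sit at the interface depths within one cell
  expect_lt(abs(pr$z[2] - 0.013), g$dx)
  expect_lt(abs(pr$z[3] - 0.017), g$dx)
  expect_lt(abs(pr$z[4] - 0.065), g$dx)
})
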