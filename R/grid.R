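# Rasterization of head scenarios onto the axisymmetric computational grid.
#
# Conventions: uniform square cells (dr = dz = dx), cell-centered fields,
# r >= 0 with the symmetry axis at r = 0, z = 0 at the transducer apex and
# increasing into the head. All grid quantities are SI (m); scenarios are mm.

# material codes
.MAT_CODES <- c(gel = 1L, skin = 2L, outer_cortical = 3L, trabecular = 4L,
                inner_cortical = 5L, brain = 6L)
# tissue each material code draws its constants from
.MAT_TISSUE <- c("gel", "skin", "cortical_bone", "trabecular_bone",
                 "cortical_bone", "brain")

#' Mesh spacing rule
#'
#' `dx = c_min / (6 N0 f0)`: the cell size that resolves `N0` harmonics of
#' the fundamental `f0` in the slowest medium with six cells per wavelength.
#'
#' @param c_min slowest sound speed in the domain, m/s
#' @param N0 number of harmonics to resolve (integer >= 1)
#' @param f0 fundamental frequency, Hz
#' @return cell size, m
#' @export
mesh_spacing <- function(c_min, N0, f0) {
  stopifnot(c_min > 0, N0 >= 1, f0 > 0)
  c_min / (6 * N0 * f0)
}

.new_grid <- function(dx, nr, nz, f0, N0, material_index, rho, c0, delta,
                      beta, absorber, source_mask, brain_mask,
                      scenario = NULL) {
  structure(
    list(dx = dx, nr = nr, nz = nz,
         r = (seq_len(nr) - 0.5) * dx,
         z = attr(material_index, "z_centers"),
         f0 = f0, N0 = N0,
         material_index = material_index,
         material_names = names(.MAT_CODES),
         rho = rho, c0 = c0, delta = delta, beta = beta,
         absorber = absorber, source_mask = source_mask,
         brain_mask = brain_mask, scenario = scenario,
         c_min = min(c0), c_max = max(c0)),
    class = "grid_model")
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf("<grid_model> %d x %d cells (r x z), dx = %.4g mm, f0 = %.3g MHz\n",
              x$nr, x$nz, x$dx * 1e3, x$f0 / 1e6))
  cat(sprintf("  z span [%.1f, %.1f] mm, absorber width %.2f mm, %d source cells\n",
              min(x$z) * 1e3, max(x$z) * 1e3, x$absorber$width * 1e3,
              sum(x$source_mask)))
  invisible(x)
}

# quadratic normalized ramp 0 -> 1 across an absorber of n_abs cells at
# the ends of coordinate vector x (centers), used for both PML and sponge
.ramp <- function(x, lo, hi, width) {
  d <- pmax(lo - x, x - hi, 0)
  pmin(d / width, 1)
}

#' Rasterize a head scenario onto an axisymmetric grid
#'
#' Builds the computational domain: concentric circular-arc interfaces for
#' skin and the three skull layers (arcs of radius `roc` and inward offsets,
#' all centred on the axis), gel filling the transducer-to-skin space, brain
#' beyond the inner cortical table, and an absorbing ring of width
#' `absorber_wavelengths` wavelengths (at `f0` in the slowest medium) on the
#' open boundaries. Per-cell material fields are filled from
#' [material_table()] at `f0`; the transducer is a spherically focused cap
#' whose cells are marked in `source_mask`.
#'
#' @param scenario a [head_scenario()]
#' @param N0 harmonics to resolve in the mesh rule (default 2: fundamental
#'   plus second harmonic)
#' @param dx optional explicit cell size, m; default [mesh_spacing()]
#' @param cell_budget maximum allowed number of cells
#' @param absorber_wavelengths absorber ring width in slowest-medium
#'   wavelengths (>= 2 recommended)
#' @param margin_mm radial clearance between the aperture edge and the
#'   absorber, mm
#' @return a `grid_model`
#' @export
rasterize <- function(scenario, N0 = 2, dx = NULL, cell_budget = 2e6,
                      absorber_wavelengths = 2, margin_mm = 5) {
  sc <- validate_scenario(scenario)
  tab <- material_table()
  f0 <- sc$source_frequency
  c_all <- vapply(tab, function(t) t$sos, 0)
  c_min <- min(c_all)
  if (is.null(dx)) dx <- mesh_spacing(c_min, N0, f0)

  mm <- 1e-3
  g <- sc$gel_thickness * mm
  s <- sc$skin_thickness * mm
  Tsk <- sc$skull_thickness * mm
  t_oc <- sc$outer_cortical * mm
  t_tb <- sc$trabecular * mm
  roc <- sc$roc * mm
  a2 <- sc$aperture_diameter * mm / 2
  Fgeo <- sc$transducer_focal_length * mm
  z1 <- g + s                      # skin-skull interface on the axis
  zcen <- z1 + roc                 # common centre of the interface arcs
  Labs <- absorber_wavelengths * c_min / f0

  z_lo <- -Labs
  z_hi <- z1 + Tsk + sc$brain_depth * mm + Labs
  r_hi <- a2 + margin_mm * mm + Labs

  nr <- ceiling(r_hi / dx)
  nz <- ceiling((z_hi - z_lo) / dx)
  if (nr * nz > cell_budget)
    stop(sprintf(paste0("grid of %d x %d = %g cells exceeds the budget of %g; ",
                        "required dx = %.4g mm at f0 = %.3g MHz, N0 = %d"),
                 nr, nz, nr * nz, cell_budget, dx * 1e3, f0 / 1e6, N0))

  r <- (seq_len(nr) - 0.5) * dx
  z <- z_lo + (seq_len(nz) - 0.5) * dx

  # distance of each cell centre from the arc centre
  d <- sqrt(outer(r^2, (z - zcen)^2, "+"))
  mat <- matrix(.MAT_CODES[["gel"]], nr, nz)
  mat[d <= roc + s] <- .MAT_CODES[["skin"]]
  mat[d <= roc] <- .MAT_CODES[["outer_cortical"]]
  mat[d <= roc - t_oc] <- .MAT_CODES[["trabecular"]]
  mat[d <= roc - t_oc - t_tb] <- .MAT_CODES[["inner_cortical"]]
  mat[d <= roc - Tsk] <- .MAT_CODES[["brain"]]
  attr(mat, "z_centers") <- z

  tiss <- lapply(.MAT_TISSUE, function(nm) tab[[nm]])
  rho <- matrix(vapply(tiss, function(t) t$density, 0)[mat], nr, nz)
  c0 <- matrix(vapply(tiss, function(t) t$sos, 0)[mat], nr, nz)
  delta <- matrix(vapply(tiss, function(t) tissue_diffusivity(t, f0), 0)[mat],
                  nr, nz)
  beta <- matrix(nonlinearity_coefficient(
    vapply(tiss, function(t) t$b_over_a, 0))[mat], nr, nz)

  # absorber: normalized quadratic-ready distance fields on the three open
  # sides (outer r, both z ends)
  dr_norm <- .ramp(r, -Inf, r_hi - Labs, Labs)
  dz_norm <- .ramp(z, z_lo + Labs, z_hi - Labs, Labs)
  dnorm <- pmax(matrix(dr_norm, nr, nz), matrix(dz_norm, nr, nz, byrow = TRUE))
  absorber <- list(width = Labs, widths = c(r = Labs, zlo = Labs, zhi = Labs),
                   wavelengths = absorber_wavelengths,
                   r_norm = dr_norm, z_norm = dz_norm, dnorm = dnorm)

  # focused-cap source: one cell per radial column, on the bowl surface,
  # with per-cell time delays compensating the staircase snapping
  src <- matrix(FALSE, nr, nz)
  tau <- matrix(0, nr, nz)
  icols <- which(r <= a2)
  zcap <- Fgeo - sqrt(Fgeo^2 - r[icols]^2)
  kcap <- pmin(pmax(round((zcap - z_lo) / dx + 0.5), 1L), nz)
  src[cbind(icols, kcap)] <- TRUE
  c_src <- tab$gel$sos
  tau[cbind(icols, kcap)] <- (z[kcap] - zcap) / c_src

  brain_mask <- mat == .MAT_CODES[["brain"]] & dnorm == 0

  g <- .new_grid(dx, nr, nz, f0, N0, mat, rho, c0, delta, beta, absorber, src,
                 brain_mask, scenario = sc)
  g$source_delay <- tau
  g
}

#' Build a homogeneous grid (testing and verification oracles)
#'
#' A uniform single-tissue grid with optional loss/nonlinearity overrides and
#' a configurable absorber. By default there is no source; set one with
#' [plane_source_mask()] or by assigning `grid$source_mask`.
#'
#' @param tissue tissue name or [tissue_acoustics()] record
#' @param nr,nz grid dimensions
#' @param dx cell size, m
#' @param f0 reference frequency for the delta field, Hz
#' @param delta override diffusivity (scalar, m^2/s); `NULL` uses the tissue
#'   value at `f0`
#' @param beta override nonlinearity coefficient; `NULL` uses `1 + B/(2A)`
#' @param absorber_cells number of absorber cells per open side: a scalar
#'   (all of outer r and both z ends) or a named vector
#'   `c(r = , zlo = , zhi = )`; 0 disables a side
#' @return a `grid_model`
#' @export
grid_homogeneous <- function(tissue, nr, nz, dx, f0,
                             delta = NULL, beta = NULL, absorber_cells = 0L) {
  t <- .get_tissue(tissue)
  if (is.null(delta)) delta <- tissue_diffusivity(t, f0)
  if (is.null(beta)) beta <- nonlinearity_coefficient(t$b_over_a)
  code <- switch(t$name, gel = 1L, skin = 2L, cortical_bone = 3L,
                 trabecular_bone = 4L, 6L)
  mat <- matrix(code, nr, nz)
  z <- (seq_len(nz) - 0.5) * dx
  attr(mat, "z_centers") <- z
  r <- (seq_len(nr) - 0.5) * dx
  if (length(absorber_cells) == 1L)
    absorber_cells <- c(r = absorber_cells, zlo = absorber_cells,
                        zhi = absorber_cells)
  widths <- absorber_cells[c("r", "zlo", "zhi")] * dx
  widths[is.na(widths)] <- 0
  dr_norm <- if (widths[["r"]] > 0)
    .ramp(r, -Inf, nr * dx - widths[["r"]], widths[["r"]]) else numeric(nr)
  dz_lo <- if (widths[["zlo"]] > 0)
    .ramp(z, widths[["zlo"]], Inf, widths[["zlo"]]) else numeric(nz)
  dz_hi <- if (widths[["zhi"]] > 0)
    .ramp(z, -Inf, nz * dx - widths[["zhi"]], widths[["zhi"]]) else numeric(nz)
  dz_norm <- pmax(dz_lo, dz_hi)
  dnorm <- pmax(matrix(dr_norm, nr, nz), matrix(dz_norm, nr, nz, byrow = TRUE))
  absorber <- list(width = max(widths), widths = widths,
                   wavelengths = max(widths) * f0 / t$sos,
                   r_norm = dr_norm, z_norm = dz_norm, dnorm = dnorm)
  .new_grid(dx, nr, nz, f0, NA_integer_, mat,
            rho = matrix(t$density, nr, nz), c0 = matrix(t$sos, nr, nz),
            delta = matrix(delta, nr, nz), beta = matrix(beta, nr, nz),
            absorber = absorber, source_mask = matrix(FALSE, nr, nz),
            brain_mask = dnorm == 0, scenario = NULL)
}

#' Spherically focused cap source mask on an arbitrary grid
#'
#' Marks one cell per radial column on the bowl surface
#' `z = z_apex + F - sqrt(F^2 - r^2)`, out to the aperture radius.
#' [rasterize()] applies the same rule; this helper serves homogeneous
#' verification grids.
#'
#' @param grid a `grid_model`
#' @param aperture_diameter aperture diameter, m
#' @param focal_length geometric focal length, m
#' @param z_apex z of the cap apex, m
#' @return logical matrix usable as `grid$source_mask`
#' @export
cap_source_mask <- function(grid, aperture_diameter, focal_length,
                            z_apex = 0) {
  stopifnot(focal_length >= aperture_diameter / 2)
  m <- matrix(FALSE, grid$nr, grid$nz)
  z_lo <- grid$z[1] - grid$dx / 2
  icols <- which(grid$r <= aperture_diameter / 2)
  zcap <- z_apex + focal_length - sqrt(focal_length^2 - grid$r[icols]^2)
  kcap <- pmin(pmax(round((zcap - z_lo) / grid$dx + 0.5), 1L), grid$nz)
  m[cbind(icols, kcap)] <- TRUE
  # staircase compensation: delay of the snapped cell behind the true cap
  tau <- matrix(0, grid$nr, grid$nz)
  tau[cbind(icols, kcap)] <- (grid$z[kcap] - zcap) / grid$c0[cbind(icols, kcap)]
  attr(m, "delay") <- tau
  m
}

#' Plane source mask across the full radius at one axial index
#' @param grid a `grid_model`
#' @param k axial cell index (1-based)
#' @return logical matrix usable as `grid$source_mask`
#' @export
plane_source_mask <- function(grid, k) {
  m <- matrix(FALSE, grid$nr, grid$nz)
  m[, k] <- TRUE
  m
}

#' Standard probe positions for a scenario grid
#'
#' Probes on the symmetry axis: `source` (first gel cell beyond the cap
#' apex), `skin_skull` and `skull_brain` (the two bone interfaces), and
#' `focus` (the geometric focal length).
#'
#' @param grid a `grid_model` built by [rasterize()]
#' @return data.frame with columns label, i, k, r, z
#' @export
standard_probes <- function(grid) {
  sc <- grid$scenario
  if (is.null(sc)) stop("standard probes require a scenario-backed grid")
  mm <- 1e-3
  z1 <- (sc$gel_thickness + sc$skin_thickness) * mm
  zq <- c(source = 0, skin_skull = z1,
          skull_brain = z1 + sc$skull_thickness * mm,
          focus = sc$transducer_focal_length * mm)
  k <- vapply(zq, function(zz) which.min(abs(grid$z - zz)), 0L)
  # source probe: first on-axis gel cell beyond the cap surface
  kc <- which(grid$source_mask[1, ])[1]
  k[["source"]] <- kc + 1L
  data.frame(label = names(zq), i = 1L, k = as.integer(k),
             r = grid$r[1], z = grid$z[k], row.names = NULL)
}
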