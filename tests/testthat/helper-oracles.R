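# Shared builders and independent oracles for the solver tests.

# quasi-1-D column of a single tissue along z (3 cells wide, rigid side
# walls; plane waves have no radial dependence so the column is exactly 1-D)
column_grid <- function(tissue, f, ppw, length_m, absorber_zhi = 2 * ppw,
                        delta = NULL, beta = NULL) {
  t <- tfusim::material_table()[[tissue]]
  dx <- t$sos / f / ppw
  nz <- round(length_m / dx) + absorber_zhi
  g <- tfusim::grid_homogeneous(tissue, 3, nz, dx, f, delta = delta,
                                beta = beta,
                                absorber_cells = c(r = 0, zlo = 0,
                                                   zhi = absorber_zhi))
  g$source_mask <- tfusim::plane_source_mask(g, 3)
  g
}

# slope fit of log |p| on the axis over a window clear of source and absorber
fit_alpha <- function(p_axis, z, from_cell, to_cell) {
  sel <- from_cell:to_cell
  -unname(stats::coef(stats::lm(log(p_axis[sel]) ~ z[sel]))[2])
}

# Rayleigh integral over a spherical cap with uniform normal velocity u0:
# on-axis |p| of the classical focused radiator (evaluated numerically)
rayleigh_onaxis <- function(z, a2, Fg, k, rho, c0, u0) {
  thmax <- asin(a2 / Fg)
  vapply(z, function(zz) {
    Rfun <- function(th) sqrt((Fg * sin(th))^2 + (zz - Fg + Fg * cos(th))^2)
    re <- stats::integrate(function(th) cos(-k * Rfun(th)) / Rfun(th) * sin(th),
                           0, thmax, rel.tol = 1e-10)$value
    im <- stats::integrate(function(th) sin(-k * Rfun(th)) / Rfun(th) * sin(th),
                           0, thmax, rel.tol = 1e-10)$value
    Mod(1i * k * c0 * rho * u0 * Fg^2 * complex(real = re, imaginary = im))
  }, 0)
}

# reduced-scale temporal scenario used by the heavier checks
reduced_temporal <- function(f = 0.5e6) {
  tfusim::region_preset("temporal", 3.5, 65, source_frequency = f,
                        brain_depth = 60)
}
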