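# Linear frequency-domain solver: inhomogeneous Helmholtz equation with
# equivalent-fluid losses on the axisymmetric grid, second-order conservative
# finite differences, complex-coordinate-stretching PML on the open
# boundaries, and a sparse direct solve.
#
#   div( -(1/rho_c) grad p ) - keq^2 p / rho_c = 0,   keq = omega / c_c
#
# with rho_c, c_c the complex equivalent-fluid constants per cell, a pressure
# Dirichlet source on the transducer cap, symmetry at r = 0 (natural in the
# cell-centered radial flux form) and rigid walls behind the PML.

#' Solve the lossy Helmholtz equation on a grid
#'
#' @param grid a `grid_model`; its `delta` field must correspond to the
#'   requested frequency (grids from [rasterize()] are built at the scenario
#'   frequency -- use [frequency_sweep()] to revisit several frequencies)
#' @param f frequency, Hz (default the grid's `f0`)
#' @param source_amplitude pressure amplitude imposed on the source cells, Pa
#' @param source_mask optional logical matrix overriding `grid$source_mask`
#' @param source_model `dirichlet` (pressure imposed on the cap cells,
#'   default) or `monopole`: the frequency-domain counterpart of the
#'   time-explicit soft source (additive forcing, transparent to returning
#'   reflections, radiating `source_amplitude`)
#' @param absorber_model `pml` (complex coordinate stretching, default) or
#'   `sponge`: the exact frequency-domain counterpart of the time-explicit
#'   Rayleigh sponge, obtained by the complex-frequency substitution
#'   `i omega -> i omega + gamma(x)` in both the continuity and momentum
#'   equations -- used when cross-validating against the time-explicit
#'   solver on the same grid
#' @param loss_model `equivalent_fluid` (complex density and sound speed,
#'   default) or `diffusivity`: the frequency-domain form of the
#'   time-explicit dissipation term `delta grad(div u)`, which yields the
#'   same plane-wave attenuation but leaves interface impedances untouched
#'   -- used when cross-validating against the time-explicit solver
#' @param sponge_reflection round-trip amplitude target of the sponge
#'   (sponge mode only; match the time-explicit run)
#' @param pml_reflection target theoretical PML reflection coefficient
#' @param dispersion_correction replace `keq` by the modified wavenumber
#'   `(2/dx) sin(keq dx / 2)`, which makes axial plane waves dispersion-free
#'   on the second-order stencil (default on; disable to compare against
#'   other second-order discretizations on the same mesh)
#' @param tol maximum acceptable relative residual of the discrete solve
#' @return object of class `freq_solution` with fields `pressure` (complex
#'   nr x nz, Pa), `frequency`, `grid`, `residual`
#' @export
helmholtz_solve <- function(grid, f = grid$f0, source_amplitude = 1e6,
                            source_mask = NULL,
                            source_model = c("dirichlet", "monopole"),
                            absorber_model = c("pml", "sponge"),
                            loss_model = c("equivalent_fluid", "diffusivity"),
                            sponge_reflection = 1e-4, pml_reflection = 1e-6,
                            dispersion_correction = TRUE, tol = 1e-8) {
  source_model <- match.arg(source_model)
  absorber_model <- match.arg(absorber_model)
  loss_model <- match.arg(loss_model)
  stopifnot(inherits(grid, "grid_model"))
  if (is.null(source_mask)) source_mask <- grid$source_mask
  if (!any(source_mask)) stop("no source cells set on this grid")
  nr <- grid$nr; nz <- grid$nz; dx <- grid$dx
  omega <- 2 * pi * f
  lam_min <- grid$c_min / f
  widths <- grid$absorber$widths
  if (is.null(widths)) widths <- rep(grid$absorber$width, 3)
  active <- widths > 0
  if (any(active) && any(widths[active] < lam_min))
    stop(sprintf("PML thinner than one wavelength (%.3g mm < %.3g mm)",
                 min(widths[active]) * 1e3, lam_min * 1e3))

  IDX <- matrix(seq_len(nr * nz), nr, nz)
  ti <- tj <- integer(0); tx <- complex(0)
  add <- function(ii, jj, vv) {
    ti <<- c(ti, ii); tj <<- c(tj, jj); tx <<- c(tx, vv)
  }
  rho <- grid$rho; c0 <- grid$c0; delta <- grid$delta
  Kc <- rho * c0^2

  if (loss_model == "diffusivity") {
    # exact frequency-domain mirror of the time-explicit semi-discrete
    # operator: same staggered fluxes, same face averages, same Rayleigh
    # sponge -- the steady state of the time stepper up to time-integration
    # error. Used for solver cross-validation.
    if (absorber_model != "sponge")
      stop("loss_model = 'diffusivity' mirrors the time-explicit solver; ",
           "use absorber_model = 'sponge'")
    gam <- .sponge_gamma(grid, sponge_reflection)
    s_c <- 1i * omega + gam
    gfac <- s_c / Kc
    diag_acc <- gfac
    if (nr > 1) {
      lo <- 1:(nr - 1); hi <- 2:nr
      irf <- 0.5 * (1 / rho[lo, , drop = FALSE] + 1 / rho[hi, , drop = FALSE])
      df <- 0.5 * (delta[lo, , drop = FALSE] + delta[hi, , drop = FALSE])
      sf <- 1i * omega + 0.5 * (gam[lo, , drop = FALSE] +
                                gam[hi, , drop = FALSE])
      cR <- (irf + df * gfac[hi, ]) / (sf * dx)
      cL <- (irf + df * gfac[lo, ]) / (sf * dx)
      rf <- lo * dx
      fup <- rf / (grid$r[lo] * dx)
      fdn <- rf / (grid$r[hi] * dx)
      add(IDX[lo, ], IDX[hi, ], -fup * cR)
      diag_acc[lo, ] <- diag_acc[lo, ] + fup * cL
      add(IDX[hi, ], IDX[lo, ], -fdn * cL)
      diag_acc[hi, ] <- diag_acc[hi, ] + fdn * cR
    }
    if (nz > 1) {
      lo <- 1:(nz - 1); hi <- 2:nz
      irf <- 0.5 * (1 / rho[, lo, drop = FALSE] + 1 / rho[, hi, drop = FALSE])
      df <- 0.5 * (delta[, lo, drop = FALSE] + delta[, hi, drop = FALSE])
      sf <- 1i * omega + 0.5 * (gam[, lo, drop = FALSE] +
                                gam[, hi, drop = FALSE])
      cR <- (irf + df * gfac[, hi]) / (sf * dx)
      cL <- (irf + df * gfac[, lo]) / (sf * dx)
      add(IDX[, lo], IDX[, hi], -cR / dx)
      diag_acc[, lo] <- diag_acc[, lo] + cL / dx
      add(IDX[, hi], IDX[, lo], -cL / dx)
      diag_acc[, hi] <- diag_acc[, hi] + cR / dx
    }
    add(as.vector(IDX), as.vector(IDX), as.vector(diag_acc))
  } else {
    # equivalent-fluid coefficients
    fac <- sqrt(1 + 1i * omega * delta / c0^2)
    w <- 1 / (rho * fac)                          # 1/rho_c
    keq <- omega / (c0 * fac)
    if (dispersion_correction) keq <- (2 / dx) * sin(keq * dx / 2)
    kk <- w * keq^2
    if (absorber_model == "sponge") {
      # i*omega -> i*omega + gamma in continuity and momentum
      gam <- .sponge_gamma(grid, sponge_reflection)
      w <- w * (1i * omega) / (1i * omega + gam)
      kk <- kk * (1 - 1i * gam / omega)
    }

    # PML profiles: sigma_hat (1/m) and its integral for the stretched
    # radius, quadratic ramp, amplitude set by the target reflection
    lnR <- log(1 / pml_reflection)
    r_c <- grid$r
    z_c <- grid$z
    r_f <- seq(0, nr) * dx
    z_f <- c(z_c - dx / 2, z_c[nz] + dx / 2)
    Lr <- widths[1]
    prof <- function(x, lo, hi, L) {
      if (L <= 0 || absorber_model == "sponge")
        return(list(sig = numeric(length(x)), S = numeric(length(x))))
      n <- pmin(pmax(pmax(lo - x, x - hi) / L, 0), 1)
      list(sig = 1.5 * lnR / L * n^2, S = 0.5 * lnR * n^3)
    }
    r_in <- max(r_f) - Lr
    pr_c <- prof(r_c, -Inf, r_in, Lr); pr_f <- prof(r_f, -Inf, r_in, Lr)
    Lzl <- if (length(widths) >= 2) widths[2] else widths[1]
    Lzh <- if (length(widths) >= 3) widths[3] else widths[1]
    zl_in <- min(z_f) + Lzl; zh_in <- max(z_f) - Lzh
    pzl_c <- prof(z_c, zl_in, Inf, Lzl); pzl_f <- prof(z_f, zl_in, Inf, Lzl)
    pzh_c <- prof(z_c, -Inf, zh_in, Lzh); pzh_f <- prof(z_f, -Inf, zh_in, Lzh)
    sigz_c <- pzl_c$sig + pzh_c$sig
    sigz_f <- pzl_f$sig + pzh_f$sig

    # per-cell stretch factors and stretched radius
    sr_c <- 1 - 1i * c0 * matrix(pr_c$sig, nr, nz) / omega
    sz_c <- 1 - 1i * c0 * matrix(sigz_c, nr, nz, byrow = TRUE) / omega
    rt_c <- matrix(r_c, nr, nz) - 1i * c0 * matrix(pr_c$S, nr, nz) / omega

    diag_acc <- kk
    # radial faces j = 1..nr-1 between cells (j, k) and (j+1, k)
    if (nr > 1) {
      lo <- 1:(nr - 1); hi <- 2:nr
      cf <- 0.5 * (c0[lo, , drop = FALSE] + c0[hi, , drop = FALSE])
      wf <- 2 * w[lo, , drop = FALSE] * w[hi, , drop = FALSE] /
        (w[lo, , drop = FALSE] + w[hi, , drop = FALSE])
      srf <- 1 - 1i * cf * pr_f$sig[hi] / omega
      rtf <- r_f[hi] - 1i * cf * pr_f$S[hi] / omega
      Crf <- rtf * wf / (srf * dx^2)
      pre <- 1 / (sr_c * rt_c)
      add(IDX[lo, ], IDX[hi, ], pre[lo, ] * Crf)
      add(IDX[hi, ], IDX[lo, ], pre[hi, ] * Crf)
      diag_acc[lo, ] <- diag_acc[lo, ] - pre[lo, ] * Crf
      diag_acc[hi, ] <- diag_acc[hi, ] - pre[hi, ] * Crf
    }
    # axial faces m = 1..nz-1 between cells (i, m) and (i, m+1)
    if (nz > 1) {
      lo <- 1:(nz - 1); hi <- 2:nz
      cf <- 0.5 * (c0[, lo, drop = FALSE] + c0[, hi, drop = FALSE])
      wf <- 2 * w[, lo, drop = FALSE] * w[, hi, drop = FALSE] /
        (w[, lo, drop = FALSE] + w[, hi, drop = FALSE])
      szf <- 1 - 1i * cf * matrix(sigz_f[hi], nr, nz - 1, byrow = TRUE) /
        omega
      Czf <- wf / (szf * dx^2)
      prez <- 1 / sz_c
      add(IDX[, lo], IDX[, hi], prez[, lo] * Czf)
      add(IDX[, hi], IDX[, lo], prez[, hi] * Czf)
      diag_acc[, lo] <- diag_acc[, lo] - prez[, lo] * Czf
      diag_acc[, hi] <- diag_acc[, hi] - prez[, hi] * Czf
    }
    add(as.vector(IDX), as.vector(IDX), as.vector(diag_acc))
  }

  # source term, phased by the staircase-compensation delays when the grid
  # provides them
  N <- nr * nz
  src <- which(source_mask)
  tau <- attr(source_mask, "delay")
  if (is.null(tau)) tau <- grid$source_delay
  phase <- if (is.null(tau)) rep(1 + 0i, length(src)) else
    exp(-1i * omega * tau[src])
  b <- complex(N)
  if (source_model == "dirichlet") {
    # replace the cap-cell rows with p = amplitude
    is_src <- logical(N); is_src[src] <- TRUE
    keep <- !is_src[ti]
    ti <- c(ti[keep], src); tj <- c(tj[keep], src)
    tx <- c(tx[keep], rep(1 + 0i, length(src)))
    b[src] <- source_amplitude * phase
  } else {
    # additive monopole sheet matching the time-explicit soft source:
    # a dp/dt forcing of S = (2 c / dx) g(t) on the cap cells
    if (loss_model == "diffusivity") {
      # assembled equation is s p / K + div u = S_hat / K
      b[src] <- -1i * (2 * c0[src] / dx) * source_amplitude * phase / Kc[src]
    } else {
      # assembled equation is div(w grad p) + kk p = -i omega S_hat / K
      b[src] <- -(2 * c0[src] * omega * source_amplitude /
                    (dx * Kc[src])) * phase
    }
  }

  # complex system as an equivalent real 2N x 2N block system
  xr <- Re(tx); xi <- Im(tx)
  A2 <- Matrix::sparseMatrix(
    i = c(ti, ti, ti + N, ti + N),
    j = c(tj, tj + N, tj, tj + N),
    x = c(xr, -xi, xi, xr), dims = c(2 * N, 2 * N))
  b2 <- c(Re(b), Im(b))
  fac_lu <- Matrix::lu(A2)
  x2 <- as.numeric(Matrix::solve(fac_lu, b2))
  nb <- sqrt(sum(b2^2))
  res <- sqrt(sum((as.numeric(A2 %*% x2) - b2)^2)) / nb
  for (it in 1:2) {   # iterative refinement against round-off at large N
    if (res <= tol) break
    r2 <- b2 - as.numeric(A2 %*% x2)
    x2 <- x2 + as.numeric(Matrix::solve(fac_lu, r2))
    res <- sqrt(sum((as.numeric(A2 %*% x2) - b2)^2)) / nb
  }
  if (!is.finite(res) || res > tol)
    stop(sprintf("Helmholtz solve failed: relative residual %.3g > %.3g",
                 res, tol))
  p <- matrix(complex(real = x2[1:N], imaginary = x2[(N + 1):(2 * N)]), nr, nz)
  if (any(!is.finite(Re(p))))
    stop("Helmholtz solution contains non-finite values")
  structure(list(pressure = p, frequency = f, grid = grid, residual = res),
            class = "freq_solution")
}

#' @export
print.freq_solution <- function(x, ...) {
  cat(sprintf("<freq_solution> %.3g MHz, %d x %d, max |p| = %.4g Pa, residual %.2g\n",
              x$frequency / 1e6, nrow(x$pressure), ncol(x$pressure),
              max(Mod(x$pressure)), x$residual))
  invisible(x)
}

#' Frequency sweep of the linear solver over one scenario
#'
#' Re-rasterizes the scenario for each requested frequency (the mesh rule and
#' the diffusivity field are frequency-dependent) and solves each case.
#'
#' @param scenario a `head_scenario`
#' @param frequencies frequencies, Hz, within \[0.5e6, 5e6\]
#' @param N0 harmonics to resolve in the mesh rule
#' @param ... passed to [rasterize()] and [helmholtz_solve()]
#' @return list of `freq_solution`, named by frequency in MHz
#' @export
frequency_sweep <- function(scenario, frequencies, N0 = 1, ...) {
  if (any(frequencies < 0.5e6 | frequencies > 5e6))
    stop("frequencies must lie within [0.5, 5] MHz")
  dots <- list(...)
  ras_args <- dots[names(dots) %in% names(formals(rasterize))]
  sol_args <- dots[names(dots) %in% names(formals(helmholtz_solve))]
  out <- lapply(frequencies, function(f) {
    sc <- scenario
    sc$source_frequency <- f
    g <- do.call(rasterize, c(list(scenario = sc, N0 = N0), ras_args))
    do.call(helmholtz_solve,
            c(list(grid = g, f = f,
                   source_amplitude = scenario$source_pressure), sol_args))
  })
  names(out) <- sprintf("%gMHz", frequencies / 1e6)
  out
}

#' Save a frequency-domain field with its grid metadata
#'
#' Writes the complex pressure as a two-plane (real, imaginary) array with
#' grid spacing and axes, in R's serialized container format.
#'
#' @param solution a `freq_solution`
#' @param path output path
#' @export
write_field <- function(solution, path) {
  stopifnot(inherits(solution, "freq_solution"))
  saveRDS(list(real = Re(solution$pressure), imag = Im(solution$pressure),
               dx = solution$grid$dx, r = solution$grid$r, z = solution$grid$z,
               frequency = solution$frequency), path)
  invisible(path)
}
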