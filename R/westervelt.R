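# Nonlinear time-explicit solver: R-facing interface to the conservative
# Westervelt kernel (staggered axisymmetric grid, classical RK4 at fixed
# step, exponential sponge absorber, pressure-Dirichlet cap source).

#' Quiescent time-domain state for a grid
#'
#' Pressure and particle velocity start at zero everywhere (fluid at rest);
#' all subsequent motion is generated by the source pulse.
#'
#' @param grid a `grid_model`
#' @return object of class `time_state` with fields `p`, `ur`, `uz`, `t`
#' @export
time_state <- function(grid) {
  structure(list(p = matrix(0, grid$nr, grid$nz),
                 ur = matrix(0, grid$nr + 1, grid$nz),
                 uz = matrix(0, grid$nr, grid$nz + 1),
                 t = 0), class = "time_state")
}

#' Largest stable time step for a grid
#'
#' `dt = min` over cells of `CFL * dx / c0` with the CFL number set per
#' material class: `cfl_soft` for gel, skin and brain, `cfl_bone` for
#' cortical and trabecular bone (the stiffer bone domains need the smaller
#' Courant number).
#'
#' @param grid a `grid_model`
#' @param cfl_soft Courant number for soft tissue and gel
#' @param cfl_bone Courant number for the skull domains
#' @return time step, s
#' @export
stable_timestep <- function(grid, cfl_soft = 0.2, cfl_bone = 0.1) {
  stopifnot(inherits(grid, "grid_model"))
  if (length(grid$c0) == 0) stop("empty grid")
  bone <- grid$material_index %in% c(3L, 4L, 5L)
  cfl <- ifelse(bone, cfl_bone, cfl_soft)
  min(cfl * grid$dx / grid$c0)
}

#' Realized Courant numbers per material class
#'
#' @param grid a `grid_model`
#' @param dt time step, s
#' @return named vector: max `c0 dt / dx` over soft-tissue cells and over
#'   bone cells (`NA` if a class is absent)
#' @export
cfl_numbers <- function(grid, dt) {
  bone <- grid$material_index %in% c(3L, 4L, 5L)
  cn <- grid$c0 * dt / grid$dx
  c(soft = if (any(!bone)) max(cn[!bone]) else NA_real_,
    bone = if (any(bone)) max(cn[bone]) else NA_real_)
}

#' Local sound speed under finite-amplitude perturbation
#'
#' Diagnostic form `c = c0 + (beta - 1) u`: the convective speed-up that
#' drives waveform steepening and harmonic generation.
#'
#' @param c0 quiescent sound speed, m/s
#' @param beta nonlinearity coefficient
#' @param u acoustic particle velocity, m/s
#' @return local sound speed, m/s
#' @export
local_sos <- function(c0, beta, u) c0 + (beta - 1) * u

.sponge_gamma <- function(grid, sponge_reflection) {
  ab <- grid$absorber
  if (is.null(ab) || max(ab$dnorm) == 0 || all(unlist(ab$widths) == 0))
    return(matrix(0, grid$nr, grid$nz))
  L <- max(ab$widths)
  1.5 * log(1 / sponge_reflection) / L * grid$c0 * ab$dnorm^2
}

.source_delays <- function(grid) {
  tau <- attr(grid$source_mask, "delay")
  if (is.null(tau)) tau <- grid$source_delay
  idx <- which(grid$source_mask)
  if (is.null(tau)) numeric(length(idx)) else tau[idx]
}

# plane-sheet forcing scale: a dp/dt source of S = (2c/dx) g(t) on one cell
# sheet radiates a wave of amplitude max|g| to each side
.soft_scale <- function(grid) {
  idx <- which(grid$source_mask)
  if (!length(idx)) return(0)
  2 * mean(grid$c0[idx]) / grid$dx
}

.resample_pulse <- function(pulse, dt) {
  if (1 / pulse$sample_rate <= dt * (1 + 1e-9)) return(pulse)
  t <- seq(0, max(pulse$sample_times), by = dt)
  p <- stats::spline(pulse$sample_times, pulse$pressures, xout = t)$y
  pulse$sample_times <- t
  pulse$pressures <- p
  pulse$sample_rate <- 1 / dt
  pulse
}

#' Advance a time-domain state by explicit Runge-Kutta steps
#'
#' One or more classical RK4 updates of the coupled continuity/momentum
#' system at fixed step `dt` (which must respect [stable_timestep()]).
#' Exposed mainly for audits (energy conservation, convergence studies);
#' full runs use [westervelt_run()].
#'
#' @param state a `time_state`
#' @param grid a `grid_model`
#' @param dt time step, s
#' @param nsteps number of steps
#' @param pulse optional `source_pulse` driving the grid's source cells
#'   (Dirichlet); `NULL` leaves the source silent
#' @param linear if `TRUE`, force the nonlinear flux factor to one
#'   (verification mode equivalent to beta = 0)
#' @param sponge_reflection round-trip amplitude target of the sponge ring
#' @return updated `time_state`
#' @export
westervelt_step <- function(state, grid, dt, nsteps = 1L, pulse = NULL,
                            linear = FALSE, sponge_reflection = 1e-4,
                            source_model = c("dirichlet", "soft")) {
  stopifnot(inherits(state, "time_state"), inherits(grid, "grid_model"))
  source_model <- match.arg(source_model)
  if (dt > stable_timestep(grid) * (1 + 1e-9))
    stop("dt exceeds the stable time step for this grid")
  if (is.null(pulse)) {
    ps <- c(0, 0); prate <- 1; pt0 <- 0
  } else {
    pulse <- .resample_pulse(pulse, dt)
    ps <- pulse$pressures; prate <- pulse$sample_rate; pt0 <- 0
  }
  gamma <- .sponge_gamma(grid, sponge_reflection)
  out <- .westervelt_chunk(state$p, state$ur, state$uz,
                           grid$rho, grid$rho * grid$c0^2, grid$delta,
                           grid$beta, gamma,
                           which(grid$source_mask) - 1L, .source_delays(grid),
                           ps, prate, pt0,
                           state$t, dt, as.integer(nsteps), grid$dx,
                           linear, source_model == "soft",
                           .soft_scale(grid), integer(0),
                           matrix(0, grid$nr, grid$nz), 0)
  structure(list(p = out$p, ur = out$ur, uz = out$uz, t = out$t),
            class = "time_state")
}

#' Discrete acoustic energy of a state
#'
#' `E = sum 2 pi r dx^2 [ p^2/(2 rho c0^2) + rho |u|^2 / 2 ]` with the face
#' velocities averaged to cell centers. Conserved (to discretization error)
#' in lossless linear runs until the field reaches the sponge.
#'
#' @param state a `time_state`
#' @param grid a `grid_model`
#' @return energy, J
#' @export
acoustic_energy <- function(state, grid) {
  urc <- 0.5 * (state$ur[-(grid$nr + 1), , drop = FALSE] +
                state$ur[-1, , drop = FALSE])
  uzc <- 0.5 * (state$uz[, -(grid$nz + 1), drop = FALSE] +
                state$uz[, -1, drop = FALSE])
  dens <- state$p^2 / (2 * grid$rho * grid$c0^2) +
    grid$rho * (urc^2 + uzc^2) / 2
  sum(2 * pi * grid$r * dens) * grid$dx^2
}

#' Run a full time-explicit simulation
#'
#' Drives the grid's source cells with the pulse, integrates until the input
#' has traversed the domain (axial length over the slowest on-axis speed,
#' times 1.2, plus the pulse duration), and records per-cell peak |p|
#' (the envelope) plus pressure traces at the probes.
#'
#' @param grid a `grid_model` with a nonempty `source_mask`
#' @param pulse a [synth_pulse()] source pulse
#' @param probes data.frame with columns `label`, `i`, `k` (1-based cell
#'   indices); default [standard_probes()] for scenario grids, none otherwise
#' @param duration total simulated time, s; `NULL` applies the traversal rule
#' @param dt time step, s; `NULL` uses [stable_timestep()]
#' @param linear verification mode: force the nonlinear flux factor to one
#' @param sponge_reflection round-trip amplitude target of the sponge ring
#' @param envelope_start time (s) from which the envelope accumulates
#'   (excludes the start-up transient in steady-state comparisons)
#' @param source_model `dirichlet` (pressure imposed on the cap cells,
#'   default) or `soft` (additive forcing transparent to returning
#'   reflections, radiating the pulse amplitude)
#' @param cfl_soft,cfl_bone Courant numbers for the default step
#' @return object of class `td_run`: `probes` (list of data.frames
#'   `time`/`pressure`), `envelope` (nr x nz peak |p|, Pa), `state` (final
#'   `time_state`), and a `manifest` (dx, dt, steps, realized CFL, duration)
#' @export
westervelt_run <- function(grid, pulse, probes = NULL, duration = NULL,
                           dt = NULL, linear = FALSE,
                           sponge_reflection = 1e-4, envelope_start = 0,
                           source_model = c("dirichlet", "soft"),
                           cfl_soft = 0.2, cfl_bone = 0.1) {
  stopifnot(inherits(grid, "grid_model"), inherits(pulse, "source_pulse"))
  source_model <- match.arg(source_model)
  if (!any(grid$source_mask)) stop("grid has no source cells")
  if (is.null(dt)) dt <- stable_timestep(grid, cfl_soft, cfl_bone)
  if (is.null(probes) && !is.null(grid$scenario)) probes <- standard_probes(grid)
  if (!is.null(probes)) {
    if (any(probes$i < 1 | probes$i > grid$nr |
            probes$k < 1 | probes$k > grid$nz))
      stop("probe outside the computational domain")
    pcells <- (probes$i - 1L) + (probes$k - 1L) * grid$nr
  } else pcells <- integer(0)
  if (is.null(duration)) {
    Lz <- grid$dx * grid$nz
    c_axis <- min(grid$c0[1, ])
    duration <- 1.2 * Lz / c_axis + max(pulse$sample_times)
  }
  nsteps <- ceiling(duration / dt)
  pulse <- .resample_pulse(pulse, dt)
  gamma <- .sponge_gamma(grid, sponge_reflection)
  out <- .westervelt_chunk(matrix(0, grid$nr, grid$nz),
                           matrix(0, grid$nr + 1, grid$nz),
                           matrix(0, grid$nr, grid$nz + 1),
                           grid$rho, grid$rho * grid$c0^2, grid$delta,
                           grid$beta, gamma,
                           which(grid$source_mask) - 1L, .source_delays(grid),
                           pulse$pressures, pulse$sample_rate, 0,
                           0, dt, as.integer(nsteps), grid$dx,
                           linear, source_model == "soft", .soft_scale(grid),
                           pcells, matrix(0, grid$nr, grid$nz),
                           envelope_start)
  precs <- NULL
  if (length(pcells)) {
    precs <- lapply(seq_along(pcells), function(q)
      data.frame(time = out$probe_times, pressure = out$probe_pressures[, q]))
    names(precs) <- probes$label
  }
  structure(
    list(probes = precs, envelope = out$envelope,
         state = structure(list(p = out$p, ur = out$ur, uz = out$uz,
                                t = out$t), class = "time_state"),
         manifest = list(dx = grid$dx, dt = dt, nsteps = nsteps,
                         duration = duration, linear = linear,
                         source_model = source_model,
                         cfl = cfl_numbers(grid, dt))),
    class = "td_run")
}

#' @export
print.td_run <- function(x, ...) {
  cat(sprintf("<td_run> %d steps, dt = %.3g ns, peak envelope %.4g Pa%s\n",
              x$manifest$nsteps, x$manifest$dt * 1e9, max(x$envelope),
              if (x$manifest$linear) " (linear mode)" else ""))
  invisible(x)
}

#' Write a run manifest (grid spacing, step, realized Courant numbers,
#' duration) as JSON
#' @param run a `td_run`
#' @param path output file
#' @export
write_run_manifest <- function(run, path) {
  stopifnot(inherits(run, "td_run"))
  m <- run$manifest
  m$cfl <- as.list(m$cfl)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write probe records as CSV files (one per probe)
#' @param run a `td_run`
#' @param dir output directory
#' @return written paths
#' @export
write_probe_csv <- function(run, dir) {
  stopifnot(inherits(run, "td_run"))
  if (is.null(run$probes)) stop("run has no probe records")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(run$probes), function(lb) {
    p <- file.path(dir, paste0("probe_", lb, ".csv"))
    utils::write.csv(run$probes[[lb]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
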