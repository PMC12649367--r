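# Outcome metrics: sound transmission loss, maximum pressure ratio, focal
# depth, the 5%-of-peak focus zone, and harmonic spectra of probe records.

#' Sound transmission loss in dB
#'
#' `STL = 20 log10(p_transducer / p_focus)`: the pressure drop from the
#' transducer surface to the focal point. Log-additive along a path:
#' `stl_db(a, b) + stl_db(b, c) = stl_db(a, c)`.
#'
#' @param p_transducer pressure amplitude at the transducer probe, Pa (> 0)
#' @param p_focus pressure amplitude at the focus, Pa (> 0)
#' @return STL, dB (positive when the focus is quieter than the source)
#' @export
stl_db <- function(p_transducer, p_focus) {
  if (any(!is.finite(p_transducer)) || any(p_transducer <= 0) ||
      any(!is.finite(p_focus)) || any(p_focus <= 0))
    stop("pressures must be positive and finite")
  20 * log10(p_transducer / p_focus)
}

# connected component (4-neighbour) of `mask` containing `seed` (i, k)
.flood_component <- function(mask, seed) {
  nr <- nrow(mask); nz <- ncol(mask)
  comp <- matrix(FALSE, nr, nz)
  stack <- integer(sum(mask)); top <- 1L
  stack[1] <- (seed[2] - 1L) * nr + seed[1]
  comp[stack[1]] <- TRUE
  while (top > 0L) {
    c0 <- stack[top]; top <- top - 1L
    i <- (c0 - 1L) %% nr + 1L
    k <- (c0 - 1L) %/% nr + 1L
    for (nb in c(if (i > 1) c0 - 1L, if (i < nr) c0 + 1L,
                 if (k > 1) c0 - nr, if (k < nz) c0 + nr)) {
      if (mask[nb] && !comp[nb]) {
        comp[nb] <- TRUE
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, integer(length(stack)))
        stack[top] <- nb
      }
    }
  }
  comp
}

#' Focal metrics of a pressure envelope
#'
#' The peak is the maximum envelope value inside the brain mask. The focus
#' zone is the connected component (4-neighbour, restricted to brain) of
#' cells exceeding `threshold_fraction` of the peak that contains the peak.
#' Depths are measured along the axis from the transducer apex (z = 0);
#' the intracranial depth subtracts the on-axis depth of the inner cortical
#' surface.
#'
#' @param envelope nonnegative nr x nz field of peak |p| (time-explicit
#'   envelope or frequency-domain |p|), Pa
#' @param grid the `grid_model` the envelope lives on
#' @param source_amplitude source pressure amplitude, Pa (for the ratio)
#' @param threshold_fraction focus-zone threshold as a fraction of the peak
#' @return object of class `focal_metrics`: `max_pressure_ratio`,
#'   `focal_depth_mm`, `focal_depth_intracranial_mm`, `focus_zone_axial_mm`,
#'   `focus_zone_area_mm2`, `peak_location_mm` (r, z), `peak_pressure`
#' @export
focal_metrics <- function(envelope, grid, source_amplitude,
                          threshold_fraction = 0.05) {
  stopifnot(inherits(grid, "grid_model"))
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  bm <- grid$brain_mask
  if (!any(bm)) stop("brain mask is empty")
  if (max(envelope[bm]) <= 0)
    stop("envelope is zero inside the brain: focal metrics undefined")
  env_b <- ifelse(bm, envelope, -Inf)
  peak <- max(env_b)
  pk <- which(env_b == peak, arr.ind = TRUE)[1, ]
  # focal depth from the on-axis envelope restricted to brain
  ax <- which(bm[1, ])
  k_ax <- ax[which.max(envelope[1, ax])]
  focal_depth <- grid$z[k_ax]
  # on-axis inner cortical surface: first brain cell on the axis
  z_inner <- grid$z[min(ax)]
  mask <- bm & (envelope > threshold_fraction * peak)
  comp <- .flood_component(mask, as.integer(pk))
  kz <- range(which(colSums(comp) > 0))
  axial <- (kz[2] - kz[1] + 1) * grid$dx
  area <- sum(comp) * grid$dx^2
  structure(
    list(max_pressure_ratio = peak / source_amplitude,
         peak_pressure = peak,
         focal_depth_mm = focal_depth * 1e3,
         focal_depth_intracranial_mm = (focal_depth - z_inner) * 1e3,
         focus_zone_axial_mm = axial * 1e3,
         focus_zone_area_mm2 = area * 1e6,
         peak_location_mm = c(r = unname(grid$r[pk[1]]) * 1e3,
                              z = unname(grid$z[pk[2]]) * 1e3),
         threshold_fraction = threshold_fraction),
    class = "focal_metrics")
}

#' @export
print.focal_metrics <- function(x, ...) {
  cat(sprintf(paste0("<focal_metrics> peak ratio %.4g, depth %.1f mm ",
                     "(%.1f mm intracranial)\n  focus zone: %.1f mm axial, ",
                     "%.1f mm^2 (threshold %g%% of peak)\n"),
              x$max_pressure_ratio, x$focal_depth_mm,
              x$focal_depth_intracranial_mm, x$focus_zone_axial_mm,
              x$focus_zone_area_mm2, 100 * x$threshold_fraction))
  invisible(x)
}

#' Harmonic amplitudes of a probe record
#'
#' Projects the record onto the harmonics of `f0` over a Hann window spanning
#' an integer number of fundamental periods at the end of the record (where
#' the nonlinear steady state lives in a tone-burst run).
#'
#' @param record data.frame with columns `time` (s, uniform) and `pressure`
#'   (Pa), at least 4 periods of `f0` long
#' @param f0 fundamental frequency, Hz
#' @param n_harmonics number of harmonics to report
#' @param n_periods window length in fundamental periods; default the
#'   largest integer number available
#' @return named numeric vector: amplitude (Pa) at `k * f0`, k = 1..n
#' @export
harmonic_spectrum <- function(record, f0, n_harmonics = 3, n_periods = NULL) {
  t <- record$time; p <- record$pressure
  dt <- t[2] - t[1]
  Tp <- 1 / f0
  total <- t[length(t)] - t[1]
  if (total < 4 * Tp) stop("record shorter than 4 periods of f0")
  if (is.null(n_periods)) n_periods <- floor(total / Tp)
  wlen <- n_periods * Tp
  if (wlen > total + dt / 2) stop("window longer than the record")
  nwin <- round(wlen / dt)
  idx <- (length(t) - nwin + 1):length(t)
  tw <- t[idx]; pw <- p[idx]
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
  amps <- vapply(seq_len(n_harmonics), function(k) {
    ph <- exp(-2i * pi * k * f0 * tw)
    2 * Mod(sum(w * pw * ph)) / sum(w)
  }, 0)
  names(amps) <- paste0("h", seq_len(n_harmonics))
  amps
}

#' Metrics table row for one completed run
#'
#' Flattens a `focal_metrics` object plus its run identifiers into a
#' one-row data.frame, the unit emitted per case by the sweep pipeline.
#'
#' @param metrics a `focal_metrics`
#' @param stl sound transmission loss, dB (or NA)
#' @param ... identifier columns (scenario id, f0, thickness, ...)
#' @return one-row data.frame
#' @export
metrics_row <- function(metrics, stl = NA_real_, ...) {
  data.frame(..., stl_db = stl,
             max_pressure_ratio = metrics$max_pressure_ratio,
             focal_depth_mm = metrics$focal_depth_mm,
             focal_depth_intracranial_mm = metrics$focal_depth_intracranial_mm,
             focus_zone_mm = metrics$focus_zone_axial_mm,
             focus_zone_mm2 = metrics$focus_zone_area_mm2,
             stringsAsFactors = FALSE)
}
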