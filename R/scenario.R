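# Scenario factory: regional skull presets, cortical/trabecular layer
# decomposition, source pulse synthesis, and scenario (de)serialization.

# Regional menus: tabulated skull thicknesses and radii of curvature (mm)
# used for the parametric geometries, plus literature RoC ranges per region.
.REGION_MENU <- list(
  frontal   = list(thickness = c(6, 7.5, 8), roc = c(45, 55, 65, 75, 85, 95),
                   roc_range = c(44, 97)),
  parietal  = list(thickness = c(5.5, 6),    roc = c(55, 65, 75, 85, 95),
                   roc_range = c(54, 97)),
  temporal  = list(thickness = c(3.5, 4),    roc = c(65, 75, 85, 95),
                   roc_range = c(65, 97)),
  occipital = list(thickness = c(8, 9),      roc = c(45, 55, 65, 75),
                   roc_range = c(47, 75))
)

# outer-to-inner cortical table thickness ratio (median over calvarial sites)
.CORTICAL_RATIO <- 1.68

#' Decompose a total skull thickness into cortical and trabecular layers
#'
#' The skull is modelled as a porous trabecular (diploe) layer sandwiched
#' between dense cortical tables. The trabecular layer takes one quarter of
#' the total thickness; the remaining cortical share is split so that the
#' outer table is 1.68 times the inner table.
#'
#' @param total total skull thickness, mm
#' @return named numeric vector `c(outer, trabecular, inner)`, mm
#' @export
decompose_skull <- function(total) {
  if (any(!is.finite(total)) || any(total <= 0))
    stop("total skull thickness must be > 0")
  trabecular <- total / 4
  inner <- 0.75 * total / (1 + .CORTICAL_RATIO)
  outer <- .CORTICAL_RATIO * inner
  if (length(total) == 1L)
    c(outer = outer, trabecular = trabecular, inner = inner)
  else
    cbind(outer = outer, trabecular = trabecular, inner = inner)
}

#' Construct a fully parameterized head scenario
#'
#' A scenario fixes everything one simulated case needs: the skull layer
#' stack, its local radius of curvature, the soft-tissue standoffs, and the
#' transducer/source settings. Layer thicknesses are in mm, pressures in Pa,
#' frequencies in Hz.
#'
#' @param region label in `frontal, parietal, temporal, occipital, custom`
#' @param skull_thickness total skull thickness, mm
#' @param roc skull radius of curvature, mm
#' @param outer_cortical,trabecular,inner_cortical optional explicit layer
#'   thicknesses, mm; default from [decompose_skull()]
#' @param gel_thickness coupling-gel standoff, mm
#' @param skin_thickness scalp thickness, mm
#' @param brain_depth modelled brain depth beyond the inner cortical surface, mm
#' @param aperture_diameter transducer aperture diameter, mm
#' @param transducer_focal_length geometric focal length of the bowl, mm
#' @param source_pressure source pressure amplitude, Pa
#' @param source_frequency source centre frequency, Hz
#' @return object of class `head_scenario`
#' @export
head_scenario <- function(region = "custom",
                          skull_thickness,
                          roc,
                          outer_cortical = NULL,
                          trabecular = NULL,
                          inner_cortical = NULL,
                          gel_thickness = 10,
                          skin_thickness = 3,
                          brain_depth = 80,
                          aperture_diameter = 74,
                          transducer_focal_length = 65,
                          source_pressure = 1e6,
                          source_frequency = 2e6) {
  if (is.null(outer_cortical) || is.null(trabecular) || is.null(inner_cortical)) {
    lay <- decompose_skull(skull_thickness)
    outer_cortical <- lay[["outer"]]
    trabecular <- lay[["trabecular"]]
    inner_cortical <- lay[["inner"]]
  }
  sc <- structure(
    list(region = region, skull_thickness = skull_thickness,
         outer_cortical = outer_cortical, trabecular = trabecular,
         inner_cortical = inner_cortical, roc = roc,
         gel_thickness = gel_thickness, skin_thickness = skin_thickness,
         brain_depth = brain_depth, aperture_diameter = aperture_diameter,
         transducer_focal_length = transducer_focal_length,
         source_pressure = source_pressure,
         source_frequency = source_frequency),
    class = "head_scenario")
  validate_scenario(sc)
}

#' Validate a head scenario
#'
#' Checks positivity of all thicknesses, that the sub-layers sum to the total
#' skull thickness within 0.01 mm, and that the curvature radius exceeds the
#' aperture radius.
#'
#' @param sc a `head_scenario`
#' @return `sc`, invisibly usable, after validation
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "head_scenario"))
  th <- c(sc$skull_thickness, sc$outer_cortical, sc$trabecular,
          sc$inner_cortical, sc$gel_thickness, sc$skin_thickness,
          sc$brain_depth, sc$aperture_diameter, sc$transducer_focal_length)
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all scenario thicknesses/lengths must be positive and finite")
  ssum <- sc$outer_cortical + sc$trabecular + sc$inner_cortical
  if (abs(ssum - sc$skull_thickness) > 0.01)
    stop(sprintf("skull layers sum to %.4f mm but total is %.4f mm",
                 ssum, sc$skull_thickness))
  if (sc$roc <= sc$aperture_diameter / 2)
    stop("radius of curvature must exceed the aperture radius")
  if (!is.finite(sc$source_pressure) || sc$source_pressure < 0)
    stop("source_pressure must be >= 0")
  if (!is.finite(sc$source_frequency) || sc$source_frequency <= 0)
    stop("source_frequency must be > 0")
  sc
}

#' @export
print.head_scenario <- function(x, ...) {
  cat(sprintf("<head_scenario: %s>\n", x$region))
  cat(sprintf("  skull %.2f mm = outer %.2f + trabecular %.2f + inner %.2f, RoC %.1f mm\n",
              x$skull_thickness, x$outer_cortical, x$trabecular,
              x$inner_cortical, x$roc))
  cat(sprintf("  gel %.1f mm, skin %.1f mm, brain depth %.1f mm\n",
              x$gel_thickness, x$skin_thickness, x$brain_depth))
  cat(sprintf("  source: %.3g MPa at %.3g MHz, aperture %.0f mm, focal length %.0f mm\n",
              x$source_pressure / 1e6, x$source_frequency / 1e6,
              x$aperture_diameter, x$transducer_focal_length))
  invisible(x)
}

#' Build a scenario from a regional preset
#'
#' Populates a [head_scenario()] for one of the tabulated head regions with
#' the decomposed skull layers and default soft-tissue/transducer settings.
#' A (thickness, RoC) pair outside the tabulated menu for that region raises
#' a warning, not an error, so off-menu sensitivity studies remain possible.
#'
#' @param region one of `frontal, parietal, temporal, occipital`
#' @param skull_thickness total skull thickness, mm
#' @param roc radius of curvature, mm
#' @param ... passed on to [head_scenario()]
#' @return a `head_scenario`
#' @export
region_preset <- function(region, skull_thickness, roc, ...) {
  if (!region %in% names(.REGION_MENU))
    stop("unknown region: ", region,
         " (known: ", paste(names(.REGION_MENU), collapse = ", "), ")")
  menu <- .REGION_MENU[[region]]
  if (!any(abs(menu$thickness - skull_thickness) < 1e-9))
    warning(sprintf("skull thickness %.2f mm is outside the %s menu {%s}",
                    skull_thickness, region,
                    paste(menu$thickness, collapse = ", ")))
  if (roc < menu$roc_range[1] || roc > menu$roc_range[2])
    warning(sprintf("RoC %.1f mm outside the reported %s range %g-%g mm",
                    roc, region, menu$roc_range[1], menu$roc_range[2]))
  head_scenario(region = region, skull_thickness = skull_thickness,
                roc = roc, ...)
}

#' Synthesize a windowed tone-burst source pulse
#'
#' A single tone burst `A sin(2 pi f0 t) w(t)`, sampled uniformly. The
#' default window is a Gaussian centred mid-burst (the transient excitation
#' pulse); `envelope = "tukey"` gives a flat-top burst with cosine ramps
#' over the first and last 20% of the duration, used to reach a quasi-steady
#' state in verification runs. The signal starts and ends at (numerically)
#' zero pressure and its discrete spectrum peaks at `f0`.
#'
#' @param f0 centre frequency, Hz
#' @param amplitude peak pressure, Pa
#' @param n_cycles number of carrier cycles in the burst (>= 1)
#' @param sample_rate sampling rate, Hz; must resolve the harmonics kept by
#'   the mesh rule (>= 20 f0)
#' @param envelope `gaussian` (default) or `tukey`
#' @return object of class `source_pulse` with `sample_times` (s) and
#'   `pressures` (Pa)
#' @export
synth_pulse <- function(f0, amplitude, n_cycles = 3, sample_rate = 40 * f0,
                        envelope = c("gaussian", "tukey")) {
  envelope <- match.arg(envelope)
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (sample_rate < 20 * f0)
    stop("sample_rate undersamples the burst; need >= 20 * f0")
  dur <- n_cycles / f0
  t <- seq(0, dur, by = 1 / sample_rate)
  if (envelope == "gaussian") {
    # ~3 sigma at the edges keeps the end points at ~1e-4 A
    sigma <- dur / 6
    w <- exp(-0.5 * ((t - dur / 2) / sigma)^2)
  } else {
    a <- 0.2
    x <- t / dur
    w <- rep(1, length(t))
    w[x < a] <- 0.5 * (1 - cos(pi * x[x < a] / a))
    w[x > 1 - a] <- 0.5 * (1 - cos(pi * (1 - x[x > 1 - a]) / a))
  }
  p <- amplitude * sin(2 * pi * f0 * t) * w
  if (amplitude > 0) p <- p * (amplitude / max(abs(p)))  # peak exactly A
  structure(list(sample_times = t, pressures = p, center_frequency = f0,
                 amplitude = amplitude, n_cycles = n_cycles,
                 sample_rate = sample_rate, envelope = envelope),
            class = "source_pulse")
}

#' @export
print.source_pulse <- function(x, ...) {
  cat(sprintf("<source_pulse> %g cycles at %.3g MHz, peak %.3g MPa, %d samples at %.3g MHz\n",
              x$n_cycles, x$center_frequency / 1e6, x$amplitude / 1e6,
              length(x$sample_times), x$sample_rate / 1e6))
  invisible(x)
}

#' Export a pulse as a two-column CSV (time s, pressure Pa)
#' @param pulse a `source_pulse`
#' @param path output file
#' @export
write_pulse_csv <- function(pulse, path) {
  stopifnot(inherits(pulse, "source_pulse"))
  utils::write.csv(data.frame(time_s = pulse$sample_times,
                              pressure_pa = pulse$pressures),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a scenario to a flat YAML file
#' @param sc a `head_scenario`
#' @param path output file
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "head_scenario"))
  yaml::write_yaml(unclass(sc), path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML file written by [write_scenario()]
#' @param path input file
#' @return a `head_scenario`
#' @export
read_scenario <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(head_scenario, v)
}
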