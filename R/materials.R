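# Tissue acoustic property database and constitutive relations for the
# five-layer head model: density, sound speed, nonlinearity ratio B/A, and
# frequency-indexed sound diffusivity for gel, skin, cortical bone,
# trabecular bone and brain.

.tfusim_env <- new.env(parent = emptyenv())

# Tabulated diffusivity frequencies, MHz
.DELTA_FREQS_MHZ <- c(0.5, 1, 2, 4, 5)

#' Construct a tissue acoustic property record
#'
#' @param name tissue label
#' @param density quiescent density, kg/m^3
#' @param sos small-signal sound speed, m/s
#' @param b_over_a thermodynamic nonlinearity ratio B/A (dimensionless)
#' @param diffusivity named numeric vector of sound diffusivity (m^2/s) at
#'   0.5, 1, 2, 4 and 5 MHz, in that order
#' @param gel_alpha optional frequency-independent absorption coefficient
#'   (1/m); only the coupling gel carries one
#' @return an object of class `tissue_acoustics`
#' @export
tissue_acoustics <- function(name, density, sos, b_over_a, diffusivity,
                             gel_alpha = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(sos) || sos <= 0) stop("sos must be > 0")
  if (!is.finite(b_over_a) || b_over_a < 0) stop("b_over_a must be >= 0")
  diffusivity <- as.numeric(diffusivity)
  if (length(diffusivity) != length(.DELTA_FREQS_MHZ) || any(diffusivity < 0))
    stop("diffusivity must give five nonnegative values at 0.5/1/2/4/5 MHz")
  names(diffusivity) <- paste0(.DELTA_FREQS_MHZ, "MHz")
  structure(
    list(name = name, density = density, sos = sos, b_over_a = b_over_a,
         diffusivity = diffusivity, gel_alpha = gel_alpha),
    class = "tissue_acoustics")
}

#' @export
print.tissue_acoustics <- function(x, ...) {
  cat(sprintf("<tissue_acoustics: %s>  rho = %g kg/m^3, c = %g m/s, B/A = %g\n",
              x$name, x$density, x$sos, x$b_over_a))
  cat("  delta (m^2/s):", paste(sprintf("%s=%g", names(x$diffusivity),
                                        x$diffusivity), collapse = ", "), "\n")
  invisible(x)
}

#' Load the tissue property table
#'
#' Reads the five-tissue acoustic constants (density, sound speed, B/A, and
#' sound diffusivity tabulated at 0.5--5 MHz) shipped with the package, or a
#' user-supplied table in the same CSV schema
#' (`name, density, sos, b_over_a, delta_0.5MHz ... delta_5MHz, gel_alpha`).
#'
#' @param path optional path to a replacement CSV; default uses the packaged
#'   table
#' @return named list of [tissue_acoustics()] records
#' @export
material_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tfusim_env$materials)) return(.tfusim_env$materials)
    path <- system.file("extdata", "tissue_acoustics.csv", package = "tfusim",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "density", "sos", "b_over_a",
            paste0("delta_", .DELTA_FREQS_MHZ, "MHz"), "gel_alpha")
  if (!all(need %in% names(df)))
    stop("tissue table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  tissues <- lapply(seq_len(nrow(df)), function(i) {
    tissue_acoustics(
      name = df$name[i], density = df$density[i], sos = df$sos[i],
      b_over_a = df$b_over_a[i],
      diffusivity = as.numeric(df[i, paste0("delta_", .DELTA_FREQS_MHZ, "MHz")]),
      gel_alpha = df$gel_alpha[i])
  })
  names(tissues) <- df$name
  if (cache) .tfusim_env$materials <- tissues
  tissues
}

.get_tissue <- function(tissue) {
  if (inherits(tissue, "tissue_acoustics")) return(tissue)
  tab <- material_table()
  if (!is.character(tissue) || length(tissue) != 1L || !tissue %in% names(tab))
    stop("unknown tissue: ", paste(tissue, collapse = ", "),
         " (known: ", paste(names(tab), collapse = ", "), ")")
  tab[[tissue]]
}

#' Sound diffusivity of the coupling gel from its absorption coefficient
#'
#' For a medium whose amplitude absorption coefficient `alpha` is independent
#' of frequency, the equivalent thermoviscous sound diffusivity is
#' `delta = 2 c0^3 alpha / omega^2` with `omega = 2 pi f`, so `delta` falls
#' as 1/f^2 at fixed `alpha`.
#'
#' @param alpha amplitude absorption coefficient, 1/m (Np/m)
#' @param c0 sound speed, m/s
#' @param f frequency, Hz
#' @return sound diffusivity, m^2/s
#' @export
gel_diffusivity <- function(alpha, c0, f) {
  if (any(!is.finite(alpha)) || any(alpha < 0)) stop("alpha must be >= 0")
  if (any(!is.finite(c0)) || any(c0 <= 0)) stop("c0 must be > 0")
  if (any(!is.finite(f)) || any(f <= 0)) stop("f must be > 0")
  2 * c0^3 * alpha / (2 * pi * f)^2
}

#' Amplitude attenuation implied by a sound diffusivity
#'
#' Algebraic inverse of [gel_diffusivity()]: `alpha = delta omega^2 / (2 c0^3)`
#' (small-loss thermoviscous attenuation).
#'
#' @param delta sound diffusivity, m^2/s
#' @param c0 sound speed, m/s
#' @param f frequency, Hz
#' @return attenuation coefficient, 1/m (Np/m)
#' @export
attenuation_from_diffusivity <- function(delta, c0, f) {
  if (any(!is.finite(delta)) || any(delta < 0)) stop("delta must be >= 0")
  if (any(!is.finite(c0)) || any(c0 <= 0)) stop("c0 must be > 0")
  if (any(!is.finite(f)) || any(f <= 0)) stop("f must be > 0")
  delta * (2 * pi * f)^2 / (2 * c0^3)
}

#' Sound diffusivity of a tissue at an arbitrary in-band frequency
#'
#' At the tabulated frequencies (0.5, 1, 2, 4, 5 MHz) the tabulated value is
#' returned exactly. Between them, a piecewise power law `delta = delta0 f^n`
#' is fitted through the bracketing pair (log-log interpolation), matching the
#' functional form of the frequency-dependent diffusivity model on each
#' interval. No extrapolation outside 0.5--5 MHz.
#'
#' @param tissue a [tissue_acoustics()] record or a tissue name
#' @param f frequency, Hz, within \[0.5e6, 5e6\]
#' @return sound diffusivity, m^2/s
#' @export
tissue_diffusivity <- function(tissue, f) {
  tissue <- .get_tissue(tissue)
  f_mhz <- f / 1e6
  if (any(!is.finite(f_mhz)) || any(f_mhz < 0.5 - 1e-12) ||
      any(f_mhz > 5 + 1e-12))
    stop("frequency outside the tabulated range [0.5, 5] MHz; no extrapolation")
  f_mhz <- pmin(pmax(f_mhz, 0.5), 5)
  hit <- match(round(f_mhz, 12), .DELTA_FREQS_MHZ)
  out <- numeric(length(f_mhz))
  exact <- !is.na(hit)
  out[exact] <- unname(tissue$diffusivity[hit[exact]])
  if (any(!exact)) {
    lf <- log(.DELTA_FREQS_MHZ)
    ld <- log(tissue$diffusivity)
    out[!exact] <- exp(stats::approx(lf, ld, xout = log(f_mhz[!exact]))$y)
  }
  out
}

#' Nonlinearity coefficient from the B/A ratio
#'
#' `beta = 1 + B/(2A)`; beta = 1 recovers a linear fluid.
#'
#' @param b_over_a B/A ratio, dimensionless, >= 0
#' @return nonlinearity coefficient beta
#' @export
nonlinearity_coefficient <- function(b_over_a) {
  if (any(!is.finite(b_over_a)) || any(b_over_a < 0))
    stop("b_over_a must be >= 0")
  1 + b_over_a / 2
}

#' Equivalent-fluid complex density and sound speed
#'
#' Represents thermoviscous losses in the frequency domain by complex
#' material constants: with loss parameter `eps = omega delta / c^2`,
#' `cc = c (1 + i eps)^(1/2)` and `rhoc = rho (1 + i eps)^(1/2)`.
#' Both reduce to the real constants when `delta = 0`, and the implied
#' plane-wave attenuation `|Im(omega/cc)|` equals `delta omega^2 / (2 c^3)`
#' in the small-loss limit `eps << 1`, consistent with
#' [attenuation_from_diffusivity()].
#'
#' @param tissue a [tissue_acoustics()] record or tissue name
#' @param f frequency, Hz
#' @param delta optional diffusivity override (m^2/s); default
#'   `tissue_diffusivity(tissue, f)`
#' @return list with complex `rho_c` (kg/m^3) and `c_c` (m/s), plus the loss
#'   parameter `eps`
#' @export
equivalent_fluid <- function(tissue, f, delta = NULL) {
  tissue <- .get_tissue(tissue)
  if (is.null(delta)) delta <- tissue_diffusivity(tissue, f)
  omega <- 2 * pi * f
  eps <- omega * delta / tissue$sos^2
  fac <- sqrt(1 + 1i * eps)
  list(rho_c = tissue$density * fac, c_c = tissue$sos * fac, eps = eps)
}
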