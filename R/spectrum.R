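#' Compute a phased real spectrum from an FID
#'
#' Applies the discrete Fourier transform to the time-domain signal and the
#' usual zero/first-order phase correction
#' \code{y = Re(F(fid) * exp(-1i * (phi0 + phi1 * f)))}.
#'
#' The DFT convention is \code{X(f_k) = dt * sum_t y_t exp(-2i*pi*f_k*t*dt)},
#' i.e. a plain forward DFT scaled by the dwell time (a Riemann-sum
#' approximation of the continuous transform), with the output reordered so
#' the frequency axis ascends from \code{-1/(2*dt)}. The global scale cancels
#' in intensity ratios and mole fractions. By default the first FID point is
#' halved before transforming (the standard half-point correction that
#' suppresses the constant offset it otherwise induces).
#'
#' @param fid A \code{qnmr_fid}.
#' @param phi0 Zero-order phase in rad.
#' @param phi1 First-order phase in rad/Hz, applied against absolute
#'   frequency with its pivot at f = 0 (centre of the spectrum).
#' @param half_first_point Halve the first time-domain sample before the DFT.
#' @return An object of class \code{"qnmr_spectrum"} with elements
#'   \code{freq_hz}, \code{real} (the phased real part), \code{complex}
#'   (the retained complex spectrum after phasing), \code{phase}
#'   (accumulated \code{c(phi0, phi1)}), and \code{params}.
#' @export
compute_spectrum <- function(fid, phi0 = 0, phi1 = 0,
                             half_first_point = TRUE) {
  stopifnot(inherits(fid, "qnmr_fid"))
  s <- fid$samples
  if (any(!is.finite(Re(s))) || any(!is.finite(Im(s))))
    stop("FID contains non-finite samples; cannot transform")
  if (half_first_point) s[1L] <- s[1L] / 2
  n <- length(s)
  X <- fid$params$dwell_time * stats::fft(s)
  # reorder 0..n-1 cycles to ascending -n/2 .. n/2-1
  X <- X[c((n %/% 2L + 1L):n, 1L:(n %/% 2L))]
  f <- freq_grid(fid$params)
  Xp <- X * exp(-1i * (phi0 + phi1 * f))
  structure(list(freq_hz = f,
                 real = Re(Xp),
                 complex = Xp,
                 phase = c(phi0 = phi0, phi1 = phi1),
                 params = fid$params),
            class = "qnmr_spectrum")
}

#' Construct a spectrum object directly from values on a grid
#'
#' Used by the JCAMP-DX reader and the synthetic generator when only a real
#' (already phased) spectrum is available. If \code{complex_values} is NULL
#' the spectrum cannot be re-phased later.
#'
#' @param real_values Real intensities.
#' @param params A \code{qnmr_acq} matching the grid.
#' @param complex_values Optional retained complex spectrum.
#' @param phase Accumulated phase record \code{c(phi0, phi1)}.
#' @return A \code{qnmr_spectrum}.
#' @export
nmr_spectrum <- function(real_values, params, complex_values = NULL,
                         phase = c(phi0 = 0, phi1 = 0)) {
  stopifnot(inherits(params, "qnmr_acq"))
  if (length(real_values) != params$n_points)
    stop("spectrum length does not match params$n_points")
  structure(list(freq_hz = freq_grid(params),
                 real = as.numeric(real_values),
                 complex = if (!is.null(complex_values))
                   as.complex(complex_values),
                 phase = c(phi0 = unname(phase[1]), phi1 = unname(phase[2])),
                 params = params),
            class = "qnmr_spectrum")
}

#' Re-phase a spectrum without recomputing the DFT
#'
#' Rotates the retained complex spectrum by an additional
#' \code{exp(-1i * (phi0 + phi1 * f))} and updates the real part pointwise.
#' The phase record of the result is the composition (sum) of the previous
#' and the new angles, so rotations form a group action on spectra.
#'
#' @param spectrum A \code{qnmr_spectrum} with complex values present.
#' @param phi0 Additional zero-order phase, rad.
#' @param phi1 Additional first-order phase, rad/Hz (pivot at f = 0).
#' @return The rotated \code{qnmr_spectrum}.
#' @export
phase_rotate <- function(spectrum, phi0 = 0, phi1 = 0) {
  stopifnot(inherits(spectrum, "qnmr_spectrum"))
  if (is.null(spectrum$complex))
    stop("spectrum has no retained complex values; ",
         "recompute it from the FID with compute_spectrum()")
  rot <- exp(-1i * (phi0 + phi1 * spectrum$freq_hz))
  spectrum$complex <- spectrum$complex * rot
  spectrum$real <- Re(spectrum$complex)
  spectrum$phase <- c(phi0 = unname(spectrum$phase[1]) + phi0,
                      phi1 = unname(spectrum$phase[2]) + phi1)
  spectrum
}

#' @export
print.qnmr_spectrum <- function(x, ...) {
  cat(sprintf("NMR spectrum: %d points, %g to %g Hz (d f = %g Hz)\n",
              length(x$real), min(x$freq_hz), max(x$freq_hz),
              x$freq_hz[2] - x$freq_hz[1]))
  cat(sprintf("  phase: phi0 = %g rad, phi1 = %g rad/Hz; complex %s\n",
              x$phase[1], x$phase[2],
              if (is.null(x$complex)) "dropped" else "retained"))
  invisible(x)
}

#' @export
as.data.frame.qnmr_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freq_hz,
             ppm = hz_to_ppm(x$freq_hz, x$params),
             intensity = x$real)
}

#' @export
plot.qnmr_spectrum <- function(x, xlab = "chemical shift (ppm)",
                               ylab = "intensity (a.u.)", type = "l", ...) {
  d <- as.data.frame(x)
  plot(d$ppm, d$intensity, type = type, xlim = rev(range(d$ppm)),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a spectrum as CSV
#'
#' Writes (freq_hz, ppm, intensity) triples.
#'
#' @param spectrum A \code{qnmr_spectrum}.
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
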