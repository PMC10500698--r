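#' Acquisition parameters for a 1D NMR experiment
#'
#' Bundles the sampling (dwell) time, number of points, spectrometer operating
#' frequency and spectral offset that together define the frequency grid of a
#' spectrum. The spectral width is \code{1/dwell_time} Hz.
#'
#' @param dwell_time Sampling interval of the FID in seconds (> 0).
#' @param n_points Number of complex time-domain points (integer, >= 8).
#' @param frequency_mhz Operating (Larmor) frequency of the spectrometer in
#'   MHz; used to convert chemical shifts between ppm and Hz.
#' @param offset_ppm Spectral offset in ppm: the chemical shift that maps to
#'   0 Hz at the centre of the spectrum.
#'
#' @return An object of class \code{"qnmr_acq"}.
#' @export
#' @examples
#' acq_params(dwell_time = 1e-3, n_points = 4096, frequency_mhz = 400)
acq_params <- function(dwell_time, n_points, frequency_mhz = 400,
                       offset_ppm = 0) {
  stopifnot(is.numeric(dwell_time), length(dwell_time) == 1L,
            is.finite(dwell_time), dwell_time > 0)
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1L, !is.na(n_points), n_points >= 8L)
  stopifnot(is.numeric(frequency_mhz), frequency_mhz > 0,
            is.numeric(offset_ppm), is.finite(offset_ppm))
  structure(list(dwell_time = dwell_time,
                 n_points = n_points,
                 frequency_mhz = frequency_mhz,
                 offset_ppm = offset_ppm),
            class = "qnmr_acq")
}

#' @export
print.qnmr_acq <- function(x, ...) {
  cat("NMR acquisition parameters\n")
  cat(sprintf("  points:          %d\n", x$n_points))
  cat(sprintf("  dwell time:      %g s (spectral width %g Hz)\n",
              x$dwell_time, 1 / x$dwell_time))
  cat(sprintf("  B0 frequency:    %g MHz\n", x$frequency_mhz))
  cat(sprintf("  offset:          %g ppm\n", x$offset_ppm))
  invisible(x)
}

#' Frequency grid associated with acquisition parameters
#'
#' Uniform ascending grid in Hz spanning \code{[-1/(2*dt), 1/(2*dt))} with
#' spacing \code{1/(n*dt)}; index 0-based frequency k maps to
#' \code{(k - n/2) / (n*dt)}.
#'
#' @param params A \code{qnmr_acq} object.
#' @return Numeric vector of length \code{n_points}, in Hz.
#' @export
freq_grid <- function(params) {
  stopifnot(inherits(params, "qnmr_acq"))
  n <- params$n_points
  df <- 1 / (n * params$dwell_time)
  (seq_len(n) - 1L - n %/% 2L) * df
}

#' Convert between Hz and ppm on an acquisition grid
#'
#' The ppm axis is \code{delta = f / B0 + f0} where \code{B0} is the
#' spectrometer frequency in MHz (so Hz / MHz = ppm) and \code{f0} the
#' spectral offset in ppm; larger ppm corresponds to larger Hz.
#'
#' @param f Frequencies in Hz.
#' @param params A \code{qnmr_acq} object.
#' @return Chemical shifts in ppm.
#' @export
hz_to_ppm <- function(f, params) {
  f / params$frequency_mhz + params$offset_ppm
}

#' @rdname hz_to_ppm
#' @param delta Chemical shifts in ppm.
#' @export
ppm_to_hz <- function(delta, params) {
  (delta - params$offset_ppm) * params$frequency_mhz
}

#' Construct a free induction decay object
#'
#' @param samples Complex vector of time-domain samples; length must equal
#'   \code{params$n_points}.
#' @param params A \code{qnmr_acq} object.
#' @return An object of class \code{"qnmr_fid"}.
#' @export
nmr_fid <- function(samples, params) {
  stopifnot(inherits(params, "qnmr_acq"))
  samples <- as.complex(samples)
  if (length(samples) != params$n_points)
    stop("FID length (", length(samples),
         ") does not match params$n_points (", params$n_points, ")")
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("FID contains non-finite samples")
  structure(list(samples = samples, params = params), class = "qnmr_fid")
}

#' @export
print.qnmr_fid <- function(x, ...) {
  cat(sprintf("NMR FID: %d complex points, dwell %g s\n",
              length(x$samples), x$params$dwell_time))
  invisible(x)
}

#' @export
length.qnmr_fid <- function(x) length(x$samples)
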