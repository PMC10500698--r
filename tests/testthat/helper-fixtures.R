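# Shared fixtures, all generated in code.

std_params <- function(n = 4096, dt = 1e-3, b0 = 400, f0 = 0)
  acq_params(dwell_time = dt, n_points = n, frequency_mhz = b0,
             offset_ppm = f0)

# Exact single-Lorentzian complex spectrum from the closed form
# dt / (alpha + 2i pi (f - fp)), optionally rotated by a phase error.
analytic_lorentzian_spectrum <- function(params, fp_hz, alpha,
                                         phase_err = 0) {
  f <- freq_grid(params)
  Cc <- params$dwell_time /
    complex(real = alpha, imaginary = 2 * pi * (f - fp_hz))
  Cp <- Cc * exp(1i * phase_err)
  nmr_spectrum(Re(Cp), params, complex_values = Cp)
}

single_peak_signature <- function(params, fp_hz, alpha, name = "A")
  signature(name, peak_table(fp_hz / params$frequency_mhz +
                               params$offset_ppm, alpha), protons = 1)

# O(n * w) brute-force sliding median with reflected edges
naive_sliding_median <- function(v, w) {
  h <- (w - 1L) %/% 2L
  n <- length(v)
  padded <- c(v[h:1], v, v[n:(n - h + 1L)])
  vapply(seq_len(n), function(i) stats::median(padded[i:(i + 2L * h)]),
         numeric(1))
}

# three-species mixture with distinct linewidths, used by the simulation
# study: lineshape misspecification then affects each species differently
study_signatures <- function() {
  list(signature("monoamine", peak_table(c(-0.70, -0.55), pi * 2.0, c(1, 1)),
                 protons = 4),
       signature("ether", peak_table(c(-0.10, 0.05, 0.20), pi * 3.0,
                                     c(1, 2, 1)), protons = 3),
       signature("carbonyl", peak_table(c(0.60, 0.80), pi * 4.5, c(3, 1)),
                 protons = 2))
}

study_distortion <- function() {
  mean_fwhm <- mean(c(2.0, 3.0, 4.5))
  distortion_spec(gaussian_fwhm_hz = 0.5 * mean_fwhm, phi0 = 0.05,
                  snr = 500)
}
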