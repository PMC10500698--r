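#' Controlled lineshape-distortion specification
#'
#' Describes how a simulated mixture FID deviates from the ideal
#' mono-exponential Lorentzian model: Gaussian broadening from field
#' inhomogeneity (parameterized as the added Gaussian FWHM in Hz),
#' second/third-order (possibly complex) decay terms
#' \code{exp(-alpha t - beta2 t^2 - beta3 t^3)}, zero/first-order phase
#' errors, a constant baseline offset, and Gaussian noise at a target
#' peak signal-to-noise ratio (tallest peak height over the noise standard
#' deviation in the real spectrum).
#'
#' @param gaussian_fwhm_hz Added Gaussian FWHM, Hz (>= 0).
#' @param beta2 Quadratic decay coefficient, 1/s^2 (may be complex).
#' @param beta3 Cubic decay coefficient, 1/s^3 (may be complex).
#' @param phi0,phi1 Phase error injected into the data, rad and rad/Hz.
#' @param baseline_offset Constant offset added to the real spectrum, in
#'   units of the tallest peak height (a.u. fraction).
#' @param snr Target peak SNR; \code{Inf} disables noise.
#' @return An object of class \code{"qnmr_distortion"}.
#' @export
distortion_spec <- function(gaussian_fwhm_hz = 0, beta2 = 0, beta3 = 0,
                            phi0 = 0, phi1 = 0, baseline_offset = 0,
                            snr = Inf) {
  stopifnot(gaussian_fwhm_hz >= 0)
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive (or Inf)")
  structure(list(gaussian_fwhm_hz = gaussian_fwhm_hz,
                 beta2 = beta2, beta3 = beta3,
                 phi0 = phi0, phi1 = phi1,
                 baseline_offset = baseline_offset,
                 snr = snr),
            class = "qnmr_distortion")
}

resolve_signature <- function(x, params, alpha) {
  if (inherits(x, "qnmr_signature")) return(x)
  if (inherits(x, "qnmr_spin_system"))
    return(spin_signature(x, frequency_mhz = params$frequency_mhz,
                          offset_ppm = params$offset_ppm, alpha = alpha))
  stop("mixture components must be qnmr_signature or qnmr_spin_system")
}

#' Simulate a mixture FID with controlled misspecification
#'
#' Sums proton-count-weighted, mole-fraction-weighted per-peak FIDs
#' \code{b_p exp(2i pi f_p t) exp(-alpha_p t - beta2 t^2 - beta3 t^3)},
#' multiplies by the Gaussian inhomogeneity envelope
#' \code{exp(-(pi sigma_g t)^2 / (4 log 2))} (so the added Gaussian FWHM is
#' \code{sigma_g} Hz), applies the phase error, adds the baseline offset as
#' a spike at t = 0, and adds complex white Gaussian noise calibrated so the
#' tallest peak's spectral SNR matches the request. Each signature's peak
#' intensities are rescaled to sum to its proton count, so a species'
#' integrated signal is proportional to (mole fraction x protons).
#'
#' @param mixture List of \code{qnmr_signature} / \code{qnmr_spin_system}.
#' @param fractions Mole fractions (>= 0, summing to 1 within 1e-9).
#' @param params A \code{qnmr_acq}.
#' @param distortion A \code{\link{distortion_spec}}.
#' @param seed Integer seed for the noise (ignored when \code{snr = Inf}).
#' @param alpha Decay rate handed to spin systems without one, 1/s.
#' @return A \code{qnmr_fid} with attributes \code{signatures} (the
#'   resolved signature list), \code{fractions}, and \code{noise_sd}
#'   (realized noise standard deviation in the real spectrum; 0 if none).
#' @export
simulate_fid <- function(mixture, fractions, params,
                         distortion = distortion_spec(), seed = NULL,
                         alpha = 3) {
  stopifnot(inherits(params, "qnmr_acq"),
            inherits(distortion, "qnmr_distortion"))
  if (inherits(mixture, "qnmr_signature") ||
      inherits(mixture, "qnmr_spin_system")) mixture <- list(mixture)
  if (length(fractions) != length(mixture))
    stop("fractions must match the number of mixture components")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  sigs <- as_signature_list(lapply(mixture, resolve_signature, params, alpha))
  n <- params$n_points
  t <- (seq_len(n) - 1L) * params$dwell_time
  fid <- complex(n)
  for (k in seq_along(sigs)) {
    pk <- sigs[[k]]$peaks
    scale_b <- sigs[[k]]$protons / sum(pk$b)  # per-proton convention
    for (p in seq_len(nrow(pk))) {
      f_p <- ppm_to_hz(pk$delta_ppm[p], params)
      fid <- fid + fractions[k] * scale_b * pk$b[p] *
        exp((2i * pi * f_p - pk$alpha[p]) * t -
              distortion$beta2 * t^2 - distortion$beta3 * t^3)
    }
  }
  if (distortion$gaussian_fwhm_hz > 0)
    fid <- fid * exp(-(pi * distortion$gaussian_fwhm_hz * t)^2 / (4 * log(2)))
  # tallest-peak reference height, taken before phase errors and noise
  ref_height <- max(compute_spectrum(nmr_fid(fid, params))$real)
  # phase error: phi0 in the time domain; phi1 via the frequency domain
  if (distortion$phi0 != 0) fid <- fid * exp(1i * distortion$phi0)
  if (distortion$phi1 != 0) {
    f <- freq_grid(params)
    X <- stats::fft(fid)
    X <- X[c((n %/% 2L + 1L):n, 1L:(n %/% 2L))]
    X <- X * exp(1i * distortion$phi1 * f)
    X <- X[c((n %/% 2L + 1L):n, 1L:(n %/% 2L))]
    fid <- stats::fft(X, inverse = TRUE) / n
  }
  if (distortion$baseline_offset != 0) {
    # a constant offset in the spectrum is a spike at t = 0 of size
    # offset * n * df ... = offset / dt in the (dt-scaled) DFT convention
    fid[1L] <- fid[1L] + distortion$baseline_offset * ref_height /
      params$dwell_time * 2  # doubled: the first point is halved in the DFT
  }
  noise_sd <- 0
  if (is.finite(distortion$snr)) {
    sigma_spec <- ref_height / distortion$snr
    sigma_t <- sigma_spec / (params$dwell_time * sqrt(n))
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    fid <- fid + complex(real = stats::rnorm(n, 0, sigma_t),
                         imaginary = stats::rnorm(n, 0, sigma_t))
    noise_sd <- sigma_spec
  }
  out <- nmr_fid(fid, params)
  attr(out, "signatures") <- sigs
  attr(out, "fractions") <- stats::setNames(fractions, names(sigs))
  attr(out, "noise_sd") <- noise_sd
  out
}

# fractions uniform on the simplex, rejected until inside [lo, hi]
sample_fractions <- function(K, lo, hi, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    e <- stats::rexp(K)
    x <- e / sum(e)
    if (all(x >= lo) && all(x <= hi)) return(x)
  }
  stop("could not sample fractions in [", lo, ", ", hi, "] for K = ", K,
       "; constraints appear infeasible")
}

#' Generate a reproducible synthetic mixture dataset
#'
#' Emulates a gravimetric calibration study: a set of samples of the same
#' species at varying compositions, simulated with a shared distortion
#' specification. Per-sample noise seeds are derived from the master seed
#' by a simple counter (\code{master_seed + sample index}) and recorded in
#' the manifest, so reruns are byte-identical.
#'
#' @param mixture List of signatures / spin systems.
#' @param n_samples Number of samples.
#' @param params A \code{qnmr_acq}.
#' @param distortion A \code{\link{distortion_spec}} shared by all samples.
#' @param fraction_range Length-2 range every mole fraction must fall in.
#' @param fractions Optional n_samples x K matrix of fixed compositions
#'   (rows summing to 1); when given, \code{fraction_range} is ignored.
#' @param master_seed Integer master seed.
#' @param alpha Decay rate for spin systems.
#' @return An object of class \code{"qnmr_dataset"}: list with
#'   \code{fids} (list of \code{qnmr_fid}), \code{truth} (matrix of mole
#'   fractions), and \code{manifest} (config echo including per-sample
#'   seeds).
#' @export
generate_dataset <- function(mixture, n_samples, params,
                             distortion = distortion_spec(),
                             fraction_range = c(0.02, 0.95),
                             fractions = NULL, master_seed = 1L,
                             alpha = 3) {
  if (inherits(mixture, "qnmr_signature") ||
      inherits(mixture, "qnmr_spin_system")) mixture <- list(mixture)
  K <- length(mixture)
  if (!is.null(fractions)) {
    fractions <- as.matrix(fractions)
    stopifnot(nrow(fractions) == n_samples, ncol(fractions) == K)
    if (any(abs(rowSums(fractions) - 1) > 1e-9))
      stop("each row of fractions must sum to 1")
  } else {
    if (K > 1 && fraction_range[1] * K > 1)
      stop("infeasible fraction range: K * lower bound exceeds 1")
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(master_seed)
    fr <- vapply(seq_len(n_samples), function(i)
      if (K == 1) 1 else sample_fractions(K, fraction_range[1],
                                          fraction_range[2]),
      numeric(K))
    fractions <- if (K == 1) matrix(fr, ncol = 1) else t(fr)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  seeds <- master_seed + seq_len(n_samples)
  fids <- lapply(seq_len(n_samples), function(i)
    simulate_fid(mixture, fractions[i, ], params, distortion,
                 seed = seeds[i], alpha = alpha))
  sig_names <- names(attr(fids[[1]], "signatures"))
  colnames(fractions) <- sig_names
  manifest <- list(n_samples = n_samples, species = sig_names,
                   master_seed = master_seed, sample_seeds = seeds,
                   fraction_range = fraction_range,
                   truth = lapply(seq_len(n_samples), function(i)
                     as.list(stats::setNames(fractions[i, ], sig_names))),
                   distortion = unclass(distortion),
                   acquisition = unclass(params))
  structure(list(fids = fids, truth = fractions, manifest = manifest,
                 params = params,
                 signatures = attr(fids[[1]], "signatures")),
            class = "qnmr_dataset")
}

#' @export
print.qnmr_dataset <- function(x, ...) {
  cat(sprintf("Synthetic qNMR dataset: %d sample(s) of %d species (%s)\n",
              length(x$fids), ncol(x$truth),
              paste(colnames(x$truth), collapse = ", ")))
  cat(sprintf("  master seed %d; n = %d points per FID\n",
              x$manifest$master_seed, x$params$n_points))
  invisible(x)
}

#' Write a dataset to disk as JCAMP-DX files plus a JSON manifest
#'
#' @param dataset A \code{qnmr_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qnmr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(dataset$fids))
  for (i in seq_along(dataset$fids)) {
    paths[i] <- file.path(dir, sprintf("sample_%03d.jdx", i))
    write_jcamp(dataset$fids[[i]], paths[i],
                title = sprintf("synthetic sample %d", i))
  }
  manifest <- dataset$manifest
  manifest$files <- basename(paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
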