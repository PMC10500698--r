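#' Lorentzian lineshape
#'
#' Absorption-mode Lorentzian evaluated on a frequency grid:
#' \deqn{u(f) = \alpha \Delta t / ((2\pi(f - f_p))^2 + \alpha^2)}
#' with peak centre \code{f_p} (Hz), time-domain decay rate \code{alpha}
#' (1/s), full width at half maximum \code{alpha/pi} Hz and peak height
#' \code{dt/alpha}. This is the spectrum of a mono-exponentially decaying
#' FID under the package's DFT convention; the integral over all
#' frequencies is \code{dt/2} independent of \code{alpha}.
#'
#' @param f Frequency grid, Hz.
#' @param f_p Peak centre, Hz.
#' @param alpha Decay rate, 1/s (> 0).
#' @param dt Dwell time, s (scale factor only).
#' @return Intensity vector of \code{length(f)}.
#' @export
lorentzian <- function(f, f_p, alpha, dt = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  alpha * dt / ((2 * pi * (f - f_p))^2 + alpha^2)
}

#' Peak table constructor
#'
#' A peak table is a data frame with one row per Lorentzian component:
#' chemical shift (ppm), decay rate alpha (1/s; FWHM = alpha/pi Hz), and
#' relative intensity b (dimensionless, >= 0). Relative intensities within a
#' signature are fixed by the molecule's atomic composition and are never
#' varied during fitting.
#'
#' @param delta_ppm Chemical shifts, ppm.
#' @param alpha Decay rates, 1/s.
#' @param b Relative intensities, >= 0.
#' @return A data frame with columns \code{delta_ppm}, \code{alpha}, \code{b}.
#' @export
peak_table <- function(delta_ppm, alpha, b = rep(1, length(delta_ppm))) {
  stopifnot(length(delta_ppm) >= 1L,
            length(alpha) %in% c(1L, length(delta_ppm)),
            length(b) %in% c(1L, length(delta_ppm)))
  alpha <- rep_len(alpha, length(delta_ppm))
  b <- rep_len(b, length(delta_ppm))
  if (any(alpha <= 0)) stop("all decay rates must be positive")
  if (any(b < 0)) stop("relative intensities must be non-negative")
  data.frame(delta_ppm = delta_ppm, alpha = alpha, b = b)
}

#' Species signature
#'
#' The ideal spectral response of one chemical species: a set of Lorentzian
#' peaks with fixed relative intensities, plus the number of contributing
#' protons (used only when converting intensities to mole fractions).
#'
#' @param species Species name (unique within a model).
#' @param peaks A peak table from \code{\link{peak_table}}.
#' @param protons Positive integer proton count.
#' @return An object of class \code{"qnmr_signature"}.
#' @export
signature <- function(species, peaks, protons = 1L) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1L,
            all(c("delta_ppm", "alpha", "b") %in% names(peaks)))
  protons <- as.integer(protons)
  stopifnot(protons >= 1L)
  if (any(peaks$alpha <= 0)) stop("all decay rates must be positive")
  if (any(peaks$b < 0)) stop("relative intensities must be non-negative")
  structure(list(species = species,
                 peaks = peaks[c("delta_ppm", "alpha", "b")],
                 protons = protons),
            class = "qnmr_signature")
}

#' @export
print.qnmr_signature <- function(x, ...) {
  cat(sprintf("Signature '%s': %d peak(s), %d proton(s)\n",
              x$species, nrow(x$peaks), x$protons))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

as_signature_list <- function(sigs) {
  if (inherits(sigs, "qnmr_signature")) sigs <- list(sigs)
  stopifnot(length(sigs) >= 1L,
            all(vapply(sigs, inherits, logical(1), "qnmr_signature")))
  nms <- vapply(sigs, `[[`, character(1), "species")
  if (anyDuplicated(nms)) stop("duplicate species names: ",
                               paste(unique(nms[duplicated(nms)]),
                                     collapse = ", "))
  names(sigs) <- nms
  sigs
}

#' Evaluate a signature spectrum on a grid
#'
#' Sum of the signature's Lorentzian peaks,
#' \code{sum_p b_p u(f | f_p, alpha_p)}, with the ppm-to-Hz conversion
#' \code{f_p = B0 * (delta_p - f0)}. A per-signature shift offset (ppm) and
#' width scale can be applied; these are the free nonlinear parameters used
#' during fitting, which preserve the fixed intensity ratios \code{b_p}.
#'
#' @param sig A \code{qnmr_signature}.
#' @param grid Frequency grid in Hz (matching \code{params}).
#' @param params A \code{qnmr_acq}.
#' @param shift_offset Added to every peak's chemical shift, ppm.
#' @param width_scale Multiplies every peak's decay rate (dimensionless > 0).
#' @return Intensity vector of \code{length(grid)}.
#' @export
signature_spectrum <- function(sig, grid, params, shift_offset = 0,
                               width_scale = 1) {
  stopifnot(inherits(sig, "qnmr_signature"), inherits(params, "qnmr_acq"),
            width_scale > 0)
  f_p <- ppm_to_hz(sig$peaks$delta_ppm + shift_offset, params)
  out_of_grid <- f_p < min(grid) | f_p > max(grid)
  if (any(out_of_grid & sig$peaks$b > 0))
    warning(sprintf("signature '%s': %d peak(s) outside the frequency grid; ",
                    sig$species, sum(out_of_grid)),
            "their contribution is truncated", call. = FALSE)
  y <- numeric(length(grid))
  for (p in seq_along(f_p)) {
    if (sig$peaks$b[p] == 0) next
    y <- y + sig$peaks$b[p] *
      lorentzian(grid, f_p[p], sig$peaks$alpha[p] * width_scale,
                 params$dwell_time)
  }
  y
}

#' Assemble the model matrix
#'
#' Builds the n x (K + L) matrix whose first K columns are signature spectra
#' evaluated at the current nonlinear parameters and whose last L columns are
#' the polynomial baseline basis \code{f^(l-1)}, l = 1..L (so L = 1 adds a
#' single constant column). The baseline columns are scaled to unit maximum
#' absolute value for conditioning; quantification never uses their
#' coefficients.
#'
#' @param sigs A \code{qnmr_signature} or list of them (unique species names).
#' @param grid Frequency grid, Hz.
#' @param params A \code{qnmr_acq}.
#' @param theta A \code{\link{fit_params}} object, or NULL for zero offsets
#'   and unit width scales.
#' @param baseline_order Number L >= 0 of polynomial baseline columns.
#' @return An object of class \code{"qnmr_model_matrix"}: the numeric matrix
#'   with attributes \code{column_roles} (character, "signature"/"baseline"),
#'   \code{species}, and \code{grid}.
#' @export
build_model_matrix <- function(sigs, grid, params, theta = NULL,
                               baseline_order = 1L) {
  sigs <- as_signature_list(sigs)
  L <- as.integer(baseline_order)
  stopifnot(L >= 0L)
  K <- length(sigs)
  n <- length(grid)
  Z <- matrix(0, n, K + L)
  for (k in seq_len(K)) {
    nm <- names(sigs)[k]
    so <- if (is.null(theta)) 0 else theta$shift_offset[[nm]]
    ws <- if (is.null(theta)) 1 else theta$width_scale[[nm]]
    Z[, k] <- signature_spectrum(sigs[[k]], grid, params,
                                 shift_offset = so, width_scale = ws)
    if (all(Z[, k] == 0))
      stop("signature '", nm, "' evaluates to an all-zero column")
  }
  if (L > 0L) {
    fr <- max(abs(grid))
    for (l in seq_len(L))
      Z[, K + l] <- if (l == 1L) 1 else (grid / fr)^(l - 1L)
  }
  structure(Z,
            column_roles = c(rep("signature", K), rep("baseline", L)),
            species = names(sigs),
            grid = grid,
            class = c("qnmr_model_matrix", "matrix", "array"))
}

signature_columns <- function(Z) {
  roles <- attr(Z, "column_roles")
  if (is.null(roles)) seq_len(ncol(Z)) else which(roles == "signature")
}

#' Read and write signature tables
#'
#' Signatures are stored as CSV with columns
#' \code{species, delta_ppm, alpha_per_s, b_rel, protons} (one row per peak)
#' or as JSON with one record per species.
#'
#' @param path File path; format chosen by extension (.csv or .json).
#' @return \code{read_signatures} returns a named list of
#'   \code{qnmr_signature}; \code{write_signatures} returns \code{path}
#'   invisibly.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    sigs <- lapply(recs, function(r)
      signature(r$species,
                peak_table(unlist(r$delta_ppm), unlist(r$alpha_per_s),
                           unlist(r$b_rel)),
                protons = r$protons))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("species", "delta_ppm", "alpha_per_s", "b_rel", "protons")
    if (!all(need %in% names(d)))
      stop("signature CSV must have columns: ", paste(need, collapse = ", "))
    sigs <- lapply(split(d, d$species), function(g)
      signature(g$species[1],
                peak_table(g$delta_ppm, g$alpha_per_s, g$b_rel),
                protons = g$protons[1]))
  }
  as_signature_list(sigs)
}

#' @rdname read_signatures
#' @param sigs A list of \code{qnmr_signature}.
#' @export
write_signatures <- function(sigs, path) {
  sigs <- as_signature_list(sigs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(sigs, function(s)
      list(species = s$species, delta_ppm = s$peaks$delta_ppm,
           alpha_per_s = s$peaks$alpha, b_rel = s$peaks$b,
           protons = s$protons))
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  } else {
    d <- do.call(rbind, lapply(sigs, function(s)
      data.frame(species = s$species, delta_ppm = s$peaks$delta_ppm,
                 alpha_per_s = s$peaks$alpha, b_rel = s$peaks$b,
                 protons = s$protons)))
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
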