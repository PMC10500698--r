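#' Nonlinear fit parameters
#'
#' The collective nonlinear parameter set theta of the signature model:
#' one chemical-shift offset (ppm) and one width scale (dimensionless) per
#' signature — which preserve each signature's fixed intensity ratios —
#' plus the zero/first-order phase correction applied to the complex
#' spectrum before taking the real part.
#'
#' @param species Character vector of species names.
#' @param shift_offset Per-species shift offsets, ppm (recycled).
#' @param width_scale Per-species width scales (> 0, recycled).
#' @param phi0 Zero-order phase, rad.
#' @param phi1 First-order phase, rad/Hz.
#' @return An object of class \code{"qnmr_fit_params"}.
#' @export
fit_params <- function(species, shift_offset = 0, width_scale = 1,
                       phi0 = 0, phi1 = 0) {
  stopifnot(length(species) >= 1L)
  so <- rep_len(shift_offset, length(species))
  ws <- rep_len(width_scale, length(species))
  if (any(ws <= 0)) stop("width scales must be positive")
  structure(list(shift_offset = stats::setNames(as.numeric(so), species),
                 width_scale = stats::setNames(as.numeric(ws), species),
                 phi0 = phi0, phi1 = phi1),
            class = "qnmr_fit_params")
}

#' @export
print.qnmr_fit_params <- function(x, ...) {
  cat("Fit parameters (theta):\n")
  print(data.frame(species = names(x$shift_offset),
                   shift_offset_ppm = unname(x$shift_offset),
                   width_scale = unname(x$width_scale)),
        row.names = FALSE)
  cat(sprintf("  phase: phi0 = %g rad, phi1 = %g rad/Hz\n", x$phi0, x$phi1))
  invisible(x)
}

#' Closed-form intensity solve
#'
#' Least-squares solution of \code{Z c ~ y} via the singular value
#' decomposition (rank-revealing; never forms the normal equations). If the
#' condition number exceeds 1e10 the minimum-norm solution is returned with
#' a warning and the result is flagged.
#'
#' @param Z Model matrix, n x (K+L), with n >= K+L.
#' @param y Spectrum vector of length n.
#' @return Numeric coefficient vector of length \code{ncol(Z)} with logical
#'   attribute \code{"rank_deficient"}.
#' @export
solve_intensities <- function(Z, y) {
  if (nrow(Z) < ncol(Z)) stop("underdetermined system: n < K + L")
  sv <- svd(Z)
  d <- sv$d
  deficient <- d[1] <= 0 || d[length(d)] / d[1] < 1e-10
  if (deficient)
    warning("model matrix is rank deficient (condition > 1e10); ",
            "returning the minimum-norm solution", call. = FALSE)
  tol <- max(dim(Z)) * .Machine$double.eps * d[1]
  dinv <- ifelse(d > max(tol, d[1] * 1e-15), 1 / d, 0)
  c_hat <- sv$v %*% (dinv * crossprod(sv$u, y))
  structure(as.numeric(c_hat), rank_deficient = deficient)
}

# phased real part of a spectrum at incremental phase (phi0, phi1)
phased_real <- function(spectrum, phi0, phi1) {
  if (phi0 == 0 && phi1 == 0) return(spectrum$real)
  if (is.null(spectrum$complex))
    stop("spectrum has no retained complex values; phase cannot vary")
  Re(spectrum$complex * exp(-1i * (phi0 + phi1 * spectrum$freq_hz)))
}

#' Variable-projection objective
#'
#' The squared norm of the projection of the phased data onto the orthogonal
#' complement of the model column space,
#' \code{||y - Z(theta) c_hat(theta)||^2} with the intensities eliminated in
#' closed form. The phase in \code{theta} is applied as an increment to the
#' spectrum's stored phase.
#'
#' @param theta A \code{qnmr_fit_params}.
#' @param spectrum A \code{qnmr_spectrum} (complex values required if the
#'   phase in theta is nonzero).
#' @param sigs Signature list.
#' @param baseline_order Polynomial baseline order L.
#' @return The scalar objective.
#' @export
varpro_objective <- function(theta, spectrum, sigs, baseline_order = 1L) {
  sigs <- as_signature_list(sigs)
  y <- phased_real(spectrum, theta$phi0, theta$phi1)
  Z <- build_model_matrix(sigs, spectrum$freq_hz, spectrum$params,
                          theta = theta, baseline_order = baseline_order)
  c_hat <- solve_intensities(Z, y)
  r <- y - as.numeric(Z %*% c_hat)
  sum(r * r)
}

fit_bounds_default <- function(spectrum, mean_fwhm_ppm) {
  list(shift_offset = 20 * mean_fwhm_ppm,  # +-20 linewidths, in ppm
       width_scale = c(0.2, 5),
       phi0 = 0.5,
       phi1 = 0.5 / max(abs(spectrum$freq_hz)))
}

theta_flatten <- function(theta, phase_free) {
  p <- c(theta$shift_offset, theta$width_scale)
  if (phase_free) p <- c(p, phi0 = theta$phi0, phi1 = theta$phi1)
  p
}

theta_unflatten <- function(p, species, phase_free, base) {
  K <- length(species)
  th <- fit_params(species,
                   shift_offset = p[seq_len(K)],
                   width_scale = p[K + seq_len(K)],
                   phi0 = if (phase_free) p[2 * K + 1] else base$phi0,
                   phi1 = if (phase_free) p[2 * K + 2] else base$phi1)
  th
}

#' Fit a signature model to a spectrum by variable-projection least squares
#'
#' Minimizes the residual norm \code{||y - Z c||^2} over the nonlinear
#' parameters (per-signature shift offsets and width scales, optionally the
#' phase correction), with the component intensities eliminated in closed
#' form at every step. The outer problem is solved with a bounded
#' derivative-free quadratic-model optimizer (BOBYQA) on scale-normalized
#' parameters; the fit is deterministic for identical inputs and options.
#'
#' @param spectrum A \code{qnmr_spectrum}. Complex values must be retained
#'   when \code{phase = "free"}.
#' @param sigs A \code{qnmr_signature} or list of signatures.
#' @param baseline_order Polynomial baseline order L (default 1: a constant
#'   offset column).
#' @param init Initial \code{\link{fit_params}}; defaults to zero offsets,
#'   unit widths, zero phase.
#' @param phase \code{"free"} to optimize phi0/phi1 jointly with shifts and
#'   widths, \code{"fixed"} to hold them at \code{init}.
#' @param bounds Optional list overriding any of \code{shift_offset}
#'   (half-width of the box in ppm), \code{width_scale} (length-2 range),
#'   \code{phi0}, \code{phi1} (half-widths about the initial values).
#' @param control List: \code{rhoend} (final trust-region radius on the
#'   scaled parameters, default 1e-9), \code{maxfun}.
#' @return An object of class \code{"qnmr_fit"} with components
#'   \code{theta} (optimal parameters), \code{Z} (model matrix at the
#'   optimum), \code{c_hat} (intensities, named by species then baseline),
#'   \code{fitted}, \code{residual}, \code{objective}, \code{y} (the phased
#'   data actually fitted), \code{convergence}, and the inputs.
#' @seealso \code{\link{run_adjustment}} for the residual-based intensity
#'   and phase adjustment of a fit.
#' @export
qnmr_fit <- function(spectrum, sigs, baseline_order = 1L, init = NULL,
                     phase = c("free", "fixed"), bounds = list(),
                     control = list()) {
  stopifnot(inherits(spectrum, "qnmr_spectrum"))
  sigs <- as_signature_list(sigs)
  phase <- match.arg(phase)
  phase_free <- phase == "free"
  if (phase_free && is.null(spectrum$complex))
    stop("phase = \"free\" requires retained complex values; ",
         "use phase = \"fixed\" or recompute the spectrum from the FID")
  species <- names(sigs)
  K <- length(species)
  if (is.null(init)) init <- fit_params(species)
  stopifnot(inherits(init, "qnmr_fit_params"))
  mean_fwhm_ppm <- mean(vapply(sigs, function(s) mean(s$peaks$alpha), 0)) /
    pi / spectrum$params$frequency_mhz
  b <- utils::modifyList(fit_bounds_default(spectrum, mean_fwhm_ppm), bounds)
  ctrl <- utils::modifyList(list(rhoend = 1e-9, maxfun = 20000L), control)

  p0 <- theta_flatten(init, phase_free)
  lower <- c(init$shift_offset - b$shift_offset,
             rep(b$width_scale[1], K))
  upper <- c(init$shift_offset + b$shift_offset,
             rep(b$width_scale[2], K))
  if (phase_free) {
    lower <- c(lower, init$phi0 - b$phi0, init$phi1 - b$phi1)
    upper <- c(upper, init$phi0 + b$phi0, init$phi1 + b$phi1)
  }
  # scale so one unit ~ one FWHM in shift, full range in width/phase
  scl <- c(rep(max(mean_fwhm_ppm, 1e-12), K), rep(1, K))
  if (phase_free) scl <- c(scl, 0.25, 0.25 / max(abs(spectrum$freq_hz)))

  obj <- function(ps) {
    th <- theta_unflatten(ps * scl, species, phase_free, init)
    varpro_objective(th, spectrum, sigs, baseline_order)
  }
  opt <- minqa::bobyqa(par = p0 / scl, fn = obj,
                       lower = lower / scl, upper = upper / scl,
                       control = list(rhobeg = 0.5, rhoend = ctrl$rhoend,
                                      maxfun = ctrl$maxfun, iprint = 0))
  converged <- opt$ierr == 0
  if (!converged)
    warning("optimizer did not report convergence (ierr = ", opt$ierr,
            "); returning the best iterate", call. = FALSE)
  theta_hat <- theta_unflatten(opt$par * scl, species, phase_free, init)
  y <- phased_real(spectrum, theta_hat$phi0, theta_hat$phi1)
  Z <- build_model_matrix(sigs, spectrum$freq_hz, spectrum$params,
                          theta = theta_hat, baseline_order = baseline_order)
  c_hat <- solve_intensities(Z, y)
  fitted <- as.numeric(Z %*% c_hat)
  r <- y - fitted
  names(c_hat) <- c(species,
                    if (baseline_order > 0)
                      paste0("baseline", seq_len(baseline_order)))
  structure(list(theta = theta_hat,
                 Z = Z,
                 c_hat = c_hat,
                 fitted = fitted,
                 residual = r,
                 objective = sum(r * r),
                 y = y,
                 spectrum = spectrum,
                 sigs = sigs,
                 baseline_order = as.integer(baseline_order),
                 phase_mode = phase,
                 convergence = list(converged = converged, ierr = opt$ierr,
                                    feval = opt$feval, msg = opt$msg),
                 rank_deficient = isTRUE(attr(c_hat, "rank_deficient"))),
            class = "qnmr_fit")
}

#' Average fitted full width at half maximum, in Hz and grid points
#' @param fit A \code{qnmr_fit}.
#' @return Named numeric: \code{hz} and \code{points}.
#' @export
fit_fwhm <- function(fit) {
  ws <- fit$theta$width_scale
  fw <- mean(unlist(lapply(seq_along(fit$sigs), function(k)
    fit$sigs[[k]]$peaks$alpha * ws[[k]]))) / pi
  df <- fit$spectrum$freq_hz[2] - fit$spectrum$freq_hz[1]
  c(hz = fw, points = fw / df)
}

#' @export
print.qnmr_fit <- function(x, ...) {
  cat(sprintf("Signature model fit: K = %d species, L = %d baseline, n = %d\n",
              length(x$sigs), x$baseline_order, length(x$y)))
  cat(sprintf("  objective ||r||^2 = %.6g  (phase %s%s)\n", x$objective,
              x$phase_mode,
              if (!x$convergence$converged) "; NOT converged" else ""))
  ks <- seq_along(x$sigs)
  cat("  intensities:\n")
  print(round(x$c_hat[ks], 6))
  invisible(x)
}

#' @export
summary.qnmr_fit <- function(object, ...) {
  ks <- seq_along(object$sigs)
  out <- list(fit = object,
              table = data.frame(
                species = names(object$c_hat)[ks],
                intensity = unname(object$c_hat[ks]),
                shift_offset_ppm = unname(object$theta$shift_offset),
                width_scale = unname(object$theta$width_scale),
                mole_fraction = unname(mole_fractions(object$c_hat[ks],
                                                      object$sigs))),
              phase = c(phi0 = object$theta$phi0, phi1 = object$theta$phi1),
              objective = object$objective,
              rmse_points = sqrt(object$objective / length(object$y)))
  class(out) <- "summary.qnmr_fit"
  out
}

#' @export
print.summary.qnmr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-species parameters and mole fractions:\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat(sprintf("\nPhase: phi0 = %g rad, phi1 = %g rad/Hz; per-point rms residual %.4g\n",
              x$phase[1], x$phase[2], x$rmse_points))
  invisible(x)
}

#' @export
coef.qnmr_fit <- function(object, ...) object$c_hat

#' @export
fitted.qnmr_fit <- function(object, ...) object$fitted

#' @export
residuals.qnmr_fit <- function(object, ...) object$residual

#' @export
plot.qnmr_fit <- function(x, ...) {
  ppm <- hz_to_ppm(x$spectrum$freq_hz, x$spectrum$params)
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(ppm, x$y, type = "l", xlim = rev(range(ppm)),
       xlab = "", ylab = "intensity (a.u.)", ...)
  lines(ppm, x$fitted, col = 2)
  legend("topleft", c("data", "fit"), col = 1:2, lty = 1, bty = "n")
  plot(ppm, x$residual, type = "l", xlim = rev(range(ppm)),
       xlab = "chemical shift (ppm)", ylab = "residual")
  invisible(x)
}

#' Export a fit report as JSON
#'
#' @param fit A \code{qnmr_fit}.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(species = names(fit$sigs),
              intensities = unname(fit$c_hat[seq_along(fit$sigs)]),
              baseline_coefficients =
                if (fit$baseline_order > 0)
                  unname(fit$c_hat[length(fit$sigs) + seq_len(fit$baseline_order)]),
              shift_offset_ppm = unname(fit$theta$shift_offset),
              width_scale = unname(fit$theta$width_scale),
              phi0 = fit$theta$phi0, phi1 = fit$theta$phi1,
              objective = fit$objective,
              convergence = fit$convergence)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
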