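# Orthonormal discrete wavelet transform with periodic boundary handling.
# Filter banks are the standard published orthonormal coefficients; the
# high-pass filter is the quadrature mirror g[m] = (-1)^m h[L-1-m].

wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605, -0.1432942383508097,
           -0.061273359067658524, 0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
           0.049137179673607506, 0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609)
)

get_wavelet <- function(name) {
  if (!name %in% names(wavelet_filters))
    stop("unsupported wavelet '", name, "'; supported: ",
         paste(names(wavelet_filters), collapse = ", "))
  lo <- wavelet_filters[[name]]
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(lo = lo, hi = hi, len = L)
}

# one analysis level, periodic: a[k] = sum_m lo[m+1] x[(2k+m) mod n]
dwt_step <- function(x, filt) {
  n <- length(x)
  half <- n %/% 2L
  base <- 2L * (seq_len(half) - 1L)          # 0-based start of each window
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(filt$len)) {
    xi <- x[(base + (m - 1L)) %% n + 1L]
    a <- a + filt$lo[m] * xi
    d <- d + filt$hi[m] * xi
  }
  list(a = a, d = d)
}

# transpose (= inverse, filters orthonormal) of dwt_step
idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(filt$len)) {
    # for fixed m the windows start at even offsets, so indices are unique
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + filt$lo[m] * a + filt$hi[m] * d
  }
  x
}

#' Periodic orthonormal discrete wavelet transform
#'
#' Mallat pyramid with periodic boundary handling. The input length must be
#' divisible by \code{2^levels}; higher-level callers pad by reflection.
#'
#' @param x Numeric vector.
#' @param wavelet Filter name: one of \code{"haar"}, \code{"db4"},
#'   \code{"sym4"}, \code{"sym8"}.
#' @param levels Decomposition depth.
#' @return List with \code{approx} (coarsest approximation) and
#'   \code{details} (list of detail vectors, finest first).
#' @keywords internal
#' @export
dwt_periodic <- function(x, wavelet = "sym8", levels = 1L) {
  filt <- get_wavelet(wavelet)
  n <- length(x)
  if (levels < 1L) stop("levels must be >= 1")
  if (n %% 2L^levels != 0L)
    stop("length (", n, ") must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels)
}

#' @rdname dwt_periodic
#' @param w A decomposition from \code{dwt_periodic}.
#' @export
idwt_periodic <- function(w) {
  filt <- get_wavelet(w$wavelet)
  a <- w$approx
  for (j in rev(seq_len(w$levels)))
    a <- idwt_step(a, w$details[[j]], filt)
  a
}

#' Wavelet soft-threshold denoising (operator D)
#'
#' Removes stochastic fluctuations from a residual while preserving its
#' spiky deterministic features. The signal is decomposed with an
#' orthonormal wavelet (default: symlet with eight vanishing moments), and
#' each detail level j is soft-thresholded at the level-dependent universal
#' threshold \code{sigma_j * sqrt(2 * log(n_j))}, where \code{sigma_j} is
#' the median absolute deviation of that level's coefficients scaled to the
#' Gaussian (\code{/ 0.6745}) and \code{n_j} the number of coefficients on
#' the level. Approximation coefficients are untouched. Inputs whose length
#' is not divisible by \code{2^levels} are padded by reflection and the
#' result truncated.
#'
#' @param r Numeric vector (length >= \code{2^levels}).
#' @param wavelet Wavelet family name (see \code{\link{dwt_periodic}}).
#' @param levels Decomposition depth; default
#'   \code{max(floor(log2(n)) - 4, 1)}, capped so every level holds at
#'   least as many coefficients as the filter length.
#' @param threshold_scale Multiplier on the universal threshold (default 1).
#' @return The denoised vector, same length as \code{r}.
#' @export
denoise_residual <- function(r, wavelet = "sym8", levels = NULL,
                             threshold_scale = 1) {
  n <- length(r)
  filt <- get_wavelet(wavelet)
  if (is.null(levels)) {
    levels <- max(floor(log2(n)) - 4L, 1L)
    while (levels > 1L && n / 2^levels < filt$len) levels <- levels - 1L
  }
  levels <- as.integer(levels)
  if (n < 2L^levels) stop("input shorter than 2^levels")
  if (all(r == 0)) return(r)
  block <- 2L^levels
  pad <- (block - n %% block) %% block
  x <- if (pad > 0) c(r, rev(r)[seq_len(pad)]) else r
  w <- dwt_periodic(x, wavelet, levels)
  for (j in seq_len(levels)) {
    d <- w$details[[j]]
    sigma <- stats::median(abs(d)) / 0.6745
    thr <- threshold_scale * sigma * sqrt(2 * log(length(d)))
    w$details[[j]] <- sign(d) * pmax(abs(d) - thr, 0)
  }
  out <- idwt_periodic(w)
  out[seq_len(n)]
}
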