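#' Minimal liquid-state spin system
#'
#' Isotropic chemical shifts plus scalar J couplings for a set of spin-1/2
#' nuclei. The Hamiltonian (in frequency units, Hz) is
#' \deqn{H = \sum_i \nu_i I_{z,i} + \sum_{i<j} J_{ij} I_i \cdot I_j}
#' with \code{nu_i = B0 * (delta_i - f0)}. Equivalent-spin groups (e.g. a
#' CH3) are entered literally as spins with equal shifts. Systems are
#' limited to 10 spins (dense per-sector eigensolve).
#'
#' @param shifts_ppm Chemical shift per spin, ppm.
#' @param J_hz Symmetric coupling matrix in Hz with zero diagonal; a scalar 0
#'   is accepted for uncoupled systems.
#' @param species Species name.
#' @return An object of class \code{"qnmr_spin_system"}.
#' @export
spin_system <- function(shifts_ppm, J_hz = NULL, species = "species") {
  N <- length(shifts_ppm)
  if (N < 1L) stop("at least one spin required")
  if (N > 10L)
    stop("systems with more than 10 spins are not supported; ",
         "reduce equivalent groups to composite spins or split the molecule")
  if (is.null(J_hz)) J_hz <- matrix(0, N, N)
  J_hz <- as.matrix(J_hz)
  if (!all(dim(J_hz) == c(N, N))) stop("J matrix must be ", N, " x ", N)
  if (max(abs(J_hz - t(J_hz))) > 1e-9 * max(1, max(abs(J_hz))))
    stop("J coupling matrix must be symmetric")
  diag(J_hz) <- 0
  structure(list(shifts_ppm = as.numeric(shifts_ppm), J_hz = J_hz,
                 species = species, n_spins = N),
            class = "qnmr_spin_system")
}

#' @export
print.qnmr_spin_system <- function(x, ...) {
  cat(sprintf("Spin system '%s': %d spin(s) at ppm [%s]\n", x$species,
              x$n_spins, paste(signif(x$shifts_ppm, 6), collapse = ", ")))
  if (any(x$J_hz != 0)) {
    cat("  J couplings (Hz):\n")
    print(signif(x$J_hz, 6))
  }
  invisible(x)
}

# Hamiltonian block for the basis states in `states` (bit i-1 set = spin i up)
spin_hamiltonian_block <- function(states, nu, J) {
  N <- length(nu)
  nb <- length(states)
  m <- matrix(0, nb, N)  # m_i = +-1/2
  for (i in seq_len(N))
    m[, i] <- ifelse(bitwAnd(states, bitwShiftL(1L, i - 1L)) != 0L, 0.5, -0.5)
  H <- matrix(0, nb, nb)
  diag(H) <- as.numeric(m %*% nu) +
    0.5 * rowSums((m %*% J) * m)  # sum_{i<j} J_ij m_i m_j
  idx <- integer(2L^N); idx[states + 1L] <- seq_len(nb)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (J[i, j] == 0) next
    bi <- bitwShiftL(1L, i - 1L); bj <- bitwShiftL(1L, j - 1L)
    # flip-flop couples states with antiparallel (i, j)
    anti <- which(xor(bitwAnd(states, bi) != 0L, bitwAnd(states, bj) != 0L))
    for (a in anti) {
      s2 <- bitwXor(bitwXor(states[a], bi), bj)
      bpos <- idx[s2 + 1L]
      if (bpos > a) {
        H[a, bpos] <- H[a, bpos] + J[i, j] / 2
        H[bpos, a] <- H[a, bpos]
      }
    }
  }
  H
}

#' Simulate a signature peak table from a spin system
#'
#' Diagonalizes the isotropic spin Hamiltonian per total-Iz sector and emits
#' one Lorentzian peak per allowed single-quantum transition: the frequency
#' is the eigenvalue difference between connected states and the relative
#' intensity is \code{|<b| sum_i I-_i |a>|^2}, normalized so the total
#' intensity equals the number of spins (sum rule). Degenerate transitions
#' are merged; lines weaker than \code{prune} times the strongest are
#' dropped. Lineshape is not part of the Hamiltonian: a single user-supplied
#' decay rate is attached to all transitions.
#'
#' @param sys A \code{qnmr_spin_system}.
#' @param frequency_mhz Spectrometer frequency B0, MHz.
#' @param offset_ppm Spectral offset f0, ppm.
#' @param alpha Decay rate attached to every transition, 1/s (> 0).
#' @param prune Relative intensity threshold below which lines are dropped.
#' @param merge_tol_hz Transitions closer than this are merged into one line.
#' @return A \code{\link{signature}} whose proton count is the number of
#'   spins and whose \code{b} column sums (before pruning) to that count.
#' @export
spin_signature <- function(sys, frequency_mhz, offset_ppm = 0, alpha = 3,
                           prune = 1e-6, merge_tol_hz = 1e-6) {
  stopifnot(inherits(sys, "qnmr_spin_system"))
  if (alpha <= 0) stop("alpha must be positive")
  N <- sys$n_spins
  nu <- (sys$shifts_ppm - offset_ppm) * frequency_mhz
  states <- 0:(2L^N - 1L)
  nup <- vapply(states, function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(N - 1L))) != 0L),
                integer(1))
  sectors <- lapply(0:N, function(k) states[nup == k])  # by number of up spins
  eig <- lapply(sectors, function(st) {
    H <- spin_hamiltonian_block(st, nu, sys$J_hz)
    e <- eigen(H, symmetric = TRUE)
    list(states = st, values = e$values, vectors = e$vectors)
  })
  freqs <- numeric(0); ints <- numeric(0)
  for (k in seq_len(N)) {             # transitions from k up-spins to k-1
    hi <- eig[[k + 1L]]; lo <- eig[[k]]
    # sparse F- map between sectors: flipping one up spin down
    Tm <- matrix(0, length(lo$states), length(hi$states))
    lo_idx <- integer(2L^N); lo_idx[lo$states + 1L] <- seq_along(lo$states)
    for (a in seq_along(hi$states)) {
      s <- hi$states[a]
      for (i in seq_len(N)) {
        bi <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(s, bi) != 0L) {
          b <- lo_idx[bitwXor(s, bi) + 1L]
          Tm[b, a] <- Tm[b, a] + 1
        }
      }
    }
    A <- crossprod(lo$vectors, Tm %*% hi$vectors)  # <b|F-|a>
    I2 <- A^2
    keep <- which(I2 > 0, arr.ind = TRUE)
    if (nrow(keep)) {
      freqs <- c(freqs, hi$values[keep[, 2]] - lo$values[keep[, 1]])
      ints <- c(ints, I2[keep])
    }
  }
  ints <- ints / 2^(N - 1L)  # sum rule: total intensity = N
  ord <- order(freqs)
  freqs <- freqs[ord]; ints <- ints[ord]
  # merge transitions that are degenerate to within merge_tol_hz
  grp <- cumsum(c(TRUE, diff(freqs) > merge_tol_hz))
  fm <- as.numeric(tapply(freqs * ints, grp, sum) / tapply(ints, grp, sum))
  bm <- as.numeric(tapply(ints, grp, sum))
  total <- sum(bm)
  keep <- bm >= prune * max(bm)
  fm <- fm[keep]; bm <- bm[keep]
  sig <- signature(sys$species,
                   peak_table(delta_ppm = fm / frequency_mhz + offset_ppm,
                              alpha = alpha, b = bm),
                   protons = N)
  attr(sig, "total_intensity") <- total
  sig
}
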