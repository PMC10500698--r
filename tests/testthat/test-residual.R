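test_that("the residual decomposition reconstructs r exactly", {
  # zero residual: all parts zero
  d0 <- decompose_residual(numeric(512), smooth_widths = 11)
  expect_equal(d0$rm, numeric(512))
  expect_equal(d0$rb, numeric(512))
  expect_equal(d0$rn, numeric(512))

  # algebraic identity rm + rb + rn = r at machine precision
  for (seed in 1:5) {
    set.seed(seed)
    r <- rnorm(1000) + sin(seq(0, 6, length.out = 1000))
    for (dn in c(TRUE, FALSE)) {
      d <- decompose_residual(r, smooth_widths = c(11, 51), denoise = dn)
      expect_equal(d$rm + d$rb + d$rn, r, tolerance = 1e-13)
    }
  }
})

test_that("a misphased peak leaves a sharp sign transition in rb", {
  p <- std_params(n = 8192)
  alpha <- pi * 5
  sp <- analytic_lorentzian_spectrum(p, 37.3, alpha, phase_err = 0.25)
  sig <- single_peak_signature(p, 37.3, alpha)
  fit <- qnmr_fit(sp, sig, baseline_order = 0, phase = "fixed")
  fwhm_pts <- unname(fit_fwhm(fit)["points"])
  d <- decompose_residual(fit$residual,
                          smooth_widths = 2 * ceiling(8 * fwhm_pts) + 1)
  i0 <- which.min(abs(sp$freq_hz - 37.3))
  win <- 3 * ceiling(fwhm_pts)
  left <- d$rb[(i0 - win):(i0 - 1)]
  right <- d$rb[(i0 + 1):(i0 + win)]
  # opposite-signed lobes either side of the peak centre
  expect_true(mean(sign(left)) * mean(sign(right)) < 0)
  # the transition is localized: |rb| peaks near the line, and the largest
  # point-to-point jump sits within a linewidth of the centre
  expect_lt(abs(which.max(abs(d$rb)) - i0), 10 * fwhm_pts)
  expect_lt(abs(which.max(abs(diff(d$rb))) - i0), fwhm_pts)
})

test_that("allocation weights are row-stochastic with sane fallbacks", {
  p <- std_params(n = 1024)
  f <- freq_grid(p)
  sA <- signature("A", peak_table(-0.5, pi * 3), protons = 1)
  sB <- signature("B", peak_table(0.5, pi * 3), protons = 1)

  # K = 1: all weights are one
  Z1 <- build_model_matrix(sA, f, p, baseline_order = 0)
  W1 <- allocation_weights(Z1, c(2))
  expect_equal(as.numeric(W1), rep(1, 1024))

  # rows always sum to one (baseline column excluded)
  Z2 <- build_model_matrix(list(sA, sB), f, p, baseline_order = 1)
  W2 <- allocation_weights(Z2, c(2, 3, 0.1))
  expect_equal(rowSums(W2), rep(1, 1024), tolerance = 1e-12)
  expect_true(all(W2 >= 0))

  # two components with equal model value split 0.5 / 0.5
  Zeq <- structure(cbind(rep(2, 8), rep(2, 8)),
                   column_roles = c("signature", "signature"),
                   species = c("x", "y"))
  Weq <- allocation_weights(Zeq, c(1, 1))
  expect_equal(as.numeric(Weq), rep(0.5, 16))

  # negative terms are clipped and flagged; empty rows fall back to 1/K
  Zneg <- structure(cbind(c(1, 0, -1), c(1, 0, 2)),
                    column_roles = c("signature", "signature"),
                    species = c("x", "y"))
  Wneg <- allocation_weights(Zneg, c(1, 1))
  expect_equal(attr(Wneg, "n_clipped"), 1L)
  expect_equal(attr(Wneg, "n_uniform"), 1L)
  expect_equal(as.numeric(Wneg[2, ]), c(0.5, 0.5))
  expect_equal(as.numeric(Wneg[3, ]), c(0, 1))
  expect_equal(rowSums(Wneg), rep(1, 3))
})

test_that("intensity adjustment conserves total area and fixes K = 1", {
  p <- std_params(n = 2048)
  sig <- single_peak_signature(p, 20, pi * 4)
  sp <- analytic_lorentzian_spectrum(p, 20, pi * 4)
  fit <- qnmr_fit(sp, sig, baseline_order = 0, phase = "fixed")

  # rm = 0 preserves the intensities exactly
  d0 <- decompose_residual(numeric(2048), smooth_widths = 11)
  adj0 <- adjust_intensities(fit, d0)
  expect_equal(adj0$c_tilde, adj0$c_hat)

  # K = 1 closed form: c~ = c^ + sum(rm) / sum(Z)
  set.seed(8)
  r <- rnorm(2048, 0, 1e-6)
  d1 <- decompose_residual(r, smooth_widths = 0, denoise = FALSE)
  d1$rm <- d1$rb  # force all signal into the misfit term for the check
  d1$rb <- numeric(2048)
  adj1 <- adjust_intensities(fit, d1)
  expect_equal(unname(adj1$c_tilde),
               unname(fit$c_hat[1]) + sum(d1$rm) / sum(unclass(fit$Z)[, 1]),
               tolerance = 1e-12)

  # bookkeeping identity on a random multi-species setup
  f <- freq_grid(p)
  sigs <- list(signature("A", peak_table(-0.5, pi * 3), protons = 1),
               signature("B", peak_table(0.5, pi * 4), protons = 2))
  Z <- build_model_matrix(sigs, f, p, baseline_order = 1)
  y <- as.numeric(Z %*% c(2, 1, 0.01)) + rnorm(2048, 0, 1e-7)
  fit2 <- qnmr_fit(nmr_spectrum(y, p), sigs, phase = "fixed")
  d2 <- decompose_residual(fit2$residual, smooth_widths = 101)
  W <- allocation_weights(fit2$Z, fit2$c_hat)
  adj2 <- adjust_intensities(fit2, d2, W)
  ks <- 1:2
  colsums <- colSums(unclass(fit2$Z)[, ks])
  lhs <- sum(adj2$c_tilde * colsums)
  rhs <- sum(fit2$c_hat[ks] * colsums) + sum(d2$rm)
  expect_equal(lhs, rhs, tolerance = 1e-9 * max(1, abs(rhs)))
})

test_that("phase adjustment recovers an injected phase error", {
  p <- std_params(n = 16384)
  df <- 1 / (16384 * 1e-3)
  alpha <- pi * 20 * df  # FWHM spans 20 grid points
  sp <- analytic_lorentzian_spectrum(p, 37.3, alpha, phase_err = 0.25)
  sig <- single_peak_signature(p, 37.3, alpha)
  fit <- qnmr_fit(sp, sig, phase = "fixed")

  adj <- adjust_phase(fit, schedule = c(16, 400), optimize_phi1 = FALSE)
  expect_equal(adj$theta$phi0, 0.25, tolerance = 0.02)

  # the residual baseline shrinks even though ||r|| need not
  w <- 2 * ceiling(8 * 20) + 1
  rb_before <- sum(decompose_residual(fit$residual, w)$rb^2)
  rb_after <- sum(decompose_residual(adj$residual, w)$rb^2)
  expect_lt(rb_after, rb_before)

  # fixed point: adjusting again moves the phase by less than 1e-3 rad
  adj2 <- adjust_phase(adj, schedule = c(16, 400), optimize_phi1 = FALSE)
  expect_lt(abs(adj2$theta$phi0 - adj$theta$phi0), 1e-3)
})

test_that("with no smoothing and no denoising, the rb criterion reduces to
           least squares", {
  p <- std_params(n = 4096)
  sp <- analytic_lorentzian_spectrum(p, 37.3, pi * 5, phase_err = 0.25)
  sig <- single_peak_signature(p, 37.3, pi * 5)
  fit <- qnmr_fit(sp, sig, phase = "fixed")
  cost_r <- function(ph) {
    r <- qnmradjust:::residual_at_phase(fit, ph)
    sum(r^2)
  }
  cost_rb <- function(ph) {
    r <- qnmradjust:::residual_at_phase(fit, ph)
    sum(decompose_residual(r, smooth_widths = 0, denoise = FALSE)$rb^2)
  }
  o_r <- stats::optimize(cost_r, c(0, 0.5), tol = 1e-9)
  o_rb <- stats::optimize(cost_rb, c(0, 0.5), tol = 1e-9)
  expect_equal(o_rb$minimum, o_r$minimum, tolerance = 1e-6)
})

test_that("run_adjustment is the identity on perfectly modelled data", {
  p <- std_params(n = 4096)
  sp <- analytic_lorentzian_spectrum(p, 25, pi * 4)
  sig <- single_peak_signature(p, 25, pi * 4)
  fit <- qnmr_fit(sp, sig, phase = "fixed")
  adj <- run_adjustment(fit)
  expect_equal(unname(adj$c_tilde), unname(fit$c_hat[1]), tolerance = 1e-6)
  expect_equal(unname(adj$phase), c(0, 0), tolerance = 1e-6)
  # final residual baseline is flat at the numerical noise level
  expect_lt(adj$diagnostics$rb_peak_to_peak, 1e-9 * max(sp$real))
})
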