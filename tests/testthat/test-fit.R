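test_that("solve_intensities matches dense oracles and flags deficiency", {
  set.seed(31)
  # consistent system recovers the generating coefficients
  Z <- matrix(rnorm(200 * 4), 200, 4)
  c0 <- rnorm(4)
  ch <- solve_intensities(Z, as.numeric(Z %*% c0))
  expect_equal(as.numeric(ch), c0, tolerance = 1e-9)

  # y orthogonal to the column space gives zero coefficients
  qr_Z <- qr(Z)
  y_perp <- rnorm(200)
  y_perp <- y_perp - qr.fitted(qr_Z, y_perp)
  expect_equal(as.numeric(solve_intensities(Z, y_perp)), rep(0, 4),
               tolerance = 1e-9)

  # random 50 x 3 against the explicit normal-equations oracle
  for (seed in 1:5) {
    set.seed(seed)
    Z2 <- matrix(rnorm(150), 50, 3)
    y2 <- rnorm(50)
    oracle <- solve(crossprod(Z2), crossprod(Z2, y2))
    expect_equal(as.numeric(solve_intensities(Z2, y2)),
                 as.numeric(oracle), tolerance = 1e-8)
  }

  # rank-deficient matrix warns and returns the minimum-norm solution
  Z3 <- cbind(Z[, 1], Z[, 1], Z[, 2])
  expect_warning(ch3 <- solve_intensities(Z3, as.numeric(Z %*% c0)),
                 "rank deficient")
  expect_true(attr(ch3, "rank_deficient"))
  expect_equal(ch3[1], ch3[2], tolerance = 1e-8)  # minimum norm splits evenly

  expect_error(solve_intensities(matrix(1, 2, 3), 1:2), "underdetermined")
})

test_that("the variable-projection objective equals the explicit residual", {
  p <- std_params(n = 2048)
  f <- freq_grid(p)
  sigs <- list(signature("a", peak_table(-0.3, pi * 3), protons = 1),
               signature("b", peak_table(0.4, pi * 3), protons = 1))
  th <- fit_params(c("a", "b"), shift_offset = c(0.001, -0.002),
                   width_scale = c(1.1, 0.9))

  # y inside the column space: objective vanishes
  Z <- build_model_matrix(sigs, f, p, th, baseline_order = 1)
  y_in <- as.numeric(Z %*% c(3, 1, 0.01))
  sp_in <- nmr_spectrum(y_in, p)
  expect_lt(varpro_objective(th, sp_in, sigs), 1e-12 * sum(y_in^2))

  # generic y: objective equals ||r||^2 of the explicit solve
  set.seed(4)
  y <- y_in + rnorm(2048, 0, 1e-5)
  sp <- nmr_spectrum(y, p)
  ch <- solve_intensities(Z, y)
  r <- y - as.numeric(Z %*% ch)
  expect_equal(varpro_objective(th, sp, sigs), sum(r^2), tolerance = 1e-10)

  # invariant to a global rescaling of any signature's b values
  sigs2 <- sigs
  sigs2[[1]] <- signature("a", peak_table(-0.3, pi * 3, b = 7), protons = 1)
  expect_equal(varpro_objective(th, sp, sigs2),
               varpro_objective(th, sp, sigs), tolerance = 1e-9)
})

test_that("zero-noise model data is recovered to optimizer tolerance", {
  p <- std_params(n = 4096)
  f <- freq_grid(p)
  sigs <- list(signature("a", peak_table(c(-0.4, -0.3), pi * 3, c(1, 1)),
                         protons = 2),
               signature("b", peak_table(c(0.3, 0.45), pi * 4, c(2, 1)),
                         protons = 3))
  th_star <- fit_params(c("a", "b"), shift_offset = c(0.002, -0.003),
                        width_scale = c(1.2, 0.8))
  Z <- build_model_matrix(sigs, f, p, th_star, baseline_order = 1)
  c_star <- c(2, 1, 0.001)
  y <- as.numeric(Z %*% c_star)
  sp <- nmr_spectrum(y, p)

  fit <- qnmr_fit(sp, sigs, phase = "fixed")
  expect_equal(unname(fit$theta$shift_offset),
               unname(th_star$shift_offset), tolerance = 1e-6)
  expect_equal(unname(fit$theta$width_scale),
               unname(th_star$width_scale), tolerance = 1e-6)
  expect_lt(fit$objective, 1e-16 * sum(y^2))
  expect_equal(as.numeric(fit$c_hat), c_star, tolerance = 1e-6)

  # residual identity holds exactly as stored
  expect_equal(fit$residual, fit$y - fit$fitted)
  expect_equal(fit$objective, sum(fit$residual^2))

  # basin check: a perturbed start lands on the same optimum
  fit2 <- qnmr_fit(sp, sigs, phase = "fixed",
                   init = fit_params(c("a", "b"),
                                     shift_offset = c(0.010, -0.011),
                                     width_scale = c(1.5, 1.3)))
  expect_equal(unname(fit2$theta$shift_offset),
               unname(fit$theta$shift_offset), tolerance = 1e-4)
  expect_equal(unname(fit2$theta$width_scale),
               unname(fit$theta$width_scale), tolerance = 1e-4)

  # monotone improvement over the initial objective
  init <- fit_params(c("a", "b"), shift_offset = c(0.01, 0.01))
  expect_lte(qnmr_fit(sp, sigs, phase = "fixed", init = init)$objective,
             varpro_objective(init, sp, sigs))

  # stationarity: central-difference gradient is negligible at the optimum
  eps <- 1e-7
  for (nm in c("a", "b")) {
    up <- fit$theta; up$shift_offset[nm] <- up$shift_offset[nm] + eps
    dn <- fit$theta; dn$shift_offset[nm] <- dn$shift_offset[nm] - eps
    g <- (varpro_objective(up, sp, sigs) -
            varpro_objective(dn, sp, sigs)) / (2 * eps)
    expect_lt(abs(g), 1e-6 * sum(y^2))
  }
})

test_that("an uncorrected phase error biases position and width", {
  p <- std_params(n = 8192)
  alpha <- pi * 5
  sp <- analytic_lorentzian_spectrum(p, fp_hz = 37.3, alpha = alpha,
                                     phase_err = 0.25)
  sig <- single_peak_signature(p, 37.3, alpha)
  fit <- qnmr_fit(sp, sig, baseline_order = 0, phase = "fixed")
  fwhm_ppm <- (alpha / pi) / 400

  # chemical shift pulled off centre by a noticeable fraction of the FWHM
  expect_gt(abs(fit$theta$shift_offset) / fwhm_ppm, 0.05)
  # residual is far from zero and has the antisymmetric two-lobed shape
  expect_gt(fit$objective, 1e-6 * sum(sp$real^2))
  near <- abs(sp$freq_hz - 37.3) < 20 * (alpha / pi)
  expect_lt(min(fit$residual[near]), -0.1 * max(abs(fit$residual)))
  expect_gt(max(fit$residual[near]), 0.1 * max(abs(fit$residual)))
})

test_that("phase-error bias curves have the expected parity", {
  p <- std_params(n = 4096)
  alpha <- pi * 5
  sig <- single_peak_signature(p, 37.3, alpha)
  errs <- function(phi) {
    sp <- analytic_lorentzian_spectrum(p, 37.3, alpha, phase_err = phi)
    fit <- qnmr_fit(sp, sig, baseline_order = 0, phase = "fixed")
    c(intensity = unname(fit$c_hat[1]) - 1,
      shift = unname(fit$theta$shift_offset))
  }
  for (phi in c(0.1, 0.25, 0.4, 0.5)) {
    plus <- errs(phi)
    minus <- errs(-phi)
    # intensity error is even, chemical-shift error odd in the phase error
    # (agreement limited by the optimizer's termination precision)
    expect_equal(plus["intensity"], minus["intensity"], tolerance = 5e-3,
                 ignore_attr = TRUE)
    expect_equal(plus["shift"], -minus["shift"], tolerance = 5e-3,
                 ignore_attr = TRUE)
    expect_gt(abs(plus["shift"]), 1e-4 * phi)  # genuinely odd, not zero
  }
})

test_that("free-phase fitting recovers an injected phase error", {
  p <- std_params(n = 4096)
  sp <- analytic_lorentzian_spectrum(p, 37.3, pi * 5, phase_err = 0.2)
  sig <- single_peak_signature(p, 37.3, pi * 5)
  fit <- qnmr_fit(sp, sig, phase = "free")
  # a single resonance pins down only the local phase phi0 + phi1 * f_p
  expect_equal(fit$theta$phi0 + fit$theta$phi1 * 37.3, 0.2,
               tolerance = 1e-3)
  expect_equal(unname(fit$c_hat[1]), 1, tolerance = 1e-3)
})
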