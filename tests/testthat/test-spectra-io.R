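test_that("compute_spectrum produces the documented grid and locates peaks", {
  p <- std_params(n = 1024, dt = 5e-4)
  t <- (0:1023) * 5e-4

  # all-zero FID -> all-zero spectrum
  sp0 <- compute_spectrum(nmr_fid(complex(1024), p))
  expect_equal(sp0$real, numeric(1024))

  # grid endpoints: min = -1/(2 dt), span = 1/dt
  sp <- compute_spectrum(nmr_fid(exp((2i * pi * 123 - 8) * t), p))
  expect_equal(min(sp$freq_hz), -1 / (2 * 5e-4))
  df <- sp$freq_hz[2] - sp$freq_hz[1]
  expect_equal(df, 1 / (1024 * 5e-4), tolerance = 1e-12)
  expect_equal(max(sp$freq_hz) + df - min(sp$freq_hz), 1 / 5e-4,
               tolerance = 1e-12)

  # noiseless decaying exponential peaks at the grid point nearest f_c
  for (fc in c(123, -310.7, 55.3)) {
    spc <- compute_spectrum(nmr_fid(exp((2i * pi * fc - 8) * t), p))
    expect_equal(spc$freq_hz[which.max(spc$real)],
                 spc$freq_hz[which.min(abs(spc$freq_hz - fc))])
  }

  # direct-DFT oracle on a small grid
  psmall <- std_params(n = 64, dt = 1e-3)
  set.seed(42)
  s <- complex(real = rnorm(64), imaginary = rnorm(64))
  spd <- compute_spectrum(nmr_fid(s, psmall), half_first_point = FALSE)
  tt <- (0:63) * 1e-3
  oracle <- vapply(spd$freq_hz, function(fk)
    1e-3 * sum(s * exp(-2i * pi * fk * tt)), complex(1))
  expect_equal(spd$complex, oracle, tolerance = 1e-10)

  expect_error(nmr_fid(c(1 + 0i, NaN), std_params(n = 8)), "length")
  expect_error(nmr_fid(complex(real = c(1, NA), imaginary = c(0, 0),
                               length.out = 8), std_params(n = 8)),
               "non-finite")
})

test_that("DFT preserves total power under the documented scaling", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 512
    dt <- 2.5e-4
    s <- complex(real = rnorm(n), imaginary = rnorm(n))
    sp <- compute_spectrum(nmr_fid(s, std_params(n = n, dt = dt)),
                           half_first_point = FALSE)
    expect_equal(sum(Mod(sp$complex)^2), n * dt^2 * sum(Mod(s)^2),
                 tolerance = 1e-9)
  }
})

test_that("phase rotation is an exact group action on spectra", {
  p <- std_params(n = 512)
  set.seed(7)
  sp <- compute_spectrum(nmr_fid(complex(real = rnorm(512),
                                         imaginary = rnorm(512)), p))
  # identity and inverse
  expect_equal(phase_rotate(sp, 0, 0), sp)
  back <- phase_rotate(phase_rotate(sp, 0.3, 1e-4), -0.3, -1e-4)
  expect_equal(back$real, sp$real, tolerance = 1e-12)
  expect_equal(back$complex, sp$complex, tolerance = 1e-12)

  # composition equals rotation by summed angles
  for (i in 1:5) {
    set.seed(i)
    a <- runif(2, -0.5, 0.5)
    b <- runif(2, -0.5, 0.5)
    two <- phase_rotate(phase_rotate(sp, a[1], a[2]), b[1], b[2])
    one <- phase_rotate(sp, a[1] + b[1], a[2] + b[2])
    expect_equal(two$complex, one$complex, tolerance = 1e-12)
    expect_equal(unname(two$phase), unname(one$phase))
  }

  # pure absorption rotated by pi/2 gives the antisymmetric dispersion shape
  abs_sp <- analytic_lorentzian_spectrum(p, fp_hz = 0, alpha = 20)
  disp <- phase_rotate(abs_sp, pi / 2, 0)
  i0 <- which(abs_sp$freq_hz == 0)
  k <- 1:200
  expect_equal(disp$real[i0 + k], -disp$real[i0 - k], tolerance = 1e-10)
  expect_lt(abs(disp$real[i0]), 1e-12)

  sp$complex <- NULL
  expect_error(phase_rotate(sp, 0.1), "complex")
})

test_that("JCAMP-DX round trips FIDs and spectra and rejects bad input", {
  p <- std_params(n = 256, dt = 2e-4, f0 = 4.7)
  set.seed(11)
  fid <- nmr_fid(complex(real = rnorm(256), imaginary = rnorm(256)), p)
  tf <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(fid, tf)
  fid2 <- read_jcamp(tf)
  expect_s3_class(fid2, "qnmr_fid")
  expect_equal(fid2$samples, fid$samples, tolerance = 1e-9)
  expect_equal(fid2$params$dwell_time, 2e-4, tolerance = 1e-12)
  expect_equal(fid2$params$offset_ppm, 4.7)

  sp <- compute_spectrum(fid)
  ts <- withr::local_tempfile(fileext = ".jdx")
  write_jcamp(sp, ts)
  sp2 <- read_jcamp(ts)
  expect_s3_class(sp2, "qnmr_spectrum")
  expect_equal(sp2$real, sp$real, tolerance = 1e-9)
  expect_equal(sp2$freq_hz, sp$freq_hz, tolerance = 1e-9)

  # truncated file is an error, not a silent partial read
  lines <- readLines(ts)
  writeLines(lines[1:18], ts)
  expect_error(read_jcamp(ts), "truncated")

  expect_error(read_jcamp(withr::local_tempfile(fileext = ".jdx")),
               "not found")
})

test_that("a minimal hand-written AFFN XYDATA record is readable", {
  fixture <- c(
    "##TITLE= minimal synthetic spectrum",
    "##JCAMP-DX= 5.00",
    "##DATA TYPE= NMR SPECTRUM",
    "##.OBSERVE FREQUENCY= 100",
    "##XUNITS= HZ",
    "##YUNITS= ARBITRARY UNITS",
    "##NPOINTS= 16",
    "##FIRSTX= -8",
    "##LASTX= 7",
    "##XFACTOR= 1",
    "##YFACTOR= 0.5",
    "##XYDATA= (X++(Y..Y))",
    "-8 0 2 4 6 8 10",
    "-2 12 14 16 14 12 10",
    "4 8 6 4 2",
    "##END=")
  tf <- withr::local_tempfile(fileext = ".jdx")
  writeLines(fixture, tf)
  sp <- read_jcamp(tf)
  expect_length(sp$real, 16)
  expect_equal(sp$freq_hz, seq(-8, 7))
  expect_equal(sp$real[1:4], c(0, 1, 2, 3))  # YFACTOR applied
  expect_equal(sp$params$frequency_mhz, 100)

  # compressed (ASDF) data is rejected with a clear message
  fixture[13] <- "-8 0 J2K4L6"
  writeLines(fixture, tf)
  expect_error(read_jcamp(tf), "AFFN")
})

test_that("spectra export to CSV with both frequency axes", {
  p <- std_params(n = 64, b0 = 200, f0 = 2)
  sp <- compute_spectrum(nmr_fid(complex(real = 1:64, imaginary = 0), p))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, tf)
  d <- read.csv(tf)
  expect_named(d, c("freq_hz", "ppm", "intensity"))
  expect_equal(d$ppm, d$freq_hz / 200 + 2)
})
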