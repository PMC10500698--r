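# qnmradjust

Model-based quantitative NMR (qNMR) of known mixtures, with a residual
adjustment step that de-biases concentration estimates when real lineshapes
deviate from the fitted model.

## What it does

Given a 1D spectrum of a mixture whose species are known, the package fits
a linear combination of parametric *signature spectra* — Lorentzian peak
tables, or multiplets simulated from a minimal spin Hamiltonian (shifts +
J couplings) — and reads mole fractions off the fitted intensities:

- the spectrum is modelled as *x = Zc*, where the columns of *Z* hold the
  signatures z_k(f) = Σ_p b_p · u(f | f_p, α_p) (Lorentzians with FWHM
  α_p/π Hz) plus a polynomial baseline basis;
- fitting minimizes ‖y − Zc‖² over shifts, widths and phase by variable
  projection: the intensities are always solved in closed form,
  ĉ = Z⁺y, inside the nonlinear search.

Least squares alone is biased whenever peaks are not exactly Lorentzian
(field inhomogeneity, diffusion, higher-order couplings). The package's
core contribution is the post-fit adjustment:

1. decompose the residual exactly as r = r_m + r_b + r_n, with the noise
   removed by wavelet soft-thresholding (operator D) and the slowly varying
   residual baseline extracted by multistage median filtering (operator S):
   r_n = r − Dr, r_b = SDr, r_m = Dr − SDr;
2. fine-tune the phasing by minimizing ‖r_b(φ0, φ1)‖² — misphased peaks
   leave sharp sign transitions in the median-filtered residual, so
   flattening r_b is a sensitive phase criterion;
3. reallocate the misfit term r_m to the components with row-stochastic
   weights W_ik = Ẑ_ik ĉ_k / Σ_k Ẑ_ik ĉ_k, giving adjusted intensities
   c̃_k = ĉ_k + (Σ_i W_ik r_m,i) / (Σ_i Ẑ_ik), which recovers the signal
   that peak integration would have counted but the rigid model missed.

A synthetic-data module generates mixture FIDs with controlled
misspecification (Gaussian broadening, higher-order decay, phase errors,
baseline offsets, calibrated noise) so the whole pipeline can be exercised
and scored against known ground truth without any external data. JCAMP-DX
input/output (uncompressed AFFN) is included.

## Worked example

```r
library(qnmradjust)

p <- acq_params(dwell_time = 1e-3, n_points = 4096, frequency_mhz = 400)
sigs <- list(
  signature("methanol_like", peak_table(c(-0.70, -0.55), pi * 2.0, c(1, 1)),
            protons = 4),
  signature("ether_like", peak_table(c(-0.10, 0.05, 0.20), pi * 3.0,
                                     c(1, 2, 1)), protons = 3),
  signature("ester_like", peak_table(c(0.60, 0.80), pi * 4.5, c(3, 1)),
            protons = 2))

# five samples with Gaussian-broadened peaks, a 0.05 rad phase error,
# and SNR 500 -- i.e. data the Lorentzian model cannot fit exactly
ds <- generate_dataset(sigs, n_samples = 5, params = p,
                       distortion = distortion_spec(gaussian_fwhm_hz = 1.6,
                                                    phi0 = 0.05, snr = 500),
                       master_seed = 7)
report <- run_pipeline(ds)
report
#> qNMR quantification report: 5 sample(s), 3 species
#>   RMSE_avg (least squares): 0.00425701 mol/mol
#>   RMSE_avg (adjusted):      0.00225092 mol/mol
#>   improvement: 47.1 %

round(rbind(truth = ds$truth[1, ], ls = report$fractions_ls[1, ],
            adjusted = report$fractions_adj[1, ]), 4)
#>          methanol_like ether_like ester_like
#> truth           0.2042     0.1372     0.6587
#> ls              0.2103     0.1389     0.6508
#> adjusted        0.2044     0.1407     0.6549
```

The report carries both estimators side by side: `fractions_ls` are the
plain variable-projection least-squares mole fractions, `fractions_adj`
the residual-adjusted ones, each with per-sample and average RMSE against
the generating truth (mol/mol). Here the adjustment roughly halves the
average error.

Single spectra follow the usual modelling idiom:

```r
spec <- compute_spectrum(ds$fids[[1]])
fit  <- qnmr_fit(spec, sigs)          # S3 object: coef(), residuals(), plot()
adj  <- run_adjustment(fit)           # phase tuning + misfit reallocation
coef(adj)                             # adjusted intensities
```

A thin command-line front end over the same functions is installed at
`inst/cli/qnmr.R` (subcommands `simulate`, `fit`, `adjust`, `quantify`).

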