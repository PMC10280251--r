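# ivaecg

Blind removal of the three hardest ECG contaminants — baseline wander (BW),
electrode movement (EM) and muscle artifact (MA) — from multichannel
recordings by **independent vector analysis (IVA)**, with FastICA and
CCA-based separation as single-data-set baselines. The package is aimed at
biomedical signal-processing researchers who want a reproducible,
self-contained benchmark of joint blind source separation for ECG
de-noising: seeded generators for all four sources, the delayed-data-set
construction, three IVA variants, alignment and scoring, and a Monte-Carlo
harness with tidy outputs.

## Model

A K-channel acquisition is modelled as an instantaneous linear mixture
`X^d = A^d S^d` over `d = 1..D` data sets; here the data sets are the
recording and its delayed copies. Separation estimates un-mixing matrices
`W^d` with `Y^d = W^d X^d` by minimizing the IVA mutual-information cost

    I_IVA = sum_k ( sum_d H[y_k^d] - I[y_k] ) - sum_d log|det W^d| - C,

where `y_k = (y_k^1, ..., y_k^D)` is the k-th *source component vector*
(SCV): independent of the other SCVs, dependent within. The entropy terms
are realized by an SCV prior — multivariate Gaussian (`iva_g()`, second-order
statistics), Laplacian (`iva_l()`, higher-order statistics) or generalized
Gaussian with per-SCV shape estimation (`iva_ggd()`, both). Quality is
scored on the global matrices `G^d = W^d A^d` via the joint
inter-symbol-interference index `isi_com()` (0 = ideal, 1 = worst), the
leakage index `u_wa()`, and the relative RMS error `crmse()` of the
reconstructed ECG after `align_sources()`.

## Worked example

```r
library(ivaecg)

src  <- gen_standard_sources(fs = 360, duration = 8, seed = 1)
src
#> <source_set> 4 sources x 2880 samples @ 360 Hz [ECG, BW, EM, MA]

coll <- make_datasets(src, delays = c(0, 1, 2, 3), snr_db = 20,
                      mixing_seed = 2)
coll
#> <dataset_collection> D = 4 data sets, 4 x 2877 each (snr = 20 dB)

fit <- iva_g(coll)
fit
#> <unmixing_result> iva_g: D = 4, K = 4, 96 iterations, converged

evaluate_run(fit, coll)
#> # A tibble: 1 x 6
#>   algorithm isi_com  u_wa crmse n_iterations converged
#>   <chr>       <dbl> <dbl> <dbl>        <int> <lgl>
#> 1 iva_g       0.149  1.72 0.531           96 TRUE
```

`isi_com = 0.149` says the cross-data-set global matrix is close to a scaled
permutation (0 would be perfect un-mixing); `crmse = 0.531` is the relative
RMS error of the recovered ECG against the ground-truth source at this 20 dB
noise level. For a recording without ground truth, `denoise(recording,
algorithm = "iva_g")` runs the full pipeline and picks the ECG component by
a QRS-periodicity score. `run_grid(grid_config(...))` sweeps algorithms,
block lengths, SNRs and replicates into a tidy tibble
(`summarize_grid()`, `plot_grid_summary()`), and `reproduce_table(1:3)`
regenerates the three benchmark table layouts. A thin command line lives at
`inst/cli/ivaecg.R` (subcommands `simulate`, `denoise`, `grid`, `table`).

Real recordings in WFDB format (16 and 212) are read with `read_wfdb()`;
to benchmark against real artifacts, download the PhysioNet Noise Stress
Test Database (`nstdb`: records `bw`, `em`, `ma`) and pass the record paths
via `grid_config(data_source = "wfdb", records = ...)`.

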