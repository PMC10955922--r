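# gasblendr

Multicomponent trace-gas analysis from blended mid-infrared absorbance
spectra: physical forward simulation, multi-task neural retrieval, and
gradient-based attribution — in one R package.

## The problem

Broadband absorption spectroscopy of gas mixtures (here: methane, acetone
and water vapour in the 2950–3150 cm⁻¹ window over a 580 m multipass
path) produces *blended* spectra in which the rovibrational features of
all components overlap. Two questions must be answered at once: **which**
components are present, and **how much** of each. Regression alone cannot
distinguish "a tiny amount" from "absent plus model error"; `gasblendr`
answers both jointly.

## What the package does

1. **Forward model** — line-by-line Beer–Lambert absorbance
   `α(ν) = S(T)·φ(ν)·P·c·L` with Voigt line shapes (Humlicek's
   complex-probability approximation), HITRAN-format 160-character `.par`
   line-list ingest, PNNL-style cross-section tables (absorbance per
   ppm·m), and linear blending of per-gas unit spectra on a shared
   3321-point grid.
2. **Corpus generator** — seven mixture classes (MAW, MA, MW, AW, M, A,
   W) with uniform concentration draws (0–50 ppm trace gases, 1000–2000
   ppm water), six-digit labels (3 presence flags + 3 concentrations),
   and four instrument-perturbation channels: source power fluctuation,
   unknown-absorber bands, white noise, baseline miscalibration.
   Synthetic line-list fixtures make every example and test run with no
   database download.
3. **Multi-task network** — a 3321-196-74-211-6 perceptron with three
   sigmoid presence heads and three linear concentration heads, trained
   with Adam (β₁ = 0.5, β₂ = 0.999) on the joint loss
   `L = BCE(presence) + 100·MSE(concentration)`, written from scratch in
   vectorised R on BLAS. Inference is **confidence-gated**: a
   concentration is reported only when its presence probability exceeds
   0.5, otherwise it is forced to zero.
4. **Metrics** — exact match ratio (EMR), Hamming accuracy (HA), a
   composition confusion matrix with a "none" bucket, and per-gas R² /
   MAE / MRE (relative errors over truly-present samples).
5. **Gradient activation maps** — last-hidden activation map `M`, guided
   input gradients `g_b`, and their fusion `g_a = g_b · M̃` interpolated
   onto the spectral grid, highlighting the regions that drive a
   prediction.

## Worked example

The compact benchmark: simulate a 1750-sample fixture corpus, train for
100 epochs, evaluate the 9:1 holdout.

```r
library(gasblendr)

cfg <- benchmark_config()               # 1750 samples, 100 epochs, batch 256
ds  <- run_simulate(cfg, seed = 1)      # unit spectra + corpus (~2 s)
res <- run_train(cfg, ds, seed = 1)     # Adam training (~40 s, 1 CPU)
report <- run_eval(res$state, ds, indices = res$split$test)
print(report)
#> <metrics_report> EMR = 0.9543, HA = 0.9848
#> <regression_metrics>
#>      gas        r2       mae        mre n_present
#>  methane 0.9869608  1.085803 0.11523096       106
#>  acetone 0.9970518  0.473191 0.11689162        93
#>    water 0.9913428 43.579322 0.05680025        99

pred <- predict_gated(res$state, ds$X[res$split$test[1], ])
print(pred)
#> <sam_prediction> ci_prob = (1.000, 1.000, 0.985), cr_gated ppm = (42.63, 44.98, 1226)
# true label of that spectrum: present/present/present, (43.71, 44.44, 1214.41) ppm
```

Reading the numbers: 95.4% of held-out spectra have all three presence
flags exactly right, 98.5% of individual flags are correct, and the
retrieved concentrations track truth with R² ≥ 0.987 per gas. The
residual identification errors sit at trace concentrations of a few ppm,
where a gas's signature is comparable to the unknown-absorber
perturbations — the detection-limit regime discussed in the methods
vignette (`vignettes/gasblendr-methods.Rmd`).

Attribution for any spectrum:

```r
g <- gam(res$state, ds$X[1, ], default_grid(), targets = c(1, 4))  # methane heads
plot(wavenumbers(default_grid()), abs(g$g_a), type = "h")
```

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gasblendr.R", package="gasblendr"))') \
    simulate --config pipeline.yaml --out corpus.h5
# also: train, eval, predict, gam, cv — each with --config/--seed/--out
```

## Scaling up

The same code paths run the full-scale recipe: point the pipeline config
at real line lists and a measured acetone cross-section
(`gases: {source: files, methane_par: ..., water_par: ..., acetone_xsec: ...}`),
set `dataset: {m: 17500}` and `train: {epochs: 500}`, and use
`run_simulate`/`run_train`/`run_cv` unchanged.
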