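---
title: "Blended-spectrum simulation and multi-task retrieval: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blended-spectrum simulation and multi-task retrieval: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasblendr)
```

## The problem

Broadband mid-infrared absorption spectroscopy can in principle identify
and quantify every infrared-active gas in a mixture at once, but in
practice the rovibrational bands of small molecules overlap heavily. In
the 2950--3150 cm$^{-1}$ window used throughout this package, methane's
$\nu_3$ C--H stretch manifold, water vapour's dense line forest and
acetone's broad C--H stretch band all interleave, so no single isolated
feature identifies any one component. `gasblendr` implements the full
workflow for this setting: a line-by-line physical forward model, a
labelled synthetic training corpus with realistic instrument
perturbations, a multi-task neural network that jointly decides *which*
gases are present and *how much* of each, standard multi-label and
regression metrics, and a gradient-based attribution map that shows which
spectral regions drive a given prediction.

## Forward model

Beer--Lambert absorbance at wavenumber $\nu$ for one transition is

$$\alpha(\nu) = S(T)\,\phi(\nu)\,P\,c_g\,L,$$

with line intensity $S(T)$, normalised line shape $\phi$, pressure $P$,
mixing ratio $c_g$ and path length $L$. The package evaluates this per
line with:

* **Voigt line shapes.** $\phi$ is the convolution of the
  pressure-broadened Lorentzian (HWHM $\gamma_\mathrm{air} P
  (296/T)^{n_\mathrm{air}}$; self-broadening is neglected in the trace
  regime) with the thermal Doppler Gaussian. The complex probability
  function is evaluated with Humlicek's four-region rational
  approximation, the standard in line-by-line atmospheric codes; its real
  part is accurate to better than $10^{-4}$ relative everywhere, which the
  test suite verifies against a brute-force numerical convolution of the
  two shapes.
* **Line intensities at the 296 K reference.** The operating point
  (1 atm, 296 K) coincides with the database reference temperature, so
  $S(T) = S(T_\mathrm{ref})$; the lower-state energy and temperature
  exponent are retained in the data model for future non-reference
  evaluation.
* **Molecular column.** The symbolic $P c_g L$ is implemented as
  ideal-gas number density $n = P/k_B T$ (molecules cm$^{-3}$) times the
  mixing ratio times $L$ in cm, so intensities in cm$^{-1}$/(molecule
  cm$^{-2}$) yield dimensionless absorbance. A unit test pins this
  conversion against an independent scalar evaluation.
* **Wing cutoff.** Each line is evaluated within $\pm 25$ cm$^{-1}$ of
  its centre (configurable), the usual convention balancing wing accuracy
  against cost.
* **Cross-section gases.** Acetone-like absorbers come as composite
  tables of absorbance per (ppm m) versus wavenumber. Such tables are
  conventionally base-10; ingest multiplies by $\ln 10$ (configurable via
  `xsec_log_base`) and by the path length, interpolates linearly onto the
  grid, refuses extrapolation, and clips negative baseline artifacts to
  zero with a reported count.

The shared spectral axis is 2950--3150 cm$^{-1}$ with exactly 3321
inclusive points (spacing $200/3320 \approx 0.0602$ cm$^{-1}$). Where a
nominal resolution of 0.06 or 0.062 cm$^{-1}$ might be quoted for such a
system, the package treats the point count as the defining contract, and
every artifact (dataset container, checkpoint, attribution map) carries it
end to end.

Mixture spectra are linear: $S_b = \sum_i c_i u_i + N$, where $u_i$ is the
*unit absorbance* of gas $i$ (absorbance of 1 ppm under the stated
conditions) and $N$ collects noise. Unit spectra are computed once and
cached by the generator, so corpus synthesis is a matrix product.

## Synthetic corpus

The generator draws seven mixture classes — MAW, MA, MW, AW, M, A, W over
(methane, acetone, water) — by default in equal numbers. Present gases
get uniform concentrations: 0--50 ppm for the two trace gases, 1000--2000
ppm for water (normal indoor humidity over a 580 m multipass path);
absent gases are exactly 0 with presence flag 0. Labels are six digits:
three binary component identifiers (CI) then three concentrations (CR).

Four perturbation channels harden the corpus, applied in a fixed order
(they do not commute):

1. **Source power fluctuation** — a multiplicative gain $1 +
   A\sin(2\pi f u + \varphi)$ in transmittance space, $A = 2\%$, at most
   3 cycles across the window;
2. **Unknown absorbers** — 0--3 additive Gaussian or Lorentzian bands per
   sample, HWHM 1--20 cm$^{-1}$, peak depth up to 0.1 absorbance,
   truncated to zero beyond 5 widths;
3. **White detection noise** — $\sigma$ resolved so the water-band peak at
   mid-range concentration has SNR $\approx 150$, the realistic figure
   for the strongest absorber in such a system (about $6\times10^{-3}$
   absorbance for the default fixtures);
4. **Baseline miscalibration** — a polynomial of order $\le 2$ with
   coefficients up to 0.05 absorbance, emulating non-standard
   normalisation.

Each channel can be disabled individually and a disabled channel is the
identity, which the tests exploit. Generation is a pure function of
(configuration, seed).

**Fixtures.** So that everything runs without any database download, the
package ships a synthetic fixture generator: `dense-narrow` draws 50--500
random Voigt lines (methane/water-like), `broad-band` a smooth multi-hump
cross-section (acetone-like). The three default fixture gases were scaled
once for realistic peak absorbances over 580 m — roughly 0.015, 0.038 and
$6\times10^{-4}$ per ppm for the methane-, acetone- and water-like gas —
giving typical mixture peaks of order 0.1--1. The fixtures emulate the
*structure* of real line lists (dense overlapping narrow lines vs. one
broad band, overlapping supports) but not their true intensity patterns,
band shapes or temperature dependence; results on fixtures therefore
validate the pipeline's mechanics and learnability, not radiometric
accuracy against real gases.

## The multi-task network

The analysis model is a fully connected perceptron
3321--196--74--211--6 with ReLU hidden units and dropout 0.2 between the
last hidden layer and the output layer. The six outputs split into three
sigmoid presence heads (CI) and three linear concentration heads (CR).
Training minimises

$$\mathcal{L} = \mathcal{L}_\mathrm{iden} + \lambda\,\mathcal{L}_\mathrm{con},$$

the mean binary cross-entropy over presence flags plus $\lambda = 100$
times the mean squared error over concentrations (absent gases included
with target 0). The optimiser is Adam with $\beta_1 = 0.5$, $\beta_2 =
0.999$; the full-scale recipe is batch 256, 500 epochs, learning rate
0.01. Implementation choices the architecture leaves open:

* **Hidden activation** is ReLU — the standard MLP default, and the choice
  that makes guided backpropagation well defined. `tanh` and `identity`
  are available via configuration.
* **Concentration scaling.** The gases span two orders of magnitude in
  ppm, so CR targets are normalised per gas by (50, 50, 2000) and the
  scaling inverted at prediction; raw-ppm training is available by setting
  the scale to ones.
* **Cross-entropy clamping** at $\varepsilon = 10^{-7}$.
* **Initialisation** defaults to fan-in-scaled uniform. A second mode,
  `"spectral"`, sets the first layer to whitened principal-component
  loadings of the training spectra with a positive bias shift (so units
  start active and the network begins as a well-conditioned near-linear
  map of standardised PC scores), deeper layers to scaled orthogonal
  matrices, and the output layer to zero.
* **Learning-rate schedule** defaults to constant; `"cosine_tail"` holds
  the rate for the first half of training and decays it to zero along a
  cosine over the second half.

**Gating.** At inference a concentration is reported only when its CI
probability strictly exceeds 0.5; otherwise it is forced to 0 (and
reported concentrations are clipped at 0). A probability of exactly 0.5
gates to absent. Gating converts the classic ambiguity of near-zero
regression outputs — model error or genuinely absent gas? — into an
explicit decision, and is idempotent.

## The compact benchmark and its numerical rationale

The package's reference small-scale protocol (`benchmark_config()`) is
1750 samples (250 per class), a 9:1 holdout, 100 epochs at batch 256 —
700 optimiser steps. Two findings, reproducible with the shipped tests,
fixed its remaining knobs:

* At 700 steps the full-scale constant rate of 0.01 is far beyond Adam's
  stability boundary for this architecture on nonnegative, strongly
  correlated absorbance inputs: most ReLU units die within the first
  epochs (an always-off unit receives zero gradient and never recovers)
  and the loss oscillates an order of magnitude above its floor. The
  boundary sits near 0.003; the benchmark uses 0.002 with the cosine
  tail, the value that minimises the *training* objective.
* Spectral initialisation roughly halves the identification loss
  reachable in 100 epochs compared with fan-in random initialisation,
  and markedly reduces seed-to-seed spread.

With this protocol the holdout exact-match ratio typically lands in the
low-to-mid 0.9s with Hamming accuracy near 0.98 and per-gas $R^2$ above
0.985. The residual identification errors are not optimisation noise:
across independent training seeds the misidentified samples are the
*same* spectra, namely those whose present trace gas sits below a few ppm
— a regime in which its spectral contribution is comparable to the
unknown-absorber perturbation envelope (0.1 absorbance $\approx$ 2.6 ppm
of the acetone-like fixture) and the uniform concentration prior makes
"absent" the better-calibrated call. Because presence labels follow the
concentration down to 0 ppm, a fraction of held-out samples is
irreducibly ambiguous for *any* classifier under these conditions; the
exact-match ceiling of a draw can be estimated by counting held-out
samples with a present trace gas under about 3 ppm. Larger corpora push
the detection threshold down only slowly (it is set by the perturbation
envelope, not by sample noise). This is the expected behaviour of the
real measurement problem, not an artifact: a sensor with a finite
detection limit cannot certify the presence of an arbitrarily small
admixture.

## Evaluation metrics

* **Exact match ratio (EMR)** — fraction of samples whose three presence
  flags are all correct;
* **Hamming accuracy (HA)** — fraction of individual flags correct;
  always $\ge$ EMR;
* **Composition confusion** — presence patterns mapped to the seven
  classes plus a "none" bucket (a model may predict no gas at all), with
  row-normalised proportions;
* **Regression metrics** — per-gas $R^2 = 1 - \sum(c-\hat c)^2 /
  \sum(c-\bar c)^2$, MAE in ppm, and relative errors computed only over
  samples where the gas is truly present with $c > 0$ (relative error is
  undefined at zero truth; absent-gas behaviour is already captured by the
  identification metrics). $R^2$ of a zero-variance truth column is
  reported as `NA` with a warning.

All four families are pinned to scalar brute-force oracles in the tests.

## Gradient activation maps

For a prediction of interest the package computes three objects:

* the **activation map** $M_x = \sum_{n \in \mathrm{targets}} W_{n}^{x}
  a^{(L)}_x$ over the 211 last-hidden units — the last-hidden activation
  weighted by its connections to the targeted outputs (attribution acts on
  the pre-activation output scores, which are linear in $a^{(L)}$);
* **guided backpropagation gradients** $g_b$ of the summed target scores
  with respect to the input, zeroing the backward signal at every ReLU
  whose forward pre-activation was non-positive or whose upstream gradient
  was negative (subgradient at exactly 0 taken as 0);
* the **fused map** $g_a = g_b \cdot \tilde M$, where $\tilde M$ is $M$
  linearly interpolated from the 211-unit axis onto the 3321-point grid
  (uniform stretch, endpoints preserved). The dimension mismatch between
  the hidden-unit axis and the spectral axis has no canonical resolution
  for a fully connected network; linear upsampling is this package's
  documented choice, in the spirit of class-activation-map upsampling for
  convolutional models. Both raw and rectified fused maps are available;
  raw is the default.

Default targets are all six outputs; per-output maps (e.g. only the
methane concentration head) support diagnostics. The guided rule is
defined only for ReLU; other activations degrade to plain gradients with
a warning, and `plain_gradient()` is also the finite-difference-checkable
baseline used by the tests.

**Known limitations.** Two behaviours of desk-scale attribution deserve
explicit mention. First, guided backpropagation can vanish identically on
some trained networks (every backward path hits a masked unit),
especially under spectral initialisation whose first layer contains
sign-paired global features; plain gradients remain informative there.
Second, gradient attributions of a small-corpus model do not concentrate
sharply on narrow absorption lines: with a few thousand training spectra
the learned readout spreads weight over many correlated channels rather
than recovering the matched filter, and even the ideal matched filter
places only about 60% of its absolute mass on grid points where the
dense-narrow fixtures exceed 10% of their peak absorbance (their many
weak lines and Voigt wings carry the rest). Attribution mass fractions on
the broad-band gas are substantially higher. Maps should therefore be
read qualitatively — which regions matter — rather than as line-resolved
detections.

## Reproducibility and problem sizes

Every stochastic component draws from a per-stage seed derived
deterministically from one global seed, so stages rerun independently and
bit-identically. The shipped tests run the compact benchmark (1750
samples, 100 epochs — well under a minute per seed on one CPU with a
threaded BLAS) plus sub-second unit oracles; the full-scale recipe
(17,500 samples, 500 epochs) uses the same code paths with different
arguments and real line-list inputs via the HITRAN-format and
cross-section readers.
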