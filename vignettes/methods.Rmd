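---
title: "Unsupervised circadian phase inference: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised circadian phase inference: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphase)
```

## The problem

Proteomic studies of circadian biology frequently lack collection-time
labels: postmortem tissue, biobanked fluids, or simply unannotated designs.
Without sample times, rhythmic proteins are invisible — their values look
like unstructured scatter. `circaphase` assigns each sample a position on the
24-hour cycle (a *phase*) using only the expression matrix itself: no time
labels, no reference set of known rhythmic proteins. The recovered phases are
identifiable only up to a global rotation and a reflection of the circle,
which is all that any unsupervised method can promise; evaluation against
known times therefore aligns over those two symmetries first.

## The model

Samples are embedded onto a circle in three steps.

**Normalization.** Each protein is z-scored across samples (population SD).
This puts all proteins on one scale for network training. Matrices with at
least 5000 proteins are first reduced to the configured cap (default 5000),
ranking proteins by raw-scale variance (after z-scoring all row variances are
equal, so the ranking must come from the original scale); a seeded k-means
variant that keeps whole high-variance clusters is also provided.

**Greedy layer-wise pretraining.** A stack of shallow autoencoders — tanh
hidden layer, linear decoder, mean-squared reconstruction loss — is trained
one layer at a time, each consuming the previous hidden representation.
Layer widths run from $2^{\lfloor \log_2 f \rfloor}$ (with $f$ the feature
count) down to a 2-unit bottleneck, geometrically interpolated over six
layers and truncated to integers. The two bottleneck activations $(s_i, c_i)$
are read as an initial phase $\phi_i^0 = \operatorname{atan2}(s_i, c_i)$. A
cosinor (least-squares single-cosine) fit of every protein against these
initial phases supplies starting values for the mesor $L_p$, amplitude $A_p$
and acrophase offset $\psi_p$.

**Fine-tuning.** The stacked encoder (weights transferred from pretraining)
maps each sample to its phase, and each protein is modelled as

$$\hat{x}_{ip} = L_p + A_p \cos(\omega_p \hat\phi_i + \psi_p),$$

with $2\pi/\omega_p$ the protein's period ($\omega_p = 1$ is 24 h;
$\omega_p = 2$ is a 12-h ultradian rhythm). Encoder weights and all cosine
parameters are optimized jointly under

$$\mathcal{L} = \frac{1}{m}\sum_i \frac{1}{n}\sum_p |x_{ip}-\hat{x}_{ip}|^q
  \;+\; \lambda R(\Theta),$$

with defaults $q = 1$ (robust to heavy-tailed proteomic noise) and
$\lambda = 0$. Optional regularizers are the $\ell_1$/$\ell_2$ norms of the
parameters and a total-variation penalty on sorted sample phases (which
telescopes to the phase range and discourages abrupt gaps).

**Outlier screening.** After fine-tuning, signed mean residuals are computed
per sample ($E_i$, mean over proteins) and per protein ($D_p$, mean over
samples). Entities deviating from the respective mean by more than
`outlier_sigma` (default 2) population SDs are flagged; flagged proteins are
*rescued* when their predicted amplitude reaches the 75th percentile of all
predicted amplitudes, so strongly rhythmic proteins are never removed. The
means are signed by definition, so opposite residuals can cancel — a protein
that is badly fit but symmetric about its mesor escapes the screen. The
cancellation is structural: the cosinor initialization is least-squares, so
every protein *starts* with a signed mean residual of exactly zero, and the
robust l1 fit keeps mesors near the median afterwards. The screen therefore
flags drift during fine-tuning, not gross symmetric corruption; we keep the
signed form deliberately and note this as a known limit.
After removal the network is retrained from a fresh pretraining
initialization for `retrain_epochs` (default 200) epochs; with nothing
removed this is simply a longer fine-tune of the same data.

**Rhythmicity statistics.** Per-protein statistics (mesor, amplitude,
relative amplitude rAMP $= A/|L|$, $R^2$, cosinor F-test p-value with
Benjamini–Hochberg adjustment) are refit on the *original-scale* matrix at
the fixed 24-h period using the final phases. Computing them on z-scored
data would force the mesor to zero and make rAMP degenerate. A protein is
called rhythmic when FDR < 0.05, rAMP ≥ 0.1 and $R^2$ ≥ 0.1; ultradian calls
refit every protein at the 12-h period and require FDR < 5e-4, rAMP ≥ 0.2
and $R^2$ ≥ 0.6, with a separate FDR family per analysis.

## Numerical and design choices

* **Epochs are full-batch updates.** With tens of samples there is no
  minibatching; one epoch is one gradient step. The schedule follows the
  reference setting: 7 epochs for each of the first five autoencoders, 20
  for the bottleneck autoencoder, 20 for fine-tuning, 200 for retraining.
* **Optimizers.** Pretraining defaults to the learning-rate-free
  D-Adaptation SGD; Adam (0.001) and SGD (0.1, momentum 0.85) are also
  available per configuration. The choice matters more than usual because
  the schedule allows each autoencoder only a handful of full-batch
  updates: a small fixed learning rate leaves the stack essentially at its
  random initialization, and a six-layer product of near-random matrices
  tends to collapse the two-unit bottleneck toward a single direction,
  destroying the angular readout. The D-Adaptation step size grows
  geometrically while gradients stay correlated and trains each layer
  meaningfully within seven updates. For the *joint* fine-tuning stage the
  gradient scales of encoder weight matrices and per-protein cosine
  parameters differ by orders of magnitude; a single global step size
  adapts too slowly within the fixed epoch budgets, so fine-tuning defaults
  to per-coordinate Adam steps at 0.01 (a deliberately large step for a
  small number of full-batch updates; `optimizer = "dadapt_sgd"` selects
  the global variant there too).
* **Activation.** Hyperbolic tangent on every encoder layer: bounded and
  symmetric, which suits z-scored inputs and a bottleneck read as an angle.
* **Period bounds.** $\omega_p$ is parameterized through a scaled logistic
  and confined to $[0.9, 3.1]$: initialization at exactly 1 (24 h), room for
  ultradian solutions down to just under 8 h, no period collapse to zero.
* **Canonicalization.** Amplitude-sign folding ($A<0 \Rightarrow A \to -A,
  \psi \to \psi + \pi$) and reduction of angles into $[0, 2\pi)$ happen only
  at read-out; during optimization the parameters move freely so gradients
  stay continuous.
* **Best-iterate tracking.** The returned iterate is the best loss seen
  (including the initialization), so training can never end worse than it
  started; there is no other early stopping.
* **Architecture truncation.** Intermediate layer widths use the floor of
  the geometric interpolation (e.g. $f = 1000$ gives 512, 168, 55, 18, 6,
  2); repeated widths at tiny $f$ are deduplicated.
* **Initial phase at the quadrant level.** The bottleneck angle uses the
  two-argument arctangent; a plain $\arctan(s/c)$ would fold opposite
  quadrants together.
* **Alignment for evaluation.** Orientation $\in \{+1, -1\}$ and offset on a
  0.05-h grid minimize the mean circular error; the error-threshold curve
  uses a 0.1-h grid from 0 to 12 h and the normalized AUC divides the
  trapezoidal area by 12, so random predictions score about 0.5 and
  antipodal predictions about 0. Both grids are finer than the reporting
  precision of the score.
* **Degenerate inputs.** Zero-variance proteins are dropped at
  normalization; a bottleneck pair at exactly (0, 0) is an error; collinear
  cosinor designs (all phases equal modulo the period) are reported as
  failed fits and excluded from the FDR family; if outlier removal would
  leave fewer than 3 samples or 2 proteins the run aborts with the report.

## The synthetic generator

All tests and the acceptance benchmark run on generated data with known
truth. Rhythmic proteins follow $L + A\cos(\omega(t - \text{peak}))$ with
mesors uniform on [5, 15] and amplitudes uniform on [0.5, 3] — chosen so
relative amplitudes straddle the 0.1 calling gate — plus Gaussian or
Student-t (3 d.f.) noise; non-rhythmic proteins are mesor plus noise.
Corrupted "outlier" proteins are rhythmic templates whose values are
shuffled across samples and variance-inflated fivefold. The benchmark suite
spans four regimes — (m, n) of (6, 800), (12, 1800), (16, 2500), (24, 1400)
— at a 0.3 rhythmic fraction with noise SD set to half the median planted
amplitude, and collection times on a two-day evenly spaced design. Real
two-day designs revisit the same clock times on both days, so the m samples
cover m/2 distinct phases; the generator reproduces that faithfully rather
than forcing m distinct phases.

What the generator does *not* emulate: mass-spectrometry missingness
mechanisms, batch effects, inter-subject variability in amplitude or phase,
and postmortem-interval artifacts. Passing the synthetic benchmark shows the
method recovers planted circular structure at realistic sizes and noise; it
does not certify performance on any particular real acquisition pipeline.

## Problem sizes used in the shipped checks

The acceptance benchmark runs the four regimes above with three generator
seeds each (12 full pipeline runs) and reports the mean aligned normalized
AUC. Unit and property tests use smaller instances (m between 8 and 24,
n between 20 and 800) so the whole suite stays fast; the golden regression
fixture is a single m = 16, n = 300 run frozen byte-for-byte.

## Known limitations

* Phases are recovered up to rotation and reflection only; downstream
  analyses must anchor them (e.g. to a reference protein via
  `anchor_to_reference`) before interpreting absolute clock times.
* The signed residual screen can miss symmetric corruption (see above).
* With very few samples (m = 6) the two-day design leaves only three
  distinct phases; alignment is then coarse and the error curve jumps in
  large steps.
* Group comparisons of rhythmicity (gain/loss between conditions) are out of
  scope; the per-group fits and anchored acrophases exported here are the
  intended inputs to such analyses.
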