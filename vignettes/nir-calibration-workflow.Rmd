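---
title: "NIR calibration of grain protein: models, parameters and design notes"
author: "NIRcal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR calibration of grain protein: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NIRcal)
```

# The problem

Near-infrared reflectance spectra of ground grain carry overtone and
combination absorptions of X–H bonds; protein shows through N–H, C–H and
O–H related features near 994, 1212 and 1466 nm. A calibration model maps
a 128-channel spectrum over 940–1660 nm to protein content in % mass,
replacing slow wet chemistry (Kjeldahl/Dumas) for routine quality
control. The obstacles are physical rather than statistical: particle-size
dependent multiplicative and additive scatter, baseline drift, detector
noise, and heavy collinearity among neighbouring channels. The workflow in
this package — preprocessing, wavelength selection, latent-variable or
kernel regression, RPD-based validation — is the field's standard answer,
implemented here as one coherent, tested toolchain.

# The synthetic data generator

Raw spectra from studies of this kind are usually not deposited, so the
package treats a generative stand-in as a first-class module. Each
measurement (sample $i$, replicate $r$) is

$$x(\lambda) = a + b\left[\textstyle\sum_k c_k\,\varepsilon_k(\lambda) +
d\,\tilde\lambda\right] + \epsilon(\lambda),$$

with Gaussian bands $\varepsilon_k$, protein-linked concentrations
$c_k = \text{strength}_k \times \text{protein}_i$, interferent bands with
concentrations independent of protein, per-measurement scatter
$a \sim N(0, \sigma_{\text{off}})$, $b \sim N(1, \sigma_{\text{slope}})$,
linear drift $d \sim N(0, \sigma_{\text{drift}})$ on the normalized
wavelength $\tilde\lambda \in [0,1]$, and white channel noise. This
Beer–Lambert-plus-degradations family is exactly what MSC, SNV and
derivative preprocessing are designed to invert, which is what makes
parameter-recovery tests on it meaningful.

Default configuration (all overridable in `syntheticConfig()`):

* 92 samples × 3 replicates, 128 equally spaced channels over
  940–1660 nm; protein truncated-normal, mean 9.79 %, SD 0.7 %, range
  8.43–11.25 % — the sample statistics of a typical corn-flour calibration
  study.
* Protein bands at 994/1212/1466 nm (widths 28/32/36 nm, strengths
  0.020/0.026/0.022 AU per % protein).
* Four broad interferent bands at 1000/1200/1460/1590 nm (widths
  80–180 nm) with a mean constituent level of 75 % — a starch/water-like
  matrix background of roughly 1.5 AU that dominates the spectrum and
  overlaps the protein bands, bounding achievable accuracy away from
  perfection the way real grain matrices do.
* Scatter slope SD 0.10, offset SD 0.02 AU, drift 0.05 AU per unit
  $\tilde\lambda$, channel noise 0.002 AU.

The noise/scatter levels were fixed once so that the best pipeline
(1D+MSC with CV-tuned PLSR) lands in the performance regime reported for
real corn-flour studies — median $R_p \approx 0.92$, RPD $\approx 3.5$
over ten seeds — rather than at an unrealistic ceiling. A modelling point
worth recording: with a weak background, MSC's per-spectrum slope
regression absorbs part of the protein contrast itself (the "closure"
artifact) and caps $R_p$ near 0.82 even on noise-free data; a dominant
matrix background, as in real spectra, makes that artifact negligible.

**What the generator does not emulate:** radiative-transfer or
particle-scattering physics, moisture bands and drying effects,
wavelength-correlated (pink) detector noise, instrument drift over time,
or nonlinearity between concentration and absorbance. Passing
parameter-recovery tests therefore demonstrates that the algorithms invert
the degradation family they target, not that any particular instrument
will achieve these numbers. The generator emits one smooth
absorbance-like intensity scale; the pipeline itself is agnostic to the
physical unit and applies no reflectance-to-absorbance transform anywhere.

# Preprocessing

All eight variants share one contract (`applyPreprocessing()`): stateful
steps are fitted on calibration rows only and applied unchanged to
prediction rows (verified by a permutation test), and combined variants
apply the first derivative **first**, then the smoothing/scatter step —
the natural reading of "smoothing based on the first derivative"; the
opposite order would also have been defensible, and is the main open
choice here.

* **Savitzky−Golay** (`sgSmooth`): window 5 points, polynomial order 2.
  The window matches the common 5-point choice for ~5.7 nm channel
  spacing; order 2 is the classic peak-shape-preserving choice. Boundary
  points are taken from the polynomial fitted to the first/last window
  (the `signal::sgolayfilt` convention), so the output keeps all 128
  channels and channel indexing stays stable for feature selection.
* **MSC** (`mscFit`/`mscApply`): reference = mean **calibration**
  spectrum; per-spectrum OLS slope/intercept; correction $(x - b_0)/b$.
  Spectra whose slope magnitude falls below $10^{-12}$ raise a
  degenerate-sample error rather than exploding.
* **SNV** (`snv`): per-spectrum centering and scaling with the sample SD
  ($n-1$ denominator, the common chemometrics convention — documented
  because the two denominators differ at these row lengths). Constant
  rows are an error naming the row.
* **First derivative** (`firstDerivative`): central differences scaled by
  the actual wavelength spacing, one-sided at the ends. Finite
  differences (rather than an SG derivative) keep `1D` and `SG` distinct
  steps so their combinations remain meaningful.

# Wavelength selection

**SPA** (`spaSelect`) grows, from every possible starting channel, a chain
in which each new channel maximizes the residual norm after orthogonal
projection onto the span of the chain so far — the incremental
Gram–Schmidt update is verified against a from-scratch QR oracle in the
tests. Every chain prefix is scored by multiple-linear-regression RMSE
under seeded 5-fold cross-validation (the original SPA validation idea,
adapted to CV because no separate validation set exists at these sample
sizes), and the global minimizer wins; ties resolve to the earliest
(smallest start, fewest channels) candidate. `maxVars` defaults to 20,
the upper end of typical SPA subset sizes on 128-channel spectra, and is
additionally capped so every CV fold stays overdetermined.

**UVE** (`uveSelect`) appends one artificial uniform-noise column per real
channel, scaled by $10^{-10}$ — small enough not to perturb the PLS
decomposition, while stability $\text{mean}/\text{SD}$ is scale-invariant
so the noise columns still yield usable coefficients. Coefficients are
resampled by leave-one-out (deterministic, the original formulation);
stability is $s_j = \bar b_j / \mathrm{SD}(b_j)$, the threshold
$h_{\max} = \max_j |s_j|$ over noise columns, and real channels need
$|s_j| > h_{\max}$ **strictly**, so an artificial column can never be
selected. A coefficient with zero spread across folds gets infinite
signed stability (or 0 if it is identically zero). The latent-variable
count inside UVE is chosen beforehand by the PLSR CV selector on the real
channels.

# Regression models

* **PLSR** (`plsrFit`): univariate-y NIPALS on column-centered data;
  coefficients via the rotation $W(P'W)^{-1}q$, computed incrementally so
  one decomposition yields the whole component path (used by the CV
  selector). At full rank it reproduces the OLS normal-equations solution
  to $10^{-8}$ (tested); score orthogonality is a class validity
  invariant. Component extraction stops early with a warning when the
  residual covariance vanishes. The component cap defaults to 20.
* **ε-SVR** (`svrFit`): libsvm through e1071, `scale = FALSE` so the
  model sees exactly the preprocessed features. The tuning grid is
  $2^e$, $e = -10, -9.5, \dots, 10$ — typical reported optima
  (724.0773, 90.5097, 11.3137, 2.8284, 0.0625, 0.0442) are all
  half-integer powers of two, so this grid contains them; ties break to
  smaller $c$, then smaller $g$. The linear kernel ignores $g$ and
  reports `NA`. ε defaults to 0.01 in protein-% units (about 1/70 of the
  reference SD).
* **ELM** (`elmFit`): inputs min-max scaled to $[-1, 1]$ with training
  bounds stored in the model; input weights and biases uniform$(-1,1)$
  from a seed; output weights by Moore–Penrose pseudoinverse, so
  overparameterized layers are handled. Candidate sizes 10–60 cover the
  optima usually reported for this problem class; the same layer seed is
  reused across candidates so the CV comparison is deterministic.
* All tuners use seeded 5-fold CV; k = 5 is the customary compromise at
  69 calibration samples.

# Partitioning and evaluation

`concentrationGradientSplit()` sorts samples by reference value (ties by
original index), cuts consecutive blocks of 4 (for 3:1), and sends the
block's second-smallest member to the prediction set; remainders go to
calibration. A mid-block position guarantees deterministically that the
prediction range is contained in the calibration range — the defining
property of concentration-gradient partitioning; the exact published rule
varies between groups, and this is one consistent realization. 92 samples
give the canonical 69/23.

The metrics follow the printed conventions of calibration tables in this
field exactly: $R = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ (no square
root) and RMSE with an $N-1$ denominator; conventional Pearson-$r$ and
$N$-denominator variants sit behind flags for comparison.
$\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSEP}$ uses the sample SD of the
prediction-set reference values, making a reference SD of 0.7 % at RMSEP
0.3 % consistent with a reported RPD of 2.3. Reference protein and RMSE
are kept on a single unit (% mass) throughout; tables that print RMSE in
g/kg next to an SD in % only reconcile with their RPD on a shared scale.
A perfect prediction set yields an infinite-RPD sentinel with a warning.
Display rounding is two decimals (`formatReportTable()`), with raw values
retained.

# Orchestration and determinism

`runExperiment()` executes the 8 × 3 full-wavelength grid and the
{X, 1D+MSC, 1D+SNV} × {SPA, UVE} × PLSR selection grid. Every row carries
seed, preprocessing, selection, model, band count and hyperparameters —
enough to regenerate it; failing cells are recorded and skipped rather
than aborting the run. All randomness (generator, folds, noise columns,
ELM layers) derives from the configuration seed, and outputs contain no
timestamps, so a repeated run is `identical()` — asserted in the tests.

# Problem sizes used in the test suite

Unit tests run on 20–50-sample instances with 5–10 channels against
closed-form or brute-force oracles; parameter-recovery and ablation
checks use the full study geometry (92 × 3 × 128) over ten seeds;
UVE support-recovery uses a single-band known-support configuration over
ten to twenty seeds; the orchestration tests use a reduced 32-sample
configuration. These sizes were chosen as the smallest instances that
still exercise each property at study-realistic dimensionality.

# Known limitations

* The generator's linearity means nonlinear models (RBF-SVR, ELM) cannot
  show their comparative advantage here; on this data the linear methods
  win, which mirrors the usual finding on ground-grain spectra but is
  partly built into the simulation.
* SPA's subset scoring uses MLR; a PLSR-based scoring variant would be a
  reasonable alternative when selected subsets stay collinear.
* UVE's leave-one-out resampling is $O(n)$ PLS fits per call; at study
  sizes this is fast, but jackknife blocks would be preferable for
  thousands of samples.
* `Partition` containment, and therefore the RPD interpretation bands,
  assume the reference values are on one consistent scale; the package
  never rescales units.
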