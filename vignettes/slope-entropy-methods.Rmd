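---
title: "Slope Entropy with asymmetric thresholds: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slope Entropy with asymmetric thresholds: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopentropy)
```

## The measure

Slope Entropy (SlpEn) quantifies the complexity of a univariate time series
$x = \{x_0, \dots, x_{N-1}\}$ through the symbolic dynamics of its
consecutive-sample gradients. The series is divided into the $N - m + 1$
overlapping epochs of length $m$; within each epoch every difference
$d = x_{k+1} - x_k$ is mapped to one of five symbols using two amplitude
thresholds, a gradient threshold $\gamma$ and a tie half-width $\delta$:

* $d > \gamma_1$ → **+2** (steep rise)
* $\delta < d \le \gamma_1$ → **+1** (moderate rise)
* $|d| \le \delta$ → **0** (tie: near-equal consecutive samples)
* $-\delta > d \ge \gamma_2$ → **−1** (moderate fall)
* $d < \gamma_2$ → **−2** (steep fall)

Each epoch thus yields a pattern of $m-1$ symbols over the alphabet
$\{-2,-1,0,+1,+2\}$. Writing $p_k$ for the relative frequency of each
observed pattern (count divided by the total number of epochs, so
$\sum_k p_k = 1$), the entropy is the Shannon expression with natural
logarithm,

$$\mathrm{SlpEn}(x; m, \gamma_1, \gamma_2, \delta) = -\sum_k p_k \ln p_k,$$

bounded by $0 \le \mathrm{SlpEn} \le \ln\min(N-m+1,\, 5^{m-1})$.

Three symbolisation forms are supported:

1. **Symmetric** (the classical form): $\gamma_2 = -\gamma_1$, with a small
   fixed tie region, conventionally $\delta = 0.001$.
2. **Asymmetric $\gamma$ with $\delta$**: independent $\gamma_1 > 0$ and
   $\gamma_2 < 0$, a symmetric tie region of half-width $\delta$.
3. **Asymmetric $\gamma$, $\delta$ omitted**: no tie region at all; the 0
   region is absorbed into +1 and −1 with the boundary at the zero-slope
   line.

```{r example}
x <- c(4, 7, 9, 10, 6, 11, 3)
cfg <- slpen_config(m = 4, gamma_pos = 2.5, delta = 0.001)
symbolize(x, cfg)
slope_entropy(x, cfg)   # ln(4): four epochs, four distinct patterns
```

### Numerical and boundary conventions

Several corners of the rule list are under-determined and are fixed here
once, each isolated in one function so a different convention is a one-line
change:

* **Histogram normalisation.** Counts are divided by the **total number of
  epochs** $N - m + 1$, not by the number of distinct patterns. This is the
  only convention under which the $p_k$ form a probability distribution
  ($\sum p_k = 1$), it matches the original formulation of the measure, and
  it reproduces the worked example above. The two conventions coincide
  exactly when all observed counts are equal.
* **Boundaries are strict as written**: $d = \gamma_1$ gives +1, $|d| =
  \delta$ gives 0, $d = \gamma_2$ gives −1.
* **Rule order resolves overlaps.** The five rules are applied in the fixed
  order above, so configurations with $\delta > \gamma_1$ (which do occur as
  grid-search optima) remain well defined: the +2 rule is tested first and
  wins inside the overlap. Such configurations are therefore accepted, and
  the grid search does not exclude them unless `constrain_delta = TRUE`.
* **Zero difference without $\delta$.** The $\delta$-omitted form attaches
  $d = 0$ to the non-negative side (+1). Any other choice only matters for
  series with exact ties; the convention lives in `symbols_impl()`.
* **Non-finite samples** (NaN/Inf/NA) are rejected with an error rather than
  silently propagated into the histogram.
* **Logarithm**: natural, so results are in nats; this is forced by the
  worked example ($-4 \cdot \tfrac14 \ln \tfrac14 = 1.3863$).
* Pattern counting goes through exact base-5 integer codes (exact in doubles
  up to $m = 9$ since $5^8 < 2^{53}$) and is insensitive to the order in
  which epochs are encountered.

## Classification and evaluation

The discriminative use of SlpEn is deliberately minimal: each series
contributes one scalar feature, and a two-class prediction is made by a
single threshold on that feature. `fit_threshold()` tries every achievable
split — midpoints between consecutive distinct sorted values plus the two
infinite cuts, in both directions — and keeps the accuracy maximiser
$(TP + TN)/(TP + TN + FP + FN)$. Ties are broken by the smallest cut, then
by the class-1-above direction, making the fit deterministic. This is the
smallest classifier consistent with "classification based on a single
entropy feature"; anything richer (LDA, logistic regression) would
confound the evaluation of the symbolisation itself.

`evaluate_config()` reports **resubstitution** accuracy: the threshold is
fitted and scored on the full dataset. `grid_search()` repeats this for
every configuration in a `grid_spec()` and returns the first maximiser in a
fixed enumeration order ($m$ ascending, then $\gamma_1$, then $|\gamma_2|$,
then $\delta$), so results are reproducible and independent of any
evaluation schedule. Resubstitution accuracy at a grid optimum is an
optimistically biased estimate — the search adapts up to several thousand
configurations to 40 labels — which is why `train_validate()` exists: per
repeat, a stratified random fraction of each class (default 30%, floored,
at least one series) is used for the grid search *and* the threshold fit,
and the frozen classifier is scored on the held-out series. The threshold
is never refitted on validation data. Across repeats the mean and the
population standard deviation (divide by $n$, the repeat count) are
reported.

### Search ranges

The default grid follows the conventional ranges: $m \in \{3,\dots,9\}$,
$\gamma_1 \in \{0.05, 0.10, \dots, 1.00\}$, $\gamma_2$ the negatives of the
same values, and $\delta$ over the same 0.05-step range when present. The
$\delta$ step is not prescribed anywhere authoritative; 0.05 was chosen to
match the $\gamma$ step. The symmetric variant enumerates only
$\gamma_2 = -\gamma_1$ pairs (140 configurations with a single $\delta$);
the asymmetric $\delta$-omitted variant has $7 \times 20 \times 20 = 2800$.

## Amplitude scale and normalisation

Slope symbols compare raw differences against thresholds in $[0.05, 1]$, so
they are meaningful only when the series amplitude is of order one. Slopes
are invariant to any constant offset, but not to scale: a Gaussian series
with SD 5 has essentially all $|d| > 1$, and every sub-unit $\gamma$
collapses its symbols to $\pm 2$. For this reason the dataset-level
evaluators take a `normalize` flag which divides each series by its sample
standard deviation (after centering; a constant series is left at zero
rather than divided by zero). Min–max scaling was considered and rejected:
it ties the scale to the two most extreme samples, so for heavy-tailed or
long series it compresses almost all slopes toward zero and makes the
symbolisation degenerate.

`slope_entropy()` itself never rescales — the thresholds the caller supplies
are taken at face value — and `normalize = FALSE` is the default everywhere,
so normalisation is always an explicit, visible choice. The benchmark
reproduction below is the one place the package switches it on, because
that is the only reading under which a $\gamma \le 1$ grid interacts
non-trivially with signals whose natural scales differ by a factor of 20.

## The synthetic benchmark

`generate_synth()` builds the two-class benchmark used for validation:
class 0 is Gaussian white noise (mean 0; SD 5, 10 or 20 for the three
standard variants `synth1`/`synth2`/`synth3`) and class 1 is uniform white
noise on $[-1, 1]$; 20 series of 3000 samples per class. After unit-scaling
both classes have the same first two moments, and the two classes differ
only in the *shape* of the slope distribution (Gaussian-difference versus
triangular), which is exactly the kind of contrast the five-region
symbolisation can detect at fine thresholds but a coarse one cannot — an
accuracy around 85–90% rather than at either extreme.

What this benchmark does **not** emulate: temporal dependence (both classes
are white), nonstationarity, ties (draws are continuous, so the $\delta$
region is exercised only by the threshold, not by exact equality), outliers,
or any of the narrowband structure of physiological signals. Passing the
benchmark therefore validates the computational pipeline and the
discriminability of distributional shape, not performance on real EEG or RR
data, for which the plain-text loader and manifest interface are provided.

Reproducibility: the master seed is expanded once into one sub-seed per
series via `sample.int`, and each series is drawn under its own sub-seed
(`withr::with_seed`, leaving the caller's RNG state untouched). A series is
therefore identical regardless of how many siblings are generated, and
datasets are identical across platforms for a fixed seed.

```{r synth, eval = FALSE}
ds <- synth_dataset("synth1", seed = 1)
evaluate_config(ds, slpen_config(8, 0.70, -0.75, 0.05), normalize = TRUE)
```

## Problem sizes used in the shipped checks

The test suite exercises the full benchmark geometry (20 + 20 series of
3000 samples) for single-configuration evaluations, averaged over five
seeded realisations, and uses a coarse search grid ($\gamma$ step 0.10,
$m \in \{3, 5, 8\}$, fixed $\delta = 0.05$; 300 configurations) for the
asymmetric-versus-symmetric expressivity comparison. Property checks run on
100 random series of length up to 50 with $m \in \{2,\dots,6\}$ against a
naive reference implementation written independently of the optimised path.
These sizes keep the whole suite under a minute while leaving every
quantity at, or within sampling error of, its full-scale value; the
exhaustive default grids (up to tens of thousands of configurations) are
available through the same functions for real studies.

## Known limitations

* The expected accuracy of a published grid-search optimum, re-evaluated on
  freshly generated data, is lower than the optimum itself (selection bias
  over thousands of configurations adapted to 40 instances). Re-evaluations
  here of published optima on regenerated Gaussian-vs-uniform data land a
  few points below the published maxima for exactly this reason; the
  shortfall shrinks as the number of series grows.
* Only two-class problems and a single scalar feature are supported;
  multi-feature or multi-class extensions are out of scope.
* The five-symbol alphabet and symmetric $\delta$ are fixed; asymmetric
  $\delta$ variants and multiscale analyses are not implemented.
* Grid evaluation is exhaustive by design; no surrogate-assisted or
  early-stopping search is provided.
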