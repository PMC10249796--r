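---
title: "Wavelet multifractal descriptors for 1D spectra: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet multifractal descriptors for 1D spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfspectra)
```

## The model

A 1D intensity trace (a ¹H-NMR spectrum, read as a signal over the
chemical-shift axis) is characterized by the distribution of its local
Hölder regularity rather than by individual peaks. The analysis has two
stages.

**Partition function.** The signal is decomposed by an orthonormal
discrete wavelet transform and the detail coefficients are rescaled to the
L1-normalized convention: at the level holding $2^j$ coefficients the
orthonormal details are divided by $\sqrt{N/2^j}$, where $N$ is the
analyzed length. Under this convention a signal of Hölder regularity $H$
has normalized details of magnitude $\sim 2^{-jH}$, so the empirical
moments

$$\hat S_j(q) = 2^{-j}\sum_k |d_{jk}|^q$$

decay as $2^{-jT(q)}$ and the partition function $T(q)$ is estimated per
moment order $q$ by plain OLS of $\log_2 \hat S_j(q)$ on $j$. Two
consequences of the normalization are load-bearing: $\hat S_j(0)=1$
identically, so $T(0)=0$ *exactly*, and therefore the Legendre spectrum's
apex is pinned at height 0 — which is what makes a fixed broadness
threshold meaningful across signals.

**Legendre step.** The singularity strength is $\alpha(q) = T'(q)$,
computed by central differences (one-sided at the endpoints), and the
spectrum is evaluated parametrically, $f(\alpha(q)) = q\,\alpha(q) -
T(q)$. The resolution of the resulting curve is set by the q grid: the
spectrum can only be evaluated at the $\alpha$ values the grid reaches.
The direct definition $f_L(\alpha)=\inf_q\{q\alpha - T(q)\}$
(`legendre_bruteforce()`) is retained as an independent oracle; for a
concave $T$ the two routes coincide at $\alpha = \alpha(q)$, and the
package's tests verify this to $10^{-6}$. Although the definition is
written as an infimum, for concave $T$ the objective $q\alpha - T(q)$ is
convex in $q$, so the parametric point *is* the infimum; the spectrum lies
at or below 0 with its apex at the $q=0$ point.

**Descriptors.** The spectrum is reduced to six geometric descriptors:
spectral mode `SM` (the $\alpha$ at maximal $f$; exact ties resolved
toward the smallest $|q|$), broadness `B` (the distance between the two
interpolated roots of $f(\alpha) + 0.2 = 0$), secant slopes `LS`
$= 0.2/(SM-\alpha_1)$ and `RS` $= -0.2/(\alpha_2-SM)$, and the local
secants `LT`, `RT` of the discrete bracketing pairs at the crossings.
Crossings are searched *outward from the apex* and the first bracketing
pair wins; this innermost-crossing rule is stable when estimation noise
makes the discrete spectrum non-monotone.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `wavelet` | `db6` | — | six vanishing moments comfortably exceed the regularity range of interest ($H < 1$), so smooth trends are annihilated; configurable (`haar`–`db8`) |
| `q_grid` | $-5,\dots,5$ step $0.1$ | moment order | covers both tails; the step sets the spectrum's resolution |
| `eps_floor` | $10^{-12}$ | coefficient magnitude | negative moments blow up on near-zero coefficients; the floor excludes them (only for $q<0$ — $q=0$ is never touched, preserving $T(0)=0$) |
| `scale_range` | $j = 3,\dots,J-3$ | dyadic level | drops the coarsest levels (too few coefficients) and the finest (discretization effects) |
| `threshold` | 0.2 | spectrum height | the broadness definition; can be halved automatically per signal (`auto_relax`) down to a floor when a narrow spectrum never reaches it |
| `folds`, `replications` | 10, 100 | — | CV protocol; the emulated study used 1000 replications (CLI `--replications 1000`) |

## Boundary handling

The transform is periodized, and a periodized transform of a
*nonstationary* trace sees the wrap-around jump between the last and first
sample; that jump contaminates the moments at every scale (for fBm it
biased the apex by $+0.09$ in our experiments). `pad_mode = "reflect"`
therefore always appends the mirrored signal, making the periodic
extension continuous, before decomposing; non-dyadic lengths are first
reflection-padded to the next power of two. `pad_mode = "none"` (plain
periodized transform) is kept for didactic use on dyadic toy inputs.

## Numerical choices and degenerate inputs

* $T(0)=0$ holds exactly by construction; the tests assert it to
  $10^{-9}$, as well as the amplitude invariance of $T$, $\alpha$, $f$
  and all descriptors under rescaling of the signal.
* Where the estimated $T$ is not numerically concave, $\alpha(q)$ is not
  monotone; the package flags this (a warning condition and a
  `non_concave` attribute) but does not repair the curve — the Legendre
  step is kept faithful to the two-step procedure. A consequence is that
  the raw parametric $f$ can exceed 0 away from the apex on noisy
  signals; the $q=0$ point remains pinned at 0.
* In rare degenerate cases (roughly 1 in 500 synthetic cohort samples) a
  flagged non-concave branch never descends below any threshold, so the
  crossing-based descriptors do not exist. Cohort runs record `SM`
  (always defined) and set the others to `NA`, report the count, and the
  pipeline excludes those rows from the model stages. Single-spectrum
  calls raise a typed error naming the side instead.
* The auto-relaxation floor is 0.01 for single-spectrum work; cohort runs
  use $10^{-4}$ so that one narrow spectrum cannot abort a 120-sample
  batch. Relaxations are logged and the threshold actually used is
  recorded per sample.

## Simulators: what they emulate, and what they do not

`simulate_fgn()` draws exact-covariance fractional Gaussian noise by
circulant embedding and `simulate_fbm()` cumulates it; the embedding is
exact for $H$ up to about 0.93 and clamps relatively tiny negative
eigenvalues (below $10^{-3}$ of the maximum) above that.
`simulate_cascade()` builds a binomial multiplicative cascade, the
canonical broad-spectrum counterexample: its box partition exponents equal
$-\log_2(p^q + (1-p)^q)$ exactly in expectation, which the tests verify by
direct box counting.

`simulate_cohort()` emulates the feeding-study design: 4 High and 8 Low
subjects, depletion and repletion periods, 5 daily draws per period (Day
model, 120 spectra) or 7 hourly draws on the first and last day of each
period (Hour model, 336 spectra). Each spectrum is a shared Lorentzian
peak envelope (40 peaks, half-widths 4–30 bins, per-sample amplitude
jitter) plus a unit-sd fBm texture whose Hurst parameter carries the group
regularity target (0.810 High, 0.879 Low), small per-subject offsets (sd
0.01, switchable off for exact model-match testing), and no
depletion/repletion effect by default. The spectrum length defaults to
4096 bins. Because the envelope shifts the estimated apex slightly
relative to the texture's $H$, the generator maps the target through a
frozen affine calibration ($H_{used} = (target - 0.0193)/0.9606$), fitted
once from 80-replicate calibration runs at the defaults. The emulation is
deliberately limited: peak chemistry, metabolite concentrations and
depletion kinetics are not modeled — the analysis consumes regularity, not
peak assignments — so passing tests demonstrate that the *estimation
machinery* recovers known regularity structure, not that real NMR data
behave like the generator.

`simulate_descriptors()` skips the signal stage and draws the descriptor
triplets directly from normal distributions calibrated to the reference study's
per-cell means with SDs recovered from the standard errors
($sd = SE\sqrt{n}$). The three features share a latent within-sample
factor (correlation 0.8; positive for SM and B, negative for LS), because
all three derive from one spectrum — this is also what concentrates more
than 90% of the variance on two principal components, as observed in the
real data. This generator, not the signal-level one, is the right
reference for the ANOVA and discrimination protocols: per-spectrum
descriptor noise of the real study (SE$\sqrt{n} \approx 0.032$ for SM) is
about half the estimation noise of the signal pipeline at 4096 bins, so
the signal route understates the discriminability the descriptor tables
describe.

## Statistical stages

The per-descriptor model is a three-way *main-effects* ANOVA (group,
depletion/repletion, time; no interactions and no subject term, exactly as
the emulated study specified, even though repeated measures exist — the
model is kept for fidelity, and the generator's subject switch exists
precisely to test the consequences). Factors are coded sum-to-zero and
each effect is tested by its Type III F statistic; with no interaction
terms Type II and Type III coincide, which sidesteps the usual ambiguity
on unbalanced designs. The tests verify the F statistics against a
brute-force nested-RSS oracle to $10^{-10}$ and against an independent
Type III implementation.

Discrimination standardizes the three features before PCA (the variance
fractions depend on this; the switch is the `features`/scaling behavior of
`pca_project()`), fixes component signs by the largest loading, and
evaluates seven classifiers. Hyperparameters the protocol left open are
defaults here: Gaussian-kernel width by the median pairwise-distance
heuristic, $k=5$ neighbors, trees grown to purity (minimum leaf 1), and
Gaussian class-conditional naive Bayes. AUC is rank-based with ties
counting one half; CV AUC pools held-out scores within a replicate and
averages across replicates (the aggregation the protocol did not specify).

## Problem sizes used by the test suite

The suite exercises fBm recovery with 50 traces of 4096 points (median
apex within $\pm 0.08$ of $H=1/3$), the Low-group anchor with 60 traces
(mean apex within $\pm 0.05$ of 0.8789), 20 full Day-model cohort
replicates for the calibration recovery (group difference within
$\pm 0.03$ of 0.069), 200 descriptor-level replicates for the
group-effect significance bound, and 50 paired seeds for the
cascade-vs-fBm broadness ordering. These sizes give stable Monte-Carlo
estimates for every tolerance while keeping a full run to a few minutes.

## Known limitations

* Real ¹H-NMR preprocessing (phasing, baseline, alignment) is out of
  scope; the package consumes plain intensity vectors (CSV), and vendor
  formats are expected to be converted upstream.
* Wavelet-leader and WTMM variants of the formalism, and the direct
  counting-technique spectrum, are not implemented; the counting route is
  impractical numerically and the leader variants change the estimand.
* Negative-moment estimates are intrinsically heavy-tailed on Gaussian
  textures; the right branch of an estimated spectrum is noisier than the
  left, and the apex of a single trace has sd $\approx 0.05$–$0.1$ at
  4096 points. Averaging over traces (as every calibrated check does) is
  essential.
* The affine generator calibration is specific to the default envelope
  and length; changing `generator_config()` materially re-opens it
  (`calibrate = FALSE` disables the mapping).
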