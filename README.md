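# mfspectra

Wavelet-based multifractal analysis of one-dimensional biomedical spectra,
with the downstream group-comparison and discrimination stages used in
metabolomics studies of ¹H-NMR profiles.

## Who this is for

Metabolomics and biosignal researchers who want to characterize a spectrum
(or any 1D intensity trace) not by individual peaks but by the
*inhomogeneity of its regularity* — how the local Hölder smoothness varies
across the trace — and then ask whether experimental groups differ in that
regularity structure. The package was built around a feeding-study design
(two dose groups, depletion/repletion phases, daily and hourly blood draws),
but every stage takes plain tibbles and runs on any cohort of 1D signals.

## The method

For a signal with L1-normalized discrete wavelet coefficients `d_jk`
(level `j` holds `2^j` coefficients), the **partition function** is the
scaling exponent of the empirical moments across dyadic scales,

    Ŝ_j(q) = 2^-j Σ_k |d_jk|^q ,     log2 Ŝ_j(q) ≈ -j T(q),

estimated per moment order `q` by OLS over a range of levels. The
**multifractal spectrum** follows by the Legendre step,

    α(q) = T'(q)  (finite differences),   f(α(q)) = q α(q) − T(q),

and is summarized by six geometric descriptors:

| descriptor | meaning |
|---|---|
| `SM` | spectral mode, the α at the apex (= Hurst exponent for a monofractal) |
| `B`  | broadness: distance between the two roots of `f(α) + 0.2 = 0` |
| `LS`, `RS` | secant slopes from the apex to the left/right crossing |
| `LT`, `RT` | local secants of the discrete spectrum at the crossings |

Monofractal signals (fractional Brownian motion) collapse toward the point
`(H, 0)`; genuinely multifractal signals (multiplicative cascades, real
NMR spectra) are broad. Group comparisons use an unbalanced three-way
main-effects ANOVA per descriptor (group, depletion/repletion, time);
discrimination projects `(SM, B, LS)` onto two principal components and
evaluates seven classifiers (linear/Gaussian SVM, naive Bayes, LDA, QDA,
k-NN, decision tree) with repeated stratified 10-fold cross-validation and
rank-based AUC.

## Worked example

```r
library(mfspectra)

# a monofractal reference trace: fBm with H = 1/3
x  <- simulate_fbm(4096, H = 1/3, seed = 1)
sp <- multifractal_spectrum(x)
sp
#> <mf_spectrum> 101 points, alpha in [0.2742, 1.055], apex f = 0
mf_descriptors(sp, auto_relax = TRUE)
#> # A tibble: 1 × 10
#>      SM    LS    LT     B     RS    RT alpha1 alpha2 threshold_used relaxed
#> 1 0.405  1.89  4.05 0.354 -0.806 -1.05  0.299  0.653            0.2 FALSE
```

The apex `SM = 0.405` recovers the Hurst exponent (1/3) up to estimation
noise of a single trace, and the width `B = 0.35` is small, as expected for
a monofractal.

A full synthetic cohort, calibrated to the descriptor statistics of the
emulated feeding study (High group SM ≈ 0.810, Low ≈ 0.879):

```r
d <- simulate_descriptors("day", seed = 1)     # 120 samples, (SM, LS, B)
anova_table(day_descriptors = d)
#>   model effect                    SM       LS        B
#> 1 day   Group               6.61e-23 1.56e-19 1.44e-14
#> 2 day   Depletion/Repletion 2.78e- 1 2.95e- 1 3.55e- 1
#> 3 day   Time                4.94e- 1 2.84e- 1 1.84e- 2

pca <- pca_project(d)
pca
#> <mf_pca> 120 samples on (SM, B, LS); first two components explain 92.9% ...
evaluate_classifiers(tidy(pca), replications = 10, seed = 1)
#>     classifier auc_all_data ... auc_cv_mean ...
#>     svm_linear        0.978           0.972
#>            lda        0.978           0.974
#>  decision_tree        1.000           0.888
```

The group effect is overwhelmingly significant while depletion/repletion is
not, and the two groups are strongly discriminable in the PC plane —
resubstitution AUC always at least the cross-validated AUC.

Signal-level cohorts (`simulate_cohort()`) generate NMR-like spectra
(Lorentzian peak envelope + fBm texture carrying the group regularity) and
run through `cohort_descriptors()` / `run_pipeline()`; a thin CLI wraps the
same functions:

```sh
Rscript inst/cli/mfnmr simulate --model day --seed 1 --out-dir out/
Rscript inst/cli/mfnmr run --model hour --seed 1 --out-dir out/
```

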