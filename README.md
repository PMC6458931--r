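# mvmfe

Multivariate multiscale fuzzy entropy feature extraction for multichannel
biomedical signals, aimed at motor-imagery EEG (MI-EEG) brain–computer
interfaces. The package is for researchers who need trial-level complexity
features from few-channel epoched recordings, together with the
surrounding machinery: band-pass preprocessing, Fisher-score channel
selection, a leakage-safe SVM cross-validation harness with Cohen's kappa,
a seeded synthetic EEG generator, and a command-line front end.

## The estimators

For a trial with channels $c = 1..p$, each channel is coarse-grained at
scale $\tau$ into block means starting at offset $k$, the multichannel
coarse series is embedded into composite delay vectors ($m_c$ lagged
samples per channel, delay $\lambda_c$, Chebyshev distance between
vectors), and vector similarity is the fuzzy membership
$\mu(d) = e^{-d^2/r}$. With $\phi_m$ the average membership grade at
embedding dimension $m = \sum_c m_c$ and $\phi_{m+1}$ the grade of the
pooled one-sample extensions, the entropy at scale $\tau$ is

$$E(\tau) \;=\; -\ln\frac{\bar\phi_{m+1}(r)}{\bar\phi_m(r)} .$$

Three estimators share this core:

| variant | offsets per scale | median pre-filter |
|---|---|---|
| `mvMFE` | $k = 1$ only | no |
| `RCmvMFE` | all $k = 1..\tau$, grades averaged before the log | no |
| `IRCmvMFE` | all $k = 1..\tau$ | yes (sliding median, default window 3) |

The refined-composite averaging stabilizes entropies at coarse scales on
short trials; the median pre-filter removes the impulse artifacts (blinks,
motion) that the mean filtering implicit in coarse-graining only smears.
Channel ranking uses the Fisher score of band power,
$F(i) = (P_1(i)-P_2(i))^2 / (\mathrm{var}(P_1(i)) + \mathrm{var}(P_2(i)))$,
and evaluation reports repeated stratified 10×10-fold CV accuracy plus
$\kappa = (p_0 - p_e)/(1 - p_e)$ with $p_e = 0.5$ for balanced two-class
designs.

## Worked example

```r
library(mvmfe)

# two-class synthetic MI-EEG: 3 channels, 128 Hz, 450-sample imagery window
ep <- generate_epochs(synth_spec(n_trials_per_class = 20, seed = 42))
ep
#> <epoch_set> 40 trials x 3 channels x 450 samples @ 128 Hz
#>   labels: class 1 = 20, class 2 = 20
#>   channels: C3, Cz, C4

fisher_scores(ep, band = c(8, 32))[, c("channel_name", "fisher_score")]
#> # A tibble: 3 × 2
#>   channel_name fisher_score
#>   <chr>               <dbl>
#> 1 C3                  204.
#> 2 Cz                  166.
#> 3 C4                   86.9

cfg <- entropy_config(variant = "IRCmvMFE", scale_max = 10)
head(entropy_profile(ep, cfg, trial = 1), 4)
#> # A tibble: 4 × 5
#>   scale entropy valid   phi_m  phi_m1
#>   <int>   <dbl> <lgl>   <dbl>   <dbl>
#> 1     1   0.715 TRUE  0.00458 0.00224
#> 2     2   0.676 TRUE  0.00417 0.00212
#> 3     3   0.595 TRUE  0.00589 0.00325
#> 4     4   0.527 TRUE  0.00670 0.00396

feats  <- build_features(ep, cfg)           # 40 trials x 10 scales
report <- crossvalidate(feats, repeats = 10, folds = 10, seed = 1)
report
#> <mvmfe_eval> 10 x 10-fold CV on 40 trials, 10 features
#>   accuracy: 92.25% +/- 13.62%   kappa: 0.8450
#>   modal hyperparameters: cost = 1, gamma = 0.125
```

All three channels carry the class contrast (the Fisher scores are all
large), per-trial profiles decay with scale as the coarse-graining smooths
the series, and the 10-scale feature vector separates the two classes at
92% held-out accuracy on this small 40-trial set (kappa 0.845, i.e. well
above chance agreement). `glance(report)` and `tidy(report)` give one-row
and per-fold tibbles; `autoplot(report)`, `plot_entropy_profiles(feats)`
and `plot_fisher_scores()` draw the standard figures.

A shell front end with the same stages is installed at
`system.file("cli", "mvmfe", package = "mvmfe")`
(`simulate`, `preprocess`, `select-channels`, `entropy`, `classify`,
`sweep`, `run`).

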