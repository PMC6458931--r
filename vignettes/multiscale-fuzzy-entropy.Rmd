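---
title: "Multivariate multiscale fuzzy entropy for motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate multiscale fuzzy entropy for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmfe)
```

## The problem

Motor imagery modulates the mu (8–13 Hz) and beta (14–32 Hz) rhythms of the
sensorimotor cortex. A brain–computer interface must turn a few seconds of
multichannel EEG into a feature vector that separates, say, imagined left-
from right-hand movement. Entropy estimators quantify signal complexity and
are attractive features here, but classical single-channel estimators ignore
the cross-channel dynamics that carry much of the information, and at coarse
time scales their estimates become unstable because the coarse-grained
series are short. mvmfe implements a family of multivariate multiscale fuzzy
entropy estimators addressing both points, plus everything needed to run and
evaluate them end to end on epoched data.

## The estimators

All three estimators share the same core. For one trial, channels are
(optionally) standardized, and at each scale factor $\tau$ each channel is
coarse-grained into block means of length $\tau$ starting at offset $k$:
$$y^{k,\tau}(j) = \frac{1}{\tau}\sum_{s=(j-1)\tau+k}^{j\tau+k-1} x(s),
\qquad j = 1, \dots, \lfloor (N-k+1)/\tau \rfloor .$$
The multichannel coarse series is embedded into composite delay vectors
that concatenate $m_c$ lagged samples (delay $\lambda_c$) from every channel
$c$; with $n = \max(m)\max(\lambda)$ there are $V = N' - n$ vectors of total
dimension $m = \sum_c m_c$. Similarity of two vectors is the fuzzy
membership $\mu(d) = e^{-d^2/r}$ of their Chebyshev distance $d$, and the
average membership grade $\phi_m$ is the mean of $\mu$ over all ordered
pairs of distinct vectors. The embedding is then extended to dimension
$m+1$: each base vector gains one extra sample of one channel, and the
grades are pooled over all $p \cdot V$ extended vectors. The scale's entropy
is
$$E(\tau) = -\ln\frac{\bar\phi_{m+1}}{\bar\phi_m}.$$

The variants differ only in two switches:

* **mvMFE** uses the single offset $k = 1$ per scale.
* **RCmvMFE** ("refined composite") computes the grades at every offset
  $k = 1..\tau$ and averages the *grades* — not the entropies — across
  offsets before the logarithm, which stabilizes large-scale estimates on
  short trials.
* **IRCmvMFE** additionally passes each channel through a sliding median
  filter before coarse-graining. The mean filter implicit in
  coarse-graining attenuates Gaussian noise but merely smears a
  high-amplitude impulse (an eye blink, a motion artifact); a rank filter
  removes it.

`entropy_profile()` computes all of this for one trial;
`entropy_profile_naive()` is a deliberately independent loop-by-loop
re-derivation used to cross-check it (they agree to ~1e-14 on random
inputs, which the test suite and the acceptance script both verify).

### Numerical conventions

Several details are choices this package makes explicitly:

* **Distance.** The distance between composite vectors is the standard
  Chebyshev metric $\max_l |u_l - v_l|$ between corresponding components.
* **Membership-grade divisors.** $\phi$ is the flat average over ordered
  pairs of distinct vectors (outer divisor $V$, inner $V-1$), the
  convention of the multivariate sample-entropy family.
* **Self-pairs in the extended set.** Two extended vectors that share the
  same base time index differ only in their final component; counting them
  would let $\bar\phi_{m+1}$ exceed $\bar\phi_m$ on weakly self-similar
  data (observed on short white-noise inputs), i.e. negative entropies.
  They are excluded as self-pairs, which makes
  $\bar\phi_{m+1} \le \bar\phi_m$ provable — every counted extended pair
  dominates its base pair's distance — so profiles are non-negative
  wherever valid. At $p = 1$ this reduces exactly to the univariate
  convention.
* **Filter-before-standardize.** Each channel is standardized to zero
  mean, unit SD *after* the median filter. Measured the other way round, a
  1% contamination with ±10 SD impulses inflates the raw SD enough that
  the rescaling alone perturbs the profile more than the impulses it was
  meant to remove (mean profile shift 0.17 vs 0.011 on the robustness
  protocol below), defeating the estimator's purpose. With
  standardization on, the threshold `r` is in units of the (filtered)
  per-channel SD; with it off, `r` is scaled by the pooled SD of the
  trial.
* **Median filter.** Applied once per trial, before all scales (it acts on
  the raw series, so applying it per scale would be identical). Window
  centered, truncated at the edges (no fabricated padding samples); an
  even window averages the two middle order statistics. The default
  window of 3 is the smallest that rejects isolated impulses. The window
  is independent of $\tau$.
* **Offset lengths.** At offset $k$ the coarse series has
  $\lfloor (N-k+1)/\tau \rfloor$ complete windows, so offsets may differ
  by one sample; a single shared length would read past the end of the
  trial for $k > 1$.
* **Degenerate scales.** A scale where any offset yields fewer than two
  delay vectors, or where a grade underflows to zero, is flagged invalid
  (`NA`) rather than raising, so profiles over a scale range degrade
  gracefully.
* **Identities.** `IRCmvMFE` with `median_window = 1` equals `RCmvMFE`
  exactly; `RCmvMFE` and `mvMFE` coincide at $\tau = 1$; both facts are
  asserted as exact identities in the tests.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 2 per channel | embedding dimension; 2 is the standard choice for short biomedical epochs |
| `lam` | 1 | time delay in samples |
| `r` | 0.2 | fuzzy threshold, in units of the standardized channel SD |
| `scale_max` | 20 | largest coarse-graining factor |
| `median_window` | 3 | median filter length in samples (IRCmvMFE only) |
| `normalize` | TRUE | per-channel standardization after the filter |

The useful `scale_max` depends on trial length: at scale $\tau$ only
$\lfloor N/\tau \rfloor$ samples remain, and scales with fewer than
$\max(m)\max(\lambda) + 2$ of them are invalid. `scale_sweep()` reports CV
accuracy as a function of the maximum scale so the user can choose it;
no optimum is chosen automatically.

## Channel selection

Channels are ranked by the Fisher score of band power,
$$F(i) = \frac{(P_1(i) - P_2(i))^2}{\operatorname{var}(P_1(i)) +
\operatorname{var}(P_2(i))},$$
where $P_c(i)$ is the class mean of per-trial band power on channel $i$ and
the variances are unbiased ($n-1$) across-trial variances of the same
per-trial quantity (averaging order: per-trial mean PSD over in-band bins
first, then across trials). Band power is a Welch estimate — Hann-windowed,
mean-detrended segments of $\min(N, f_s)$ samples with 50% overlap — written
directly on `stats::fft` since no installed package exposes a Welch
routine. Ties in `select_channels()` break toward the lower channel index;
channels with zero power variance in both classes score `NaN` and rank
last.

## Evaluation protocol

`crossvalidate()` runs repeated stratified $k$-fold CV (default 10×10) with
a Gaussian-kernel SVM. Within each training fold, features are min–max
scaled to $[0,1]$ and the cost/kernel-width pair is picked by an inner
5-fold grid search (cost $2^{-5..15}$, width $2^{-15..3}$, exponential
steps) — both computed from training data only, so nothing leaks from the
held-out fold; a canary test (a feature constant in training but
label-valued in the test fold must not change fold accuracy) guards this.
Kappa is $(p_0 - p_e)/(1 - p_e)$ with $p_e = 0.5$ for the balanced
two-class design, i.e. $2 p_0 - 1$. Trials with any invalid entropy scale
are dropped with a message, not imputed. The grid uses steps of $2^5$ and
$2^6$ rather than every power of two, which keeps the nested search
affordable without changing the span.

## The synthetic generator

`generate_epochs()` draws two-class, few-channel epochs as the sum of

1. a mu-band and a beta-band sinusoid with class-dependent per-channel
   amplitudes, frequencies drawn uniformly within each band per trial (so
   features cannot latch onto a single spectral line) and random phases,
2. AR(1) colored background noise (coefficient 0.9, innovation SD 0.2),
3. white Gaussian noise (SD 0.5), and
4. optionally a Bernoulli train of ±`impulse_amp`·SD impulses.

The default amplitudes give class 1 a strong sensorimotor rhythm (mu 1.2,
beta 0.8) and class 2 an attenuated one (mu 0.45, beta 0.3) — the
event-related-desynchronization contrast of imagery paradigms — at the
geometry of a classic 3-channel, 128-Hz benchmark recording cut to a
450-sample imagery window. Everything is seeded; identical spec + seed is
bit-identical.

What the generator does *not* emulate: volume conduction and realistic
cross-channel mixing, non-stationarity within a trial, 1/f background
spectra, or ERP morphology. Passing tests on this generator therefore
demonstrate the estimator and protocol mechanics — not performance on real
recordings, which depends on artifacts and inter-subject variability the
model omits.

One empirical finding is worth knowing: the median pre-filter of IRCmvMFE
strips exactly the sample-scale irregularity that distinguishes white noise
from a rhythm, so a "noisier class ⇒ higher small-scale entropy" contrast
is clearly visible for the unfiltered estimators (RCmvMFE: 0.69 vs 0.82 in
the test conditions) but washed out after median filtering. The
class-separability that drives classification on the defaults instead lives
in the mid-scale shape of the profile.

## Study sizes used by the tests and the acceptance script

All empirical checks are scaled to desk size, chosen as the smallest
conditions that make the statistical assertions stable:

* estimator-vs-reference agreement: 50 random inputs, $N \le 64$,
  $p \le 3$, $\tau \le 4$, tolerance 1e-10;
* impulse robustness: 100 seeded replicates of a clean 3-channel,
  256-sample trial, contaminated at 1% with ±10 SD impulses; the mean
  absolute profile change of IRCmvMFE (window 3) must be smaller than
  RCmvMFE's in ≥ 90;
* white-noise ordering: 100 seeded replicates of 3-channel, 450-sample
  white noise; entropy at $\tau = 1$ exceeds $\tau = 10$ in ≥ 95;
* end-to-end: 60 trials/class at the default generator settings,
  `scale_max = 10`, 10×10-fold CV (accuracy ≥ 0.95), and a permutation
  null averaged over 5 label shuffles × 2 repeats × 10 folds (chance
  within ±0.1). A single shuffle is too variable: structured features
  under permuted labels show the usual mild CV anti-learning
  (single-shuffle accuracies 0.39–0.57 around a ~0.47 mean), while
  pure-noise features sit at chance.

## Known limitations

* The estimators are $O(V^2)$ per offset; trials much longer than a few
  thousand samples per channel get slow even with the compiled kernel.
* Only integer scale factors and two-class designs are supported.
* The literal class-averaged feature-vector view (one vector per class,
  fused across classes) is a diagnostic, not the classification input;
  per-trial vectors feed the CV, which is the only reading consistent with
  a trial-level protocol.
* EDF/GDF or MATLAB container adapters are not included; epochs come from
  the two plain-text layouts or are constructed in code.
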