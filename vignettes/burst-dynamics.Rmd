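---
title: "Burst micro-architecture of cortical theta and delta rhythms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst micro-architecture of cortical theta and delta rhythms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcrit)
```

## The problem

Across the sleep-wake cycle, rodent cortical EEG alternates between epochs
dominated by delta-band power (0.5-4 Hz, slow-wave activity of quiet states)
and epochs dominated by theta-band power (4-8 Hz, arousal, wake and REM).
`sleepcrit` treats this alternation as a point process of *bursts*: maximal
runs of consecutive analysis windows in which the ratio
$R_{\theta\delta} = S(\theta)/S(\delta)$ of Welch band powers stays above
(theta) or below (delta) a threshold. The package quantifies the temporal
organization of these bursts — duration distributions, scaling collapses,
quiet-time self-similarity, long-range correlations, and the anti-correlated
coupling between consecutive bursts — the statistical signatures by which
non-equilibrium systems self-organizing at criticality are recognized:
power-law distributed active events coexisting with exponential-tailed
quiescence.

No public recordings accompany the analysis, so the package ships a
first-class synthetic-data module that renders burst sequences with the
assumed statistical structure as EEG-like signals; every stage of the
pipeline is exercised against generated data with known ground truth.

## Spectral pipeline

A recording (plain text samples or 16-bit EDF; the analysed channel is the
frontal minus parietal differential) is z-scored over its usable samples and
bandpass filtered to 0.5-25 Hz with a 513-tap linear-phase windowed-sinc FIR
(group delay compensated). 513 taps at 256 Hz give a transition band sharp
enough to define the 0.5 Hz edge while keeping edge transients to one
second. Manual artifact rejection is replaced by a reproducible amplitude
flagger: stretches with $|z| > 8$ (robust median/MAD scaling, so an artifact
cannot inflate its own threshold) lasting more than 0.5 s are masked, and
user-supplied bad-interval files are honoured.

Band powers are computed in non-overlapping windows of `w` seconds
(default 5 s), anchored at the start of each contiguous usable segment; a
masked gap restarts the tiling so no window mixes data across a gap. Within
each window the PSD is estimated by Welch's method with Hann-tapered
segments of length `w/2` and 50 % overlap — a standard bias/variance
compromise at `w = 5` s and 256 Hz — and the band power is the integral of
the PSD over the half-open band, with fractional coverage of edge bins so
that band edges are honoured exactly rather than rounded to the frequency
grid. Bands are half-open (`[0.5, 4)`, `[4, 8)`): the 4 Hz boundary belongs
to theta, a deterministic tie rule. The sub-0.5 Hz content is excluded from
the delta band, matching the filter's lower edge.

## Burst detection and quiet times

With thresholds `th_theta >= 1 >= th_delta > 0`, windows with
`R > th_theta` form theta-bursts, `R < th_delta` delta-bursts, and the
remainder unassigned bursts; at the headline setting
`th_theta = th_delta = 1` every valid window is theta or delta (values
exactly at a threshold are unassigned — measure zero in practice). The
duration of a burst is `d = n w`. Bursts touching a record boundary, masked
gap or period edge are flagged truncated and excluded from duration
statistics: their true duration is censored, and including them would bias
the short-duration end for the long-tailed theta distribution. Both
single-threshold parameterizations of the threshold sweep are exposed:
`(Th, 1/Th)` for the theta sweep and `(1, 1/Th)` for the delta sweep.

Quiet times are gaps between consecutive non-truncated theta-bursts longer
than `D0`, measured end-to-start in seconds; unassigned windows count as
quiescence, since quiescence is defined purely by theta-event endpoints. At
`D0 = 0` on a gap-free threshold-1 sequence, quiet times coincide with the
delta durations lying between two untruncated theta events.

## Duration statistics

Theta durations are binned logarithmically (`b_{i+1} = b_i 10^c`,
first edge `0.5 w`, default `c = 0.2`); delta durations and quiet times use
the recursive scheme whose bin widths grow geometrically
(`e_n = e_1 + w \sum_{i=2}^{n} g^{i-1}`, default `g = 1.2`). Densities are
`count/(N dD)` with binomial error bars
$\delta P = \frac{1}{dD}\sqrt{p(1-p)/N}$, `p = P dD`. Underflow below the
first edge is tallied and reported, and `N` always counts all inputs, so
bin densities remain unbiased estimates of the underlying density whatever
the bin coverage.

Power laws $P_\theta(d) \sim d^{-\alpha}$ are fitted by OLS of
$\log_{10} P$ on $\log_{10} d$. The default range excludes the half-window
first bin and stops where fewer than 10 events remain in the tail, keeping
the exponential cut-off out of the fit. Weibull
($P_\delta(d) = \frac{\beta}{\lambda}(d/\lambda)^{\beta-1}
e^{-(d/\lambda)^\beta}$) and generalized-Gamma
($G(x; b, \nu, p) \propto x^{\nu-1} e^{-(x/b)^p}$) densities are fitted by
Levenberg-Marquardt weighted least squares with weights $W = 1/P^2$
(relative residuals), dropping bins with fewer than 2 counts where the
weight diverges. Two numerical choices matter here:

* the model is evaluated as the *bin-averaged* density via its CDF rather
  than at a bin centre — the binned estimate has expectation exactly
  `(F(hi)-F(lo))/dD`, so the fit stays consistent for wide bins on steep
  densities (evaluating at centres biases the recovered Weibull shape
  upward by several percent at the default binning);
* parameters are optimized on the log scale (positivity for free), with a
  method-of-moments seed plus perturbed multi-starts — the relative
  least-squares objective is multimodal at small shape values, and the
  generalized Gamma is nearly degenerate around its Weibull/exponential
  reductions, where different parameter triples produce almost identical
  densities. Fits report a convergence flag and the best SSR across starts.

The characteristic scale printed for the delta Weibull (0.16 for the
control group at `w = 5` s) cannot be in seconds, since no duration is
shorter than one window; the package stores `lambda` in seconds, reads such
printed values as minutes (0.16 min = 9.6 s — giving a mean delta duration
near 17 s, physiologically sensible), and reports both the seconds value
and the window-unit value in analysis summaries.

## Scaling collapses

Four rescaling transforms test scale invariance: the threshold collapse
`x = d Th^\epsilon`, `y = P d^\alpha` for theta; the mean-rescaled collapse
`x = d/\langle d\rangle^\eta`, `y = P \langle d\rangle^\eta` for delta; the
window collapse `x = d/w`, `y = P w`; and the quiet-time collapse
`x = \Delta t/\langle\Delta t\rangle`,
`y = P \langle\Delta t\rangle`. The collapse misfit is the mean squared
deviation of the curves from their pointwise log-space mean, computed on a
common logarithmic grid by linear interpolation in log-log space; it is
zero exactly when the rescaled curves coincide on shared support. Free
exponents ($\epsilon$, $\eta$) are estimated by grid search (default step
0.05) followed by golden-section refinement; on a synthetic family built
with $\epsilon = 0.8$ the estimator recovers the exponent to better than
0.05. The master curve is the pointwise log-space mean. When curves share
no support after rescaling the collapse errors out rather than
extrapolating.

## DFA and coupling

DFA integrates the mean-subtracted duration sequence, removes a per-box
polynomial trend of order 1 in non-overlapping boxes, and reports the
r.m.s. fluctuation `F(n)`. Boxes are taken from both ends and the two
passes averaged, so trailing data contribute; this is the one deviation
from the plain one-pass recipe, and a literal one-pass transcription is
kept as a regression oracle in the test-suite. The default grid is ~20
log-spaced scales from 4 to length/4 and the exponent is fitted over the
full grid unless a range is given. On i.i.d. noise the estimator yields
$\alpha_d = 0.50 \pm 0.02$; on circulant-embedding fractional Gaussian
noise it recovers the Hurst exponent to $\pm 0.03$ at length $2^{14}$.

Coupling between consecutive bursts is quantified by the Spearman
coefficient of the paired durations (each delta with the immediately
following theta by default), with averaged tied ranks. Significance comes
from full-order reshuffling surrogates: the theta- and delta-duration lists
are permuted independently, preserving both marginals and alternation while
destroying the pairing; across 1000 reshuffles of a 5000-pair sequence the
surrogate mean satisfies $|\bar\rho_s| < 10^{-3}$. The conditional analysis
compares $P(d_\delta \mid d_{\theta,\mathrm{prev}} > d^*)$ with the
unconditional density bin by bin; a bin is flagged when the absolute
difference exceeds the binomial error of the conditional estimate (the
package flags both directions and records the sign; the probability mass of
the shortest delta bin grows with $d^*$ under anti-correlated coupling).

## The anti-correlated pairing model

The phenomenological model draws `N` theta durations from a truncated power
law and `N` delta durations from a Weibull law, quantizes them to multiples
of `w` (ceiling, so every burst spans at least one window), sorts each list
so position equals rank, and chains alternating draws: the next rank is
Gaussian around the mirror `1 + N - k` with standard deviation `sigma`,
rounded and clipped to `[1, N]`, sampled with replacement. The sequence is
binarized (one ±1 label per window) and coarse-grained by majority rule
over `Delta` odd windows.

Model defaults are `w = 2` s, `Delta = 5` (coarse windows of 10 s), theta
law $\alpha = 2.35$ on $[2, 100]$ s and delta law $(\beta, \lambda) =
(0.59, 9.6\ \mathrm{s})$: the draws emulate the *empirical* duration
distributions, whose theta branch carries an exponential cut-off near
100 s — the cut-off matters, because the coarse-grained tail beyond it is
built by burst merging and is what separates the coupled and uncoupled
regimes.

Two properties of the rank chain deserve note. First, clipping to `[1, N]`
inflates boundary ranks; for `sigma` comparable to `N` most draws clip and
the generated durations pile onto the extremes of the lists, destroying the
coarse-grained scaling laws. The model therefore operates in the regime
`sigma/N` of a few percent (default `N/20`, fine-level
$\rho_s \approx -0.8$), where the coupling-dependent duality is robust:
anti-correlated pairing preserves a power-law theta distribution and a
stretched-exponential delta distribution after coarse-graining, while
random pairing of the same marginals produces exponential-family curves.
The discriminator used in the tests is the error-bar-weighted misfit of a
power-law fit to the coarse-grained theta density; the random control's
misfit exceeds the anti-correlated one by more than a factor of 5 across
seeds. Second, with quantized durations the $\sigma \to 0$ limit
degenerates: the deterministic mirror visits only two ranks and nearby
ranks share one quantized duration, so the rank variance vanishes. The
$\rho_s \to -1$ limit is therefore exercised on continuous distinct
duration lists, where it is a pure statement about the pairing rule. A
calibration helper (`calibrate_sigma()`) maps `sigma` to the expected
$\rho_s$ by simulation. At the default coupling the paired theta marginal
tracks the drawn law to a Kolmogorov-Smirnov distance of about 0.04; the
chain visits ranks slightly non-uniformly, which is the price of the
single-knob design.

## Synthetic data: what it does and does not emulate

`generate_duration_sequence()` produces alternating sequences with the
assumed marginals, independent or model-coupled.
`generate_fgn()` produces exact fractional Gaussian noise by
Davies-Harte circulant embedding (testable against the closed-form
autocovariance $\gamma(1) = 2^{2H-1}-1$), used to validate DFA;
rank-mapping fGn through a target quantile function yields long-range
correlated duration sequences with a chosen marginal (an approximation —
the rank map distorts linear correlations slightly).
`synthesize_eeg()` renders a burst sequence as band-limited Gaussian noise
in the epoch's dominant band at a configured SNR (default 10 dB against
the in-band share of a broadband 0.5-25 Hz background), with 50 ms
raised-cosine crossfades, epoch boundaries aligned to the window grid, and
the generating labels retained for scoring; at 10 dB the full pipeline
recovers over 95 % of window labels.

The renderer is deliberately minimal: flat in-band spectra, no 1/f slope,
no spindles or K-complexes, no genuine threshold-dependent cut-off
behaviour in $R_{\theta\delta}$. Passing tests therefore demonstrate that
the pipeline's machinery is correct and self-consistent — not that rat
cortical EEG satisfies the generator's assumptions; the threshold-collapse
exponent of real data, in particular, is not constrained by the renderer.

## Problem sizes and runtime

The test-suite and the acceptance script run at desk scale: $10^5$ samples
for fit-recovery checks, ten sequences of length $2^{14}$ for DFA, $10^5$
pairing iterations for the model, and a few hundred rendered bursts
(roughly an hour of 256 Hz signal) for end-to-end recovery — sizes at which
every stochastic tolerance above holds with margin while the whole suite
completes in about a minute.

## Known limitations

* Weighted fits use the observed density in the weights, as specified; on
  sparsely populated tails this adds variance to shape estimates (the
  recovered Weibull shape scatters by about ±0.02 at $10^5$ samples).
* The generalized-Gamma family is close to non-identifiable near its
  reductions; only the shape `nu` is asserted against a reference value,
  and the density itself is the meaningful fit product elsewhere.
* The pairing model's clipping rule restricts the usable coupling range;
  matching weak empirical anti-correlations (|rho| ~ 0.2-0.4) while
  preserving the coarse-grained scaling laws would require a different
  boundary rule (e.g. reflection), which the package does not implement.
* Group-level inference across animals (t-tests between cohorts) is out of
  scope; per-recording results are reported descriptively and pooled by
  concatenation.
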