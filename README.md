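# sleepcrit

Burst micro-architecture of cortical theta and delta rhythms: an R package
for analysing the intermittent alternation between theta-dominated
(4-8 Hz, arousal/wake/REM) and delta-dominated (0.5-4 Hz, slow-wave)
epochs in long-term rodent EEG, through the lens of non-equilibrium
critical dynamics. It is written for sleep physiologists and
statistical-physics-minded neuroscientists who want the full chain — from
raw signal to scaling exponents — as tested, scriptable functions.

## What it computes

Windows of `w` seconds yield Welch band powers and the ratio
`R_θδ = S(θ)/S(δ)`. Maximal runs with `R_θδ > Th` are theta-bursts, runs
with `R_θδ < 1/Th` delta-bursts, each with duration `d = n·w`. On these
sequences the package provides:

* **Duration distributions** with logarithmic or geometrically growing
  bins, binomial error bars `δP = (1/dD)·sqrt(p(1−p)/N)`, and fits:
  power law `P_θ(d) ∼ d^(−α)` (log-log least squares), Weibull
  `P_δ(d) = (β/λ)(d/λ)^(β−1)·exp[−(d/λ)^β]` and generalized Gamma
  `G(x; b, ν, p) ∝ x^(ν−1)·exp[−(x/b)^p]` (Levenberg-Marquardt with
  weights `W = 1/P²`).
* **Scaling collapses** over threshold, window size and quiet-time
  threshold — e.g. `P_θ(d) ∼ d^(−α)·f_θ(d·Th^ε)` — with the rescaling
  exponent estimated by minimizing the spread of the rescaled curves
  around their log-space mean.
* **Quiet-time analysis**: interevent times between theta-bursts longer
  than `D0`, their mean-rescaled collapse and generalized-Gamma master
  curve.
* **Detrended fluctuation analysis** (DFA-1) of burst-duration sequences,
  `F(n) ∝ n^α_d`.
* **Coupling tests**: Spearman rank correlation between consecutive
  delta- and theta-burst durations, full-order reshuffling surrogates, and
  conditional distributions `P(d_δ | d_θ,prev > d*)`.
* **A phenomenological coupling model**: Gaussian-rank anti-correlated
  pairing of power-law theta and Weibull delta durations, binarization and
  majority-rule coarse-graining — reproducing the duality of power-law
  active phases and exponential-tailed quiescence only when consecutive
  bursts are anti-correlated.
* **Synthetic data**: seeded generators for duration sequences, exact
  fractional Gaussian noise (circulant embedding), and EEG-like signal
  rendering with per-window ground truth.

Input formats: 16-bit EDF or single-column text for signals; TSV for
schedules (`state, start_s, end_s`) and bad intervals; YAML for
configuration. Outputs are TSV tables and JSON summaries.

## Worked example

Generate an alternating burst sequence (power-law theta, Weibull delta),
render it as ~9.6 h of 256 Hz EEG at 10 dB SNR, and run the analysis:

```r
library(sleepcrit)

bs  <- generate_duration_sequence(N = 2000, w = 5, seed = 42)
rec <- synthesize_eeg(bs, eeg_synth_spec(snr_db = 10, seed = 43))
rs  <- band_power_series(preprocess(rec), w = 5)
det <- detect_bursts(rs, th_theta = 1, th_delta = 1)
det
#> burst_sequence (h24): 2000 bursts (1000 theta, 1000 delta, 0 unassigned), w = 5 s

th <- burst_durations(det, "theta")
fit_power_law(empirical_pdf(th, make_bins("logarithmic", w = 5, c = 0.2,
                                          d_max = max(th))))
#> power-law fit: alpha = 2.828 +/- 0.406 (5 bins, 4.99-79.1)

dl <- burst_durations(det, "delta")
fit_weibull(empirical_pdf(dl, make_bins("recursive", w = 5, growth = 1.2,
                                        d_max = max(dl))))
#> Weibull fit: beta = 0.543, lambda = 7.96

dfa(det$bursts$d[det$bursts$kind == "theta"])
#> DFA-1: alpha_d = 0.488 +/- 0.018 over scales 4-250

surrogate_coupling_test(det, n_surr = 200, seed = 44)
#> coupling surrogate test: rho_s = -0.027 vs 0.0011 +/- 0.032 (200 surrogates), z = -0.9
```

Reading the output: every analysis window recovers its generating rhythm,
so the detected bursts mirror the generated ones. The power-law exponent
(generating value 2.35) carries a ±0.4 standard error at 1000 bursts —
exponent estimates at this sample size are dominated by tail noise, which
is why the recovery checks below use 10⁵ samples. The Weibull shape sits
below the generating 0.59 because durations are quantized to 5 s windows,
which piles half of the delta mass onto the first bin. The duration
sequence is uncorrelated (`alpha_d ≈ 0.5`) and uncoupled (`z = -0.9`), as
it should be for independently drawn bursts; a model-coupled sequence
(`coupling = "model"`) instead gives a strongly negative `rho_s` and a
large negative `z`.

The orchestrated pipeline over recordings (periods, sweeps, collapses,
quiet times, DFA, coupling, conditionals, TSV/JSON reports) is
`run_analysis()`; `scripts/sleepcrit.R` wraps it for the shell, with
`simulate`, `model` and `dfa` subcommands.

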