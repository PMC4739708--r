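---
title: "Classifying plasticity outcomes and simulating input mixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plasticity outcomes and simulating input mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmix)
```

## The scientific problem

Pairing pre- and postsynaptic activity at excitatory synapses between
layer-4 neurons of primary visual cortex can potentiate (LTP), depress
(LTD) or leave unchanged (NC) the synaptic response. Two stimulation
modes probe this: *single-cell stimulation* (SCS) measures one unitary
connection at a time, while *extracellular stimulation* (ECS) drives
many afferents at once and measures the compound response. With
inhibition intact the compound response barely changes after pairing;
with GABA~A~ receptors blocked (bicuculline), individual cells show the
full range of outcomes. Since unitary connections themselves show mixed
outcomes, the natural question is whether the compound outcomes are just
sums of independently behaving unitary inputs — or whether the inputs
converging on one cell are *segregated* by plasticity state.

`plastmix` implements that full analysis chain: quality control and
outcome classification of sweep recordings, and a Monte Carlo that
assembles simulated compound responses (SCRs) from a unitary-connection
database under a tunable segregation parameter.

## The classifier

Each experiment has a pre-pairing epoch and a post-pairing epoch of peak
response amplitudes (EPSC in pA under voltage clamp, EPSP in mV under
current clamp). The normalized strength change is

$$\Delta_N = 100\,\frac{\bar A_{\text{post}} - \bar A_{\text{pre}}}{\bar A_{\text{pre}}}\ (\%)$$

and a cell is labelled LTP when the pre/post difference is significant
(two-sample two-tailed t-test, $p < \alpha = 0.05$) *and*
$\Delta_N > +15$; LTD when significant and $\Delta_N < -15$; NC
otherwise. Properties that follow, and that the test suite checks: the
label is invariant to rescaling the amplitudes (so pA and mV recordings
are handled identically and conditions can be compared on $\Delta_N$);
swapping the epochs maps $\Delta_N \mapsto \Delta_N'$ with
$(1+\Delta_N/100)(1+\Delta_N'/100)=1$ and exchanges LTP and LTD; and the
joint criterion is conservative — on null data the plastic-label rate is
below $\alpha$, because significance alone never suffices.

Decisions the verbal rule leaves open, and our defaults:

* **t-test variant.** Classical pooled-variance Student's test
  (`variant = "student"`); Welch is available. With 120 sweeps per epoch
  and comparable variances the two are practically identical.
* **Threshold strictness.** "Exceeds 15%" is read strictly:
  $\Delta_N = +15.0$ exactly is NC.
* **Baseline for $\Delta_N$.** The mean of *all* retained baseline
  sweeps (no trailing sub-window). `classify_dataset(use_bins = TRUE)`
  exposes the alternative of testing minute-bin means instead of raw
  sweeps; with equal-size bins the point estimate of $\Delta_N$ is
  unchanged and only the t-test's effective sample size differs.
* **Degenerate input.** Two zero-variance epochs with equal means give
  $p = 1$ (NC) by convention; with unequal means $p = 0$.

## Quality control

Five exclusion rules, applied per recording by `qc_experiment()` with
thresholds in `qc_thresholds()`:

| rule | code | default |
|---|---|---|
| absolute access resistance | `ra_absolute` | max Ra > 40 MΩ |
| relative access resistance | `ra_relative` | max Ra > 20% of input resistance |
| access-resistance drift | `ra_drift` | \|Ra last − Ra first\|/Ra first > 20% |
| membrane potential | `vm` | Vm more positive than −60 mV |
| baseline stability | `baseline_trend` | OLS slope of amplitude on time, p < 0.05 |

The drift reference point is the *first* reading (the rule only says
"changed by more than 20%"); the absolute and relative ceilings use the
maximum reading so that a transient excursion is caught. The trend test
is an ordinary least-squares slope t-test; note that it *excludes* truly
stable cells at its false-positive rate α = 0.05, so in any clean
dataset about 5% of cells are expected to fall to `baseline_trend` —
that is a property of the published rule, not a bug, and the pipeline
lists every exclusion rather than silently dropping rows.

## The input-mixing Monte Carlo

A simulated compound response is built from a unitary database
(`conn_id`, `strength_pre_pa`, `strength_post_pa`, `outcome`):

1. Draw the first connection's class from the marginal class
   probabilities (default: the empirical frequencies 7/43 LTP, 18/43
   LTD, 18/43 NC), then a member uniformly within that class.
2. For each subsequent draw, keep the first class with probability $S$,
   otherwise draw a class from the marginals; member again uniform
   within class.
3. Stop at the first draw where the summed pre-pairing strength reaches
   350 pA (the typical compound response size). SCR$_\text{pre}$ and
   SCR$_\text{post}$ are the member sums before and after pairing, and
   the SCR $\Delta_N$ uses the same normalization as the classifier.

`sweep_segregation()` repeats this `n_scr` times (default 26, the size
of the observed compound dataset) at each $S$ on a grid (default 0 to 1
in 0.1 steps) and compares the SCR $\Delta_N$ variance with the observed
reference variance by the two-sided F-test.

Design choices where the verbal description is under-determined:

* **Replacement.** Within-SCR sampling is *with replacement* by
  default. This is forced at $S = 1$: the LTP class holds 7 connections
  of ~20 pA, which cannot plausibly sum to 350 pA without reuse. A
  without-replacement mode is retained for sensitivity analysis and
  raises an explicit error naming the exhausted class.
* **Two-stage draw.** Class probabilities are specified; the uniform
  choice of a member within the class is the maximum-entropy
  completion. When the marginals equal the empirical class frequencies
  (the default), the $S = 0$ procedure coincides with a uniform draw
  over all entries.
* **Unbiased first draw.** The first connection is drawn from the
  marginals at every $S$; segregation biases only subsequent draws.
* **F-test sidedness.** Two-sided (the comparison is of inequality of
  variances without a stated direction). The statistic is oriented
  simulated-over-reference; `f_test_variance(x, y)` and
  `f_test_variance(y, x)` return reciprocal statistics and, by
  construction of the p-value as
  $2\min\{P(F \le f),\,P(F \ge f)\}$ evaluated via the swapped-df lower
  tail, *exactly* equal p-values.
* **Database size.** Default 43 entries with class probabilities over
  43 (the frequencies as printed with the outcome tables); the size is
  a parameter.

An analytic anchor: at $S = 1$ with many inputs per SCR, each SCR's
$\Delta_N$ concentrates near the strength-weighted mean change $d_c$ of
its single class, so the SCR variance approaches the between-class
variance $\sum_c p_c d_c^2 - (\sum_c p_c d_c)^2$. This closed form
(`segregation_variance_limit()`) is computed from the database alone —
independently of the sampler — and the tests require the simulated
$S = 1$ variance at `n_scr = 2000` to land within 10% of it, and the
variance to grow from $S=0$ to $S=1$.

## What the synthetic generators emulate — and what they do not

`simulate_recording()` emulates the protocol skeleton: 120 baseline
stimuli at 0.2 Hz, 60 pairing events at 0.1 Hz (a time gap only — no
amplitudes are recorded during pairing, and no biophysics of induction
is modelled), then 120 post-test stimuli at 0.2 Hz. Amplitudes are
baseline mean × (1 + multiplicative Gaussian noise), with a step change
of `true_delta_pct` percent in the post epoch, optional linear drift,
and a linearly drifting access-resistance series.

Parameters and their defaults:

* `baseline_mean`: 375 pA (V-clamp) / 4 mV (I-clamp) — the middle of
  the stated target response ranges (350–400 pA, 3–5 mV).
* `sweep_noise_cv = 0.10`: no sweep-to-sweep noise statistic is
  published; 10% CV makes the between-cell group SDs (±7.6 to ±20.4
  percentage points) dominate the within-cell measurement error of
  $\Delta_N$ (≈1.3 points at n = 120 per epoch), which is what the
  printed group statistics implicitly assume. Configurable.
* Group effect sizes: the printed per-group mean ± SD percent changes
  (+39.9 ± 14.7 LTP, −38.5 ± 20.4 LTD, −3.0 ± 7.6 NC for the
  disinhibited set; 1/3/24 with ±30%/0% effects for the control set).
  Draws are **truncated at the ±15% class boundary** (strictly outside
  for LTP/LTD, closed inside for NC): the published group statistics
  describe *classified* cells, so ground truth must respect the class
  definition for round-trip counts to be exact.
* Unitary strengths: normal, mean 19.4 pA (= 350 pA ÷ 18.05 mean
  inputs per compound response), SD 6 pA, truncated positive. The
  per-connection strength distribution is not published; these are
  stand-ins, configurable.
* Unitary per-class percent changes: the published per-connection
  values are likewise unavailable, so `scs_delta_models()` reuses the
  compound-dataset group statistics as a synthetic calibration.

Consequently, passing tests demonstrate the *procedural* correctness of
the pipeline and the *qualitative* behaviour of the mixing model
(variance broadening with $S$, narrow random-mixing distributions,
homogeneity at $S = 1$). They do not certify quantitative statements
that depend on the unpublished per-connection values — in particular the
exact $S$ value at which the simulated variance stops differing from the
observed one, which on real data was near complete segregation
($S \ge 0.9$) and on synthetic runs lands nearby but not identically.

## Numerical choices and problem sizes

* Truncated normals are drawn by rejection sampling (the truncation
  regions always carry substantial mass here; a hard iteration cap
  guards degenerate models).
* The KDE uses Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`)
  with a Gaussian kernel evaluated directly on an arbitrary grid
  (default: data range ± 4 bandwidths, 512 points, over which the raw
  density integrates to 1 within 1%); `normalize_peak = TRUE` rescales
  to a maximum of 1 for overlaying distributions.
* The KS p-value is the asymptotic formula; at the sample sizes in play
  (26–43) the exact/asymptotic difference is immaterial at the decision
  thresholds used.
* All stochastic stages accept a `seed` and restore the caller's RNG
  state; `pipeline_config()` derives per-stage sub-seeds from one master
  seed so a single integer fixes every number in the report.
* Test problem sizes were chosen for tight Monte Carlo error at desk
  scale: 10,000 SCRs for class-frequency checks (binomial SE ≈ 0.4
  points), 2,000 SCRs per point for variance comparisons, 10⁶ draws per
  grid point for the linear-bias law, 10,000 replicates for F-test
  type-I calibration, and 1,000 null experiments for classifier
  conservatism.

## Known limitations

* No biophysics: dendritic nonlinearities, inhibitory-synapse
  plasticity and GABA~B~ effects are outside the model, as they were
  outside the original simulation.
* The pipeline reads the flat CSV schemas written by its own
  generators; raw acquisition formats (ABF, or the public repository
  deposit of the original recordings) are not parsed.
* Pairing-epoch sweeps carry no amplitudes, so nothing can be inferred
  about induction dynamics.
* The published summary of the combined control percent change appears
  twice with different SDs in the source material (±34.3 vs ±10.26);
  the pipeline therefore reports both raw-sweep and binned summaries
  side by side and does not arbitrate between them.
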