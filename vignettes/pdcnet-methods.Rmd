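---
title: "Effective connectivity, directed graph metrics and severity classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity, directed graph metrics and severity classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcnet)
```

# The analysis in one paragraph

`pdcnet` grades social-anxiety severity from resting-state EEG through a
chain of classical signal-processing and network steps: multichannel EEG
(30 channels, 10-20 montage, 256 Hz) is filtered, epoched into 3-s
segments and screened for amplitude artifacts; each subject's epochs are
modeled with an order-5 multivariate autoregressive (MVAR) process; the
MVAR coefficients yield partial directed coherence (PDC), a
frequency-domain measure of direct, directed influence between channels;
PDC is averaged within canonical bands (delta 1–3, theta 4–8, alpha 9–12,
beta 13–30 Hz) into 30×30 directed connectomes; connectomes are binarized
by proportional thresholding at the proportion maximizing global cost
efficiency; five directed graph measures (node degree, node strength,
clustering coefficient, local efficiency, modularity) summarize each
network; and per-epoch PDC (900 values) and graph features (121 values)
feed five cross-validated classifiers of the four severity groups. Group
statistics use one-way ANOVA with η² and Pearson correlations between
alpha-band PDC and the Social Interaction Anxiety Scale (SIAS).

Because no real cohort ships with the package, a first-class synthetic
generator emulates the study conditions with known ground truth, and every
downstream stage is tested against it.

# The MVAR/PDC core

Each epoch (channels × samples matrix $Y$) is modeled as
$$Y(t) = \sum_{l=1}^{p} A_l\, Y(t-l) + \varepsilon(t),$$
fit by multivariate least squares on the common lagged design; the
innovation covariance comes from the residuals. The order is $p = 5$,
which the Akaike information criterion
$\mathrm{AIC}(p) = \ln\det\hat\Sigma_\varepsilon(p) + 2pn^2/T$ selects on
3-s epochs of the synthetic generator (and which is the standard choice
for 2–3 s segments at this rate). `select_order_aic()` remains available
as a per-epoch diagnostic; note that for a single short univariate series
AIC's penalty is only $2/T$ per parameter, so its choice is noisy and the
reliable statement is about the modal choice across epochs.

PDC follows the Baccalá–Sameshima definition. With
$\bar A(f) = I - \sum_l A_l e^{-i2\pi f l/f_s}$,
$$\mathrm{PDC}_{ij}(f) = \frac{|\bar A_{ij}(f)|}
 {\sqrt{\bar a_j(f)^H \bar a_j(f)}},$$
where $\bar a_j$ is the $j$-th column of $\bar A$: the directed flow
$j\to i$, normalized per source column so that
$\sum_i \mathrm{PDC}_{ij}(f)^2 = 1$ at every frequency (asserted to
machine tolerance in the tests). Matrix entries store unsquared
$|\mathrm{PDC}|$. The frequency grid is 1–30 Hz in 0.5-Hz steps —
it covers all four bands; the resolution is a package choice. Band
averages are arithmetic means over in-band grid frequencies with the
diagonal (self-flow) set to zero; epoch averaging and band averaging are
both linear means, so their order is immaterial.

## Per-epoch versus pooled estimation

Two estimators coexist deliberately:

* **per-epoch fits** (`fit_mvar`) produce the 30×30×40 per-band feature
  tensors that classification consumes;
* a **pooled multi-trial fit** (`fit_mvar_epochs`) stacks the lagged
  normal equations across all clean epochs (lags never cross epoch
  boundaries) and is the subject-level summary used for group statistics.

The distinction matters. A per-epoch fit at $n=30$, $p=5$, $T=768$
estimates 4 500 coefficients from 763 rows; each coefficient carries a
standard error near $1/\sqrt{T}\approx 0.04$. Under the column
normalization this noise creates a *floor*: every off-diagonal PDC entry
has a positive expected value of roughly $1/\sqrt{n}$-scale even with no
true coupling, and — because the column's squared entries must sum to
one — concentrating true flow into edges can *lower* the mean of the
unsquared entries. Averaging per-epoch PDC matrices does not remove the
floor (the entries are non-negative). Pooling the fit across 40 epochs
cuts the coefficient noise by $\sqrt{40}$ and restores a monotone
relationship between coupling strength and group-mean PDC. The pipeline
therefore reports subject-level mean PDC from the pooled fit, while the
per-epoch tensors keep the documented 4×900×40 / 4×121×40 / 4×1021×40
shapes.

# Graph measures

The connectome (row = target, column = source) is thresholded by keeping
the `round(p·n(n−1))` strongest off-diagonal weights, ties broken by
fixed (row, column) order. The proportion is chosen per matrix from the
grid 0.05–0.50 (step 0.05) by maximizing **global cost efficiency**
$E_{glob} - \text{cost}$, with $E_{glob}$ the mean inverse shortest-path
length over ordered pairs of the binary digraph (unreachable pairs
contribute 0) and cost the edge density. The grid is a package choice;
only $0 < p < 1$ is inherent to the construction.

On the thresholded graph:

* **degree** — in-degree (row sums of the binary matrix), out-degree
  (column sums), and their total;
* **strength** — total thresholded in- plus out-weight;
* **clustering coefficient** — $C_i = 2n_i / (k_i(k_i-1))$ on the
  undirected skeleton ($k_i$ distinct neighbors, $n_i$ edges among them;
  $C_i = 0$ for $k_i < 2$). This is a binary formula, so it is computed
  on the binarized graph; strength is the only weighted measure;
* **local efficiency** — Latora–Marchiori: the global efficiency of the
  binary subgraph induced by a node's neighbors with the node removed;
* **modularity** — Louvain community detection on the symmetrized binary
  graph with Newman's $Q$ (undirected convention, $L$ = twice the
  undirected edge count). Louvain is a heuristic; its RNG seed is fixed
  (default 42) and recorded, and $Q$ is only invariant under channel
  relabeling up to heuristic slack.

All measures are validated against brute-force enumeration (Floyd–Warshall
paths, explicit triangle counts) on every random digraph with $n \le 5$.

# The synthetic generator

The generator defines the study conditions: 4 groups × 22 subjects,
128 s per subject at 256 Hz, 30 channels, SIAS scores in the published
group bands, and band-specific directed coupling graded
severe > moderate > mild > control in theta and alpha.

**Ground truth model.** Each subject is an order-5 MVAR process.
Source channels (frontal/midline for theta, parieto-occipital for alpha)
carry a damped in-band resonance: a conjugate pole pair at the band
center (theta 6 Hz, alpha 10.5 Hz; individual peak frequencies spread
deterministically by ±1 Hz across channels) times three fixed real poles
(−0.85, 0.75, −0.65). The real-pole triple makes the lag-5 diagonal
coefficient ≈ −0.34, so the generative order is identifiable from single
3-s epochs — a weak fifth lag would defeat AIC recovery. Sink channels
(central/temporal) are broadband AR(5) processes; their band-limited
rhythm is *inherited from their sources*, which is precisely the
effective-connectivity story the pipeline is meant to detect. Coupling is
a dense feedforward fan-out (each source drives the ten sinks) with
per-edge gains graded by group; the acyclic layout lets the coupled model
inherit the stability of the uncoupled oscillators (cyclic coupling
between near-unit-modulus resonators destabilizes at tiny gains), and the
dense/weak rather than sparse/strong choice mirrors a spatially spread
group effect while keeping the estimated PDC on the
responsive part of its range — strong sparse edges saturate the
column-normalized PDC and destroy the group gradient. A spectral-radius
rescue (shrink all poles until radius ≤ 0.98) guards custom
specifications. Innovation variances solve a single linear system so
every channel has unit stationary amplitude; `noise_sd` (default 15 µV,
12 µV in the cohort defaults) then sets resting-EEG-like channel RMS
directly.

Within-group variability comes from a log-normal per-subject gain factor
(SD 0.15 on the log scale — about the coefficient of variation of
subject-level connectivity summaries in this literature). Per-subject
seeds derive arithmetically from the master seed (no hashing), so cohorts
are bit-reproducible.

**Band bleed.** With $f_s = 256$ Hz, all analysis frequencies sit at
small normalized angles, so a 5-lag cross-coupling kernel cannot be
narrow-band: theta-band edges also raise alpha-band PDC and vice versa.
The edge-recovery tests therefore score the top-ranked entries of a band
connectome against the union of the generator's edge sets. Both bands
carry the same group gradient, so group contrasts are unaffected.

**SIAS scores.** A Gaussian copula ties scores to connectivity: the
within-group standardized mean alpha PDC $z_{pdc}$ gives
$z_1 = \rho_g z_{pdc} + \sqrt{1-\rho_g^2}\,z_{noise}$, mapped to the
group's score mean/SD (severe 67.2 ± 5.8, moderate 55.1 ± 7.2, mild
38.0 ± 5.5, control 15.7 ± 7.0, sexes pooled) and clipped to the
instrument range [0, 80]; the post-experiment score correlates with the
screening latent at 0.87. The copula targets the alpha band only, where
the symptom-severity association is reported (severe 0.61, moderate 0.82,
mild 0.85, control −0.481). At cohort generation time the per-subject
summary driving the copula is the *model-implied* (analytic) alpha PDC of
the subject's jittered coupling model, not a pipeline estimate — this
avoids a circular dependence on the estimation stage while guaranteeing
that the pipeline's own Pearson stage recovers the generating ρ within
Monte-Carlo tolerance. Note the published mild-group score mean (≈38)
lies above the mild labeling bin [20, 35); the generator keeps the
published means and treats group labels as given rather than re-deriving
them from scores.

**Artifacts.** Ocular-like transients are 0.4-s raised-cosine bumps at
Poisson times, frontally weighted, peak amplitude > 100 µV so the
rejection stage can be exercised against known event times.

**What the generator does not emulate:** volume conduction and reference
effects, 1/f background structure beyond the AR poles, non-stationarity,
drowsiness, eye-movement physiology, and any topographic realism beyond
the frontal/posterior source split. Passing tests on this cohort
demonstrate that the *pipeline* is correct and sensitive under the stated
effect structure; they do not certify performance on real EEG.

# Classification protocol

Per band (bands are never mixed in one model), one row per
(subject, epoch): the row-major vectorized connectome (900 values,
diagonal zeros retained) optionally concatenated with the 121 graph
values. Stratified 10-fold cross-validation treats epochs as samples
(the subject-dependent protocol); because epoch-level splitting is
optimistically biased when epochs of one subject land in both train and
test, a subject-grouped mode (`by_subject = TRUE`) is provided and its
caveat documented. Inside every training fold — and only there — z-score
standardization is fit, sequential forward selection (greedy wrapper
maximizing inner 5-fold accuracy, stop at `k_max` or improvement
< 1e-4) is run, and the classifier is trained; the held-out fold is then
transformed and predicted. A leakage canary (a feature equal to the label
on one fold's rows only) verifies that selection never sees test rows.

The five classifiers are K-nearest neighbors (k = 5), linear discriminant
analysis, Gaussian naive Bayes, a decision tree (maximum depth 5), and an
RBF support-vector machine (C = 1, γ = 1/d, one-vs-rest). These fixed
defaults are the package's choice — the emulated protocol leaves these
hyperparameters unspecified — and `params` plus the
documented grids allow tuning without changing the protocol. Metrics are
accuracy, sensitivity and specificity in percent; multiclass
sensitivity/specificity are macro-averaged one-vs-rest and reduce exactly
to the binary formulas for two classes, and collapsed
SAD-versus-control binary metrics are also emitted because the two
aggregations genuinely differ.

# Statistics

Severity labeling uses half-open bins on the SIAS score: control
[0, 20), mild [20, 35), moderate [35, 50), severe [50, 80] — the upper
severe bound is the only consistent reading of the published rule.
Group comparisons are classic one-way ANOVA per band with
η² = SS_between / SS_total; repeated-measures variants are approximated
by the one-way layout, matching the degrees-of-freedom pattern of the
published tables. No multiple-testing correction is applied by default
(matching the emulated protocol); single-subject groups yield
flagged `NA` dispersion rather than silent zeros. Pearson correlations
between subject-mean alpha PDC and SIAS are reported per group with
two-sided t-test p-values.

# Numerical choices and degenerate inputs

* Filtering: zero-phase (forward–backward) Butterworth — order-2
  high-pass at 0.4 Hz (higher orders are numerically fragile at a
  0.003 normalized cut-off) cascaded with an order-8 low-pass at 40 Hz
  (two-pass attenuation of a 50 Hz mains tone below 1% RMS).
* Resampling: order-8 Chebyshev decimation for integer factors,
  band-limited polyphase resampling otherwise.
* Welch band power: Hann window per 3-s epoch, periodograms averaged
  across epochs, band power = mean density over in-band bins; the
  estimate satisfies Parseval against the time-domain variance within
  10% on white noise.
* MVAR fitting errors out on rank-deficient lagged designs (suggesting a
  lower order) rather than silently regularizing; PDC errors on a zero
  column norm; `band_average` errors on bands containing no grid
  frequency; thresholding errors on all-zero matrices; artifact
  rejection errors, naming the subject, when fewer than `min_keep`
  epochs survive.
* All stochastic steps run under a private RNG stream restored on exit,
  with documented integer seeds.

# Simulation scales used by the test suite

The replicate studies in the test suite state their own problem sizes:
severity-ordering recovery runs 20 cohort replicates at n = 22 per group
with 6 pooled epochs per subject (the pooled-fit noise floor at 6 epochs
already preserves the gradient; the full 40 epochs only sharpens it), and
the null-calibration study runs 120 zero-coupling replicates on an
8-channel montage at n = 4 per group. ANOVA p-values under the null pass
a Kolmogorov–Smirnov uniformity check and the empirical type-I rate sits
at the nominal 5%.

# Known limitations

* The generator's broadband sinks mean sink channels have no intrinsic
  alpha peak; their in-band power is inherited. Real EEG mixes both.
* Pooled-fit group summaries assume within-subject stationarity across
  epochs; per-epoch tensors carry no such assumption but pay the noise
  floor documented above.
* Louvain modularity is a heuristic optimum; Q values are comparable
  only under the recorded seed.
* Epoch-level cross-validation estimates are optimistic for
  subject-level generalization; use `by_subject = TRUE` for the honest
  variant.
* The EDF reader/writer covers exactly the subset of EDF this pipeline
  produces (continuous records, uniform rate, 16-bit, µV); it is not a
  general EDF+ implementation.
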