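# pdcnet

Effective connectivity, directed graph metrics and severity
classification for resting-state EEG.

`pdcnet` is for researchers who want a tested, reproducible R
implementation of a widely used analysis chain in clinical EEG network
studies: grading social-anxiety severity (severe / moderate / mild /
control) from the *directed* information flow between scalp channels.
Undirected functional-connectivity measures (coherence, phase locking)
cannot say which region drives which; partial directed coherence (PDC)
can, and combining it with graph-theoretic summaries of the resulting
directed network is the core of this pipeline.

## The method

Each subject's 30-channel resting EEG (256 Hz, 3-s artifact-screened
epochs, at most 40 per subject) is modeled as an order-5 multivariate
autoregressive process

&nbsp;&nbsp;&nbsp;&nbsp;Y(t) = Σₗ Aₗ Y(t−l) + ε(t),&nbsp;&nbsp; l = 1…5,

fit by multivariate least squares (order chosen by AIC). With
Ā(f) = I − Σₗ Aₗ e^(−i2πfl/fs), the partial directed coherence from
channel *j* to channel *i* is

&nbsp;&nbsp;&nbsp;&nbsp;PDCᵢⱼ(f) = |Āᵢⱼ(f)| / √(āⱼ(f)ᴴ āⱼ(f)),

normalized per source column so Σᵢ PDCᵢⱼ(f)² = 1 at every frequency.
Band averages over delta (1–3 Hz), theta (4–8), alpha (9–12) and beta
(13–30) give 30×30 directed connectomes per subject. Each connectome is
binarized by proportional thresholding at the proportion maximizing
global cost efficiency (global efficiency minus edge density), and five
directed graph measures — node degree, node strength, clustering
coefficient, local efficiency, and Louvain/Newman modularity — summarize
the network (121 values per band). PDC features (900 per band) and
graph features feed five classifiers (KNN, LDA, naive Bayes, decision
tree, RBF-SVM) under stratified 10-fold cross-validation with
fold-internal standardization and sequential forward selection. Group
statistics are one-way ANOVA with η² per band, and per-group Pearson
correlations between alpha-band PDC and the Social Interaction Anxiety
Scale (SIAS).

The study's clinical EEG is not public, so the package includes a
first-class synthetic-cohort generator (`simulate_cohort`) with known
directed-coupling ground truth: 4 groups × 22 subjects, coupling gains
graded severe > moderate > mild > control in theta/alpha, SIAS scores in
the published group bands and copula-tied to alpha connectivity, EDF
output, and injectable high-amplitude artifacts. Every pipeline stage is
tested against this ground truth (see the methods vignette,
`vignettes/pdcnet-methods.Rmd`).

## Worked example

One severe-group subject, simulated and analyzed end to end:

```r
library(pdcnet)

model <- build_coupling(coupling_spec(), "severe")
rec <- simulate_recording(model, duration_s = 128, noise_sd = 12, seed = 42,
                          channel_labels = eeg_montage_30())
rec
#> <eeg_recording> sub-01: 30 channels x 32768 samples @ 256 Hz (128.0 s)

epochs <- reject_artifacts(segment_epochs(rec, epoch_length_s = 3))
epochs
#> <eeg_epochs> sub-01: 40 epochs x 30 channels x 768 samples (3 s @ 256 Hz)

select_order_aic(epochs$epochs[1, , ], p_max = 10)
#> [1] 5

conn <- subject_connectome(epochs, p = 5)
mean(conn$pooled$alpha[row(conn$pooled$alpha) != col(conn$pooled$alpha)])
#> [1] 0.0493

gm <- compute_graph_metrics(conn$pooled$alpha)
c(p_kept = gm$p_kept, modularity = round(gm$modularity, 3))
#>     p_kept modularity
#>      0.400      0.053
```

Reading the numbers: the 128-s recording segments into 42 raw epochs of
which the first 40 clean ones are kept; AIC recovers the generative
model order 5 from a single 3-s epoch; the subject's mean off-diagonal
alpha-band PDC (0.0493 here) is the connectivity summary that group
ANOVA and the SIAS correlation stage consume — severe-group subjects sit
above controls on it by construction; global-cost-efficiency selected a
40% edge-density binarization, and the near-zero modularity says this
subject's thresholded alpha network has no strong community split.

A full cohort run (simulation → preprocessing → connectomes → graph
metrics → group tables) is one call:

```r
cfg <- pipeline_config(cohort_dir = "cohort", out_dir = "results",
                       simulate = TRUE, n_per_group = 22, seed = 1)
res <- run_pipeline(cfg)
pipeline_report("results")
```

which writes per-subject connectome TSVs, a tidy subject table, and
group tables (band PDC means ± SD with F/p/η², graph-measure tables,
per-group PDC–SIAS correlations) as CSV.

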