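# Shared fixtures built once per test run (memoized in this environment).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# a clean severe-group subject: 128 s @ 256 Hz, default coupling
fix_severe_recording <- function() fixture("severe_rec", function() {
  m <- build_coupling(coupling_spec(), "severe")
  simulate_recording(m, 128, noise_sd = 12, seed = 42,
                     channel_labels = eeg_montage_30())
})

fix_severe_epochs <- function() fixture("severe_epochs", function() {
  reject_artifacts(segment_epochs(fix_severe_recording(), 3))
})

# pooled + per-epoch connectomes of the severe subject (the most expensive
# shared fixture; reused by pdc, graphs, features and acceptance tests)
fix_severe_connectome <- function() fixture("severe_conn", function() {
  subject_connectome(fix_severe_epochs(), p = 5)
})

# small stable bivariate MVAR(2) with known coefficients
fix_bivar_model <- function() {
  A1 <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.2, 0, 0.1, -0.15), 2, 2, byrow = TRUE)
  mvar_model(array(c(A1, A2), c(2, 2, 2)), diag(2), fs = 256)
}

# quick multiclass feature set: 4 Gaussian clusters, `informative` useful
# columns followed by `noise` pure-noise columns
make_clusters <- function(n_per = 30, informative = 2, noise = 8,
                          sep = 4, seed = 1) {
  withr::with_seed(seed, {
    groups <- c("severe", "moderate", "mild", "control")
    centers <- matrix(rnorm(4 * informative, sd = sep), 4, informative)
    x <- NULL; y <- c()
    for (g in 1:4) {
      xi <- matrix(rnorm(n_per * informative), n_per) +
        matrix(centers[g, ], n_per, informative, byrow = TRUE)
      x <- rbind(x, cbind(xi, matrix(rnorm(n_per * noise), n_per)))
      y <- c(y, rep(groups[g], n_per))
    }
    feature_table(x, y, subject = sprintf("s%03d", seq_along(y)),
                  epoch = rep(1L, length(y)), band = "alpha")
  })
}
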