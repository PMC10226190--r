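test_that("least-squares MVAR fitting recovers known coefficients", {
  m <- fix_bivar_model()
  rec <- simulate_recording(m, 400, noise_sd = 1, seed = 21)  # 102400 samples
  fit <- fit_mvar(rec$data, 2, fs = 256)
  expect_lt(max(abs(fit$coeffs - m$coeffs)), 0.02)
  expect_true(all(eigen(fit$noise_cov, only.values = TRUE)$values > 0))
})

test_that("white noise yields near-zero coefficients and rejects bad input", {
  x <- matrix(withr::with_seed(3, rnorm(3 * 6000)), 3)
  fit <- fit_mvar(x, 2)
  expect_lt(max(abs(fit$coeffs)), 3.5 / sqrt(6000) * 3)
  expect_error(fit_mvar(x, 0), "positive integer")
  expect_error(fit_mvar(x[, 1:20], 5), "too few samples")
  # a duplicated channel makes the lagged design rank-deficient
  xdup <- rbind(x[1, ], x[1, ], x[2, ])
  expect_error(fit_mvar(xdup, 2), "rank-deficient")
})

test_that("AIC order selection finds the generative order", {
  # univariate AR(1): AIC is noisy on a single short series (the penalty
  # is only 2/T per parameter), so the check is on the modal choice over
  # independent realizations
  ar1 <- mvar_model(array(0.7, c(1, 1, 1)), matrix(1, 1, 1), 256)
  ords1 <- vapply(1:15, function(s)
    select_order_aic(simulate_recording(ar1, 12, noise_sd = 1,
                                        seed = s)$data, p_max = 6), 0L)
  expect_equal(as.integer(names(which.max(table(ords1)))), 1L)
  # order-5 coupled generator, per 3-s epoch, majority vote
  es <- fix_severe_epochs()
  orders <- vapply(1:10, function(e)
    select_order_aic(es$epochs[e, , ], p_max = 8), 0L)
  expect_equal(as.integer(names(which.max(table(orders)))), 5L)
  expect_error(select_order_aic(rec$data, p_max = 0), "p_max")
})

test_that("AIC ties and flats resolve toward the smaller order", {
  # which.min semantics: first index wins; verify through the public surface
  # with data where orders are indistinguishable (pure white noise)
  x <- matrix(withr::with_seed(9, rnorm(2 * 4000)), 2)
  p1 <- select_order_aic(x, p_max = 4)
  expect_lte(p1, 2)    # no structure: penalty picks the smallest orders
})

test_that("PDC spectrum matches a literal transcription of its definition", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      n <- sample(2:3, 1); p <- sample(1:2, 1)
      coeffs <- array(rnorm(n * n * p, sd = 0.25), c(n, n, p))
      m <- mvar_model(coeffs, diag(n), 256)
      freqs <- seq(1, 30, by = 2.5)
      got <- pdc_spectrum(m, freqs)
      want <- oracle_pdc(coeffs, 256, freqs)
      expect_equal(got$values, want, tolerance = 1e-12)
    }
  })
})

test_that("PDC normalization and no-flow structure hold exactly", {
  # diagonal-only model: no information flow off the diagonal
  coeffs <- array(0, c(3, 3, 2))
  for (i in 1:3) coeffs[i, i, ] <- c(0.5, -0.3)
  m <- mvar_model(coeffs, diag(3), 256)
  spec <- pdc_spectrum(m)
  for (k in seq_along(spec$freqs)) {
    v <- spec$values[k, , ]
    expect_equal(diag(v), rep(1, 3), tolerance = 1e-12)
    expect_equal(v[row(v) != col(v)], rep(0, 6), tolerance = 1e-12)
    expect_equal(colSums(v^2), rep(1, 3), tolerance = 1e-8)
  }
  # column normalization for an arbitrary coupled model, every frequency
  m2 <- build_coupling(coupling_spec(), "moderate")
  s2 <- pdc_spectrum(m2)
  for (k in seq_along(s2$freqs))
    expect_equal(colSums(s2$values[k, , ]^2), rep(1, 30), tolerance = 1e-8)
})

test_that("a unidirectional driver shows up only in its own direction", {
  # x1 drives x2 at ~16 Hz; no reverse coupling
  coeffs <- array(0, c(2, 2, 2))
  th <- 2 * pi * 16 / 256
  coeffs[1, 1, ] <- c(2 * 0.9 * cos(th), -0.81)
  coeffs[2, 2, ] <- c(0.3, 0)
  coeffs[2, 1, ] <- c(0.8, 0)
  m <- mvar_model(coeffs, diag(2), 256)
  spec <- pdc_spectrum(m, seq(1, 30, 0.5))
  k16 <- which.min(abs(spec$freqs - 16))
  expect_gt(spec$values[k16, 2, 1], 0.5)              # 1 -> 2 strong
  expect_equal(max(spec$values[, 1, 2]), 0, tolerance = 1e-12)  # no 2 -> 1
})

test_that("PDC is invariant to a common channel rescaling", {
  m <- fix_bivar_model()
  rec <- simulate_recording(m, 20, noise_sd = 1, seed = 6)
  f1 <- fit_mvar(rec$data, 2)
  f2 <- fit_mvar(rec$data * 250, 2)
  expect_equal(pdc_spectrum(f1)$values, pdc_spectrum(f2)$values,
               tolerance = 1e-9)
})

test_that("band averaging is a plain mean with zero diagonal", {
  m <- fix_bivar_model()
  spec <- pdc_spectrum(m, seq(1, 30, 0.5))
  bands <- band_average(spec, list(alpha = c(9, 12), one = c(10, 10)))
  sel <- spec$freqs >= 9 & spec$freqs <= 12
  want <- apply(spec$values[sel, , ], c(2, 3), mean)
  diag(want) <- 0
  expect_equal(unclass(bands$alpha), want, ignore_attr = TRUE)
  # single-frequency band is that slice
  k <- which(spec$freqs == 10)
  slice <- spec$values[k, , ]; diag(slice) <- 0
  expect_equal(unclass(bands$one), slice, ignore_attr = TRUE)
  expect_error(band_average(spec, list(gap = c(30.2, 30.4))),
               "no grid frequency")
  expect_true(all(diag(bands$alpha) == 0))
})

test_that("subject connectomes average per-epoch results consistently", {
  es <- fix_severe_epochs()
  es3 <- epoch_set(es$epochs[1:3, , , drop = FALSE], es$fs, 3,
                   channel_labels = es$channel_labels)
  sc <- subject_connectome(es3, p = 5)
  # one epoch: the mean is that epoch
  es1 <- epoch_set(es$epochs[1, , , drop = FALSE], es$fs, 3)
  sc1 <- subject_connectome(es1, p = 5, pooled = FALSE)
  expect_equal(unclass(sc1$mean$theta), sc1$per_epoch$theta[, , 1],
               ignore_attr = TRUE)
  # permuting epochs leaves the mean unchanged
  esr <- epoch_set(es$epochs[c(3, 1, 2), , , drop = FALSE], es$fs, 3)
  scr <- subject_connectome(esr, p = 5, pooled = FALSE)
  expect_equal(scr$mean$alpha, sc$mean$alpha, tolerance = 1e-12)
  # shapes: 4 bands, 30 x 30, one slab per epoch
  expect_named(sc$per_epoch, c("delta", "theta", "alpha", "beta"))
  expect_equal(dim(sc$per_epoch$theta), c(30, 30, 3))
})

test_that("estimated connectomes recover the planted coupling edges", {
  spec <- coupling_spec()
  sc <- fix_severe_connectome()
  union_edges <- unique(rbind(spec$band_graphs$theta, spec$band_graphs$alpha))
  key <- paste(union_edges[, 2], union_edges[, 1])
  for (b in c("theta", "alpha")) {
    est <- sc$pooled[[b]]
    k <- nrow(spec$band_graphs[[b]])
    off <- which(row(est) != col(est))
    top <- off[order(-est[off])][1:k]
    precision <- mean(paste(row(est)[top], col(est)[top]) %in% key)
    expect_gte(precision, 0.8)
  }
})
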