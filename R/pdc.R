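#' Partial directed coherence spectrum of an MVAR model
#'
#' Evaluates, on a frequency grid, the partial directed coherence (PDC) of
#' Baccala and Sameshima: with
#' `Abar(f) = I - sum_l A_l exp(-i 2 pi f l / fs)`,
#' `PDC_ij(f) = |Abar_ij(f)| / sqrt(abar_j(f)^H abar_j(f))`
#' where `abar_j` is the j-th column of `Abar`. `PDC_ij(f)` measures the
#' direct, directed information flow from channel j to channel i at
#' frequency f, normalized per source column so that
#' `sum_i PDC_ij(f)^2 = 1` at every frequency.
#'
#' @param model An [mvar_model()].
#' @param freqs Frequency grid in Hz (all < fs/2). Default 1-30 Hz in
#'   0.5-Hz steps, covering the four canonical bands.
#' @return Object of class `pdc_spectrum`: list with `freqs` and `values`,
#'   a `length(freqs) x n x n` array (unsquared PDC, in `[0, 1]`).
#' @export
pdc_spectrum <- function(model, freqs = seq(1, 30, by = 0.5)) {
  stopifnot(inherits(model, "mvar_model"))
  if (any(freqs >= model$fs / 2)) stop("frequencies must be below Nyquist")
  n <- model$n_channels; p <- model$order
  vals <- array(NA_real_, c(length(freqs), n, n))
  # A(f) for all frequencies at once: (n^2 x p) coefficient matrix times
  # the (p x n_freq) complex exponential table
  E <- exp(-2i * pi * outer(seq_len(p), freqs) / model$fs)
  AF <- matrix(as.complex(model$coeffs), n * n, p) %*% E
  eye <- as.vector(diag(n)) == 1
  for (k in seq_along(freqs)) {
    Abar <- matrix(-AF[, k], n, n)
    Abar[eye] <- Abar[eye] + 1
    colnorm <- sqrt(colSums(Mod(Abar)^2))
    if (any(colnorm < 1e-12))
      stop("degenerate PDC normalization: zero column norm at f = ",
           freqs[k], " Hz")
    vals[k, , ] <- Mod(Abar) / rep(colnorm, each = n)
  }
  structure(list(freqs = freqs, values = vals, fs = model$fs,
                 n_channels = n),
            class = "pdc_spectrum")
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat(sprintf("<pdc_spectrum> %d channels, %d frequencies (%g-%g Hz)\n",
              x$n_channels, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Band-averaged directed connectomes
#'
#' Arithmetic mean of the PDC over the grid frequencies falling inside each
#' band, with the diagonal (self-flow) set to zero.
#'
#' @param spec A [pdc_spectrum()].
#' @param bands Named list of `c(lo, hi)` band edges in Hz; defaults to
#'   [connectivity_bands()].
#' @return Named list of `n x n` matrices (class `band_connectome`), entry
#'   `[i, j]` = mean PDC flow j -> i, diagonal exactly zero.
#' @export
band_average <- function(spec, bands = connectivity_bands()) {
  stopifnot(inherits(spec, "pdc_spectrum"))
  out <- lapply(names(bands), function(b) {
    sel <- spec$freqs >= bands[[b]][1] & spec$freqs <= bands[[b]][2]
    if (!any(sel))
      stop("band ", b, " contains no grid frequency")
    m <- apply(spec$values[sel, , , drop = FALSE], c(2, 3), mean)
    diag(m) <- 0
    structure(m, band = b, class = c("band_connectome", "matrix", "array"))
  })
  names(out) <- names(bands)
  out
}

#' Per-epoch and epoch-averaged band connectomes for one subject
#'
#' Fits an MVAR model of fixed order to every epoch, computes its PDC
#' spectrum and band averages, and also returns the across-epoch mean
#' connectome per band. (Averaging over epochs and over band frequencies
#' are both linear means, so their order is immaterial.)
#'
#' @param es An [epoch_set()].
#' @param p MVAR order; default 5, the order selected by AIC for 3-s
#'   resting-state epochs at 256 Hz.
#' @param bands Band table; default [connectivity_bands()].
#' @param freqs PDC frequency grid in Hz.
#' @param pooled Also compute connectomes from the pooled multi-trial fit
#'   ([fit_mvar_epochs()]); its coefficient noise floor is about
#'   `sqrt(n_epochs)` lower than any per-epoch fit, so it is the
#'   appropriate subject-level summary for group statistics (default TRUE).
#' @param per_epoch Compute the per-epoch connectome stack (default TRUE;
#'   disable when only the pooled subject summary is needed).
#' @return List with `per_epoch` (named list band -> `n x n x n_epochs`
#'   array), `mean` (named list band -> `n x n` matrix, diagonal zero),
#'   and (if `pooled`) `pooled` (same layout as `mean`).
#' @export
subject_connectome <- function(es, p = 5, bands = connectivity_bands(),
                               freqs = seq(1, 30, by = 0.5),
                               pooled = TRUE, per_epoch = TRUE) {
  stopifnot(inherits(es, "eeg_epochs"), n_epochs(es) >= 1)
  n <- dim(es$epochs)[2]; ne <- n_epochs(es)
  out <- list()
  if (per_epoch) {
    pe <- lapply(names(bands), function(b) array(0, c(n, n, ne)))
    names(pe) <- names(bands)
    for (e in seq_len(ne)) {
      fit <- fit_mvar(es$epochs[e, , ], p, fs = es$fs)
      bc <- band_average(pdc_spectrum(fit, freqs), bands)
      for (b in names(bands)) pe[[b]][, , e] <- bc[[b]]
    }
    mean_conn <- lapply(pe, function(a) {
      m <- apply(a, c(1, 2), mean)
      structure(m, class = c("band_connectome", "matrix", "array"))
    })
    for (b in names(bands)) attr(mean_conn[[b]], "band") <- b
    out$per_epoch <- pe
    out$mean <- mean_conn
  }
  if (pooled) {
    fit <- fit_mvar_epochs(es, p)
    out$pooled <- band_average(pdc_spectrum(fit, freqs), bands)
  }
  out
}
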