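#' Zero-phase band-pass filtering
#'
#' Butterworth filtering applied forward-backward (zero phase) per channel:
#' an order-2 high-pass at `lo_hz` (numerically robust at very low
#' cut-offs) cascaded with an order-8 low-pass at `hi_hz` (steep stop-band:
#' a 50 Hz mains component is attenuated below 1% with the default 40 Hz
#' edge). The mean (DC) is removed before filtering.
#'
#' @param rec An [recording()].
#' @param lo_hz,hi_hz Pass-band edges in Hz; `0 < lo < hi < fs/2`.
#' @return Filtered [recording()] of identical shape.
#' @export
bandpass_filter <- function(rec, lo_hz = 0.4, hi_hz = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz)) stop("need 0 < lo_hz < hi_hz")
  if (hi_hz >= nyq) stop("hi_hz must be below the Nyquist frequency ", nyq)
  hp <- signal::butter(2, lo_hz / nyq, type = "high")
  lp <- signal::butter(8, hi_hz / nyq, type = "low")
  out <- rec
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$data[ch, ] - mean(rec$data[ch, ])
    x <- signal::filtfilt(hp, x)
    out$data[ch, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased downsampling: for integer decimation factors an order-8
#' Chebyshev low-pass decimator (`signal::decimate`), otherwise
#' band-limited polyphase resampling (`signal::resample`).
#'
#' @param rec An [recording()].
#' @param fs_out Target sampling rate in Hz, `< fs`.
#' @return Resampled [recording()] with `round(n * fs_out / fs)` samples.
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_out >= rec$fs) stop("fs_out must be below the input rate ", rec$fs)
  q <- rec$fs / fs_out
  n_out <- round(n_samples(rec) * fs_out / rec$fs)
  data <- matrix(0, n_channels(rec), n_out)
  for (ch in seq_len(n_channels(rec))) {
    y <- if (abs(q - round(q)) < 1e-9)
      signal::decimate(rec$data[ch, ], round(q))
    else
      signal::resample(rec$data[ch, ], p = round(fs_out), q = round(rec$fs))
    data[ch, ] <- y[seq_len(n_out)]
  }
  recording(data, fs_out, rec$channel_labels, rec$subject_id)
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs; any trailing remainder shorter than
#' one epoch is dropped.
#'
#' @param rec An [recording()].
#' @param epoch_length_s Epoch length in seconds (default 3).
#' @return An [epoch_set()] with `floor(duration / epoch_length_s)` epochs.
#' @export
segment_epochs <- function(rec, epoch_length_s = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_length_s * rec$fs)
  n_ep <- n_samples(rec) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch (",
                     epoch_length_s, " s)")
  ep <- array(0, c(n_ep, n_channels(rec), len))
  for (e in seq_len(n_ep))
    ep[e, , ] <- rec$data[, ((e - 1) * len + 1):(e * len)]
  epoch_set(ep, rec$fs, epoch_length_s, seq_len(n_ep),
            rec$channel_labels, rec$subject_id)
}

#' Amplitude-based artifact rejection
#'
#' Drops every epoch whose absolute amplitude exceeds `amp_uV` on any
#' channel (the +/- 100 uV criterion by default), then keeps at most the
#' first `max_keep` clean epochs. Rejection never reorders epochs.
#'
#' @param es An [epoch_set()].
#' @param amp_uV Rejection threshold in microvolts (> 0).
#' @param max_keep Maximum clean epochs to retain (default 40).
#' @param min_keep Minimum acceptable clean epochs (default 10); fewer is
#'   an error naming the subject.
#' @return A screened [epoch_set()].
#' @export
reject_artifacts <- function(es, amp_uV = 100, max_keep = 40, min_keep = 10) {
  stopifnot(inherits(es, "eeg_epochs"))
  if (amp_uV <= 0) stop("amp_uV must be > 0")
  peak <- apply(abs(es$epochs), 1, max)
  clean <- which(peak <= amp_uV)
  if (length(clean) < min_keep)
    stop("subject ", es$subject_id, ": only ", length(clean),
         " clean epochs (minimum ", min_keep, ")")
  keep <- clean[seq_len(min(length(clean), max_keep))]
  epoch_set(es$epochs[keep, , , drop = FALSE], es$fs, es$epoch_length_s,
            es$kept_indices[keep], es$channel_labels, es$subject_id)
}

# one-sided Welch periodogram of a vector with a Hann window,
# returning density over [0, fs/2]; normalized so that
# sum(psd) * df ~= var(x) (Parseval)
welch_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  spec <- Mod(fft(xw))^2 / (fs * sum(w^2))
  half <- floor(n / 2) + 1
  psd <- spec[seq_len(half)]
  psd[2:(half - 1)] <- 2 * psd[2:(half - 1)]    # fold negative frequencies
  list(freq = (seq_len(half) - 1) * fs / n, psd = psd)
}

#' Band power by Welch averaging
#'
#' Mean spectral power density per channel and band: each epoch is Hann
#' windowed and periodogram-transformed (Welch segments of one epoch
#' length), densities are averaged across epochs, and the band power is
#' the mean density over the band's frequency bins.
#'
#' @param es An [epoch_set()].
#' @param bands Named list of band edges in Hz; default [power_bands()]
#'   (note its delta/alpha edges differ from the connectivity table).
#' @return data.frame with columns `channel`, `band`, `power`
#'   (uV^2/Hz, mean density in band).
#' @export
band_power <- function(es, bands = power_bands()) {
  stopifnot(inherits(es, "eeg_epochs"))
  hi <- max(vapply(bands, max, 0))
  if (hi >= es$fs / 2) stop("bands must lie below the Nyquist frequency")
  nch <- dim(es$epochs)[2]
  avg <- NULL
  for (e in seq_len(n_epochs(es))) {
    for (ch in seq_len(nch)) {
      pw <- welch_psd(es$epochs[e, ch, ], es$fs)
      if (is.null(avg)) avg <- matrix(0, nch, length(pw$psd))
      avg[ch, ] <- avg[ch, ] + pw$psd / n_epochs(es)
      freq <- pw$freq
    }
  }
  out <- expand.grid(channel = es$channel_labels, band = names(bands),
                     stringsAsFactors = FALSE)
  out$power <- mapply(function(ch, b) {
    sel <- freq >= bands[[b]][1] & freq <= bands[[b]][2]
    mean(avg[match(ch, es$channel_labels), sel])
  }, out$channel, out$band)
  out
}
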