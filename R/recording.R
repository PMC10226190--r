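#' Multichannel EEG recording
#'
#' Container for one subject's continuous multichannel EEG: a channels x
#' samples amplitude matrix in microvolts plus sampling rate, channel labels
#' and subject id.
#'
#' @param data Numeric matrix, channels x samples, amplitudes in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, subject_id = "sub-01") {
  data <- as.matrix(data)
  if (!all(is.finite(data)))
    stop("recording contains non-finite values; first bad index: ",
         which(!is.finite(data))[1])
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") != channel count (", nrow(data), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = subject_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Fixed-length epochs of a recording
#'
#' Container for artifact-screened, fixed-length segments of a recording:
#' an epoch x channel x sample array plus bookkeeping of which original
#' epoch positions were kept.
#'
#' @param epochs Numeric array, epoch x channel x sample (microvolts).
#' @param fs Sampling rate in Hz.
#' @param epoch_length_s Epoch length in seconds.
#' @param kept_indices Original (1-based) epoch positions, strictly increasing.
#' @param channel_labels Channel labels.
#' @param subject_id Subject identifier.
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(epochs, fs, epoch_length_s, kept_indices = NULL,
                      channel_labels = NULL, subject_id = "sub-01") {
  stopifnot(length(dim(epochs)) == 3L)
  if (dim(epochs)[3] != round(epoch_length_s * fs))
    stop("epoch sample count != round(epoch_length_s * fs)")
  if (is.null(kept_indices)) kept_indices <- seq_len(dim(epochs)[1])
  if (is.unsorted(kept_indices, strictly = TRUE))
    stop("kept_indices must be strictly increasing")
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(dim(epochs)[2]))
  structure(
    list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
         kept_indices = as.integer(kept_indices),
         channel_labels = channel_labels, subject_id = subject_id),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %s: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              x$subject_id, d[1], d[2], d[3], x$epoch_length_s, x$fs))
  invisible(x)
}

n_epochs <- function(es) dim(es$epochs)[1]
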