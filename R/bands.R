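#' Canonical frequency-band tables
#'
#' Two band tables are carried: one used for connectivity band-averaging of
#' PDC spectra (delta 1-3, theta 4-8, alpha 9-12, beta 13-30 Hz) and one used
#' for spectral band-power analysis (delta 0.5-4, theta 4-8, alpha 8-12,
#' beta 13-30 Hz). Each stage of the pipeline defaults to its own table.
#' Gamma is excluded throughout.
#'
#' @return Named list of `c(lo, hi)` frequency edges in Hz.
#' @export
connectivity_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 8), alpha = c(9, 12), beta = c(13, 30))
}

#' @rdname connectivity_bands
#' @export
power_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(13, 30))
}

#' Canonical 30-channel 10-20 montage
#'
#' The scalp montage used by the synthetic generator: thirty 10-20 labels,
#' frontal through occipital. (One published electrode list this mirrors
#' contains a duplicated "C3"; the duplicate is replaced by "CP3" here.
#' Analyses depend only on the channel count and ordering.)
#'
#' @return Character vector of 30 channel labels.
#' @export
eeg_montage_30 <- function() {
  c("FP1", "FP2", "FPz", "F7", "F8", "F3", "F4", "FC5", "FC1", "FC2",
    "FC6", "Fz", "Cz", "T8", "P7", "P8", "C3", "C4", "CP3", "CP2",
    "CP4", "CP1", "CP6", "CP5", "P3", "P4", "Pz", "O1", "O2", "POz")
}

# indices of frontal-ish and posterior-ish channels in eeg_montage_30(),
# used by the default synthetic coupling graphs
frontal_channels <- function() c(1:8, 9, 12)
posterior_channels <- function() c(25:30, 15, 16)
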