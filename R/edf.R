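#' Minimal European Data Format (EDF) input/output
#'
#' A deliberately small EDF reader/writer covering the subset of the format
#' this pipeline produces and consumes: continuous multichannel recordings,
#' identical sampling rate on every signal, 1-second data records, 16-bit
#' samples, physical units of microvolts. Physical scaling is symmetric per
#' file, so amplitudes round-trip to within one quantization step
#' (physical range / 65534).
#'
#' @param rec An [recording()] whose duration is a whole number of seconds.
#' @param path File path to write to / read from.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   [recording()].
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- n_channels(rec)
  spr <- as.integer(round(rec$fs))   # samples per 1-s record
  if (abs(rec$fs - spr) > 1e-9) stop("write_edf requires an integer fs")
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1L || n_samples(rec) %% spr != 0L)
    stop("recording length must be a whole number of seconds")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)

  phys_max <- max(200, ceiling(max(abs(rec$data))))
  dig_max <- 32767L
  pad <- function(x, w) formatC(substr(as.character(x), 1, w),
                                width = w, flag = "-")
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(rec$subject_id, 80); wr("pdcnet synthetic EEG", 80)
  wr("01.01.26", 8); wr("00.00.00", 8); wr(header_bytes, 8)
  wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (f in list(c(16, NA), c(80, ""), c(8, "uV"), c(8, -phys_max),
                 c(8, phys_max), c(8, -dig_max), c(8, dig_max),
                 c(80, ""), c(8, spr), c(32, ""))) {
    for (i in seq_len(ns)) {
      val <- if (is.na(f[2])) rec$channel_labels[i] else f[2]
      wr(val, as.integer(f[1]))
    }
  }
  scale <- phys_max / dig_max
  dig <- matrix(as.integer(pmax(pmin(round(rec$data / scale), dig_max),
                                -dig_max)), nrow = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                             # header byte count (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)     # transducer
  for (i in seq_len(ns)) rd(8)      # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)     # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports a single sampling rate across signals")
  fs <- spr[1] / rec_dur

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - scale * dig_min
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                     signed = TRUE, endian = "little")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(matrix(block, ncol = ns)) * scale + offset
  }
  recording(data, fs, labels, subject_id)
}
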