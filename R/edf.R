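#' Write a continuous multichannel recording as EDF
#'
#' Minimal European Data Format writer for continuous recordings: one data
#' record per second (a shorter final record is padded with the last sample;
#' the true sample count is stored in the recording-id field and honoured by
#' [read_edf()]).  Samples are quantized to 16-bit integers over each
#' channel's physical range, the format's native resolution.
#'
#' @param eeg channels x samples numeric matrix (\eqn{\mu V}), rownames =
#'   channel labels.
#' @param fs_hz sampling rate (samples per second, integer).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, fs_hz, path) {
  eeg <- as.matrix(eeg)
  stop_if_not(fs_hz == round(fs_hz), "write_edf needs an integer sampling rate")
  ns <- nrow(eeg)
  n_samp <- ncol(eeg)
  labels <- rownames(eeg) %||% paste0("ch", seq_len(ns))
  n_rec <- ceiling(n_samp / fs_hz)
  pad <- n_rec * fs_hz - n_samp
  if (pad > 0) eeg <- cbind(eeg, eeg[, rep(n_samp, pad), drop = FALSE])

  pmin <- apply(eeg, 1, min)
  pmax <- apply(eeg, 1, max)
  degen <- pmax - pmin < 1e-9
  pmax[degen] <- pmin[degen] + 1
  dmin <- -32768
  dmax <- 32767

  fixed <- function(x, w) {
    s <- substr(sprintf("%-*s", w, x), 1, w)
    s
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed("0", 8), fixed("X X X X", 80),
    fixed(sprintf("nsamp=%d", n_samp), 80),
    fixed("01.01.26", 8), fixed("00.00.00", 8),
    fixed(as.character(256 * (ns + 1)), 8), fixed("", 44),
    fixed(as.character(n_rec), 8), fixed("1", 8), fixed(as.character(ns), 4),
    paste(vapply(labels, fixed, "", w = 16), collapse = ""),
    paste(rep(fixed("", 80), ns), collapse = ""),
    paste(rep(fixed("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", pmin), fixed, "", w = 8), collapse = ""),
    paste(vapply(sprintf("%.8g", pmax), fixed, "", w = 8), collapse = ""),
    paste(rep(fixed(as.character(dmin), 8), ns), collapse = ""),
    paste(rep(fixed(as.character(dmax), 8), ns), collapse = ""),
    paste(rep(fixed("", 80), ns), collapse = ""),
    paste(rep(fixed(as.character(fs_hz), 8), ns), collapse = ""),
    paste(rep(fixed("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the printed physical ranges so quantization round-trips exactly
  pmin_r <- as.numeric(sprintf("%.8g", pmin))
  pmax_r <- as.numeric(sprintf("%.8g", pmax))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    sl <- ((r - 1) * fs_hz + 1):(r * fs_hz)
    for (ch in seq_len(ns)) {
      dig <- round((eeg[ch, sl] - pmin_r[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Reads EDF files with a uniform sampling rate across signals (the layout
#' [write_edf()] produces and the common continuous-EEG case).  Returns the
#' channels x samples matrix in physical units with attribute `fs_hz`; the
#' channel labels are the rownames.
#'
#' @param path EDF file path.
#' @return channels x samples numeric matrix with attribute `fs_hz`.
#' @export
read_edf <- function(path) {
  stop_if_not(file.exists(path), "no such EDF file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  stop_if_not(version == "0", "not an EDF file (version field '%s')", version)
  rd(80)
  recid <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stop_if_not(length(unique(spr)) == 1,
              "read_edf supports a uniform sampling rate only")
  seek(con, hdr_bytes)
  total <- n_rec * spr[1]
  out <- matrix(NA_real_, ns, total)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      sl <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      out[ch, sl] <- pmin[ch] + (dig - dmin[ch]) *
        (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  # honour the true (pre-padding) sample count if the writer recorded it
  m <- regmatches(recid, regexec("nsamp=([0-9]+)", recid))[[1]]
  if (length(m) == 2) out <- out[, seq_len(as.integer(m[2])), drop = FALSE]
  rownames(out) <- labels
  attr(out, "fs_hz") <- spr[1] / rec_dur
  out
}
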