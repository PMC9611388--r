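# EDF (European Data Format) writer/reader: 16-bit integer records with
# per-channel physical scaling in microvolts, 1 s record duration, plus a
# sidecar TSV event table (onset sample, condition, session).  The true
# sample count is stored in the 44-byte reserved header field ("NS=<n>") so
# the reader can trim the zero-padding of the final record.

pad_ascii <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording to EDF with a sidecar event table
#'
#' @param rec an [eeg_recording].
#' @param path output EDF path.
#' @param events_path sidecar TSV path (default `<path>.events.tsv`) with
#'   columns onset_sample, condition, session.
#' @return `path`, invisibly.
#' @seealso [read_edf] for the round-trip reader.
#' @export
write_edf <- function(rec, path, events_path = paste0(path, ".events.tsv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer needs an integer sampling rate",
                            call. = FALSE)
  x <- rec$data
  ns <- nrow(x); nt <- ncol(x)
  n_rec <- ceiling(nt / fs)
  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  # physical limits are serialized as 8-char ASCII; quantize through the
  # printed form so writer and reader share the exact same scaling
  pmin_s <- vapply(pmin_, function(v) sprintf("%-8.8s", formatC(v, format = "g", digits = 6)), "")
  pmax_s <- vapply(pmax_, function(v) sprintf("%-8.8s", formatC(v, format = "g", digits = 6)), "")
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  bad <- pmax_ <= pmin_
  pmax_[bad] <- pmin_[bad] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate 01-JAN-2000 X X synthetic", 80),
    pad_ascii("01.01.00", 8),
    pad_ascii("00.00.00", 8),
    pad_ascii(256 * (ns + 1L), 8),
    pad_ascii(paste0("NS=", nt), 44),
    pad_ascii(n_rec, 8),
    pad_ascii("1", 8),
    pad_ascii(ns, 4))
  sig <- paste0(
    paste0(vapply(rec$channels, pad_ascii, "", width = 16), collapse = ""),
    strrep(pad_ascii("synthetic EEG", 80), ns),
    strrep(pad_ascii("uV", 8), ns),
    paste0(vapply(pmin_s, pad_ascii, "", width = 8), collapse = ""),
    paste0(vapply(pmax_s, pad_ascii, "", width = 8), collapse = ""),
    strrep(pad_ascii(dmin, 8), ns),
    strrep(pad_ascii(dmax, 8), ns),
    strrep(pad_ascii("", 80), ns),
    strrep(pad_ascii(fs, 8), ns),
    strrep(pad_ascii("", 32), ns))
  writeBin(charToRaw(paste0(hdr, sig)), con)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * fs + 1L
    i1 <- min(r * fs, nt)
    block <- matrix(0, ns, fs)
    block[, seq_len(i1 - i0 + 1L)] <- x[, i0:i1, drop = FALSE]
    dig <- round((block - pmin_) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  ev <- data.frame(onset_sample = rec$events$sample,
                   condition = rec$events$condition,
                   session = rec$events$session)
  utils::write.table(ev, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an EDF recording and its sidecar event table
#'
#' Reads the dialect written by [write_edf] (any plain 16-bit EDF with
#' equal per-signal rates works; the `NS=` reserved field, when present,
#' trims final-record padding).
#'
#' @param path EDF path.
#' @param events_path sidecar TSV path; skipped if the file is absent.
#' @return an [eeg_recording].
#' @export
read_edf <- function(path, events_path = paste0(path, ".events.tsv")) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) {
    trimws(rawToChar(readBin(con, "raw", w)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                        # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))    # samples per record per signal
  rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("reader supports equal per-signal sampling rates only", call. = FALSE)
  }
  fs <- spr[1L] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1L], dimnames = list(labels, NULL))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1L])   # samples x signals
    x[, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
      t((block - rep(dmin, each = spr[1L])) * rep(scale, each = spr[1L]) +
          rep(pmin_, each = spr[1L]))
  }
  if (grepl("^NS=", reserved)) {
    nt <- as.integer(sub("^NS=", "", reserved))
    x <- x[, seq_len(nt), drop = FALSE]
  }
  events <- if (file.exists(events_path)) {
    ev <- utils::read.table(events_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c("integer", "character", "character"))
    data.frame(sample = ev$onset_sample, condition = ev$condition,
               session = ev$session, stringsAsFactors = FALSE)
  } else {
    data.frame(sample = integer(0), condition = character(0),
               session = character(0))
  }
  eeg_recording(x, fs, events)
}
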