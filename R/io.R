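## File formats: a minimal EDF reader/writer (16-bit, 1-second records),
## the annotation TSV dialect, the pre-extracted tachogram CSV dialect,
## and hypnogram output.

#' Read a (minimal) EDF file
#'
#' Parses the standard EDF header and 16-bit data records and returns the
#' requested channels as `signal_segment`s with physical units applied.
#' Covers continuous EDF with integer sampling rates; EDF+ annotation
#' streams are ignored.
#'
#' @param path EDF file.
#' @param channels optional character vector of regular expressions; only
#'   channels whose label matches one of them are returned (all by
#'   default).
#' @return named list of `signal_segment`s.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)   # version, patient, rec, date, time
  hdr(8)                                     # header bytes
  hdr(44)
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  fld <- function(nc) vapply(seq_len(ns), function(i) hdr(nc), character(1))
  labels <- fld(16)
  fld(80); fld(8)                            # transducer, physical dim
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                                    # prefiltering
  spr <- as.integer(fld(8))                  # samples per record
  fld(32)                                    # reserved
  dat <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      dat[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- which(vapply(labels, function(l)
      any(vapply(channels, function(p) grepl(p, l, ignore.case = TRUE),
                 logical(1))), logical(1)))
    assert_that(length(keep) > 0, "no channel matches the requested patterns")
  }
  out <- lapply(keep, function(i) {
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys <- pmin[i] + (dat[[i]] - dmin[i]) * scale
    signal_segment(phys, fs = spr[i] / rec_dur, label = labels[i])
  })
  names(out) <- labels[keep]
  out
}

#' Write signal segments to a (minimal) EDF file
#'
#' One-second data records; every channel must therefore have an integer
#' sampling rate and a whole-second duration (shorter channels are
#' zero-padded to the longest).
#'
#' @param segments named list of `signal_segment`s.
#' @param path output file.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(segments, path, patient = "X", recording = "capcri") {
  ns <- length(segments)
  fs <- vapply(segments, function(s) s$fs, numeric(1))
  assert_that(all(abs(fs - round(fs)) < 1e-9),
              "EDF writer requires integer sampling rates")
  n_rec <- max(ceiling(vapply(segments, seg_duration, numeric(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, nc) {
    s <- substr(paste0(x, strrep(" ", nc)), 1, nc)
    writeChar(s, con, eos = NULL)
  }
  ranges <- lapply(segments, function(s) {
    r <- range(s$samples)
    if (diff(r) <= 0) r <- r + c(-1, 1)
    r
  })
  pad("0", 8); pad(patient, 80); pad(recording, 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(as.character(256 * (1 + ns)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  for (s in segments) pad(s$label, 16)
  for (s in segments) pad("", 80)
  for (s in segments) pad("au", 8)
  for (r in ranges) pad(sprintf("%.5g", r[1]), 8)
  for (r in ranges) pad(sprintf("%.5g", r[2]), 8)
  for (s in segments) pad("-32768", 8)
  for (s in segments) pad("32767", 8)
  for (s in segments) pad("", 80)
  for (s in segments) pad(as.character(as.integer(round(s$fs))), 8)
  for (s in segments) pad("", 32)
  dig <- lapply(seq_len(ns), function(i) {
    s <- segments[[i]]; r <- ranges[[i]]
    n_full <- as.integer(round(s$fs)) * n_rec
    x <- c(s$samples, rep(0, max(0, n_full - length(s$samples))))[1:n_full]
    as.integer(round(-32768 + (x - r[1]) / (r[2] - r[1]) * 65535))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      spr <- as.integer(round(segments[[i]]$fs))
      writeBin(dig[[i]][((r - 1L) * spr + 1L):(r * spr)], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read / write the annotation TSV dialect
#'
#' Tab-separated columns `epoch_start_s`, `stage` (W, R, S1..S4) and
#' `cap_phase` (A1, A2, A3, NA for non-A NREM epochs, `-` for wake/REM).
#'
#' @param path file path.
#' @return `read_annotations_tsv` returns the 18-class label vector.
#' @export
read_annotations_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = "character", na.strings = NULL)
  assert_that(all(c("epoch_start_s", "stage", "cap_phase") %in% names(d)),
              "annotation TSV must have epoch_start_s, stage, cap_phase")
  as_stage_factor(make_label(d$stage, d$cap_phase))
}

#' @rdname read_annotations_tsv
#' @param labels 18-class labels.
#' @param epoch_s epoch length in seconds.
#' @export
write_annotations_tsv <- function(labels, path, epoch_s = 30) {
  labels <- as.character(labels)
  d <- data.frame(epoch_start_s = (seq_along(labels) - 1L) * epoch_s,
                  stage = stage_of(labels), cap_phase = phase_of(labels))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the pre-extracted tachogram CSV dialect
#'
#' Columns `time_ms` (beat time of the interval's ending beat) and `rr_ms`.
#' @param path file path.
#' @return `read_rr_csv` returns an `rri_series`.
#' @export
read_rr_csv <- function(path) {
  d <- read.csv(path)
  assert_that(all(c("time_ms", "rr_ms") %in% names(d)),
              "tachogram CSV must have columns time_ms, rr_ms")
  t_beats <- c(d$time_ms[1] - d$rr_ms[1], d$time_ms) / 1000
  rri_series(beat_times = t_beats)
}

#' @rdname read_rr_csv
#' @param rri an `rri_series`.
#' @export
write_rr_csv <- function(rri, path) {
  d <- data.frame(time_ms = rri$beat_times[-1] * 1000, rr_ms = rri$intervals)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a hypnogram TSV
#'
#' Output dialect of the classifier: `epoch_start_s`, `stage`, `cap_phase`.
#' @param labels predicted 18-class labels.
#' @param path file path.
#' @param epoch_s epoch length.
#' @export
write_hypnogram <- function(labels, path, epoch_s = 30) {
  write_annotations_tsv(labels, path, epoch_s = epoch_s)
}

#' Converter stub for the CAP Sleep Database annotation dialect
#'
#' The public database ships expert annotations in its own text layout;
#' converting them is site-specific and out of scope. This stub documents
#' the expected target: produce the TSV dialect of
#' [read_annotations_tsv()] (one row per 30-s epoch with `stage` and
#' `cap_phase`) with any external tool, then load that file.
#'
#' @param path unused.
#' @export
read_cap_annotations <- function(path) {
  stop("not implemented: convert the native annotation file to the ",
       "epoch_start_s/stage/cap_phase TSV dialect and use ",
       "read_annotations_tsv()", call. = FALSE)
}
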