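## RR-interval (tachogram) container, cleaning, R-peak detection and
## tachogram resampling.

#' RR-interval series
#'
#' Beat times in seconds (strictly increasing) with the implied RR intervals
#' in milliseconds: `intervals[i] = (beat_times[i+1] - beat_times[i]) * 1000`.
#' Construct from either beat times or intervals.
#'
#' @param beat_times numeric, beat times in seconds.
#' @param intervals_ms numeric, RR intervals in ms. When `beat_times` is
#'   missing, beats are placed cumulatively from `t0`; when both are given
#'   (one interval per beat after the first) the values may deviate from
#'   the beat-time differences - that is how a cleaned tachogram anchors
#'   corrected interval values at the original, measured beat times so the
#'   series stays aligned with the other channels.
#' @param t0 time of the first beat when building from intervals.
#' @return object of class `rri_series` with `beat_times` and `intervals`.
#' @export
rri_series <- function(beat_times = NULL, intervals_ms = NULL, t0 = 0) {
  if (is.null(beat_times)) {
    assert_that(!is.null(intervals_ms), "supply beat_times or intervals_ms")
    assert_that(all(intervals_ms > 0), "intervals must be positive")
    beat_times <- t0 + cumsum(c(0, intervals_ms)) / 1000
  }
  assert_that(length(beat_times) >= 2L, "need at least 2 beats")
  d <- diff(beat_times)
  assert_that(all(d > 0), "beat times must be strictly increasing")
  if (is.null(intervals_ms)) intervals_ms <- d * 1000
  assert_that(length(intervals_ms) == length(beat_times) - 1L,
              "need one interval per beat after the first")
  assert_that(all(intervals_ms > 0), "intervals must be positive")
  structure(list(beat_times = as.numeric(beat_times),
                 intervals = as.numeric(intervals_ms)),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series: %d beats over %.1f s, mean RR %.0f ms>\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$intervals)))
  invisible(x)
}

#' Subset an RR series to a time window
#' @param rri an `rri_series`.
#' @param t_lo,t_hi time bounds in seconds (intervals whose ending beat lies
#'   in `[t_lo, t_hi]` are kept).
#' @return an `rri_series`, or NULL if fewer than 2 beats fall in the window.
#' @export
rri_slice <- function(rri, t_lo, t_hi) {
  keep <- which(rri$beat_times >= t_lo & rri$beat_times <= t_hi)
  if (length(keep) < 2L) return(NULL)
  rri_series(beat_times = rri$beat_times[keep],
             intervals_ms = rri$intervals[keep[-1] - 1L])
}

#' Clean an RR-interval series
#'
#' An interval is flagged as an artefact when it deviates from the running
#' series mean (centred moving average over `run_beats` beats, so slow
#' baseline shifts between sleep stages do not count as deviations) by
#' more than `sd_mult` segment standard deviations, or when it changes by
#' more than +/-30% relative to the previous accepted interval
#' (`rel_lo`/`rel_hi` bounds). Flagged intervals are replaced by piecewise
#' cubic interpolation through the surrounding valid intervals and the
#' replacements are re-checked against the same gates (clamped into range
#' if the interpolant still violates them). The gates are computed once,
#' from the input segment: the normality gate is self-referential (any
#' noisy series regrows a 1.5-sigma tail after trimming), so repeated
#' re-estimation would progressively flatten genuine variability rather
#' than converge.
#'
#' @param rri an `rri_series` with at least 3 intervals.
#' @param sd_mult deviation gate in standard deviations (default 1.5).
#' @param rel_lo,rel_hi relative-change gate against the previous interval
#'   (defaults 0.7 and 1.3).
#' @param run_beats width of the running mean in beats (odd; default 61,
#'   about a minute of heartbeats).
#' @return list with `cleaned` (an `rri_series` holding the original beat
#'   times and the cleaned interval values) and `replaced` (indices of
#'   replaced intervals).
#' @export
#' @examples
#' r <- rri_series(intervals_ms = c(800, 800, 2000, 800, 800))
#' clean_rr(r)$replaced
clean_rr <- function(rri, sd_mult = 1.5, rel_lo = 0.7, rel_hi = 1.3,
                     run_beats = 61L) {
  assert_that(inherits(rri, "rri_series"), "rri must be an rri_series")
  x <- rri$intervals
  assert_that(length(x) >= 3L, "need at least 3 intervals")
  m <- running_mean(x, run_beats)
  s <- sd(x)
  bad <- abs(x - m) > sd_mult * s
  prev <- if (bad[1]) NA_real_ else x[1]
  for (i in seq_along(x)[-1]) {
    if (is.na(prev)) {
      # no accepted predecessor yet: the deviation gate alone decides
      if (!bad[i]) prev <- x[i]
      next
    }
    if (!(x[i] > rel_lo * prev && x[i] < rel_hi * prev)) bad[i] <- TRUE
    if (!bad[i]) prev <- x[i]
  }
  if (any(bad)) {
    assert_that(!all(bad), "unusable segment: every interval violates the gates")
    good <- which(!bad)
    fill <- if (length(good) >= 2L) {
      spline(good, x[good], xout = which(bad), method = "natural")$y
    } else rep(x[good], sum(bad))
    x[bad] <- pmax(fill, 1)
  }
  list(cleaned = rri_series(beat_times = rri$beat_times, intervals_ms = x),
       replaced = which(bad))
}

## centred moving average with shrinking windows at the edges
running_mean <- function(x, w) {
  n <- length(x)
  if (n <= w) return(rep(mean(x), n))
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Clean a long recording in consecutive segments
#'
#' Applies [clean_rr()] to consecutive blocks of `segment_s` seconds, so
#' the normality gate is computed on locally stationary statistics: over a
#' whole night the baseline RR differs between sleep stages by more than
#' the 1.5-sigma gate itself, and global statistics would clip entire
#' stages rather than artefacts.
#'
#' @param rri an `rri_series`.
#' @param segment_s segment length in seconds (default 300).
#' @inheritParams clean_rr
#' @return as [clean_rr()]; `replaced` indexes the full interval sequence.
#' @export
clean_rr_segmented <- function(rri, segment_s = 300, sd_mult = 1.5,
                               rel_lo = 0.7, rel_hi = 1.3) {
  x <- rri$intervals
  tt <- rri$beat_times[-1]
  blk <- floor((tt - tt[1]) / segment_s)
  out <- x
  replaced <- integer(0)
  for (b in unique(blk)) {
    idx <- which(blk == b)
    if (length(idx) < 3L) next
    cl <- tryCatch(clean_rr(rri_series(intervals_ms = x[idx]),
                            sd_mult = sd_mult, rel_lo = rel_lo,
                            rel_hi = rel_hi),
                   error = function(e) NULL)
    if (is.null(cl)) next
    out[idx] <- cl$cleaned$intervals
    replaced <- c(replaced, idx[cl$replaced])
  }
  list(cleaned = rri_series(beat_times = rri$beat_times, intervals_ms = out),
       replaced = replaced)
}

#' Detect R peaks in an ECG segment
#'
#' Derivative-square-integrate scheme: band-pass to the QRS band
#' (5-15 Hz), differentiate, square, moving-window integrate over 150 ms,
#' then pick peaks above an adaptive threshold with a 250 ms refractory
#' period and refine each location to the local extremum of the band-passed
#' ECG.
#'
#' @param ecg `signal_segment` sampled at >= 100 Hz.
#' @param min_rate,max_rate plausible heart-rate range in bpm; detections
#'   implying rates outside it are flagged via the `"rate_flag"` attribute.
#' @return numeric vector of beat times (s), strictly increasing.
#' @export
detect_r_peaks <- function(ecg, min_rate = 30, max_rate = 200) {
  ecg <- as_segment(ecg)
  fs <- ecg$fs
  assert_that(fs >= 100, "ECG must be sampled at >= 100 Hz")
  x <- ecg$samples
  assert_that(length(x) >= fs, "ECG segment too short")
  if (sd_pop(x) < 1e-12) stop("detection error: flat or saturated ECG")
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  w <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * quantile(integ, 0.99)
  if (thr <= 0) stop("detection error: no QRS energy found")
  refr <- round(0.25 * fs)
  above <- integ > thr
  cand <- which(above & c(TRUE, diff(integ) > 0) & c(diff(integ) <= 0, TRUE))
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) { peaks <- c(peaks, i); last <- i }
    else if (integ[i] > integ[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i; last <- i
    }
  }
  if (length(peaks) < 2L) stop("detection error: fewer than 2 beats found")
  # refine to the local |band-passed| maximum
  half <- as.integer(round(0.1 * fs))
  ref <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(length(xf), as.integer(i) + half)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  beat_times <- ecg$t0 + (ref - 1L) / fs
  rates <- 60 / diff(beat_times)
  attr(beat_times, "rate_flag") <- any(rates < min_rate | rates > max_rate)
  beat_times
}

#' Resample a tachogram to an evenly sampled instantaneous-RR signal
#'
#' Each interval is anchored at its ending beat time; cubic spline
#' interpolation gives the instantaneous RR (ms) on a uniform grid, the
#' representation used by the bivariate autoregressive model.
#'
#' @param rri an `rri_series`.
#' @param fs output sampling rate (default 4 Hz).
#' @param t_range optional `c(t0, t1)` to restrict/align the grid.
#' @return `signal_segment` of instantaneous RR in ms.
#' @export
resample_tachogram <- function(rri, fs = 4, t_range = NULL) {
  tt <- rri$beat_times[-1]
  x <- rri$intervals
  t_range <- t_range %||% range(tt)
  grid <- seq(t_range[1], t_range[2], by = 1 / fs)
  y <- spline(tt, x, xout = grid, method = "natural")$y
  # clamp extrapolated ends to the edge values
  y[grid < tt[1]] <- x[1]
  y[grid > tt[length(tt)]] <- x[length(x)]
  signal_segment(y, fs, t0 = t_range[1], label = "rr_inst")
}
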