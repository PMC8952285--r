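## Uniformly sampled signal container, Welch spectral estimation, the
## respiration quality statistic, window arithmetic and denoising.

#' Uniformly sampled signal segment
#'
#' @param samples numeric vector of finite samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 start time in seconds.
#' @param label channel name.
#' @return object of class `signal_segment` with fields `samples`, `fs`,
#'   `t0`, `label`.
#' @export
signal_segment <- function(samples, fs, t0 = 0, label = "") {
  assert_that(is.numeric(samples) && length(samples) >= 1L,
              "samples must be a non-empty numeric vector")
  assert_that(all(is.finite(samples)), "samples must be finite")
  assert_that(is_scalar_number(fs) && fs > 0, "fs must be a positive number")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 label = as.character(label)),
            class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment '%s': %d samples @ %g Hz, t0 = %g s (%.1f s)>\n",
              x$label, length(x$samples), x$fs, x$t0, seg_duration(x)))
  invisible(x)
}

#' @rdname signal_segment
#' @param x a `signal_segment`.
#' @export
seg_duration <- function(x) length(x$samples) / x$fs

## Accept either a signal_segment or samples + fs.
as_segment <- function(x, fs = NULL, label = "") {
  if (inherits(x, "signal_segment")) return(x)
  assert_that(!is.null(fs), "fs must be supplied for a bare numeric signal")
  signal_segment(x, fs, label = label)
}

#' Slice a signal segment by absolute time
#' @param x a `signal_segment`.
#' @param t_lo,t_hi absolute time bounds in seconds; `[t_lo, t_hi)`.
#' @return a `signal_segment`.
#' @export
seg_slice <- function(x, t_lo, t_hi) {
  i0 <- max(1L, floor((t_lo - x$t0) * x$fs) + 1L)
  i1 <- min(length(x$samples), ceiling((t_hi - x$t0) * x$fs))
  assert_that(i1 >= i0, "empty slice")
  signal_segment(x$samples[i0:i1], x$fs, t0 = x$t0 + (i0 - 1L) / x$fs,
                 label = x$label)
}

#' Welch power spectral density estimate
#'
#' Hann-tapered averaged periodogram with 50% segment overlap. Scaled as a
#' one-sided density so that `sum(psd) * df` approximates the signal power.
#'
#' @param x numeric vector or `signal_segment`.
#' @param fs sampling rate (ignored when `x` is a segment).
#' @param seg_s segment length in seconds; defaults to `min(60, duration)`.
#' @param overlap fractional overlap between segments.
#' @param demean remove the segment mean before tapering.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs = NULL, seg_s = NULL, overlap = 0.5,
                      demean = FALSE) {
  seg <- as_segment(x, fs)
  x <- seg$samples; fs <- seg$fs
  n <- length(x)
  assert_that(n >= 2L, "need at least 2 samples")
  seg_s <- seg_s %||% min(60, n / fs)
  nseg <- max(2L, min(n, round(seg_s * fs)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    xi <- x[s:(s + nseg - 1L)]
    if (demean) xi <- xi - mean(xi)
    X <- fft(xi * w)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double interior bins
  if (nseg %% 2L == 0L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd)
}

#' Respiration quality statistic
#'
#' Fraction of power-spectral-density mass falling in the respiratory band
#' (0.03-0.5 Hz by default) over the total mass. A stable narrow-band
#' respiration signal scores close to 1; segments are conventionally kept
#' when Q exceeds 0.85. Q is invariant to amplitude scaling.
#'
#' @param x respiration signal (`signal_segment` or numeric).
#' @param fs sampling rate when `x` is numeric; must be at least 1 Hz so the
#'   band is resolvable.
#' @param band numeric length-2, band edges in Hz.
#' @return Q in `[0, 1]`.
#' @export
#' @examples
#' t <- seq(0, 120, by = 0.1)[-1]
#' respiration_quality(sin(2 * pi * 0.25 * t), fs = 10)
respiration_quality <- function(x, fs = NULL, band = c(0.03, 0.5)) {
  seg <- as_segment(x, fs)
  assert_that(length(seg$samples) >= 2L, "need at least 2 samples")
  assert_that(seg$fs >= 1, "sampling rate must be at least 1 Hz")
  p <- welch_psd(seg)
  tot <- sum(p$psd)
  if (tot <= 0) return(0)
  inb <- p$freq >= band[1] & p$freq <= band[2]
  q <- sum(p$psd[inb]) / tot
  min(max(q, 0), 1)
}

#' Sliding analysis windows
#'
#' Windows of length `window_s` starting every `step_s` seconds from `t0`;
#' only complete windows are returned, so the count is
#' `floor((duration - window_s)/step_s) + 1`.
#'
#' @param duration_s total duration in seconds.
#' @param window_s window length (default 120 s).
#' @param step_s step between window starts (default 10 s).
#' @param t0 start time of the series.
#' @return data.frame with columns `start`, `end` (absolute seconds); empty
#'   (with a warning) when the series is shorter than one window.
#' @export
sliding_windows <- function(duration_s, window_s = 120, step_s = 10, t0 = 0) {
  assert_that(window_s > 0 && step_s > 0, "window_s and step_s must be > 0")
  if (duration_s < window_s) {
    warning("series shorter than one window; returning no windows")
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  k <- 0:floor((duration_s - window_s) / step_s)
  data.frame(start = t0 + k * step_s, end = t0 + k * step_s + window_s)
}

## ---- Daubechies-4 discrete wavelet transform (periodic) -----------------
## Only what baseline removal needs: analysis to level J, and synthesis of
## the approximation branch. Filters are the standard 8-tap db4 pair.

db4_h <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
           -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
           0.0328830116668852, -0.0105974017850690)

dwt_step <- function(x, h) {
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror
  L <- length(h)
  # periodic extension, convolve, downsample by 2
  idx <- outer(seq(1L, n, by = 2L) - 1L, seq_len(L) - 1L, "+") %% n + 1L
  xs <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.vector(xs %*% h), d = as.vector(xs %*% g))
}

idwt_step <- function(a, d, h) {
  n <- 2L * length(a)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  L <- length(h)
  up_a <- numeric(n); up_a[seq(1L, n, by = 2L)] <- a
  up_d <- numeric(n); up_d[seq(1L, n, by = 2L)] <- d
  out <- numeric(n)
  for (k in seq_len(L)) {
    sh <- (seq_len(n) - k) %% n + 1L
    out <- out + h[k] * up_a[sh] + g[k] * up_d[sh]
  }
  out
}

dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, db4_h)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details)
}

idwt_db4 <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]], db4_h)
  }
  a
}

#' Wavelet baseline estimate
#'
#' Reconstructs the level-`J` approximation of a db4 decomposition, with `J`
#' chosen so the approximation band `[0, fs/2^(J+1)]` lies at or below
#' `f_lo`. Subtracting it removes baseline drift without touching in-band
#' oscillations.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param f_lo low band edge in Hz.
#' @return baseline vector, same length as `x`.
#' @export
wavelet_baseline <- function(x, fs, f_lo) {
  n <- length(x)
  levels <- max(1L, ceiling(log2(fs / f_lo)) - 1L)
  levels <- min(levels, floor(log2(n)) - 2L)
  if (levels < 1L) return(rep(mean(x), n))
  # pad (symmetric reflection) to a multiple of 2^levels
  m <- 2L^levels
  pad <- (m - n %% m) %% m
  xp <- if (pad > 0L) c(x, rev(x)[seq_len(pad)]) else x
  dec <- dwt_db4(xp, levels)
  for (j in seq_along(dec$details)) dec$details[[j]][] <- 0
  idwt_db4(dec)[seq_len(n)]
}

#' Denoise a signal segment to a frequency band
#'
#' Removes baseline drift with a db4 wavelet approximation (content below
#' `band[1]`) and attenuates out-of-band noise with zero-phase Butterworth
#' filters (order-2 high-pass at the low edge, order-4 low-pass at the high
#' edge, applied forwards and backwards so phase is preserved).
#'
#' @param sig a `signal_segment`.
#' @param band numeric length-2 `(lo, hi)` in Hz with `lo < hi < fs/2`.
#' @return filtered `signal_segment` of the same length and rate.
#' @export
denoise <- function(sig, band) {
  sig <- as_segment(sig)
  lo <- band[1]; hi <- band[2]
  assert_that(lo > 0 && lo < hi && hi < sig$fs / 2,
              "band must satisfy 0 < lo < hi < fs/2")
  x <- sig$samples
  if (all(x == 0)) return(sig)
  x <- x - wavelet_baseline(x, sig$fs, lo)
  bl <- signal::butter(4, hi / (sig$fs / 2), type = "low")
  x <- signal::filtfilt(bl, x)
  bh <- signal::butter(2, lo / (sig$fs / 2), type = "high")
  x <- signal::filtfilt(bh, x)
  signal_segment(x, sig$fs, t0 = sig$t0, label = sig$label)
}

#' Resample a signal segment to a new rate
#'
#' Low-pass filters below the output Nyquist frequency when downsampling,
#' then interpolates onto the new uniform grid.
#'
#' @param sig a `signal_segment`.
#' @param fs_out output sampling rate in Hz.
#' @return resampled `signal_segment`.
#' @export
resample_signal <- function(sig, fs_out) {
  sig <- as_segment(sig)
  if (abs(sig$fs - fs_out) < 1e-12) return(sig)
  x <- sig$samples
  if (fs_out < sig$fs) {
    bl <- signal::butter(4, 0.9 * (fs_out / 2) / (sig$fs / 2), type = "low")
    x <- signal::filtfilt(bl, x)
  }
  t_in <- sig$t0 + (seq_along(x) - 1L) / sig$fs
  t_out <- seq(sig$t0, t_in[length(t_in)], by = 1 / fs_out)
  y <- approx(t_in, x, xout = t_out, rule = 2)$y
  signal_segment(y, fs_out, t0 = sig$t0, label = sig$label)
}
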