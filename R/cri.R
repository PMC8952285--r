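## Cardiopulmonary resonance indices: peak statistics of the spectral
## causality curve, and the sliding-window CRI track.

#' Extract cardiopulmonary resonance indices from a causality spectrum
#'
#' Within the respiratory band, the resonance frequency `FA` is the argmax
#' of `g(f)`, `CRA` its height, and `CRB` the full width at half maximum
#' (linear interpolation between grid points). The derived indices follow
#' the series-resonance convention with unit capacitance:
#' `CRQ = FA / CRB` (quality factor) and `CRR = CRB / (2 pi FA^2)`
#' (resonance resistance, the damping analogue), so that
#' `CRQ * CRR * 2 pi * FA = 1` identically.
#'
#' @param spec a `gc_spectrum`.
#' @param band respiratory band in Hz (default `c(0.03, 0.5)`).
#' @return one-row data.frame with columns `FA`, `CRA`, `CRB`, `CRQ`, `CRR`
#'   and `flag` ("ok", "truncated" when the curve does not fall to half
#'   maximum inside the band, or "degenerate" when there is no positive
#'   peak, in which case the indices are NA).
#' @export
extract_cri <- function(spec, band = c(0.03, 0.5)) {
  stopifnot(inherits(spec, "gc_spectrum"))
  v <- cri_from_curve(spec$freqs, spec$g, band)
  data.frame(FA = v[1], CRA = v[2], CRB = v[3], CRQ = v[4], CRR = v[5],
             flag = c("ok", "truncated", "degenerate")[v[6]],
             stringsAsFactors = FALSE)
}

## numeric core: c(FA, CRA, CRB, CRQ, CRR, flag_code) with flag_code
## 1 = ok, 2 = truncated, 3 = degenerate
cri_from_curve <- function(f, g, band) {
  degenerate <- c(rep(NA_real_, 5L), 3)
  inb <- which(f >= band[1] & f <= band[2])
  if (length(inb) < 3L) return(degenerate)
  i_pk <- inb[which.max(g[inb])]
  cra <- g[i_pk]
  if (!is.finite(cra) || cra <= 0) return(degenerate)
  fa <- f[i_pk]
  half <- cra / 2
  flag <- 1
  cross_down <- function(idx_seq) {
    # walk from the peak outward until g drops below half; interpolate
    for (k in seq_along(idx_seq)[-1]) {
      i0 <- idx_seq[k - 1]; i1 <- idx_seq[k]
      if (g[i1] < half) {
        w <- (g[i0] - half) / (g[i0] - g[i1])
        return(f[i0] + w * (f[i1] - f[i0]))
      }
    }
    NA_real_
  }
  f_left <- cross_down(rev(inb[inb <= i_pk]))
  f_right <- cross_down(inb[inb >= i_pk])
  if (is.na(f_left)) { f_left <- f[inb[1]]; flag <- 2 }
  if (is.na(f_right)) { f_right <- f[inb[length(inb)]]; flag <- 2 }
  crb <- max(f_right - f_left, f[2] - f[1])  # at least one grid step
  c(fa, cra, crb, fa / crb, crb / (2 * pi * fa^2), flag)
}

#' Sliding-window cardiopulmonary resonance track
#'
#' Cuts the recording into 120-s windows every 10 s, gates each window on
#' respiration quality, fits the bivariate AR model of instantaneous RR and
#' respiration at `fs_ar` Hz, computes the Geweke causality spectrum and
#' extracts the resonance indices. Windows failing the quality gate or
#' producing a degenerate spectrum are kept in place (all-NA row with a
#' flag) so the time grid stays regular.
#'
#' @param rri an `rri_series` (ideally cleaned with [clean_rr()]).
#' @param rsp respiration `signal_segment`.
#' @param window_s,step_s window length and step in seconds.
#' @param fs_ar modelling rate in Hz (default 4).
#' @param order AR order or "auto" (BIC).
#' @param order_max maximal order under "auto".
#' @param band respiratory band in Hz.
#' @param q_threshold respiration quality gate (keep when Q > threshold).
#' @param nfreq causality grid size.
#' @param denoise_resp band-pass the respiration channel to `band` before
#'   modelling (default TRUE; the quality gate always sees the raw signal).
#' @return data.frame of class `cri_track` with columns `t0`, `t1`, `FA`,
#'   `CRA`, `CRB`, `CRQ`, `CRR`, `quality` (the window Q) and `flag`
#'   ("ok", "truncated", "low_quality", "degenerate", "unstable").
#' @export
cri_track <- function(rri, rsp, window_s = 120, step_s = 10, fs_ar = 4,
                      order = "auto", order_max = 12L, band = c(0.03, 0.5),
                      q_threshold = 0.85, nfreq = 512L, denoise_resp = TRUE) {
  assert_that(inherits(rri, "rri_series"), "rri must be an rri_series")
  rsp <- as_segment(rsp)
  # the window grid is anchored to the respiration span; the tachogram is
  # clamped at its edges, so a whole-second recording keeps a whole grid
  t_lo <- rsp$t0
  t_hi <- rsp$t0 + seg_duration(rsp)
  overlap <- min(t_hi, rri$beat_times[length(rri$beat_times)]) -
    max(t_lo, rri$beat_times[1])
  if (overlap < window_s)
    stop("no valid windows: overlapping coverage shorter than one window")

  rr4 <- resample_tachogram(rri, fs = fs_ar, t_range = c(t_lo, t_hi))
  rsp4 <- resample_signal(rsp, fs_ar)
  n <- min(length(rr4$samples), length(rsp4$samples))
  y_raw <- rsp4$samples[1:n]
  y_all <- if (denoise_resp)
    denoise(signal_segment(y_raw, fs_ar), band)$samples else y_raw
  x_all <- rr4$samples[1:n]

  win <- sliding_windows(n / fs_ar, window_s, step_s, t0 = t_lo)
  if (nrow(win) == 0L) stop("no valid windows")
  nw <- round(window_s * fs_ar)

  # precompute the complex exponent grids for every candidate order
  p_cand <- if (identical(order, "auto")) seq_len(order_max) else as.integer(order)
  freqs <- (fs_ar / 2) * seq_len(nfreq) / nfreq
  Zfull <- exp(-2i * pi * outer(freqs / fs_ar, seq_len(max(p_cand))))

  vals <- matrix(NA_real_, nrow(win), 6L)
  flags <- character(nrow(win))
  qs <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    i0 <- round((win$start[i] - t_lo) * fs_ar) + 1L
    idx <- i0:min(i0 + nw - 1L, n)
    yv <- y_all[idx]; xv <- x_all[idx]
    q <- respiration_quality(y_raw[idx], fs = fs_ar, band = band)
    qs[i] <- q
    if (!(q > q_threshold)) { flags[i] <- "low_quality"; next }
    res <- tryCatch({
      m <- fit_bivar_ar(xv, yv, order = order, order_max = order_max,
                        fs = fs_ar)
      if (!ar_stable(m)) stop("unstable")
      g <- gc_curve(m, Zfull[, seq_len(m$order), drop = FALSE])
      cri_from_curve(freqs, g, band)
    }, error = function(e) {
      flags[i] <<- if (grepl("unstable", conditionMessage(e))) "unstable"
                   else "degenerate"
      NULL
    })
    if (!is.null(res)) {
      vals[i, ] <- res
      flags[i] <- c("ok", "truncated", "degenerate")[res[6]]
      if (flags[i] == "degenerate") vals[i, 1:5] <- NA_real_
    }
  }
  out <- data.frame(t0 = win$start, t1 = win$end,
                    FA = vals[, 1], CRA = vals[, 2], CRB = vals[, 3],
                    CRQ = vals[, 4], CRR = vals[, 5],
                    quality = qs, flag = flags, stringsAsFactors = FALSE)
  class(out) <- c("cri_track", "data.frame")
  out
}
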