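## Per-epoch feature extraction: 3 body-movement + 12 HRV + 6 resonance
## features per 30-s epoch (the 21-element base vector). Frequency-domain
## HRV and the resonance features are supported by a 120-s context centred
## on the epoch, since neither is reliable on 30 s of data; values are
## stamped to the 30-s epoch grid.

#' Heart-rate-variability features of an RR window
#'
#' Twelve standard descriptors. Time domain: SDNN (population SD of the
#' intervals, ms), RMSSD (ms), pNN50 (% of successive differences > 50 ms).
#' Frequency domain (power of the 4 Hz-resampled, demeaned tachogram, ms^2,
#' Welch estimate): VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz and
#' the LF/HF ratio. Nonlinear: Poincare SD1 = RMSSD/sqrt(2),
#' SD2 = sqrt(2 SDNN^2 - SD1^2), SD1/SD2, sample entropy and approximate
#' entropy (m = 2, r = 0.2 SD, on the interval sequence).
#'
#' @param rri an `rri_series` (the analysis window) or numeric intervals in
#'   ms.
#' @param min_beats minimum interval count; below it an all-NA vector with
#'   attribute `flag = "too_few_beats"` is returned.
#' @param fs_ar resampling rate for the spectral features.
#' @param epoch_rri optional epoch-local `rri_series`: when supplied with at
#'   least `min_epoch_beats` intervals, the time-domain and nonlinear
#'   descriptors are computed on it (transient autonomic events live at the
#'   epoch scale) while the spectral features keep the longer window.
#' @param min_epoch_beats minimum epoch-local interval count (default 20).
#' @return named numeric vector of length 12.
#' @export
hrv_features <- function(rri, min_beats = 30L, fs_ar = 4, epoch_rri = NULL,
                         min_epoch_beats = 20L) {
  nm <- cap_feature_names("hrv")
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  if (length(x) < min_beats) {
    out <- setNames(rep(NA_real_, 12L), nm)
    attr(out, "flag") <- "too_few_beats"
    return(out)
  }
  if (!is.null(epoch_rri) && length(epoch_rri$intervals) >= min_epoch_beats)
    x <- epoch_rri$intervals
  d <- diff(x)
  sdnn <- sd_pop(x)
  rmssd <- sqrt(mean(d^2))
  pnn50 <- 100 * mean(abs(d) > 50)
  rr <- if (inherits(rri, "rri_series")) rri else rri_series(intervals_ms = x)
  inst <- resample_tachogram(rr, fs = fs_ar)
  p <- welch_psd(inst$samples - mean(inst$samples), fs = fs_ar,
                 seg_s = min(60, seg_duration(inst)))
  df <- p$freq[2] - p$freq[1]
  bandpow <- function(lo, hi) sum(p$psd[p$freq >= lo & p$freq < hi]) * df
  vlf <- bandpow(0.003, 0.04); lf <- bandpow(0.04, 0.15); hf <- bandpow(0.15, 0.4)
  lf_hf <- if (hf > 0) lf / hf else NA_real_
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(2 * sdnn^2 - sd1^2, 0))
  sd1_sd2 <- if (sd2 > 0) sd1 / sd2 else NA_real_
  ent <- entropy_pair(x)
  setNames(c(sdnn, rmssd, pnn50, vlf, lf, hf, lf_hf, sd1, sd2, sd1_sd2,
             if (is.finite(ent["sampen"])) ent[["sampen"]] else NA_real_,
             ent[["apen"]]), nm)
}

#' Body-movement features of a three-axis acceleration epoch
#'
#' Variance, approximate entropy and sample entropy of the vector-magnitude
#' signal `sqrt(ax^2 + ay^2 + az^2)` - rotation-invariant, so exactly three
#' numbers summarise the three axes. A flat magnitude yields `(0, 0, 0)`
#' with attribute `flag = "flat"`.
#'
#' @param ax,ay,az equally long numeric axis signals (one epoch).
#' @return named numeric vector of length 3.
#' @export
bm_features <- function(ax, ay, az) {
  assert_that(length(ax) == length(ay) && length(ay) == length(az),
              "axis signals must have equal length")
  mag <- sqrt(ax^2 + ay^2 + az^2)
  nm <- cap_feature_names("bm")
  if (sd_pop(mag) < 1e-12) {
    out <- setNames(c(0, 0, 0), nm)
    attr(out, "flag") <- "flat"
    return(out)
  }
  ent <- entropy_pair(mag)
  setNames(c(sd_pop(mag)^2, ent[["apen"]],
             if (is.finite(ent["sampen"])) ent[["sampen"]] else NA_real_), nm)
}

#' Resonance-index features of one epoch
#'
#' CRA, CRB, CRQ and CRR are the means over track windows whose centres
#' fall inside the 30-s epoch (nearest non-missing window when none does);
#' the variance and binned Shannon entropy of CRA are taken over the 5-min
#' context centred on the epoch.
#'
#' @param track a `cri_track`.
#' @param epoch_start epoch start time in seconds.
#' @param epoch_s epoch length (default 30).
#' @param context_s context for the CRA variance/entropy (default 300).
#' @param bins histogram bins for the entropy.
#' @param cra_lim fixed per-subject bin range for the CRA entropy (1st-99th
#'   percentile of the subject's CRA by default).
#' @return named numeric vector of length 6 (all NA when the context holds
#'   no valid windows).
#' @export
cri_features <- function(track, epoch_start, epoch_s = 30, context_s = 300,
                         bins = 10L, cra_lim = NULL) {
  nm <- cap_feature_names("cri")
  ok <- is.finite(track$CRA)
  if (!any(ok)) return(setNames(rep(NA_real_, 6L), nm))
  centre <- (track$t0 + track$t1) / 2
  mid <- epoch_start + epoch_s / 2
  cra_lim <- cra_lim %||% quantile(track$CRA[ok], c(0.01, 0.99), names = FALSE)
  ine <- ok & centre >= epoch_start & centre < epoch_start + epoch_s
  if (!any(ine)) {
    ine <- seq_along(centre) == which(ok)[which.min(abs(centre[ok] - mid))]
  }
  inc <- ok & abs(centre - mid) <= context_s / 2
  if (!any(inc)) inc <- ine
  cra_ctx <- track$CRA[inc]
  setNames(c(mean(track$CRA[ine]), mean(track$CRB[ine]),
             mean(track$CRQ[ine]), mean(track$CRR[ine]),
             if (sum(inc) > 1) var(cra_ctx) else 0,
             binned_entropy(cra_ctx, bins = bins, lim = cra_lim)),
           nm)
}

#' Assemble the per-epoch feature table for one recording
#'
#' Computes the resonance track once, then for every 30-s epoch the 3
#' body-movement features (on the epoch's own acceleration samples), the 12
#' HRV features (on the 120-s RR window centred on the epoch, clipped at
#' the recording edges) and the 6 resonance features. Labels are attached
#' when an annotation vector is supplied (one label per epoch, same grid).
#'
#' @param rri cleaned `rri_series`.
#' @param rsp respiration `signal_segment`.
#' @param accel list of three axis `signal_segment`s (x, y, z).
#' @param labels optional stage labels, one per epoch.
#' @param epoch_s epoch length (default 30 s).
#' @param hrv_window_s HRV/CRI context window (default 120 s).
#' @param track optional precomputed `cri_track` (computed if NULL).
#' @param ... passed to [cri_track()].
#' @return data.frame: `epoch` (0-based), `epoch_start_s`, the 21 named
#'   features, and `label` when annotations are given. The `cri_track` used
#'   is attached as attribute `"track"`.
#' @export
assemble_epoch_features <- function(rri, rsp, accel, labels = NULL,
                                    epoch_s = 30, hrv_window_s = 120,
                                    track = NULL, ...) {
  rsp <- as_segment(rsp)
  starts <- c(rri$beat_times[1], rsp$t0,
              vapply(accel, function(a) a$t0, numeric(1)))
  assert_that(max(starts) - min(starts) <= 1,
              "channel misalignment exceeds 1 s")
  t0 <- 0
  t_end <- rsp$t0 + seg_duration(rsp)
  n_ep <- floor((t_end - t0) / epoch_s)
  assert_that(n_ep >= 1L, "recording shorter than one epoch")
  if (!is.null(labels))
    assert_that(length(labels) >= n_ep, "fewer labels than epochs")
  track <- track %||% cri_track(rri, rsp, ...)
  ok <- is.finite(track$CRA)
  cra_lim <- if (any(ok)) quantile(track$CRA[ok], c(0.01, 0.99), names = FALSE)
             else c(0, 1)

  rows <- matrix(NA_real_, n_ep, 21L,
                 dimnames = list(NULL, cap_feature_names("base")))
  for (e in seq_len(n_ep)) {
    es <- t0 + (e - 1) * epoch_s
    # body movement on the epoch itself
    seg3 <- lapply(accel, function(a) seg_slice(a, es, es + epoch_s)$samples)
    len <- min(lengths(seg3))
    bm <- bm_features(seg3[[1]][1:len], seg3[[2]][1:len], seg3[[3]][1:len])
    # HRV on the centred context window
    mid <- es + epoch_s / 2
    w_lo <- max(t0, mid - hrv_window_s / 2)
    w_hi <- min(t_end, mid + hrv_window_s / 2)
    rw <- rri_slice(rri, w_lo, w_hi)
    re <- rri_slice(rri, es, es + epoch_s)
    hrv <- if (is.null(rw)) hrv_features(numeric(0))
           else hrv_features(rw, epoch_rri = re)
    cri <- cri_features(track, es, epoch_s = epoch_s, cra_lim = cra_lim)
    rows[e, ] <- c(bm, hrv, cri)
  }
  out <- data.frame(epoch = seq_len(n_ep) - 1L,
                    epoch_start_s = t0 + (seq_len(n_ep) - 1L) * epoch_s,
                    rows, check.names = FALSE)
  if (!is.null(labels)) out$label <- as.character(labels[seq_len(n_ep)])
  attr(out, "track") <- track
  out
}
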