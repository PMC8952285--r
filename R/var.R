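## Bivariate autoregressive modelling of RR and respiration, time-domain
## Granger causality (log variance ratio) and the Geweke spectral
## decomposition. Channel 1 is always the RR series, channel 2 respiration;
## the causal direction of interest is respiration -> RR.

#' Fit a bivariate autoregressive model
#'
#' Ordinary-least-squares fit of a two-channel VAR(p). Both series are
#' centred internally. When `order = "auto"` the order is selected by BIC
#' over `1..order_max`, with all candidate orders scored on the same
#' effective sample (rows lost to the maximal lag).
#'
#' @param x channel-1 series (instantaneous RR, evenly sampled).
#' @param y channel-2 series (respiration), same length.
#' @param order integer order, or "auto" for BIC selection.
#' @param order_max maximal order considered under "auto" (default 12).
#' @param fs sampling rate of both series in Hz (default 4).
#' @return object of class `bivar_ar`: coefficient array `A` (2 x 2 x p with
#'   `A[i, j, k]` the lag-k coefficient of channel j in the equation of
#'   channel i), residual covariance `Sigma` (maximum-likelihood scaling),
#'   `order`, `fs`, `T` (series length), `n_eff`, `bic` (per candidate
#'   order), and the restricted (own-lags-only) channel-1 residual variance
#'   `sigma1_restricted` used by the causality measure.
#' @export
fit_bivar_ar <- function(x, y, order = "auto", order_max = 12L, fs = 4) {
  assert_that(length(x) == length(y), "series must have equal length")
  T_len <- length(x)
  auto <- identical(order, "auto")
  p_max <- if (auto) as.integer(order_max) else as.integer(order)
  assert_that(p_max >= 1L, "order must be >= 1")
  assert_that(p_max < T_len, "model order must satisfy p < T")
  assert_that(T_len - p_max > 2L * p_max + 2L,
              "series too short for the requested order")
  if (sd_pop(x) < 1e-12 || sd_pop(y) < 1e-12)
    stop("singular regressor matrix: (near-)constant input series")
  x <- x - mean(x); y <- y - mean(y)

  E <- stats::embed(cbind(x, y), p_max + 1L)     # [x_t y_t x_{t-1} y_{t-1} ...]
  Yc <- E[, 1:2, drop = FALSE]
  X <- E[, -(1:2), drop = FALSE]                 # 2*p_max lag columns
  n_eff <- nrow(Yc)
  XtX <- crossprod(X); XtY <- crossprod(X, Yc); YtY <- crossprod(Yc)

  fit_p <- function(p, cols) {
    idx <- cols[cols <= 2L * p]
    G <- XtX[idx, idx, drop = FALSE]
    # tiny ridge keeps band-limited (near-collinear) regressors solvable
    lam <- 1e-10 * mean(diag(G))
    B <- tryCatch(solve(G + lam * diag(length(idx)), XtY[idx, , drop = FALSE]),
                  error = function(e) stop("singular regressor matrix", call. = FALSE))
    S <- (YtY - crossprod(XtY[idx, , drop = FALSE], B)) / n_eff
    list(B = B, Sigma = S, idx = idx)
  }
  cols_all <- seq_len(2L * p_max)
  bic <- rep(NA_real_, p_max)
  orders <- if (auto) seq_len(p_max) else p_max
  best <- NULL; best_p <- p_max
  for (p in orders) {
    f <- fit_p(p, cols_all)
    detS <- det(f$Sigma)
    bic[p] <- log(max(detS, 1e-300)) + (4 * p) * log(n_eff) / n_eff
    if (is.null(best) || bic[p] < bic[best_p] - 1e-12) { best <- f; best_p <- p }
    if (!auto) { best <- f; best_p <- p }
  }
  p <- best_p
  A <- array(0, dim = c(2, 2, p))
  for (k in seq_len(p)) {
    # row order of B: x_{t-k} then y_{t-k}; columns: equations (x, y)
    A[1, 1, k] <- best$B[2 * k - 1, 1]; A[1, 2, k] <- best$B[2 * k, 1]
    A[2, 1, k] <- best$B[2 * k - 1, 2]; A[2, 2, k] <- best$B[2 * k, 2]
  }
  # restricted channel-1 model: x on its own p lags, same sample
  own <- seq(1L, 2L * p, by = 2L)
  Gr <- XtX[own, own, drop = FALSE]
  Br <- solve(Gr + 1e-10 * mean(diag(Gr)) * diag(length(own)),
              XtY[own, 1, drop = FALSE])
  s1r <- as.numeric((YtY[1, 1] - crossprod(XtY[own, 1, drop = FALSE], Br)) / n_eff)

  structure(list(A = A, Sigma = best$Sigma, order = p, fs = fs, T = T_len,
                 n_eff = n_eff, bic = bic, sigma1_restricted = s1r),
            class = "bivar_ar")
}

#' @export
print.bivar_ar <- function(x, ...) {
  cat(sprintf("<bivar_ar: order %d, T = %d, fs = %g Hz, stable = %s>\n",
              x$order, x$T, x$fs, ar_stable(x)))
  invisible(x)
}

#' Stability of a fitted bivariate AR model
#'
#' Checks that all eigenvalues of the companion matrix lie inside the unit
#' circle (equivalently, AR polynomial roots outside it).
#' @param model a `bivar_ar`.
#' @return logical.
#' @export
ar_stable <- function(model) {
  p <- model$order
  C <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) C[1:2, (2 * k - 1):(2 * k)] <- model$A[, , k]
  if (p > 1L) C[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values)) < 1
}

#' Time-domain Granger causality (respiration to RR)
#'
#' The log ratio of the channel-1 prediction-error variances of the
#' restricted model (respiration lags omitted) and the full bivariate
#' model. Non-negative by construction: the restricted least-squares fit is
#' nested in the full one over the same sample.
#'
#' @inheritParams fit_bivar_ar
#' @return list with `g` (the causality value), `model` (the full
#'   `bivar_ar` fit) and the two residual variances.
#' @export
gc_time <- function(x, y, order = "auto", order_max = 12L, fs = 4) {
  m <- fit_bivar_ar(x, y, order = order, order_max = order_max, fs = fs)
  vu <- m$Sigma[1, 1]
  if (vu <= 1e-300) stop("zero unrestricted residual variance")
  g <- log(m$sigma1_restricted / vu)
  list(g = max(g, 0), model = m, var_restricted = m$sigma1_restricted,
       var_unrestricted = vu)
}

#' Geweke spectral Granger causality (respiration to RR)
#'
#' Decomposes the causality of `gc_time` across frequency using the fitted
#' transfer function and residual covariance. Residual correlation is
#' removed by the standard rotation, so the channel-1 spectrum splits into
#' an intrinsic and a respiration-driven part:
#' `g(f) = ln( S11(f) / |H11~(f)|^2 Sigma11 )`, which is zero at every
#' frequency when the cross-coefficients vanish, and whose average over the
#' full Nyquist band recovers the time-domain measure.
#'
#' @param model a fitted `bivar_ar` (must be stable).
#' @param freqs frequency grid in Hz; defaults to `nfreq` points over
#'   `(0, fs/2]`.
#' @param nfreq grid size for the default grid (default 512).
#' @return object of class `gc_spectrum` with `freqs` and non-negative `g`.
#' @export
gc_spectrum <- function(model, freqs = NULL, nfreq = 512L) {
  assert_that(inherits(model, "bivar_ar"), "model must be a bivar_ar fit")
  if (!ar_stable(model)) stop("unstable AR model: spectral causality undefined")
  fs <- model$fs
  freqs <- freqs %||% (fs / 2) * seq_len(nfreq) / nfreq
  assert_that(all(diff(freqs) > 0), "freqs must be strictly increasing")
  Z <- exp(-2i * pi * outer(freqs / fs, seq_len(model$order)))   # nf x p
  structure(list(freqs = freqs, g = gc_curve(model, Z), fs = fs),
            class = "gc_spectrum")
}

## numeric core: causality curve from the coefficient array, residual
## covariance and a precomputed nf x p complex exponent matrix
gc_curve <- function(model, Z) {
  A11 <- 1 - as.vector(Z %*% model$A[1, 1, ])
  A12 <-   - as.vector(Z %*% model$A[1, 2, ])
  A21 <-   - as.vector(Z %*% model$A[2, 1, ])
  A22 <- 1 - as.vector(Z %*% model$A[2, 2, ])
  detA <- A11 * A22 - A12 * A21
  H11 <- A22 / detA; H12 <- -A12 / detA
  S <- model$Sigma
  Ht11 <- H11 + (S[1, 2] / S[1, 1]) * H12
  s22_t <- S[2, 2] - S[1, 2]^2 / S[1, 1]
  S11 <- Mod(Ht11)^2 * S[1, 1] + Mod(H12)^2 * s22_t
  pmax(log(S11 / (Mod(Ht11)^2 * S[1, 1])), 0)
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("<gc_spectrum: %d frequencies in (%.3g, %.3g] Hz, max g = %.3g>\n",
              length(x$freqs), min(x$freqs), max(x$freqs), max(x$g)))
  invisible(x)
}

#' Band-averaged spectral causality
#'
#' Mean of `g(f)` over a frequency band; over the full `(0, fs/2]` band this
#' approximates the Geweke integral and hence the time-domain causality.
#' @param spec a `gc_spectrum`.
#' @param band optional `c(lo, hi)` in Hz (default: the full grid).
#' @return scalar.
#' @export
gc_band_mean <- function(spec, band = NULL) {
  keep <- if (is.null(band)) rep(TRUE, length(spec$freqs))
          else spec$freqs >= band[1] & spec$freqs <= band[2]
  mean(spec$g[keep])
}

#' Simulate a bivariate VAR process
#'
#' Utility for tests and power analyses: draws from a VAR(p) with
#' coefficient array `A` (as in [fit_bivar_ar()]) and residual covariance
#' `Sigma`, after a burn-in.
#' @param n output length.
#' @param A 2 x 2 x p coefficient array.
#' @param Sigma 2 x 2 residual covariance.
#' @param burn burn-in samples.
#' @return matrix with columns x (channel 1) and y (channel 2).
#' @export
simulate_var <- function(n, A, Sigma, burn = 200L) {
  p <- dim(A)[3]
  L <- chol(Sigma)
  ntot <- n + burn + p
  e <- matrix(rnorm(2 * ntot), ncol = 2) %*% L
  out <- matrix(0, ntot, 2)
  for (t in (p + 1):ntot) {
    v <- e[t, ]
    for (k in seq_len(p)) v <- v + A[, , k] %*% out[t - k, ]
    out[t, ] <- v
  }
  out <- out[(burn + p + 1):ntot, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
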