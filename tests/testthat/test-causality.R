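# Bivariate AR fitting, time-domain causality and the Geweke spectral
# decomposition. stats::ar.ols is the independent oracle for the VAR fit.

test_that("VAR coefficients are recovered and match the ar.ols oracle", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.7, 0.5, 0, 0.8), 2, 2, byrow = TRUE)
  A[, , 2] <- matrix(c(-0.65, 0.1, 0, -0.6), 2, 2, byrow = TRUE)
  # element-wise mean across independent T = 480 realisations (estimator
  # consistency at the study window length)
  set.seed(42)
  est <- array(0, dim(A))
  reps <- 12
  for (r in seq_len(reps)) {
    sim <- simulate_var(480, A, diag(c(0.5, 0.5)))
    est <- est + fit_bivar_ar(sim[, 1], sim[, 2], order = 2)$A / reps
  }
  expect_lt(max(abs(est - A)), 0.05)

  # single fit agrees with stats::ar.ols on identical data
  set.seed(7)
  sim <- simulate_var(600, A, diag(2))
  m <- fit_bivar_ar(sim[, 1], sim[, 2], order = 2)
  o <- stats::ar.ols(sim, aic = FALSE, order.max = 2, demean = TRUE,
                     intercept = FALSE)
  for (k in 1:2) expect_equal(m$A[, , k], unname(o$ar[k, , ]),
                              tolerance = 0.02)
})

test_that("cross-coefficients of independent series are near zero", {
  set.seed(3)
  m <- fit_bivar_ar(rnorm(2000), rnorm(2000), order = 2)
  # |A12|, |A21| < 3 standard errors (~ 3/sqrt(T))
  expect_lt(max(abs(m$A[1, 2, ]), abs(m$A[2, 1, ])), 3 / sqrt(2000))
})

test_that("order preconditions and degenerate inputs error", {
  expect_error(fit_bivar_ar(rnorm(10), rnorm(10), order = 10), "p < T")
  expect_error(fit_bivar_ar(rep(1, 100), rnorm(100), order = 2), "singular")
  expect_error(fit_bivar_ar(rnorm(50), rnorm(49), order = 2), "equal length")
})

test_that("gc_time reaches the analytic ln(1.81) limit and is non-negative", {
  # x_t = 0.9 y_{t-1} + e: restricted variance 0.81 + 1, unrestricted 1
  set.seed(1)
  T_ <- 1e5
  y <- rnorm(T_); e <- rnorm(T_)
  x <- c(0, 0.9 * y[-T_]) + e
  g <- gc_time(x, y, order = 1)
  expect_equal(g$g, log(1.81), tolerance = 0.02 * log(1.81))
  # independent series: g ~ 0 (small-sample bias ~ p/T)
  set.seed(2)
  g0 <- gc_time(rnorm(5000), rnorm(5000), order = 4)
  expect_gte(g0$g, 0)
  expect_lt(g0$g, 3 * 4 / 5000 + 0.01)
})

test_that("gc_time is consistent with the full fit and always >= 0", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(400); y <- rnorm(400)
    g <- gc_time(x, y, order = 3)
    expect_gte(g$g, 0)
    expect_equal(g$var_unrestricted, g$model$Sigma[1, 1])
  }
})

test_that("spectral causality vanishes without cross-terms and is >= 0", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.6
  m <- structure(list(A = A, Sigma = diag(2), order = 1L, fs = 4,
                      T = 100L, n_eff = 99L), class = "bivar_ar")
  sp <- gc_spectrum(m)
  expect_true(all(sp$g == 0))
  expect_true(all(diff(sp$freqs) > 0))
})

test_that("band-integrated Geweke causality matches the time domain", {
  # unidirectional stable VARs: the spectral integral identity holds;
  # oracle is plain numerical quadrature (grid mean) of the curve
  shapes <- list(
    list(a11 = c(0.5, -0.2), a12 = c(0.4, 0), a22 = c(0.6, -0.3)),
    list(a11 = c(0.3, 0), a12 = c(0.8, -0.3), a22 = c(0.9, -0.4)))
  set.seed(13)
  for (s in shapes) {
    A <- array(0, c(2, 2, 2))
    A[1, 1, ] <- s$a11; A[1, 2, ] <- s$a12; A[2, 2, ] <- s$a22
    sim <- simulate_var(4000, A, diag(2))
    gt <- gc_time(sim[, 1], sim[, 2], order = 2)
    sp <- gc_spectrum(gt$model, nfreq = 2048L)
    expect_equal(gc_band_mean(sp), gt$g, tolerance = 0.05 * gt$g)
  }
})

test_that("unstable models are rejected by gc_spectrum", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 1.05; A[2, 2, 1] <- 0.5
  m <- structure(list(A = A, Sigma = diag(2), order = 1L, fs = 4,
                      T = 100L, n_eff = 99L), class = "bivar_ar")
  expect_false(ar_stable(m))
  expect_error(gc_spectrum(m), "unstable")
})

test_that("BIC order selection finds the true order of a strong VAR(2)", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.7, 0.5, 0, 0.8), 2, 2, byrow = TRUE)
  A[, , 2] <- matrix(c(-0.65, 0.1, 0, -0.6), 2, 2, byrow = TRUE)
  set.seed(21)
  sim <- simulate_var(2000, A, diag(2))
  m <- fit_bivar_ar(sim[, 1], sim[, 2], order = "auto", order_max = 8)
  expect_equal(m$order, 2L)
})
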