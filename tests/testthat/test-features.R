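# Epoch feature extraction: HRV closed forms, entropies against the
# pracma oracle, body-movement rotation invariance, CRI epoch features
# and the 21-feature assembly contract.

test_that("HRV features match closed forms on simple series", {
  # zero-variability series
  h0 <- hrv_features(rep(800, 60))
  expect_equal(unname(h0[c("sdnn", "rmssd", "pnn50", "sd1")]), c(0, 0, 0, 0))
  # alternating 800/850: RMSSD 50, SDNN 25, differences not > 50 -> pNN50 0
  h1 <- hrv_features(rep(c(800, 850), 40))
  expect_equal(unname(h1["rmssd"]), 50)
  expect_equal(unname(h1["sdnn"]), 25)
  expect_equal(unname(h1["pnn50"]), 0)
  # strictly greater than 50 ms counts
  h2 <- hrv_features(rep(c(800, 860), 40))
  expect_equal(unname(h2["pnn50"]), 100)
})

test_that("Poincare identities hold on arbitrary series", {
  set.seed(3)
  for (i in 1:5) {
    x <- 900 + cumsum(rnorm(100, 0, 10))
    h <- hrv_features(x)
    expect_equal(unname(h["sd1"]), unname(h["rmssd"]) / sqrt(2),
                 tolerance = 1e-9)
    expect_equal(unname(h["sd1"]^2 + h["sd2"]^2), 2 * unname(h["sdnn"])^2,
                 tolerance = 1e-6)
    expect_true(h["sd1"] >= 0 && h["sd2"] >= 0)
    expect_true(h["pnn50"] >= 0 && h["pnn50"] <= 100)
  }
})

test_that("hrv_features is invariant to a constant time shift", {
  set.seed(8)
  iv <- 800 + 60 * sin(2 * pi * 0.25 * (1:120) * 0.8) + rnorm(120, 0, 5)
  a <- hrv_features(rri_series(intervals_ms = iv, t0 = 0))
  b <- hrv_features(rri_series(intervals_ms = iv, t0 = 1234.5))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("too few beats yield an explicit missing vector", {
  h <- hrv_features(rep(800, 10))
  expect_true(all(is.na(h)))
  expect_identical(attr(h, "flag"), "too_few_beats")
})

test_that("frequency-domain power lands in the right band", {
  # 0.25 Hz modulation -> HF band dominates
  iv <- 1000 + 40 * sin(2 * pi * 0.25 * cumsum(rep(1, 240)))
  h <- hrv_features(rri_series(intervals_ms = iv))
  expect_gt(h[["hf"]], h[["lf"]])
  expect_gt(h[["hf"]], h[["vlf"]])
  expect_lt(h[["lf_hf"]], 1)
})

test_that("entropies agree with the pracma oracle", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (x in list(rnorm(120), sin(1:150 / 3) + rnorm(150, 0, 0.1))) {
    r <- 0.2 * sd_pop(x)
    expect_equal(approx_entropy(x, 2, r),
                 pracma::approx_entropy(x, edim = 2, r = r), tolerance = 1e-9)
    expect_equal(sample_entropy(x, 2, r),
                 pracma::sample_entropy(x, edim = 2, r = r, tau = 1),
                 tolerance = 1e-9)
    ep <- entropy_pair(x, 2, r)
    expect_equal(ep[["apen"]], approx_entropy(x, 2, r), tolerance = 1e-12)
    expect_equal(ep[["sampen"]], sample_entropy(x, 2, r), tolerance = 1e-12)
  }
})

test_that("periodic signals have lower sample entropy than noise", {
  set.seed(6)
  per <- sin(2 * pi * (1:300) / 25)
  noi <- rnorm(300, 0, sd_pop(per))
  expect_lt(sample_entropy(per), sample_entropy(noi))
})

test_that("body-movement features are rotation invariant", {
  set.seed(7)
  a <- matrix(rnorm(450), ncol = 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% R
  f1 <- bm_features(a[, 1], a[, 2], a[, 3])
  f2 <- bm_features(b[, 1], b[, 2], b[, 3])
  expect_equal(f1, f2, tolerance = 1e-9)
  # zero acceleration
  z <- bm_features(rep(0, 100), rep(0, 100), rep(0, 100))
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_identical(attr(z, "flag"), "flat")
})

test_that("CRI epoch features summarise the track correctly", {
  tr <- data.frame(t0 = seq(0, 480, by = 10), t1 = seq(120, 600, by = 10))
  tr$FA <- 0.25; tr$CRA <- 2; tr$CRB <- 0.05; tr$CRQ <- 5; tr$CRR <- 0.127
  tr$quality <- 0.95; tr$flag <- "ok"
  class(tr) <- c("cri_track", "data.frame")
  # constant context: var 0, entropy 0
  f <- cri_features(tr, 240)
  expect_equal(unname(f[c("cra", "crb", "crq", "crr")]),
               c(2, 0.05, 5, 0.127))
  expect_equal(unname(f["cra_var"]), 0)
  expect_equal(unname(f["cra_ent"]), 0)
  # single overlapping window: features equal that record
  tr1 <- tr[1, ]
  class(tr1) <- c("cri_track", "data.frame")
  f1 <- cri_features(tr1, 60)
  expect_equal(unname(f1["cra"]), 2)
  # all-missing context
  trna <- tr; trna$CRA <- NA_real_
  expect_true(all(is.na(cri_features(trna, 240))))
})

test_that("binned CRA entropy approaches log(bins) for uniform draws", {
  set.seed(9)
  x <- runif(5000)
  expect_equal(binned_entropy(x, bins = 10, lim = c(0, 1)), log(10),
               tolerance = 0.01)
  expect_equal(binned_entropy(rep(0.5, 100), bins = 10, lim = c(0, 1)), 0)
})

test_that("assembled epoch features have the full 21-feature contract", {
  rec <- fixture_recording("S2_NA", minutes = 10, seed = 14)
  sf <- process_subject(rec)
  f <- sf$features
  expect_equal(nrow(f), 20L)          # 600 s / 30 s
  nm <- cap_feature_names("base")
  expect_length(nm, 21L)
  expect_true(all(nm %in% colnames(f)))
  # finite or explicitly missing, never NaN
  expect_no_nan(f[nm])
  expect_identical(f$label, as.character(rec$labels))
  expect_equal(f$epoch_start_s, seq(0, by = 30, length.out = 20))
})

test_that("misaligned channels are rejected", {
  rec <- fixture_recording("S2_NA", minutes = 6, seed = 15)
  late <- rec$rsp; late$t0 <- 5
  expect_error(
    assemble_epoch_features(rec$rri, late, rec$accel, labels = rec$labels),
    "misalignment")
})
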