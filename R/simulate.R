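## Synthetic polysomnography: an 18-state Markov hypnogram, respiration with
## slowly wandering frequency, RR intervals modulated by respiration with a
## state-dependent gain (the respiratory-sinus-arrhythmia mechanism the
## resonance indices quantify), integrate-and-fire beat placement, chest
## acceleration with state-dependent movement bursts, and an optional
## template ECG. Everything is seeded and reproducible.

state_grid <- function() {
  lv <- cap_stage_levels()
  data.frame(state = lv, stage = stage_of(lv), phase = phase_of(lv),
             stringsAsFactors = FALSE)
}

## A-phase transient tachycardia: ~5-15% heart-rate acceleration with
## graded autonomic impact across the subtypes.
profile_table <- function(gain_na, gain_a_frac, rr0_stage, noise_stage,
                          a_noise_mult = 1.5,
                          a_rr_drop = c(A1 = 45, A2 = 75, A3 = 110)) {
  g <- state_grid()
  n <- nrow(g)
  gain <- noise <- rr0 <- numeric(n)
  for (i in seq_len(n)) {
    st <- g$stage[i]; ph <- g$phase[i]
    base <- gain_na[[st]]
    gain[i] <- if (ph %in% names(gain_a_frac)) base * gain_a_frac[[ph]] else base
    rr0[i] <- rr0_stage[[st]] - if (ph %in% names(a_rr_drop)) a_rr_drop[[ph]] else 0
    noise[i] <- noise_stage[[st]] *
      if (ph %in% c("A1", "A2", "A3")) a_noise_mult else 1
  }
  burst_prob <- burst_amp <- numeric(n)
  for (i in seq_len(n)) {
    burst_prob[i] <- switch(g$phase[i],
                            "A1" = 0.30, "A2" = 0.55, "A3" = 0.85,
                            "NA" = 0.04,
                            switch(g$stage[i], W = 0.90, R = 0.15, 0.04))
    burst_amp[i] <- switch(g$phase[i],
                           "A1" = 0.15, "A2" = 0.50, "A3" = 1.20,
                           "NA" = 0.15,
                           switch(g$stage[i], W = 1.00, R = 0.40, 0.15))
  }
  # Mayer-wave (low-frequency, ~0.1 Hz) RR oscillation amplitude: a
  # sympathetic marker, large in wake/REM and fading with sleep depth
  mayer <- c(W = 12, R = 12, S1 = 8, S2 = 6, S3 = 3.5, S4 = 1.5)[g$stage]
  data.frame(g, rr0 = rr0, gain = gain, noise_sd = noise,
             mayer_sd = as.numeric(mayer),
             burst_prob = burst_prob, burst_amp = burst_amp)
}

#' Built-in subject group profiles
#'
#' Per-state respiratory-coupling gains (ms of RR modulation per unit
#' respiration), baseline RR, non-respiratory HRV noise, movement-burst
#' rates, and respiration parameters for the three groups. The profiles
#' encode the qualitative group contrasts the method exploits: the healthy
#' group has graded coupling that deepens with NREM stage and drops during
#' A-phases; insomnia shows very high non-A coupling in deep sleep with a
#' strong A/NA swing and rigid (narrow-band) breathing; narcolepsy has
#' globally low coupling gains, noisier non-respiratory variability and a
#' lower respiratory frequency.
#'
#' @param name one of `"healthy"`, `"insomnia"`, `"narcolepsy"`.
#' @return object of class `group_profile`: `states` table (per-state rr0,
#'   gain, noise_sd, burst_prob, burst_amp), respiration parameters
#'   (`resp_f0` Hz, `resp_bw` Hz &mdash; the resonator bandwidth,
#'   `resp_noise_sd`), and `rsa_delay_s`.
#' @export
group_profile <- function(name = c("healthy", "insomnia", "narcolepsy")) {
  name <- match.arg(name)
  rr0 <- list(W = 800, R = 850, S1 = 900, S2 = 950, S3 = 1000, S4 = 1050)
  noise_h <- list(W = 20, R = 18, S1 = 11, S2 = 9.5, S3 = 7, S4 = 4.5)
  frac <- c(A1 = 0.70, A2 = 0.45, A3 = 0.22)
  p <- switch(name,
    healthy = list(
      states = profile_table(list(W = 1.5, R = 2, S1 = 3, S2 = 5,
                                  S3 = 7, S4 = 9),
                             frac, rr0, noise_h),
      resp_f0 = 0.25, resp_bw = 0.05,
      resp_noise_sd = 0.10),
    insomnia = list(
      # hyperarousal: elevated nocturnal heart rate, rigid faster breathing
      states = profile_table(list(W = 2, R = 2.5, S1 = 8, S2 = 12,
                                  S3 = 18, S4 = 22),
                             c(A1 = 0.25, A2 = 0.15, A3 = 0.08),
                             lapply(rr0, function(v) v - 120), noise_h),
      resp_f0 = 0.26, resp_bw = 0.025,
      resp_noise_sd = 0.10),
    narcolepsy = list(
      states = profile_table(list(W = 1, R = 1.5, S1 = 2, S2 = 3,
                                  S3 = 4, S4 = 5),
                             frac, rr0,
                             lapply(noise_h, function(v) v * 1.3)),
      resp_f0 = 0.21, resp_bw = 0.045,
      resp_noise_sd = 0.12))
  p$rsa_delay_s <- 0.5
  p$name <- name
  structure(p, class = "group_profile")
}

#' Default 18-state sleep-architecture transition matrix
#'
#' Row-stochastic matrix over the canonical state order: long non-A runs
#' interleaved with short (mostly single-epoch) A-phases so successive
#' CAP cycles recur within about a minute, graded stage transitions from
#' the non-A states, and occasional arousals to wake (more likely from A3).
#'
#' @return 18 x 18 matrix, rows summing to 1.
#' @export
default_transition_matrix <- function() {
  lv <- cap_stage_levels()
  A <- matrix(0, 18, 18, dimnames = list(lv, lv))
  put <- function(from, to, p) A[from, to] <<- p
  put("W", "W", 0.90); put("W", "S1_NA", 0.09); put("W", "R", 0.01)
  put("R", "R", 0.93); put("R", "S1_NA", 0.04); put("R", "W", 0.03)
  cap_in <- c(A1 = 0.13, A2 = 0.08, A3 = 0.05)
  moves <- list(S1 = c(S2_NA = 0.045, W = 0.020, R = 0.010),
                S2 = c(S3_NA = 0.030, S1_NA = 0.010, R = 0.012, W = 0.008),
                S3 = c(S4_NA = 0.035, S2_NA = 0.020),
                S4 = c(S3_NA = 0.030))
  for (s in paste0("S", 1:4)) {
    na <- paste0(s, "_NA")
    for (a in names(cap_in)) put(na, paste0(s, "_", a), cap_in[[a]])
    for (m in names(moves[[s]])) A[na, m] <- moves[[s]][[m]]
    A[na, na] <- 1 - sum(A[na, ])
    for (a in c("A1", "A2", "A3")) {
      st <- paste0(s, "_", a)
      others <- setdiff(paste0(s, "_", c("A1", "A2", "A3")), st)
      put(st, st, if (a == "A3") 0.15 else 0.18)
      put(st, others[1], 0.05); put(st, others[2], 0.05)
      put(st, "W", if (a == "A3") 0.08 else 0.02)
      A[st, na] <- 1 - sum(A[st, ])
    }
  }
  stopifnot(all(abs(rowSums(A) - 1) < 1e-12), all(A >= 0))
  A
}

#' Simulation configuration
#'
#' @param duration_s recording length in seconds (default 8 h).
#' @param seed mandatory RNG seed.
#' @param transition row-stochastic 18 x 18 matrix.
#' @param epoch_s epoch length (30 s).
#' @param fs_resp,fs_acc,fs_ecg channel sampling rates (Hz).
#' @param init_state initial hypnogram state.
#' @param make_ecg also synthesise a template ECG channel.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 8 * 3600, seed,
                       transition = default_transition_matrix(),
                       epoch_s = 30, fs_resp = 4, fs_acc = 5, fs_ecg = 250,
                       init_state = "W", make_ecg = FALSE) {
  assert_that(!missing(seed) && is_scalar_number(seed), "seed is mandatory")
  assert_that(all(dim(transition) == c(18L, 18L)) &&
                all(abs(rowSums(transition) - 1) < 1e-9) &&
                all(transition >= 0),
              "transition must be a row-stochastic 18 x 18 matrix")
  structure(list(duration_s = duration_s, seed = as.integer(seed),
                 transition = transition, epoch_s = epoch_s,
                 fs_resp = fs_resp, fs_acc = fs_acc, fs_ecg = fs_ecg,
                 init_state = init_state, make_ecg = make_ecg),
            class = "sim_config")
}

#' Simulate a hypnogram (one label per 30-s epoch)
#'
#' Markov-chain realisation of the configured transition matrix.
#' @param config a `sim_config`.
#' @return factor of 18-class labels, length `duration_s / epoch_s`.
#' @export
simulate_stage_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lv <- cap_stage_levels()
  n <- floor(config$duration_s / config$epoch_s)
  out <- integer(n)
  out[1] <- match(config$init_state, lv)
  P <- config$transition
  for (t in seq_len(n)[-1]) {
    out[t] <- sample.int(18L, 1L, prob = P[out[t - 1L], ])
  }
  factor(lv[out], levels = lv)
}

#' Simulate the cardiorespiratory and movement channels
#'
#' Respiration is a stochastic narrow-band oscillation - an AR(2) resonator
#' centred on the profile's respiratory frequency whose pole radius sets
#' the bandwidth - plus measurement noise; breathing is therefore coherent
#' over a few cycles but not deterministic, as in real recordings (and as
#' the causality analysis requires: a perfectly predictable oscillation
#' carries no incremental information). Instantaneous RR (ms)
#' is the state's baseline plus the state's coupling gain times the delayed
#' respiration plus AR(1) non-respiratory variability; heartbeats are
#' placed by integrate-and-fire on the instantaneous rate, so the RR series
#' genuinely carries the modulation. Movement bursts occur at the state's
#' rate and amplitude on the three acceleration axes.
#'
#' @param labels hypnogram (one 18-class label per epoch).
#' @param profile a `group_profile`.
#' @param config a `sim_config` (its seed is consumed here).
#' @return list with `rri` (`rri_series`), `rsp`, `accel` (list of three
#'   `signal_segment`s), optional `ecg`, `labels`, and the ground-truth
#'   `rr_inst` segment.
#' @export
simulate_cardioresp <- function(labels, profile, config) {
  stopifnot(inherits(profile, "group_profile"), inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  lv <- cap_stage_levels()
  st_idx <- match(as.character(labels), lv)
  assert_that(!anyNA(st_idx), "labels must come from the 18-class set")
  n_ep <- length(st_idx)
  fs <- config$fs_resp
  spe <- config$epoch_s * fs
  n <- n_ep * spe
  state <- rep(st_idx, each = spe)
  tab <- profile$states

  # respiration: AR(2) resonator at resp_f0; the bandwidth (pole radius)
  # follows the state - breathing grows more regular as sleep deepens
  theta <- 2 * pi * profile$resp_f0 / fs
  bw_mult <- c(W = 1.8, R = 2.5, S1 = 1.3, S2 = 1.05, S3 = 0.75, S4 = 0.5)
  bw_t <- pmax(profile$resp_bw * bw_mult[tab$stage[state]], 0.015)
  rho_t <- pmin(pmax(1 - pi * bw_t / fs, 0.5), 0.995)
  w <- rnorm(n)
  resp_clean <- numeric(n)
  resp_clean[1:2] <- w[1:2]
  for (t in 3:n) {
    resp_clean[t] <- 2 * rho_t[t] * cos(theta) * resp_clean[t - 1] -
      rho_t[t]^2 * resp_clean[t - 2] + w[t]
  }
  # per-state gain of the resonator differs; normalise amplitude locally
  k <- max(1L, round(60 * fs))
  loc_sd <- sqrt(pmax(as.numeric(stats::filter(
    c(rep(resp_clean[1]^2, k), resp_clean^2, rep(resp_clean[n]^2, k)),
    rep(1 / k, k), sides = 2))[(k + 1):(k + n)], 1e-6))
  resp_clean <- resp_clean / loc_sd
  resp <- resp_clean + rnorm(n, 0, profile$resp_noise_sd)

  # instantaneous RR: baseline + gain * delayed respiration + AR(1) noise
  lag <- round(profile$rsa_delay_s * fs)
  resp_del <- c(rep(resp_clean[1], lag), resp_clean)[seq_len(n)]
  rr0 <- tab$rr0[state]
  k <- max(1L, round(10 * fs))          # ~10-s smoothing of the baseline
  rr0 <- as.numeric(stats::filter(c(rep(rr0[1], k), rr0, rep(rr0[n], k)),
                                  rep(1 / k, k), sides = 2))[(k + 1):(k + n)]
  phi <- 0.9
  innov <- rnorm(n) * tab$noise_sd[state] * sqrt(1 - phi^2)
  arn <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  # Mayer-wave LF oscillation: narrow-band resonator at 0.1 Hz
  th_m <- 2 * pi * 0.1 / fs
  rho_m <- 1 - pi * 0.03 / fs
  mw <- as.numeric(stats::filter(rnorm(n), c(2 * rho_m * cos(th_m), -rho_m^2),
                                 method = "recursive"))
  mw <- mw / sd(mw)
  rr_inst <- pmin(pmax(rr0 + tab$gain[state] * resp_del +
                         tab$mayer_sd[state] * mw + arn, 350), 1900)

  # integrate-and-fire beat placement on the instantaneous rate
  tt <- (seq_len(n) - 1L) / fs
  cum <- cumsum(1000 / rr_inst) / fs
  nb <- floor(cum[n])
  beat_times <- approx(cum, tt, xout = seq_len(nb))$y
  rri <- rri_series(beat_times = beat_times)

  # chest acceleration with state-dependent movement bursts
  fa <- config$fs_acc
  na_ <- n_ep * config$epoch_s * fa
  acc <- replicate(3, rnorm(na_, 0, 0.03), simplify = FALSE)
  for (e in seq_len(n_ep)) {
    i <- st_idx[e]
    if (runif(1) < tab$burst_prob[i]) {
      dur <- runif(1, 2, 4)
      start <- (e - 1) * config$epoch_s + runif(1, 0, config$epoch_s - dur)
      idx <- floor(start * fa):min(na_ - 1L, floor((start + dur) * fa))
      env <- sin(pi * seq_along(idx) / length(idx))^2
      carrier <- sin(2 * pi * runif(1, 1, 3) * idx / fa + runif(1, 0, 2 * pi))
      dirv <- rnorm(3); dirv <- abs(dirv) / sqrt(sum(dirv^2))
      amp <- tab$burst_amp[i] * runif(1, 0.6, 1.4)
      for (ax in 1:3) {
        acc[[ax]][idx + 1L] <- acc[[ax]][idx + 1L] +
          amp * dirv[ax] * env * carrier +
          rnorm(length(idx), 0, 0.1 * amp)
      }
    }
  }
  accel <- lapply(seq_along(acc), function(ax)
    signal_segment(acc[[ax]], fa, label = c("acc_x", "acc_y", "acc_z")[ax]))

  out <- list(rri = rri,
              rsp = signal_segment(resp, fs, label = "resp"),
              accel = accel, labels = labels,
              rr_inst = signal_segment(rr_inst, fs, label = "rr_inst_truth"))
  if (isTRUE(config$make_ecg)) {
    fe <- config$fs_ecg
    ne <- ceiling(n_ep * config$epoch_s * fe)
    ecg <- rnorm(ne, 0, 0.02)
    w <- round(0.012 * fe)
    tpl <- exp(-0.5 * ((-3 * w):(3 * w) / w)^2)
    for (bt in beat_times) {
      c0 <- round(bt * fe)
      idx <- (c0 - 3 * w):(c0 + 3 * w)
      keep <- idx >= 0 & idx < ne
      ecg[idx[keep] + 1L] <- ecg[idx[keep] + 1L] + tpl[keep]
    }
    out$ecg <- signal_segment(ecg, fe, label = "ecg")
  }
  out
}

#' Simulate one subject
#'
#' Draws a hypnogram and channels for one subject of the given group, with
#' per-subject random effects (log-normal gain multiplier, baseline RR
#' shift, respiratory-frequency jitter).
#'
#' @param group group name (see [diagnosis_groups()]).
#' @param config a `sim_config`.
#' @param id subject identifier.
#' @return list of class `subject_record` (fields of
#'   [simulate_cardioresp()] plus `id`, `group`, `profile`).
#' @export
simulate_subject <- function(group, config, id = paste0(group, "_1")) {
  profile <- group_profile(group)
  set.seed(child_seed(config$seed, 2L))
  profile$states$gain <- profile$states$gain * rlnorm(1, 0, 0.15)
  profile$states$rr0 <- profile$states$rr0 + rnorm(1, 0, 25)
  profile$resp_f0 <- profile$resp_f0 + rnorm(1, 0, 0.01)
  labels <- simulate_stage_sequence(config)
  rec <- simulate_cardioresp(labels, profile, config)
  rec$id <- id
  rec$group <- group
  rec$profile <- profile
  class(rec) <- "subject_record"
  rec
}

#' Simulate a three-group cohort
#'
#' @param n_per_group subjects per group (>= 1).
#' @param config a `sim_config`; per-subject seeds are derived from its
#'   seed, so the same seed reproduces the cohort bit-for-bit.
#' @return list of `subject_record`s (length `3 * n_per_group`).
#' @export
simulate_cohort <- function(n_per_group, config) {
  assert_that(n_per_group >= 1L, "n_per_group must be >= 1")
  out <- list()
  k <- 0L
  for (g in diagnosis_groups()) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- child_seed(config$seed, 100L + k)
      out[[k]] <- simulate_subject(g, cfg, id = sprintf("%s_%02d", g, i))
    }
  }
  out
}
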