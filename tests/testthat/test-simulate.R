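# Synthetic-data generator: determinism, Markov-chain statistics,
# physiological ranges and the contracts the rest of the pipeline assumes.

test_that("stage sequences are reproducible and follow the chain", {
  cfg <- sim_config(duration_s = 3600, seed = 3)
  a <- simulate_stage_sequence(cfg)
  b <- simulate_stage_sequence(cfg)
  expect_identical(a, b)
  expect_length(a, 120L)
  # identity transition matrix -> constant sequence
  P <- diag(18); dimnames(P) <- list(cap_stage_levels(), cap_stage_levels())
  cfgi <- sim_config(duration_s = 1800, seed = 4, transition = P,
                     init_state = "S2_NA")
  expect_true(all(simulate_stage_sequence(cfgi) == "S2_NA"))
  # invalid matrix rejected
  expect_error(sim_config(seed = 1, transition = matrix(1, 18, 18)),
               "row-stochastic")
})

test_that("empirical transition frequencies approach the specified matrix", {
  P <- default_transition_matrix()
  cfg <- sim_config(duration_s = 3e5, seed = 6)   # 1e4 epochs
  s <- as.integer(simulate_stage_sequence(cfg))
  emp <- matrix(0, 18, 18)
  for (t in seq_along(s)[-1]) emp[s[t - 1], s[t]] <- emp[s[t - 1], s[t]] + 1
  rs <- rowSums(emp)
  visited <- rs > 500
  emp[visited, ] <- emp[visited, ] / rs[visited]
  expect_lt(max(abs(emp[visited, ] - P[visited, ])), 0.05)
})

test_that("simulated RR intervals stay physiological and nearly clean", {
  cfg <- sim_config(duration_s = 3600, seed = 7)
  rec <- simulate_subject("healthy", cfg)
  rr <- rec$rri$intervals
  expect_true(all(rr > 300 & rr < 2000))
  # relative-change artefact gate fires on < 1% of simulated beats
  rel_viol <- mean(rr[-1] <= 0.7 * head(rr, -1) |
                     rr[-1] >= 1.3 * head(rr, -1))
  expect_lt(rel_viol, 0.01)
})

test_that("respiration passes the quality gate in at least 95% of windows", {
  cfg <- sim_config(duration_s = 3600, seed = 8)
  rec <- simulate_subject("healthy", cfg)
  win <- sliding_windows(seg_duration(rec$rsp))
  q <- vapply(seq_len(nrow(win)), function(i) {
    respiration_quality(seg_slice(rec$rsp, win$start[i], win$end[i]))
  }, numeric(1))
  expect_gte(mean(q > 0.85), 0.95)
})

test_that("cohorts are reproducible and sized 3 * n", {
  cfg <- sim_config(duration_s = 1200, seed = 9)
  coh <- simulate_cohort(3, cfg)
  expect_length(coh, 9L)
  expect_equal(as.vector(table(vapply(coh, `[[`, "", "group"))), rep(3L, 3))
  coh2 <- simulate_cohort(3, cfg)
  expect_identical(coh[[5]]$rri$intervals, coh2[[5]]$rri$intervals)
  expect_identical(coh[[8]]$labels, coh2[[8]]$labels)
})

test_that("coupling gains are ordered by group in the profiles", {
  h <- group_profile("healthy"); i <- group_profile("insomnia")
  n <- group_profile("narcolepsy")
  deep_na <- function(p) p$states$gain[p$states$state %in% c("S3_NA", "S4_NA")]
  expect_true(all(deep_na(i) > deep_na(h)))
  expect_true(all(n$states$gain < h$states$gain))
  expect_true(all(h$states$gain >= 0))
})

test_that("deep-sleep CRA group means are ordered through the pipeline", {
  # insomnia(NA) > healthy(NA) > narcolepsy(NA), realized end to end
  med <- vapply(diagnosis_groups(), function(g) {
    v <- vapply(c(31, 32), function(sd_) {
      cfg <- sim_config(duration_s = 4 * 3600, seed = sd_)
      sf <- process_subject(simulate_subject(g, cfg))
      f <- sf$features
      deep <- stage_of(f$label) %in% c("S3", "S4") & phase_of(f$label) == "NA"
      median(f$cra[deep], na.rm = TRUE)
    }, numeric(1))
    mean(v)
  }, numeric(1))
  expect_gt(med[["insomnia"]], med[["healthy"]])
  expect_gt(med[["healthy"]], med[["narcolepsy"]])
})

test_that("the resonance frequency tracks the simulated breathing rate", {
  rec <- fixture_recording("S3_NA", minutes = 10, seed = 16)
  tr <- cri_track(rec$rri, rec$rsp)
  expect_lt(abs(median(tr$FA, na.rm = TRUE) - 0.25), 0.03)
  # narcolepsy breathes slower; FA follows
  recn <- fixture_recording("S3_NA", minutes = 10, seed = 16,
                            group = "narcolepsy")
  trn <- cri_track(recn$rri, recn$rsp)
  expect_lt(abs(median(trn$FA, na.rm = TRUE) - 0.21), 0.03)
})

test_that("zero coupling is indistinguishable from the null", {
  lab <- factor(rep("S2_NA", 20), levels = cap_stage_levels())
  p0 <- group_profile("healthy"); p0$states$gain[] <- 0
  null_med <- vapply(1:6, function(s) {
    rec <- simulate_cardioresp(lab, p0, sim_config(duration_s = 600, seed = s))
    median(cri_track(rec$rri, rec$rsp)$CRA, na.rm = TRUE)
  }, numeric(1))
  rec <- simulate_cardioresp(lab, p0, sim_config(duration_s = 600, seed = 99))
  med <- median(cri_track(rec$rri, rec$rsp)$CRA, na.rm = TRUE)
  expect_lte(med, quantile(null_med, 0.95) + 0.5)
})
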