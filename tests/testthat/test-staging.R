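# Supervised HMM (transition counting, Viterbi, stability features),
# training-epoch selection, outlier compensation and the two-layer stager.

test_that("transition probabilities are bigram counts", {
  lv <- cap_stage_levels()
  labs <- c("W", "W", "W", "R", "R")
  hmm <- train_hmm(c(1, 1, 1, 2, 2), labs)
  expect_equal(hmm$trans["W", "W"], 2 / 3)
  expect_equal(hmm$trans["W", "R"], 1 / 3)
  expect_equal(hmm$trans["R", "R"], 1)
  # rows sum to 1; unvisited rows uniform
  expect_equal(unname(rowSums(hmm$trans)), rep(1, 18), tolerance = 1e-9)
  expect_true(all(hmm$trans[lv[5], ] == 1 / 18))
  expect_true(lv[5] %in% hmm$unvisited)
  # single-state sequence -> identity row
  h1 <- train_hmm(c(1, 1, 1), c("S2_NA", "S2_NA", "S2_NA"))
  expect_equal(h1$trans["S2_NA", "S2_NA"], 1)
  expect_error(train_hmm(1, "W"), "2 epochs")
})

test_that("a known 18-state chain is recovered at n = 1e4", {
  # diagonally dominant chain (long dwell times, uniform off-diagonal);
  # the diagonal mass keeps every estimated entry's standard error well
  # inside the 0.03 band at 1e4 epochs
  K <- 18
  P <- matrix(0.04 / (K - 1), K, K)
  diag(P) <- 0.96
  lv <- cap_stage_levels()
  dimnames(P) <- list(lv, lv)
  set.seed(1)
  n <- 1e4
  s <- integer(n); s[1] <- 1L
  for (t in 2:n) s[t] <- sample.int(K, 1, prob = P[s[t - 1], ])
  hmm <- train_hmm(rnorm(n), lv[s])
  expect_lt(max(abs(hmm$trans - P)), 0.03)
})

test_that("Viterbi agrees with exhaustive path enumeration", {
  # small 3-state instances checked against brute force over all paths
  lv <- cap_stage_levels()
  sub <- lv[1:3]
  set.seed(4)
  for (rep in 1:5) {
    P <- matrix(runif(9, 0.05, 1), 3, 3); P <- P / rowSums(P)
    mu <- c(-1, 0, 1.5); sdv <- c(0.8, 1, 0.6)
    init <- c(0.5, 0.3, 0.2)
    trans <- matrix(1e-12, 18, 18, dimnames = list(lv, lv))
    trans[1:3, 1:3] <- P
    em <- data.frame(state = lv, mean = rep(100, 18), sd = rep(1e-6, 18))
    em$mean[1:3] <- mu; em$sd[1:3] <- sdv
    hmm <- structure(list(trans = trans,
                          emission = em,
                          init = c(init, rep(1e-12, 15)),
                          levels = lv, unvisited = character(0)),
                     class = "cap_hmm")
    obs <- rnorm(5)
    # brute force over 3^5 paths
    paths <- as.matrix(expand.grid(rep(list(1:3), 5)))
    lp <- apply(paths, 1, function(pth) {
      v <- log(init[pth[1]]) + dnorm(obs[1], mu[pth[1]], sdv[pth[1]], log = TRUE)
      for (t in 2:5) v <- v + log(P[pth[t - 1], pth[t]]) +
          dnorm(obs[t], mu[pth[t]], sdv[pth[t]], log = TRUE)
      v
    })
    best <- paths[which.max(lp), ]
    got <- as.integer(viterbi_decode(hmm, obs))
    expect_equal(got, unname(best))
  }
})

test_that("stability features read the diagonal and column sums", {
  lv <- cap_stage_levels()
  # deterministic chain: the visited state keeps its identity row; its
  # column also collects the uniform mass of the 17 unvisited rows
  hmm <- train_hmm(rep(0.5, 6), rep("S3_NA", 6))
  st <- stability_features(hmm, rep(0.5, 4))
  expect_equal(unname(st[, "stab_diag"]), rep(1, 4))
  expect_equal(unname(st[, "stab_colsum"]), rep(1 + 17 / 18, 4))
  # hand-built 2-state block [[0.9, 0.1], [0.2, 0.8]]
  trans <- diag(18); dimnames(trans) <- list(lv, lv)
  trans[1, 1] <- 0.9; trans[1, 2] <- 0.1
  trans[2, 1] <- 0.2; trans[2, 2] <- 0.8
  em <- data.frame(state = lv, mean = seq(0, 17), sd = 0.1)
  hmm2 <- structure(list(trans = trans, emission = em,
                         init = rep(1 / 18, 18), levels = lv,
                         unvisited = character(0)), class = "cap_hmm")
  st2 <- stability_features(hmm2, c(0, 0))   # decodes to state 1 (W)
  expect_equal(unname(st2[1, ]), c(0.9, 1.1))
  # all-missing CRA -> missing features
  expect_true(all(is.na(stability_features(hmm2, c(NA, NA)))))
  # appended characteristic count is 23
  expect_length(cap_feature_names("all"), 23L)
})

test_that("training-epoch selection follows the 20-epoch run rule", {
  labs <- c(rep("W", 25), rep("S3_NA", 15), rep("S2_NA", 30))
  sel <- select_training_epochs(labs)
  expect_true(all(1:25 %in% sel))          # run of 25 wake epochs
  expect_false(any(26:40 %in% sel))        # 15-epoch deep run: too short
  expect_true(all(41:70 %in% sel))
  # A-phase epochs always selected, REM always selected
  labs2 <- c(rep("S2_NA", 5), "S2_A1", rep("R", 3), rep("S4_NA", 4), "S4_A3")
  sel2 <- select_training_epochs(labs2)
  expect_true(6 %in% sel2)
  expect_true(all(7:9 %in% sel2))
  expect_true(14 %in% sel2)
  expect_false(any(1:5 %in% sel2))
})

test_that("outlier compensation winsorises to median +/- 5 MAD, idempotently", {
  set.seed(2)
  x <- matrix(rnorm(400), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  clean <- compensate_outliers(x)
  expect_equal(attr(clean, "n_winsorized"), 0)
  expect_equal(unclass(clean)[, ], x[, ])
  # single injected spike is bounded afterwards
  x[5, 2] <- 50
  comp <- compensate_outliers(x)
  st <- attr(comp, "stats")
  expect_lte(comp[5, 2], st$med[2] + 5 * st$mad[2])
  # second call with the same stats is a no-op
  comp2 <- compensate_outliers(unclass(comp), stats = st)
  expect_equal(unclass(comp2)[, ], unclass(comp)[, ])
  # the repreprocess callback gets a chance first
  fixed <- compensate_outliers(x, repreprocess = function(m, bad) {
    m[bad] <- 0; m
  })
  expect_equal(as.numeric(fixed[5, 2]), 0)
})

test_that("the two-layer stager learns separable features exactly", {
  # perfectly separable synthetic features: one informative dimension per
  # macro stage and per phase
  set.seed(10)
  lv <- cap_stage_levels()
  n <- 1200
  labs <- sample(lv, n, replace = TRUE,
                 prob = c(3, 2, rep(c(4, 1, 1, 1), 4)) / 22)
  X <- matrix(rnorm(n * 23, 0, 0.05), n, 23,
              dimnames = list(NULL, cap_feature_names("all")))
  X[, "cra"] <- match(stage_of(labs), c("W", "R", paste0("S", 1:4)))
  X[, "bm_var"] <- match(phase_of(labs), c("-", "NA", "A1", "A2", "A3"))
  fit <- train_stager(X, labs, seed = 17, num_trees = 100, select = FALSE)
  pred <- classify_stages(fit, X)
  expect_gte(mean(as.character(pred) == labs), 0.95)
  # composition: predicted W/R never carry a CAP phase
  wr <- as.character(pred) %in% c("W", "R")
  expect_true(all(phase_of(pred[wr]) == "-"))
  # determinism given the seed
  fit2 <- train_stager(X, labs, seed = 17, num_trees = 100, select = FALSE)
  expect_identical(as.character(classify_stages(fit2, X)),
                   as.character(pred))
})

test_that("permuted labels score at chance", {
  set.seed(11)
  lv <- cap_stage_levels()
  n <- 900
  labs <- sample(lv, n, replace = TRUE)
  X <- matrix(rnorm(n * 23), n, 23,
              dimnames = list(NULL, cap_feature_names("all")))
  X[, "cra"] <- match(stage_of(labs), c("W", "R", paste0("S", 1:4)))
  fit <- train_stager(X, sample(labs), seed = 3, num_trees = 100,
                      select = FALSE)
  pred <- classify_stages(fit, X)
  cm <- confusion_matrix(labs, pred)
  rep <- suppressWarnings(f1_report(cm))
  expect_lte(rep$macro_f1, 2 / 18)
})

test_that("a missing layer-2 class degenerates with a warning", {
  lv <- cap_stage_levels()
  n <- 300
  labs <- sample(c("W", "S2_NA"), n, replace = TRUE)
  X <- matrix(rnorm(n * 23), n, 23,
              dimnames = list(NULL, cap_feature_names("all")))
  X[, "cra"] <- ifelse(labs == "W", 0, 5)
  w <- capture_warnings(fit <- train_stager(X, labs, seed = 1, num_trees = 50,
                                            select = FALSE))
  expect_true(any(grepl("majority|no epochs", w)))
  pred <- classify_stages(fit, X)
  expect_true(all(as.character(pred) %in% c("W", "S2_NA")))
})
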