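# Confusion matrices, F1 reports and collapsed views, group statistics
# (ANOVA + Dunnett LSR) and cross-validation bookkeeping.

test_that("confusion counts are conserved and placed correctly", {
  a <- c("W", "W", "R", "S2_NA", "S2_A1")
  p <- c("W", "R", "R", "S2_NA", "S2_NA")
  cm <- confusion_matrix(a, p)
  expect_equal(sum(cm), 5)
  expect_equal(cm["W", "W"], 1)
  expect_equal(cm["W", "R"], 1)
  expect_equal(cm["S2_A1", "S2_NA"], 1)
  expect_error(confusion_matrix(c("W", "XX"), c("W", "W")), "unknown")
  expect_error(confusion_matrix(c("W"), c("W", "R")), "equal length")
})

test_that("per-class F1 follows the harmonic-mean formula", {
  # two-class hand example embedded in the 18-class grid
  a <- c(rep("W", 10), rep("R", 10))
  p <- c(rep("W", 8), rep("R", 2), "W", rep("R", 9))
  cm <- confusion_matrix(a, p)
  rep <- suppressWarnings(f1_report(cm))
  pc <- rep$per_class
  f1_w <- 2 * (8 / 9) * (8 / 10) / ((8 / 9) + (8 / 10))
  f1_r <- 2 * (9 / 11) * (9 / 10) / ((9 / 11) + (9 / 10))
  expect_equal(pc$f1[pc$class == "W"], f1_w, tolerance = 1e-9)
  expect_equal(pc$f1[pc$class == "R"], f1_r, tolerance = 1e-9)
  expect_equal(rep$macro_f1, (f1_w + f1_r) / 2, tolerance = 1e-9)
  # harmonic identity for every supported class
  ok <- pc$support > 0 & !is.na(pc$f1) & pc$f1 > 0
  expect_equal(pc$f1[ok],
               2 * pc$precision[ok] * pc$recall[ok] /
                 (pc$precision[ok] + pc$recall[ok]), tolerance = 1e-9)
})

test_that("a diagonal matrix scores macro F1 = 1; zero-support excluded", {
  lv <- cap_stage_levels()
  a <- rep(lv, each = 3)
  cm <- confusion_matrix(a, a)
  rep <- f1_report(cm)
  expect_equal(rep$macro_f1, 1)
  expect_equal(rep$weighted_f1, 1)
  # drop one class entirely: excluded with a warning
  a2 <- a[a != "R"]
  expect_warning(rep2 <- f1_report(confusion_matrix(a2, a2)),
                 "zero support")
  expect_equal(rep2$macro_f1, 1)
  expect_true(all(rep$per_class$f1 >= 0 & rep$per_class$f1 <= 1, na.rm = TRUE))
})

test_that("collapsed views equal metrics on collapsed label sequences", {
  set.seed(12)
  lv <- cap_stage_levels()
  a <- sample(lv, 600, replace = TRUE)
  p <- ifelse(runif(600) < 0.6, a, sample(lv, 600, replace = TRUE))
  cm <- confusion_matrix(a, p)
  rep <- suppressWarnings(f1_report(cm))
  # sleep-wake view vs direct computation on collapsed labels
  aw <- ifelse(a == "W", "W", "Sleep"); pw <- ifelse(p == "W", "W", "Sleep")
  tab <- table(aw, pw)
  f1_of <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  f1_w <- f1_of(tab["W", "W"], tab["Sleep", "W"], tab["W", "Sleep"])
  f1_s <- f1_of(tab["Sleep", "Sleep"], tab["W", "Sleep"], tab["Sleep", "W"])
  expect_equal(rep$views$sleep_wake$macro_f1, (f1_w + f1_s) / 2,
               tolerance = 1e-9)
  # six-stage view conserves counts
  expect_equal(sum(rep$views$stage6$matrix), 600)
  # pooled A/NA recall matches direct collapsed computation
  nrem <- phase_of(a) != "-"
  act_a <- phase_of(a)[nrem] %in% c("A1", "A2", "A3")
  pred_a <- phase_of(p)[nrem] %in% c("A1", "A2", "A3")
  pooled <- a_na_pooled(cm)
  expect_equal(pooled$recall_a, mean(pred_a[act_a]), tolerance = 1e-9)
})

test_that("the printed per-stage A-phase rates average to 84.7", {
  rates <- c(84.4, 90.1, 84.2, 79.9)
  expect_equal(round(mean(rates), 1), 84.7)
})

test_that("group_stats reproduces a textbook ANOVA", {
  # explicit sum-of-squares oracle on a 3-group hand example
  g1 <- c(4, 5, 6); g2 <- c(6, 7, 8); g3 <- c(9, 10, 11)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 3)
  gm <- mean(vals)
  ssb <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  Fstat <- (ssb / 2) / (ssw / 6)
  p_oracle <- pf(Fstat, 2, 6, lower.tail = FALSE)
  gs <- group_stats(vals, grp)
  expect_equal(gs$p_value, p_oracle, tolerance = 1e-9)
  # pair significant iff |mean difference| > LSR
  expect_equal(gs$table$significant,
               abs(gs$table$mean_difference) > gs$table$lsr)
  expect_true(gs$table$significant[gs$table$comparison == "c - a"])
})

test_that("group_stats flags separated groups and identical groups", {
  set.seed(13)
  x <- rnorm(100); y <- rnorm(100, 1)
  gs <- group_stats(c(x, y), rep(c("ctl", "trt"), each = 100))
  expect_lt(gs$p_value, 0.05)
  expect_true(all(gs$table$significant))
  # identical groups: zero difference, not significant
  gs0 <- group_stats(c(x, x), rep(c("ctl", "trt"), each = 100))
  expect_equal(gs0$table$mean_difference, 0, tolerance = 1e-12)
  expect_false(any(gs0$table$significant))
  expect_error(group_stats(rep(1, 10), rep(c("a", "b"), 5)), "degenerate")
})

test_that("cross-validation folds are deterministic and conserve epochs", {
  set.seed(20)
  lv <- cap_stage_levels()
  featset <- lapply(1:7, function(i) {
    n <- 60
    labs <- sample(lv, n, replace = TRUE)
    X <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, cap_feature_names("base")))
    X[, "cra"] <- match(stage_of(labs), c("W", "R", paste0("S", 1:4)))
    structure(list(features = as.data.frame(X), labels = labs,
                   cra = X[, "cra"], id = paste0("s", i), group = "healthy"),
              class = "subject_features")
  })
  cv <- suppressWarnings(crossvalidate(featset, folds = 7, seed = 5,
                                       num_trees = 30))
  # 7 subjects, 7 folds: leave-one-subject-out
  expect_equal(sort(table(cv$fold_assignment)), sort(rep(1L, 7)),
               ignore_attr = TRUE)
  expect_equal(sum(cv$pooled), 7 * 60)
  cv2 <- suppressWarnings(crossvalidate(featset, folds = 7, seed = 5,
                                        num_trees = 30))
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_error(crossvalidate(featset, folds = 9), "folds")
})
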