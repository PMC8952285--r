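## Confusion matrices, precision/recall/F1 reports with collapsed views,
## group statistics (one-way ANOVA + Dunnett least significant range) and
## the subject-level cross-validation driver.

#' 18-class confusion matrix
#'
#' Rows are the actual classes, columns the predicted classes, in the
#' canonical state order.
#'
#' @param actual,predicted equal-length label sequences.
#' @return matrix of class `cap_confusion` (18 x 18 counts).
#' @export
confusion_matrix <- function(actual, predicted) {
  assert_that(length(actual) == length(predicted),
              "actual and predicted must have equal length")
  a <- as_stage_factor(actual); p <- as_stage_factor(predicted)
  m <- unclass(table(actual = a, predicted = p))
  class(m) <- c("cap_confusion", class(m))
  m
}

collapse_confusion <- function(cm, map) {
  groups <- unique(map)
  out <- matrix(0L, length(groups), length(groups),
                dimnames = list(actual = groups, predicted = groups))
  for (i in seq_along(map)) for (j in seq_along(map)) {
    out[map[i], map[j]] <- out[map[i], map[j]] + cm[i, j]
  }
  out
}

per_class_metrics <- function(cm) {
  k <- nrow(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  f1[support > 0 & !is.na(recall) & recall == 0 &
       (is.na(precision) | precision == 0)] <- 0
  data.frame(class = rownames(cm), support = support, precision = precision,
             recall = recall, f1 = f1, row.names = NULL,
             stringsAsFactors = FALSE)
}

macro_from <- function(pc) {
  supported <- pc$support > 0
  if (!all(supported))
    warning(sprintf("%d class(es) with zero support excluded from macro F1",
                    sum(!supported)))
  f1 <- pc$f1[supported]
  w <- pc$support[supported]
  list(macro_f1 = mean(f1, na.rm = TRUE),
       weighted_f1 = sum(f1 * w, na.rm = TRUE) /
         sum(w[!is.na(f1)]))
}

#' Precision / recall / F1 report
#'
#' Per-class precision, recall and F1 of an 18-class confusion matrix,
#' with the macro F1 as the unweighted mean over supported classes (the
#' support-weighted mean is also reported, since headline figures cannot
#' always be tied to one convention), and collapsed views: sleep-wake,
#' six-stage, and per-NREM-stage A/NA (where a prediction counts as
#' A-phase whenever its predicted phase is A1/A2/A3, whatever the
#' predicted stage). The per-stage A-phase rate is reported both as the
#' recall of the merged A class and as the binary A/NA accuracy.
#'
#' @param cm a `cap_confusion` (or the actual/predicted pair via
#'   [confusion_matrix()]).
#' @return list of class `cap_report`: `per_class`, `macro_f1`,
#'   `weighted_f1`, `views` (collapsed matrices with their own metrics),
#'   `a_phase` (per-stage rates and their averages).
#' @export
f1_report <- function(cm) {
  stopifnot(inherits(cm, "cap_confusion"))
  assert_that(sum(cm) > 0, "empty confusion matrix")
  pc <- per_class_metrics(cm)
  mac <- macro_from(pc)
  lv <- cap_stage_levels()

  view <- function(map) {
    vm <- collapse_confusion(cm, map)
    vpc <- per_class_metrics(vm)
    c(list(matrix = vm, per_class = vpc),
      suppressWarnings(macro_from(vpc)))
  }
  views <- list(
    sleep_wake = view(ifelse(lv == "W", "W", "Sleep")),
    stage6 = view(macro6_of(lv)))

  a_phase <- data.frame(stage = paste0("S", 1:4), recall_a = NA_real_,
                        accuracy_a_na = NA_real_, stringsAsFactors = FALSE)
  pred_is_a <- phase_of(lv) %in% c("A1", "A2", "A3")
  for (k in 1:4) {
    s <- paste0("S", k)
    rows <- which(stage_of(lv) == s)
    act_a <- rows[phase_of(lv)[rows] != "NA"]
    act_na <- rows[phase_of(lv)[rows] == "NA"]
    n_a <- sum(cm[act_a, ]); n_na <- sum(cm[act_na, ])
    if (n_a + n_na == 0) next
    tp_a <- sum(cm[act_a, pred_is_a])
    tn_na <- sum(cm[act_na, !pred_is_a])
    a_phase$recall_a[k] <- if (n_a > 0) tp_a / n_a else NA_real_
    a_phase$accuracy_a_na[k] <- (tp_a + tn_na) / (n_a + n_na)
  }
  structure(list(per_class = pc, macro_f1 = mac$macro_f1,
                 weighted_f1 = mac$weighted_f1, views = views,
                 a_phase = a_phase,
                 a_phase_average = c(
                   recall = mean(a_phase$recall_a, na.rm = TRUE),
                   accuracy = mean(a_phase$accuracy_a_na, na.rm = TRUE))),
            class = "cap_report")
}

#' @export
print.cap_report <- function(x, ...) {
  cat(sprintf("<cap_report: macro F1 %.3f (weighted %.3f), sleep-wake F1 %.3f>\n",
              x$macro_f1, x$weighted_f1, x$views$sleep_wake$macro_f1))
  cat("A-phase rates (recall | A/NA accuracy):\n")
  for (k in 1:4)
    cat(sprintf("  S%d: %.3f | %.3f\n", k, x$a_phase$recall_a[k],
                x$a_phase$accuracy_a_na[k]))
  invisible(x)
}

#' Pooled recall of the merged A-phase class
#'
#' Recall of A (any subtype) versus non-A over all actual NREM epochs:
#' the per-stage A/NA view pooled across S1-S4.
#' @param cm a `cap_confusion`.
#' @return list with `recall_a`, `recall_na`, `accuracy`.
#' @export
a_na_pooled <- function(cm) {
  lv <- cap_stage_levels()
  pred_is_a <- phase_of(lv) %in% c("A1", "A2", "A3")
  act_a <- phase_of(lv) %in% c("A1", "A2", "A3")
  act_na <- phase_of(lv) == "NA"
  n_a <- sum(cm[act_a, ]); n_na <- sum(cm[act_na, ])
  tp_a <- sum(cm[act_a, pred_is_a]); tn <- sum(cm[act_na, !pred_is_a])
  list(recall_a = tp_a / n_a, recall_na = tn / n_na,
       accuracy = (tp_a + tn) / (n_a + n_na))
}

#' Group statistics: one-way ANOVA with Dunnett post hoc
#'
#' One-way analysis of variance over the groups, followed by Dunnett
#' contrasts of every group against the control (first level). The least
#' significant range (LSR) is the half-width of the family-wise Dunnett
#' confidence interval at level `1 - alpha`; a pair differs significantly
#' when the absolute difference of means exceeds its LSR.
#'
#' @param values numeric measurements.
#' @param groups group label per value (first level = control).
#' @param alpha significance level (default 0.05).
#' @return list with `p_value` (ANOVA) and `table` (per-pair difference of
#'   means, LSR, significance flag).
#' @export
group_stats <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2L, "need at least 2 groups")
  tb <- table(groups)
  assert_that(all(tb >= 2L), "need at least 2 values per group")
  vars <- tapply(values, groups, var)
  if (all(vars < 1e-24)) stop("degenerate variance: all groups constant")
  d <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = d)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ci <- stats::confint(gl, level = 1 - alpha)$confint
  diff <- ci[, "Estimate"]
  lsr <- diff - ci[, "lwr"]
  list(p_value = p,
       table = data.frame(comparison = rownames(ci),
                          mean_difference = as.numeric(diff),
                          lsr = as.numeric(lsr),
                          significant = abs(diff) > lsr,
                          row.names = NULL))
}

#' Subject-level cross-validation of the stager
#'
#' Deterministic subject-fold assignment, per-fold training of the HMM and
#' the two-layer stager on the training subjects, classification of the
#' held-out subjects, and the pooled confusion matrix (the sum of the fold
#' matrices).
#'
#' @param featset list of per-subject feature sets as produced by
#'   [process_subject()] (fields `features`, `labels`, `cra`, `id`).
#' @param folds number of folds (default 7; must not exceed the number of
#'   subjects).
#' @param seed fold-assignment and forest seed.
#' @param num_trees trees per forest.
#' @return list with `fold_assignment`, per-fold reports, `pooled`
#'   confusion matrix and `report`.
#' @export
crossvalidate <- function(featset, folds = 7L, seed = 17L, num_trees = 500L) {
  ns <- length(featset)
  assert_that(folds >= 2L && folds <= ns,
              "folds must be between 2 and the number of subjects")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), ns))
  pooled <- NULL
  fold_reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    ex <- run_cap_experiment(featset, test_ids = te, seed = seed,
                             num_trees = num_trees)
    pooled <- if (is.null(pooled)) ex$cm else pooled + ex$cm
    fold_reports[[f]] <- ex$report
  }
  class(pooled) <- c("cap_confusion", class(pooled))
  list(fold_assignment = assign, fold_reports = fold_reports,
       pooled = pooled, report = f1_report(pooled))
}
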