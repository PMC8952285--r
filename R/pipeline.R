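## End-to-end orchestration: per-subject feature extraction, the staging
## experiment (train/test split over subjects), and leave-one-subject-out
## diagnosis.

#' Extract the per-epoch feature set of one subject
#'
#' Cleans the RR series, computes the resonance track and assembles the
#' 21-feature table plus labels; the per-epoch CRA value is carried
#' separately for Markov-stability computation.
#'
#' @param record a `subject_record` (or any list with `rri`, `rsp`,
#'   `accel`, optional `labels`, `id`, `group`).
#' @param order AR order for the resonance track ("auto" by default).
#' @param ... further arguments to [assemble_epoch_features()].
#' @return list of class `subject_features`: `features` (data.frame),
#'   `labels`, `cra` (per-epoch), `track`, `id`, `group`.
#' @export
process_subject <- function(record, order = "auto", ...) {
  rri <- clean_rr_segmented(record$rri)$cleaned
  feats <- assemble_epoch_features(rri, record$rsp, record$accel,
                                   labels = record$labels, order = order, ...)
  structure(list(features = feats,
                 labels = if (!is.null(feats$label)) feats$label else NULL,
                 cra = feats$cra,
                 track = attr(feats, "track"),
                 id = record$id %||% "subject",
                 group = record$group %||% NA_character_),
            class = "subject_features")
}

bind_featset <- function(featset, ids) {
  do.call(rbind, lapply(featset[ids], function(s) {
    cbind(s$features, .subject = s$id)
  }))
}

#' Run a staging experiment on a processed cohort
#'
#' Trains the CRA hidden Markov model and the two-layer stager on the
#' training subjects, appends the Markov stability features to every
#' subject (decoded with the training-set HMM), classifies the held-out
#' subjects and scores them. Setting `use_cri = FALSE` drops the six
#' resonance features throughout (ablation experiments); `shuffle_labels`
#' permutes the training labels (negative control).
#'
#' @param featset list of `subject_features`.
#' @param test_ids indices of held-out subjects.
#' @param seed forest seed.
#' @param num_trees trees per forest.
#' @param use_cri include the resonance features (default TRUE).
#' @param shuffle_labels permute training labels (default FALSE).
#' @return list with the trained `hmm`, `stager`, per-subject
#'   `predictions`, pooled test confusion matrix `cm` and its `report`.
#' @export
run_cap_experiment <- function(featset, test_ids, seed = 17L,
                               num_trees = 500L, use_cri = TRUE,
                               shuffle_labels = FALSE) {
  ns <- length(featset)
  train_ids <- setdiff(seq_len(ns), test_ids)
  assert_that(length(train_ids) >= 1L && length(test_ids) >= 1L,
              "need at least one training and one test subject")
  hmm <- train_hmm(lapply(featset[train_ids], `[[`, "cra"),
                   lapply(featset[train_ids], `[[`, "labels"))
  feat_names <- cap_feature_names("all")
  if (!use_cri) feat_names <- setdiff(feat_names, cap_feature_names("cri"))
  with_stab <- lapply(featset, function(s) {
    cbind(s$features, stability_features(hmm, s$cra))
  })
  train_X <- do.call(rbind, with_stab[train_ids])
  train_y <- unlist(lapply(featset[train_ids], `[[`, "labels"))
  if (shuffle_labels) train_y <- sample(train_y)
  stager <- train_stager(train_X[, intersect(feat_names, colnames(train_X))],
                         train_y, seed = seed, num_trees = num_trees)
  predictions <- lapply(seq_len(ns), function(i)
    classify_stages(stager, with_stab[[i]]))
  test_actual <- unlist(lapply(featset[test_ids], `[[`, "labels"))
  test_pred <- unlist(lapply(predictions[test_ids], as.character))
  cm <- confusion_matrix(test_actual, test_pred)
  list(hmm = hmm, stager = stager, predictions = predictions,
       cm = cm, report = suppressWarnings(f1_report(cm)))
}

#' Leave-one-subject-out diagnosis
#'
#' Builds one summary per subject from its features and (predicted or
#' annotated) labels, then evaluates the SVM diagnoser leave-one-out.
#'
#' @param summaries matrix of subject summaries (rows = subjects).
#' @param groups true group per subject.
#' @param seed RNG seed for the inner grid search.
#' @return list with per-subject `predicted`, the `balanced_accuracy` and
#'   the `confusion` table.
#' @export
loso_diagnosis <- function(summaries, groups, seed = 1L) {
  groups <- as.character(groups)
  n <- nrow(summaries)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- train_diagnoser(summaries[-i, , drop = FALSE], groups[-i],
                           seed = seed)
    pred[i] <- diagnose(fit, summaries[i, ])$group
  }
  tab <- table(actual = groups, predicted = factor(pred, levels = sort(unique(groups))))
  recalls <- diag(prop.table(tab, 1))
  list(predicted = pred, balanced_accuracy = mean(recalls), confusion = tab)
}
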