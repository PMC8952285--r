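## Subject-level diagnosis of insomnia and narcolepsy: an order-free
## summary of the staged recording, an RBF support-vector machine over the
## summaries, and a versioned training library with explicit retraining.

#' The three diagnostic groups
#' @return character vector.
#' @export
diagnosis_groups <- function() c("healthy", "insomnia", "narcolepsy")

#' Summarise a staged recording for diagnosis
#'
#' Deterministic, epoch-order-free summary: mean and variance of each of
#' the 23 characteristics within each predicted macro stage (W, R, S1..S4),
#' the deep-sleep (S3+S4) resonance profile (mean CRA, CRB, CRQ, CRR), and
#' the A-versus-NA CRA contrast (mean CRA in A-phase epochs minus mean CRA
#' in NA epochs) per NREM stage and pooled. Stages absent from the
#' recording yield NA blocks.
#'
#' @param features feature table with the 23 characteristic columns.
#' @param labels predicted (or annotated) 18-class labels, one per row.
#' @return named numeric vector of class `subject_summary`.
#' @export
summarize_subject <- function(features, labels) {
  nm <- intersect(cap_feature_names("all"), colnames(features))
  m <- as.matrix(as.data.frame(features)[, nm, drop = FALSE])
  storage.mode(m) <- "double"
  labels <- as.character(labels)
  assert_that(nrow(m) == length(labels), "one label per feature row required")
  scored <- !is.na(labels)
  assert_that(sum(scored) >= 10L, "fewer than 10 scored epochs")
  m <- m[scored, , drop = FALSE]; labels <- labels[scored]
  macro <- macro6_of(labels); phase <- phase_of(labels)

  out <- numeric(0)
  for (s in c("W", "R", paste0("S", 1:4))) {
    rows <- macro == s
    mu <- va <- setNames(rep(NA_real_, length(nm)), nm)
    if (sum(rows) >= 1L) {
      mu <- apply(m[rows, , drop = FALSE], 2,
                  function(v) mean(v[is.finite(v)]))
      va <- apply(m[rows, , drop = FALSE], 2,
                  function(v) if (sum(is.finite(v)) > 1) var(v[is.finite(v)])
                              else NA_real_)
    }
    names(mu) <- paste0(s, "_mean_", nm)
    names(va) <- paste0(s, "_var_", nm)
    out <- c(out, mu, va)
  }
  deep <- macro %in% c("S3", "S4")
  for (f in c("cra", "crb", "crq", "crr")) {
    v <- m[deep, f]
    out[paste0("deep_", f)] <- if (any(is.finite(v))) mean(v[is.finite(v)])
                               else NA_real_
  }
  contrast <- function(rows) {
    a <- m[rows & phase %in% c("A1", "A2", "A3"), "cra"]
    na <- m[rows & phase == "NA", "cra"]
    if (any(is.finite(a)) && any(is.finite(na)))
      mean(a[is.finite(a)]) - mean(na[is.finite(na)])
    else NA_real_
  }
  for (s in paste0("S", 1:4))
    out[paste0(s, "_a_na_cra")] <- contrast(macro == s)
  out["all_a_na_cra"] <- contrast(macro %in% paste0("S", 1:4))
  nan_to_na <- is.nan(out)
  out[nan_to_na] <- NA_real_
  structure(out, class = c("subject_summary", "numeric"))
}

#' Train the subject-level diagnoser
#'
#' Radial-basis SVM over standardized subject summaries; missing entries
#' are imputed with training medians and constant columns dropped. The cost
#' and kernel width are chosen by a small inner 3-fold grid search.
#'
#' @param summaries matrix (subjects x summary entries) or list of
#'   `subject_summary` vectors.
#' @param groups group label per subject (healthy / insomnia / narcolepsy).
#' @param seed RNG seed for the inner folds.
#' @param costs,gammas grids for the search (gammas scale the 1/d default).
#' @return object of class `cap_diagnoser`.
#' @export
train_diagnoser <- function(summaries, groups, seed = 1L,
                            costs = c(1, 10, 100),
                            gammas = c(0.1, 1, 10)) {
  X <- if (is.list(summaries)) do.call(rbind, summaries) else as.matrix(summaries)
  groups <- factor(as.character(groups))
  assert_that(nrow(X) == length(groups), "one group per summary required")
  assert_that(nlevels(droplevels(groups)) >= 2L,
              "need at least two groups to train")
  tb <- table(droplevels(groups))
  assert_that(all(tb >= 3L), "need at least 3 subjects per group")

  med <- apply(X, 2, function(v) median(v[is.finite(v)]))
  med[!is.finite(med)] <- 0
  X <- impute_columns(X, med)
  keep <- apply(X, 2, function(v) sd(v) > 1e-12)
  Xk <- X[, keep, drop = FALSE]
  d <- ncol(Xk)

  set.seed(seed)
  fold <- sample(rep_len(1:3, nrow(Xk)))
  best <- NULL; best_acc <- -1
  for (co in costs) for (ga in gammas / d) {
    acc <- 0
    for (f in 1:3) {
      tr <- fold != f
      if (nlevels(droplevels(groups[tr])) < 2L) next
      fit <- e1071::svm(Xk[tr, , drop = FALSE], droplevels(groups[tr]),
                        kernel = "radial", cost = co, gamma = ga,
                        scale = TRUE)
      acc <- acc + mean(predict(fit, Xk[!tr, , drop = FALSE]) == groups[!tr])
    }
    if (acc > best_acc) { best_acc <- acc; best <- c(cost = co, gamma = ga) }
  }
  fit <- e1071::svm(Xk, droplevels(groups), kernel = "radial",
                    cost = best["cost"], gamma = best["gamma"],
                    scale = TRUE, decision.values = TRUE)
  structure(list(svm = fit, impute = med, keep = keep,
                 hyper = best, levels = levels(droplevels(groups)),
                 seed = seed),
            class = "cap_diagnoser")
}

#' Diagnose a subject from its summary
#'
#' @param model a `cap_diagnoser`.
#' @param summary a `subject_summary` (or matrix of them, one per row).
#' @return data.frame with `group` and the pairwise decision values.
#' @export
diagnose <- function(model, summary) {
  X <- if (is.null(dim(summary))) matrix(summary, nrow = 1,
                                         dimnames = list(NULL, names(summary)))
       else as.matrix(summary)
  X <- impute_columns(X, model$impute)
  Xk <- X[, model$keep, drop = FALSE]
  pr <- predict(model$svm, Xk, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  data.frame(group = as.character(pr), dv, check.names = FALSE)
}

#' Subject training library
#'
#' A versioned store of subject summaries with confirmed diagnoses.
#' Appending recomputes nothing implicitly: retraining happens only when
#' [train_diagnoser()] is called on the library contents.
#'
#' @param summaries matrix of summaries (0-row matrix allowed).
#' @param groups confirmed group per subject.
#' @param ids unique subject identifiers.
#' @return object of class `cap_library`.
#' @export
subject_library <- function(summaries = NULL, groups = character(0),
                            ids = character(0)) {
  if (is.null(summaries)) summaries <- matrix(numeric(0), 0, 0)
  structure(list(summaries = summaries, groups = as.character(groups),
                 ids = as.character(ids), version = 1L),
            class = "cap_library")
}

#' Append a confirmed subject to the library
#'
#' @param library a `cap_library`.
#' @param summary the subject's `subject_summary`.
#' @param group the confirmed diagnosis.
#' @param id unique subject identifier.
#' @return the updated library (version incremented).
#' @export
update_library <- function(library, summary, group, id) {
  assert_that(inherits(library, "cap_library"), "library must be a cap_library")
  assert_that(!(id %in% library$ids), paste0("duplicate subject id: ", id))
  v <- as.numeric(summary)
  names(v) <- names(summary)
  if (nrow(library$summaries) > 0L) {
    assert_that(length(v) == ncol(library$summaries),
                "summary dimension does not match the library")
    library$summaries <- rbind(library$summaries, v)
  } else {
    library$summaries <- matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  }
  library$groups <- c(library$groups, as.character(group))
  library$ids <- c(library$ids, as.character(id))
  library$version <- library$version + 1L
  library
}

#' Read / write a subject library
#'
#' JSON on disk; numeric precision is preserved to full double precision.
#' @param library a `cap_library`.
#' @param path file path.
#' @return `read_library` returns a `cap_library`.
#' @export
write_library <- function(library, path) {
  obj <- list(version = library$version, ids = library$ids,
              groups = library$groups,
              columns = colnames(library$summaries),
              summaries = unname(apply(library$summaries, 1, as.numeric,
                                       simplify = FALSE)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.matrix(obj$summaries)) obj$summaries
       else if (length(obj$summaries)) do.call(rbind, obj$summaries)
       else matrix(numeric(0), 0, 0)
  if (length(obj$columns)) colnames(m) <- obj$columns
  lib <- subject_library(m, obj$groups %||% character(0),
                         obj$ids %||% character(0))
  lib$version <- obj$version %||% 1L
  lib
}
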