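## Two-layer random-forest sleep/CAP stager: layer 1 separates the six
## macro stages (W, R, S1..S4); a per-stage layer 2 resolves the CAP phase
## (NA/A1/A2/A3) of epochs assigned to an NREM stage.

#' Select training epochs by label stability
#'
#' For the WAKE / LIGHT (S1, S2) / DEEP (S3, S4) macro classes, only epochs
#' inside runs of at least `min_run` identical macro labels (10 minutes at
#' 30-s epochs) are retained, so the stage classifier trains on
#' unambiguous, stationary stretches. REM epochs and all A-phase epochs are
#' always retained (the A-phase layers use every labelled epoch).
#'
#' @param labels stage labels (18-class).
#' @param min_run minimum run length in epochs (default 20).
#' @return sorted integer indices of selected epochs (possibly empty, with
#'   a warning).
#' @export
select_training_epochs <- function(labels, min_run = 20L) {
  labels <- as.character(labels)
  m3 <- macro3_of(labels)
  r <- rle(m3)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- logical(length(labels))
  for (k in seq_along(r$values)) {
    keep <- r$values[k] == "REM" ||
      (r$values[k] %in% c("WAKE", "LIGHT", "DEEP") && r$lengths[k] >= min_run)
    if (keep) sel[starts[k]:ends[k]] <- TRUE
  }
  sel[phase_of(labels) %in% c("A1", "A2", "A3")] <- TRUE
  if (!any(sel)) warning("no training epochs selected")
  which(sel)
}

#' Compensate outlying feature values
#'
#' Any feature outside `median +/- n_mad * MAD` (statistics from the
#' training set) is first, when a `repreprocess` callback is supplied,
#' given one chance to be recomputed from its source fragment; values still
#' outside the range are winsorised to the boundary. At most two passes;
#' idempotent (a second call is a no-op).
#'
#' @param x numeric feature matrix or data.frame (features in columns).
#' @param stats optional list with `med` and `mad` vectors (computed from
#'   `x` when NULL); pass the training statistics when compensating new
#'   data. The scale is the scaled MAD floored at its Gaussian-equivalent
#'   (0.6745 SD): spike-like features (movement bursts, CRA variance) have
#'   near-zero MAD although their spread is genuine, and a raw-MAD gate
#'   would winsorise the informative tail away.
#' @param n_mad gate width in scaled MADs (default 5).
#' @param repreprocess optional function `(x, bad_matrix) -> x` that
#'   re-derives flagged values from the underlying signals.
#' @return object like `x` with attributes `n_winsorized` and `stats`.
#' @export
compensate_outliers <- function(x, stats = NULL, n_mad = 5,
                                repreprocess = NULL) {
  df <- is.data.frame(x)
  m <- as.matrix(x)
  stats <- stats %||% list(
    med = apply(m, 2, median, na.rm = TRUE),
    mad = pmax(apply(m, 2, mad, na.rm = TRUE),
               0.6745 * apply(m, 2, sd, na.rm = TRUE)))
  lo <- stats$med - n_mad * stats$mad
  hi <- stats$med + n_mad * stats$mad
  flag_bad <- function(m) {
    b <- sweep(m, 2, lo, "<") | sweep(m, 2, hi, ">")
    b & !is.na(b)
  }
  bad <- flag_bad(m)
  if (any(bad) && !is.null(repreprocess)) {
    m <- as.matrix(repreprocess(m, bad))
    bad <- flag_bad(m)
  }
  n_win <- sum(bad)
  if (n_win > 0) {
    lom <- matrix(lo, nrow(m), ncol(m), byrow = TRUE)
    him <- matrix(hi, nrow(m), ncol(m), byrow = TRUE)
    m[bad & m < lom] <- lom[bad & m < lom]
    m[bad & m > him] <- him[bad & m > him]
  }
  out <- if (df) { y <- x; y[] <- m; y } else m
  attr(out, "n_winsorized") <- n_win
  attr(out, "stats") <- stats
  out
}

impute_columns <- function(m, fill) {
  for (j in seq_len(ncol(m))) {
    miss <- !is.finite(m[, j])
    if (any(miss)) m[miss, j] <- fill[j]
  }
  m
}

fit_forest <- function(m, y, seed, num_trees, class_weights = TRUE) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) {
    warning("layer degenerates to the majority class (single class present)")
    return(structure(list(majority = levels(y)[1] %||% NA_character_),
                     class = "majority_classifier"))
  }
  w <- if (class_weights) {
    tb <- table(y); as.numeric(sum(tb) / (nlevels(y) * tb))
  } else NULL
  dat <- data.frame(m, .y = y, check.names = FALSE)
  ranger::ranger(dependent.variable.name = ".y", data = dat,
                 num.trees = num_trees,
                 mtry = max(1L, floor(sqrt(ncol(m)))),
                 seed = seed, num.threads = 1L,
                 class.weights = w, verbose = FALSE)
}

predict_forest <- function(fit, m) {
  if (inherits(fit, "majority_classifier"))
    return(rep(fit$majority, nrow(m)))
  as.character(predict(fit, data.frame(m, check.names = FALSE),
                       num.threads = 1L)$predictions)
}

## Phase layer for one NREM stage: a balanced binary A/NA probability
## forest operated at the equal-recall threshold estimated from its own
## out-of-bag predictions (A-phases are ~1:4 events; the argmax operating
## point under-detects them), then a subtype forest over the A epochs.
fit_phase_layer <- function(m, phase, seed, num_trees) {
  is_a <- factor(ifelse(phase == "NA", "NA", "A"), levels = c("A", "NA"))
  if (nlevels(droplevels(is_a)) < 2L) {
    warning("phase layer degenerates to the majority class")
    return(structure(list(majority = as.character(phase[1]) %||% "NA"),
                     class = "majority_classifier"))
  }
  tb <- table(is_a)
  w <- as.numeric(sum(tb) / (2 * tb))
  dat <- data.frame(m, .y = is_a, check.names = FALSE)
  bin <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = num_trees,
                        mtry = max(1L, floor(sqrt(ncol(m)))),
                        seed = seed, num.threads = 1L, class.weights = w,
                        probability = TRUE, verbose = FALSE)
  oob <- bin$predictions[, "A"]
  ths <- seq(0.05, 0.95, by = 0.01)
  gap <- vapply(ths, function(th) {
    abs(mean(oob[is_a == "A"] > th) - mean(oob[is_a == "NA"] <= th))
  }, numeric(1))
  th <- ths[which.min(gap)]
  sub <- fit_forest(m[is_a == "A", , drop = FALSE],
                    phase[is_a == "A"], child_seed(seed, 9L), num_trees)
  structure(list(binary = bin, threshold = th, subtype = sub),
            class = "phase_layer")
}

predict_phase_layer <- function(fit, m) {
  if (inherits(fit, "majority_classifier"))
    return(rep(fit$majority, nrow(m)))
  pr <- predict(fit$binary, data.frame(m, check.names = FALSE),
                num.threads = 1L)$predictions[, "A"]
  out <- rep("NA", nrow(m))
  hit <- pr > fit$threshold
  if (any(hit)) out[hit] <- predict_forest(fit$subtype,
                                           m[hit, , drop = FALSE])
  out
}

#' Train the two-layer sleep/CAP stager
#'
#' Layer 1 is a random forest over the 23 characteristics predicting the
#' six macro stages, trained on the stability-selected epochs; layer 2 is
#' one forest per NREM stage predicting the CAP phase (NA/A1/A2/A3) from
#' all epochs of that stage. Missing feature values are imputed with
#' per-class training medians (global medians at prediction time) and
#' outliers are compensated with the training statistics.
#'
#' @param features data.frame or matrix holding the 23 characteristics
#'   (columns of [cap_feature_names()]`("all")`; extra columns are ignored).
#' @param labels 18-class stage labels, one per row.
#' @param seed RNG seed for the forests.
#' @param num_trees trees per forest (default 500).
#' @param select apply [select_training_epochs()] to layer 1 (default TRUE).
#' @param min_run run length for the selection rule.
#' @param class_weights inverse-frequency class weights in layer 1
#'   (default TRUE).
#' @return object of class `cap_stager`.
#' @export
train_stager <- function(features, labels, seed = 17L, num_trees = 500L,
                         select = TRUE, min_run = 20L,
                         class_weights = TRUE) {
  nm <- intersect(cap_feature_names("all"), colnames(features))
  assert_that(length(nm) >= 2L, "features must contain the named feature columns")
  m <- as.matrix(as.data.frame(features)[, nm, drop = FALSE])
  storage.mode(m) <- "double"
  labels <- as.character(labels)
  assert_that(nrow(m) == length(labels), "one label per feature row required")
  lab_ok <- !is.na(labels)
  m <- m[lab_ok, , drop = FALSE]; labels <- labels[lab_ok]

  # per-class median imputation, then global-median fallback
  glob_med <- apply(m, 2, function(v) median(v[is.finite(v)]))
  glob_med[!is.finite(glob_med)] <- 0
  for (cl in unique(labels)) {
    rows <- labels == cl
    med <- apply(m[rows, , drop = FALSE], 2, function(v) median(v[is.finite(v)]))
    med[!is.finite(med)] <- glob_med[!is.finite(med)]
    m[rows, ] <- impute_columns(m[rows, , drop = FALSE], med)
  }
  m <- impute_columns(m, glob_med)
  m <- compensate_outliers(m)
  out_stats <- attr(m, "stats")

  sel <- if (select) select_training_epochs(labels, min_run = min_run)
         else seq_along(labels)
  macro <- macro6_of(labels)
  l1 <- fit_forest(m[sel, , drop = FALSE], macro[sel], seed, num_trees,
                   class_weights = class_weights)
  l2 <- list()
  for (s in paste0("S", 1:4)) {
    rows <- macro == s
    if (!any(rows)) {
      warning(sprintf("no epochs of stage %s in training data", s))
      l2[[s]] <- structure(list(majority = "NA"), class = "majority_classifier")
      next
    }
    l2[[s]] <- fit_phase_layer(m[rows, , drop = FALSE],
                               phase_of(labels)[rows],
                               child_seed(seed, match(s, paste0("S", 1:4))),
                               num_trees)
  }
  structure(list(layer1 = l1, layer2 = l2, feature_names = nm,
                 impute = glob_med, outlier_stats = out_stats,
                 seed = seed, num_trees = num_trees),
            class = "cap_stager")
}

#' @export
print.cap_stager <- function(x, ...) {
  cat(sprintf("<cap_stager: %d features, %d trees, seed %d>\n",
              length(x$feature_names), x$num_trees, x$seed))
  invisible(x)
}

#' Classify epochs into the 18 sleep/CAP states
#'
#' Applies layer 1 to every epoch; epochs predicted S1-S4 are passed to
#' that stage's phase forest. Wake and REM epochs carry no CAP phase.
#'
#' @param model a `cap_stager`.
#' @param features feature table as in [train_stager()].
#' @return factor of 18-class labels.
#' @export
classify_stages <- function(model, features) {
  m <- as.matrix(as.data.frame(features)[, model$feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  m <- impute_columns(m, model$impute)
  m <- compensate_outliers(m, stats = model$outlier_stats)
  macro <- predict_forest(model$layer1, m)
  out <- macro
  for (s in paste0("S", 1:4)) {
    rows <- macro == s
    if (!any(rows)) next
    ph <- predict_phase_layer(model$layer2[[s]], m[rows, , drop = FALSE])
    out[rows] <- make_label(s, ph)
  }
  as_stage_factor(out)
}
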