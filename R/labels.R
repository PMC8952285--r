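## The 18-state sleep/CAP label set and helpers for moving between the full
## labels, the 6 macro stages and the wake/light/deep/REM grouping.

#' The 18 sleep/CAP stage labels
#'
#' Wake and REM carry no CAP phase; each NREM stage S1-S4 is split into the
#' non-A phase (`NA`) and the three A-phase subtypes `A1`, `A2`, `A3`,
#' giving exactly 18 classes. The order (W, R, then S1..S4 each as
#' NA, A1, A2, A3) is the canonical class order used by transition matrices
#' and confusion matrices throughout the package.
#'
#' @return character vector of length 18.
#' @export
#' @examples
#' cap_stage_levels()
cap_stage_levels <- function() {
  c("W", "R",
    as.vector(t(outer(paste0("S", 1:4), c("NA", "A1", "A2", "A3"),
                      paste, sep = "_"))))
}

#' Coerce labels to the 18-class factor
#'
#' @param x character or factor of stage labels.
#' @return factor with the 18 canonical levels.
#' @export
as_stage_factor <- function(x) {
  lv <- cap_stage_levels()
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  assert_that(length(bad) == 0L,
              paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  factor(x, levels = lv)
}

#' Split 18-class labels into sleep stage and CAP phase
#'
#' @param x stage labels (character or factor).
#' @return `stage_of`: one of W, R, S1..S4. `phase_of`: one of
#'   `"-"` (wake/REM), `"NA"`, `"A1"`, `"A2"`, `"A3"`.
#' @export
stage_of <- function(x) sub("_.*$", "", as.character(x))

#' @rdname stage_of
#' @export
phase_of <- function(x) {
  x <- as.character(x)
  ifelse(grepl("_", x), sub("^.*_", "", x), "-")
}

#' @rdname stage_of
#' @param stage stage component (W, R, S1..S4).
#' @param phase phase component ("-", NA-phase or A subtype).
#' @export
make_label <- function(stage, phase) {
  n <- max(length(stage), length(phase))
  stage <- rep_len(as.character(stage), n)
  phase <- rep_len(as.character(phase), n)
  ifelse(stage %in% c("W", "R"), stage, paste(stage, phase, sep = "_"))
}

#' Macro groupings of the 18 classes
#'
#' `macro6_of` collapses to the six classic stages (W, R, S1..S4);
#' `macro3_of` collapses NREM to WAKE/LIGHT/DEEP/REM, the grouping used for
#' training-epoch selection.
#' @param x stage labels.
#' @return character vector.
#' @export
macro6_of <- function(x) stage_of(x)

#' @rdname macro6_of
#' @export
macro3_of <- function(x) {
  s <- stage_of(x)
  out <- rep(NA_character_, length(s))
  out[s == "W"] <- "WAKE"
  out[s == "R"] <- "REM"
  out[s %in% c("S1", "S2")] <- "LIGHT"
  out[s %in% c("S3", "S4")] <- "DEEP"
  out
}

#' Names of the epoch feature sets
#'
#' The base vector has 21 entries: 3 body-movement, 12 heart-rate-variability
#' and 6 resonance-index features. The two Markov stability features bring
#' the full characteristic count to 23.
#'
#' @param set one of "base" (21), "all" (23), "bm", "hrv", "cri", "stability".
#' @return character vector of feature names.
#' @export
cap_feature_names <- function(set = c("base", "all", "bm", "hrv", "cri",
                                      "stability")) {
  set <- match.arg(set)
  bm  <- c("bm_var", "bm_apen", "bm_sampen")
  hrv <- c("sdnn", "rmssd", "pnn50", "vlf", "lf", "hf", "lf_hf",
           "sd1", "sd2", "sd1_sd2", "sampen", "apen")
  cri <- c("cra", "crb", "crq", "crr", "cra_var", "cra_ent")
  stab <- c("stab_diag", "stab_colsum")
  switch(set,
         bm = bm, hrv = hrv, cri = cri, stability = stab,
         base = c(bm, hrv, cri),
         all = c(bm, hrv, cri, stab))
}
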