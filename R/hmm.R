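## Supervised 18-state hidden Markov model over the CRA observation
## sequence: transition matrix estimated by bigram counting of the labelled
## state sequence, Gaussian emissions per state, Viterbi decoding, and the
## two Markov stability features (transition-matrix diagonal and column sum
## of the decoded state).

#' Train the 18-state CRA hidden Markov model
#'
#' Supervised estimation: `a_ij` is the fraction of transitions out of
#' state i that land in state j, counted over the labelled epoch sequence;
#' emissions are per-state Gaussians on CRA. Rows of states never observed
#' (or with no successor) are set to uniform and flagged.
#'
#' @param cra numeric CRA sequence (one value per epoch; NA allowed), or a
#'   list of per-subject sequences.
#' @param labels stage labels aligned with `cra` (same shape).
#' @return object of class `cap_hmm`: `trans` (18 x 18 row-stochastic
#'   matrix), `emission` (per-state mean/sd data.frame), `init` (empirical
#'   state frequencies), `unvisited` (states whose row was uniform-filled).
#' @export
train_hmm <- function(cra, labels) {
  if (!is.list(cra)) { cra <- list(cra); labels <- list(labels) }
  assert_that(length(cra) == length(labels),
              "cra and labels must have the same number of sequences")
  lv <- cap_stage_levels()
  K <- length(lv)
  counts <- matrix(0, K, K, dimnames = list(lv, lv))
  all_cra <- numeric(0); all_lab <- character(0)
  for (s in seq_along(cra)) {
    assert_that(length(cra[[s]]) == length(labels[[s]]),
                "each cra sequence must align with its labels")
    assert_that(length(labels[[s]]) >= 2L, "need at least 2 epochs")
    f <- as_stage_factor(labels[[s]])
    i <- as.integer(f[-length(f)]); j <- as.integer(f[-1])
    keep <- !is.na(i) & !is.na(j)
    for (t in which(keep)) counts[i[t], j[t]] <- counts[i[t], j[t]] + 1
    all_cra <- c(all_cra, cra[[s]]); all_lab <- c(all_lab, as.character(f))
  }
  rs <- rowSums(counts)
  trans <- counts
  unvisited <- lv[rs == 0]
  trans[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  trans[rs == 0, ] <- 1 / K
  g_mean <- mean(all_cra, na.rm = TRUE)
  g_sd <- max(sd(all_cra, na.rm = TRUE), 1e-6)
  emission <- data.frame(state = lv, mean = g_mean, sd = g_sd)
  for (k in seq_len(K)) {
    v <- all_cra[all_lab == lv[k] & !is.na(all_cra)]
    if (length(v) >= 2L) {
      emission$mean[k] <- mean(v)
      emission$sd[k] <- max(sd(v), 1e-6)
    } else if (length(v) == 1L) emission$mean[k] <- v
  }
  tab <- table(factor(all_lab, levels = lv))
  init <- as.numeric(tab) / max(sum(tab), 1)
  init[init == 0] <- 1e-6
  init <- init / sum(init)
  structure(list(trans = trans, emission = emission, init = init,
                 levels = lv, unvisited = unvisited),
            class = "cap_hmm")
}

#' @export
print.cap_hmm <- function(x, ...) {
  cat(sprintf("<cap_hmm: %d states, %d unvisited>\n",
              length(x$levels), length(x$unvisited)))
  invisible(x)
}

#' Viterbi decoding of the state sequence from CRA
#'
#' Maximum-probability state path under the trained transition matrix and
#' Gaussian emissions. Missing CRA values contribute no emission evidence
#' (the path is carried by the transition structure alone).
#'
#' @param hmm a `cap_hmm`.
#' @param cra numeric CRA sequence.
#' @return factor of decoded states (18 levels); NULL if `cra` is empty.
#' @export
viterbi_decode <- function(hmm, cra) {
  n <- length(cra)
  if (n == 0L) return(NULL)
  K <- length(hmm$levels)
  logA <- log(pmax(hmm$trans, 1e-12))
  emis <- function(t) {
    if (is.na(cra[t])) rep(0, K)
    else dnorm(cra[t], hmm$emission$mean, hmm$emission$sd, log = TRUE)
  }
  delta <- log(hmm$init) + emis(1)
  psi <- matrix(0L, n, K)
  for (t in seq_len(n)[-1]) {
    m <- delta + logA                 # K x K: from-state rows
    best <- apply(m, 2, which.max)
    delta <- m[cbind(best, seq_len(K))] + emis(t)
    psi[t, ] <- best
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in rev(seq_len(n - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  factor(hmm$levels[path], levels = hmm$levels)
}

#' Markov stability features
#'
#' For each epoch, Viterbi-decodes the state from the CRA sequence and
#' emits the transition-matrix diagonal entry of that state (its
#' self-persistence) and the sum of its column (how strongly the chain
#' flows into it) - the two stability characteristics appended to the
#' 21-feature vector.
#'
#' @param hmm a trained `cap_hmm`.
#' @param cra numeric CRA sequence.
#' @return matrix with `length(cra)` rows and columns `stab_diag`,
#'   `stab_colsum`; all-NA when no CRA value is available.
#' @export
stability_features <- function(hmm, cra) {
  nm <- cap_feature_names("stability")
  out <- matrix(NA_real_, length(cra), 2L, dimnames = list(NULL, nm))
  if (length(cra) == 0L || all(is.na(cra))) return(out)
  path <- as.integer(viterbi_decode(hmm, cra))
  out[, 1] <- diag(hmm$trans)[path]
  out[, 2] <- colSums(hmm$trans)[path]
  out
}
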