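## Approximate and sample entropy, vectorised (pairwise Chebyshev distances
## over the embedding), fast enough to run per 30-s epoch across a full
## night. Conventions: m = 2, r = 0.2 * SD unless stated; a flat signal has
## entropy defined as 0.

cheb_counts <- function(x, m, r) {
  # C[i, j] = 1 if the length-m templates at i and j match within r
  n <- length(x)
  N <- n - m + 1L
  if (N < 2L) return(NULL)
  D <- abs(outer(x, x, "-"))
  C <- D[seq_len(N), seq_len(N)]
  if (m > 1L) for (k in seq_len(m - 1L)) {
    C <- pmax(C, D[seq_len(N) + k, seq_len(N) + k])
  }
  C <= r
}

## Chebyshev template-distance matrices for lengths m and m+1, sharing one
## pairwise distance matrix (the hot path computes ApEn and SampEn together).
cheb_pair <- function(x, m, r) {
  n <- length(x)
  if (n < m + 2L) return(NULL)
  D <- abs(outer(x, x, "-"))
  Nm <- n - m + 1L
  Cm <- D[seq_len(Nm), seq_len(Nm)]
  if (m > 1L) for (k in seq_len(m - 1L)) {
    Cm <- pmax(Cm, D[seq_len(Nm) + k, seq_len(Nm) + k])
  }
  Nm1 <- n - m
  Cm1 <- pmax(Cm[seq_len(Nm1), seq_len(Nm1)],
              D[seq_len(Nm1) + m, seq_len(Nm1) + m])
  list(Cm = Cm <= r, Cm1 = Cm1 <= r)
}

#' Approximate and sample entropy together
#'
#' Computes both entropies of one series sharing the pairwise distance
#' work; identical to calling [approx_entropy()] and [sample_entropy()]
#' separately.
#' @inheritParams approx_entropy
#' @return named numeric `c(apen, sampen)`.
#' @export
entropy_pair <- function(x, m = 2L, r = NULL) {
  x <- as.numeric(x)
  s <- sd_pop(x)
  if (!is.finite(s) || s < 1e-12) return(c(apen = 0, sampen = 0))
  r <- r %||% (0.2 * s)
  cc <- cheb_pair(x, m, r)
  if (is.null(cc)) return(c(apen = NA_real_, sampen = NA_real_))
  Nm1 <- ncol(cc$Cm1)
  # ApEn: phi(m) - phi(m+1), self-matches included
  phim <- mean(log(rowMeans(cc$Cm)))
  phim1 <- mean(log(rowMeans(cc$Cm1)))
  apen <- phim - phim1
  # SampEn: counts over the common N = n - m templates, self-matches excluded
  B <- sum(cc$Cm[seq_len(Nm1), seq_len(Nm1)]) - Nm1
  A <- sum(cc$Cm1) - Nm1
  sampen <- if (B <= 0) NA_real_ else if (A <= 0) Inf else -log(A / B)
  c(apen = apen, sampen = sampen)
}

#' Approximate entropy
#'
#' ApEn(m, r) of Pincus: `phi(m) - phi(m+1)` where `phi(m)` is the mean log
#' fraction of template matches (self-matches included) within tolerance
#' `r` under the Chebyshev norm.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r tolerance (default `0.2 * sd(x)`); a flat series returns 0.
#' @return scalar entropy (nats).
#' @export
approx_entropy <- function(x, m = 2L, r = NULL) {
  x <- as.numeric(x)
  s <- sd_pop(x)
  if (!is.finite(s) || s < 1e-12) return(0)
  r <- r %||% (0.2 * s)
  phi <- function(mm) {
    M <- cheb_counts(x, mm, r)
    if (is.null(M)) return(NA_real_)
    mean(log(rowMeans(M)))
  }
  p1 <- phi(m); p2 <- phi(m + 1L)
  if (!is.finite(p1) || !is.finite(p2)) return(NA_real_)
  p1 - p2
}

#' Sample entropy
#'
#' SampEn(m, r) of Richman & Moorman: `-log(A/B)` with `B` the number of
#' length-m template matches and `A` the number of length-(m+1) matches,
#' self-matches excluded.
#'
#' @inheritParams approx_entropy
#' @return scalar entropy (nats); NA when no length-m matches exist.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  x <- as.numeric(x)
  s <- sd_pop(x)
  if (!is.finite(s) || s < 1e-12) return(0)
  r <- r %||% (0.2 * s)
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  # use N = n - m templates for both lengths (standard convention)
  N <- n - m
  Mm <- cheb_counts(x[seq_len(n - 1L)], m, r)[seq_len(N), seq_len(N)]
  B <- sum(Mm) - N
  Mm1 <- cheb_counts(x, m + 1L, r)
  A <- sum(Mm1) - nrow(Mm1)
  if (B <= 0) return(NA_real_)
  if (A <= 0) return(Inf)
  -log(A / B)
}

#' Shannon entropy of a binned sample
#'
#' Natural-log entropy of the histogram of `x` over `bins` equal-width bins
#' between `lim[1]` and `lim[2]` (values outside are clamped into the edge
#' bins). A degenerate (single-bin) distribution has entropy 0.
#'
#' @param x numeric values.
#' @param bins number of bins (default 10).
#' @param lim bin range; defaults to `range(x)`.
#' @return scalar in `[0, log(bins)]`.
#' @export
binned_entropy <- function(x, bins = 10L, lim = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  lim <- lim %||% range(x)
  if (diff(lim) <= 0) return(0)
  b <- pmin(pmax(floor((x - lim[1]) / diff(lim) * bins) + 1L, 1L), bins)
  p <- tabulate(b, bins) / length(b)
  p <- p[p > 0]
  -sum(p * log(p))
}
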