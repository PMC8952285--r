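`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Population standard deviation
#'
#' Standard deviation with the 1/n normalisation. Used for SDNN so that the
#' Poincare identities SD1 = RMSSD/sqrt(2) and SD1^2 + SD2^2 = 2*SDNN^2 hold
#' exactly.
#' @param x numeric vector
#' @return scalar
#' @keywords internal
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

## Derive a bounded child seed from a user seed (keeps values < 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
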