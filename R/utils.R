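# shared small helpers

#' Empirical quantiles with linear interpolation between closest ranks
#'
#' All quantiles and quartiles in this package use the same convention:
#' linear interpolation between order statistics (`stats::quantile`
#' type 7).
#'
#' @param x numeric vector.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @keywords internal
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

## trapezoid rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## derive a 32-bit sub-seed from a base seed and an index, both < 2^31
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 65521 * 31627 + as.numeric(index)) %%
               2147483647)
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
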