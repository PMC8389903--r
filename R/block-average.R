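#' Standard error of a time series by block averaging
#'
#' Splits the series into `n_blocks` contiguous blocks of equal length
#' (discarding the remainder at the end), and returns the standard error of
#' the block means. This is the package-wide error protocol for correlated
#' simulation time series; the default of five blocks matches the error bars
#' quoted for the activity-derivative curves.
#'
#' @param series Numeric vector (a scalar time series).
#' @param n_blocks Number of contiguous blocks, >= 2. Default 5.
#' @return Standard error of the block means (sd of block means / sqrt(n_blocks)).
#' @examples
#' block_average_error(rnorm(1e4), n_blocks = 5)
#' @export
block_average_error <- function(series, n_blocks = 5L) {
  stopifnot(is.numeric(series), length(n_blocks) == 1L, n_blocks >= 2L)
  n_blocks <- as.integer(n_blocks)
  n <- length(series)
  if (n < n_blocks) {
    stop("series length (", n, ") is shorter than n_blocks (", n_blocks, ")")
  }
  block_len <- n %/% n_blocks
  used <- series[seq_len(block_len * n_blocks)]
  means <- colMeans(matrix(used, nrow = block_len, ncol = n_blocks))
  stats::sd(means) / sqrt(n_blocks)
}

#' Block means of a time series
#'
#' Helper sharing the blocking convention of [block_average_error()]:
#' contiguous equal blocks, remainder discarded from the end.
#'
#' @inheritParams block_average_error
#' @return Numeric vector of `n_blocks` block means.
#' @export
block_means <- function(series, n_blocks = 5L) {
  stopifnot(is.numeric(series), length(n_blocks) == 1L, n_blocks >= 2L)
  n_blocks <- as.integer(n_blocks)
  n <- length(series)
  if (n < n_blocks) {
    stop("series length (", n, ") is shorter than n_blocks (", n_blocks, ")")
  }
  block_len <- n %/% n_blocks
  used <- series[seq_len(block_len * n_blocks)]
  colMeans(matrix(used, nrow = block_len, ncol = n_blocks))
}
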