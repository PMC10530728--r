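# Library sizes and read counts.

#' Draw library sizes from a left-truncated normal
#'
#' Sequencing depths are drawn from N(`mean`, `sd`^2) left-truncated at
#' `lower` (rejection sampling; acceptance ~0.99 at the defaults of mean
#' 10,000, sd 10,000/3 and truncation 2,000) and rounded to the nearest
#' integer.
#'
#' @param n Number of samples.
#' @param mean,sd Mean and sd of the untruncated normal.
#' @param lower Truncation point (all draws are >= `lower`).
#' @return Integer-valued numeric vector of length `n`.
#' @export
draw_library_sizes <- function(n, mean = 10000, sd = 10000 / 3,
                               lower = 2000) {
  stopifnot(n >= 1, lower > 0, mean > lower, sd >= 0)
  if (sd == 0) return(rep(round(mean), n))
  out <- numeric(0)
  while (length(out) < n) {
    batch <- stats::rnorm(max(n - length(out), 64L) * 2L, mean, sd)
    out <- c(out, batch[batch >= lower])
  }
  round(out[seq_len(n)])
}

#' Draw multinomial read counts
#'
#' Row `i` of the count matrix is a single multinomial draw with size
#' `library_sizes[i]` and probability vector `P[i, ]`, so row sums equal
#' library sizes exactly and counts are zero wherever `P` is zero.
#'
#' @param P `n` x `J` matrix of expected observed relative abundances.
#' @param library_sizes Length-`n` vector of positive integer depths.
#' @return `n` x `J` integer matrix.
#' @export
draw_counts <- function(P, library_sizes) {
  stopifnot(is.matrix(P), length(library_sizes) == nrow(P),
            all(library_sizes >= 1))
  n <- nrow(P)
  J <- ncol(P)
  counts <- matrix(0L, n, J)
  for (i in seq_len(n)) {
    counts[i, ] <- stats::rmultinom(1L, size = library_sizes[i],
                                    prob = P[i, ])[, 1L]
  }
  counts
}
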