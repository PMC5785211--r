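#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' (Hubert-Arabie form): 1 for identical partitions, ~0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b cluster labels (any atomic type), same length.
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(length(a))
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
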