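#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert-Arabie form), used to score planted-module recovery. 1 means
#' identical partitions up to renaming, 0 the chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}
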