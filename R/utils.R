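#' @useDynLib exococa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust as.dist median pchisq pt qnorm rnorm
#'   runif rbinom rnbinom predict sd t.test var wilcox.test quantile
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible child seed from a root seed
#'
#' All stage-level randomness is driven by small integer seeds derived
#' deterministically from one root seed, so no stage reads the global RNG
#' state left behind by another. Results stay inside the 32-bit integer
#' range R requires of `set.seed()`.
#'
#' @param seed integer root seed.
#' @param ... integers (or strings, hashed by character codes) identifying
#'   the sub-stream, e.g. a platform index and an iteration number.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    for (v in as.double(p)) h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used throughout to compare recovered subtypes with planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar; 1 for identical partitions, ~0 under independence.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

# canonicalise a label vector to integers 1..k in order of first appearance
relabel_first_appearance <- function(labels) {
  match(labels, unique(labels))
}
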