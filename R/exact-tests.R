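#' Hypergeometric tail probability
#'
#' Exact upper- or lower-tail probability for drawing `k` annotated genes
#' in a sample of `n` from a population of `N` genes of which `K` are
#' annotated: `over` is `P(X >= k)` and `under` is `P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed count (`0 <= k <= min(n, K)`).
#' @param n Sample (foreground) size.
#' @param K Annotated genes in the population.
#' @param N Population (background) size.
#' @param tail `"over"` or `"under"`.
#' @return A probability in `[0, 1]`. Vectorised over `k`, `n`, `K`, `N`.
#' @export
#' @examples
#' hypergeom_tail(4, 4, 5, 10, "over") # 5/210
hypergeom_tail <- function(k, n, K, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  ok <- k >= 0 & k <= n & n <= N & K <= N & k <= K
  if (any(!ok)) {
    abort("hypergeom_tail: need 0 <= k <= n <= N, K <= N and k <= K.")
  }
  if (tail == "over") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, capped at 1 and aligned with the input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test; the two-sided p-value sums the probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (the probability-mass rule).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5) # 2/252
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("fisher_exact_2x2: cells must be non-negative integers.")
  }
  if (sum(cells) == 0) {
    abort("fisher_exact_2x2: all-zero table.")
  }
  m <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  fisher.test(m)$p.value
}
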