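#' Upper-tail hypergeometric probability
#'
#' P(X >= x) where X counts marked elements in a draw of N from a universe
#' of U containing M marked elements:
#' `p = sum_{k=x}^{min(M,N)} C(M,k) C(U-M,N-k) / C(U,N)`.
#'
#' For small universes the tail is evaluated as a ratio of exact integer
#' binomial sums (all terms below 2^53, so the division is the only
#' rounding step); larger problems fall back to [stats::phyper()] with
#' `lower.tail = FALSE` at `x - 1`, which computes the same quantity.
#'
#' This single kernel backs both the miRNA sponge test
#' ([sponge_test()]) and Fisher over-representation ([fisher_enrichment()]).
#'
#' @param x observed count of marked elements (integer >= 0).
#' @param U universe size.
#' @param M number of marked elements in the universe.
#' @param N draw size.
#' @return the upper-tail probability in \[0, 1\]; `x = 0` gives exactly 1.
#' @export
hyper_upper_tail <- function(x, U, M, N) {
  stopifnot(length(x) == 1, length(U) == 1, length(M) == 1, length(N) == 1)
  if (any(c(x, U, M, N) %% 1 != 0)) stop("x, U, M, N must be integers")
  if (U < 1) stop("universe size U must be >= 1")
  if (M < 0 || N < 0 || M > U || N > U)
    stop("require 0 <= M <= U and 0 <= N <= U")
  if (x < 0 || x > min(M, N))
    stop("require 0 <= x <= min(M, N); got x = ", x,
         " with M = ", M, ", N = ", N)
  if (x == 0) return(1)
  if (lchoose(U, N) < 50 * log(2)) {
    k <- x:min(M, N)
    sum(choose(M, k) * choose(U - M, N - k)) / choose(U, N)
  } else {
    stats::phyper(x - 1, M, U - M, N, lower.tail = FALSE)
  }
}

#' Hypergeometric miRNA-sponge test
#'
#' Tests whether two candidate ceRNA partners share more regulator miRNAs
#' than expected by chance. For a gene pair (A, B) with regulator sets C and
#' D inside a universe of `U` miRNAs, the p-value is the upper-tail
#' probability of observing at least `x = |C intersect D|` shared regulators
#' when a set of size `N = |D|` is drawn at random from the universe
#' containing `M = |C|` marked miRNAs.
#'
#' The upper tail is taken at `x` itself (i.e. `1 - CDF(x - 1)`), so a pair
#' sharing no miRNA always scores p = 1. `tail = "at_x"` (default) selects
#' this behaviour; `tail = "above_x"` computes `1 - CDF(x)`, the literal
#' exceedance P(X > x), for comparison.
#'
#' @param x number of miRNAs shared by the two partners.
#' @param U total number of miRNAs identified (the universe).
#' @param M,N sizes of the two partners' regulator sets.
#' @param tail `"at_x"` (P(X >= x), default) or `"above_x"` (P(X > x)).
#' @return the sponge p-value.
#' @examples
#' sponge_test(3, U = 6, M = 3, N = 3)   # 1/20
#' sponge_test(0, U = 100, M = 10, N = 10)  # 1
#' @export
sponge_test <- function(x, U, M, N, tail = c("at_x", "above_x")) {
  tail <- match.arg(tail)
  if (tail == "above_x") {
    if (x >= min(M, N)) return(0)
    return(hyper_upper_tail(x + 1, U, M, N))
  }
  hyper_upper_tail(x, U, M, N)
}
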