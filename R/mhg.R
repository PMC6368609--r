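#' Minimal hypergeometric (mHG) enrichment test
#'
#' For a ranked list of N genes containing K members of a query set, the
#' mHG statistic is the minimum over all list prefixes n of the
#' hypergeometric upper tail
#' \deqn{HGT(k_n; N, K, n) = P(X \ge k_n),\quad X \sim
#'   Hypergeometric(N, K, n)}
#' where \eqn{k_n} is the number of set members in the top n. Because the
#' minimum is itself optimized over cutoffs, the statistic is not a valid
#' p-value; the exact p-value is the probability, over uniformly random
#' placements of the K members, that the minimum reaches a value at least
#' as extreme. It is computed by a dynamic program over the (n, k)
#' lattice: a random ranking is a lattice path from (0, 0) to (N, K) with
#' hypergeometric step probabilities, and the p-value is one minus the
#' probability of reaching (N, K) without entering any cell whose tail
#' probability is <= the observed statistic. O(N K) time and memory.
#'
#' @param membership logical vector along the ranked list (TRUE = gene is
#'   in the query set), best cutoff first.
#' @return list: \code{stat} (the mHG statistic), \code{p} (exact
#'   p-value), \code{n_opt} (smallest prefix length attaining the
#'   minimum), \code{N}, \code{K}. With K = 0, p = 1 by convention.
#' @export
mhg_test <- function(membership) {
  membership <- as.logical(membership)
  if (anyNA(membership)) stop("membership must not contain NA")
  N <- length(membership)
  K <- sum(membership)
  if (N < 1L) stop("empty ranked list")
  if (K == 0L)
    return(list(stat = 1, p = 1, n_opt = 0L, N = N, K = 0L))

  k_cum <- cumsum(membership)
  tails <- stats::phyper(k_cum - 1L, K, N - K, seq_len(N),
                         lower.tail = FALSE)
  stat <- min(tails)
  n_opt <- which(tails <= stat * (1 + 1e-12))[1L]

  if (stat >= 1) return(list(stat = 1, p = 1, n_opt = n_opt, N = N, K = K))

  # significant region of the lattice, with a relative tolerance so that
  # configurations tied with the observed minimum count as reached
  eps <- 1e-12
  # prob[k + 1] = P(path at (n, k) having avoided the region so far)
  prob <- c(1, rep(0, K))
  for (n in seq_len(N)) {
    new <- numeric(K + 1L)
    k_hi <- min(n - 1L, K)
    k_lo <- max(0L, n - 1L - (N - K))
    for (k in k_lo:k_hi) {
      p_here <- prob[k + 1L]
      if (p_here == 0) next
      p_member <- (K - k) / (N - n + 1L)
      new[k + 2L] <- new[k + 2L] + p_here * p_member
      new[k + 1L] <- new[k + 1L] + p_here * (1 - p_member)
    }
    # zero out cells inside the significant region at prefix length n
    ks <- max(0L, n - (N - K)):min(n, K)
    tail_nk <- stats::phyper(ks - 1L, K, N - K, n, lower.tail = FALSE)
    hit <- ks[tail_nk <= stat * (1 + eps)]
    if (length(hit)) new[hit + 1L] <- 0
    prob <- new
  }
  p <- min(1, max(stat, 1 - prob[K + 1L]))
  list(stat = stat, p = p, n_opt = n_opt, N = N, K = K)
}
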