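#' Upper-tail hypergeometric (one-sided Fisher) p-value
#'
#' Probability of drawing at least `k` marked elements when `n` elements are
#' drawn without replacement from a universe of `N` containing `K` marked
#' ones. This is the one-sided Fisher exact test for enrichment on a 2x2
#' table with fixed margins.
#'
#' @param k observed overlap.
#' @param K marked elements in the universe (e.g. genes in the GO term).
#' @param n draws (e.g. targets of the TF).
#' @param N universe size.
#' @return upper-tail p-value; vectorized over its arguments.
#' @export
fisherUpperTail <- function(k, K, n, N) {
  stopifnot(all(K <= N), all(n <= N), all(k >= 0))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U test with midranks. For small samples (both
#' groups of size at most `exactMax`) the p-value is computed by exhaustive
#' enumeration of all assignments of the pooled midranks, which is exact
#' also under ties; for larger samples the normal approximation with tie
#' correction (and no continuity correction) is used. The direction is read
#' from the rank sum: `"greater"` means `x` tends to be larger than `y`.
#'
#' @param x,y numeric vectors.
#' @param exactMax maximum per-group size for exact enumeration (default 8).
#' @return list with `U` (Mann-Whitney U for `x`), `p.value` (two-sided),
#'   `direction` (`"greater"`, `"less"`, or `"tied"`), and `exact`.
#' @export
rankSumTest <- function(x, y, exactMax = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])            # rank sum of x
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  direction <- if (U > mu) "greater" else if (U < mu) "less" else "tied"
  if (n1 <= exactMax && n2 <= exactMax) {
    ## exhaustive permutation of which pooled observations land in group x
    idx <- combn(n1 + n2, n1)
    Ws <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(Ws - (n1 * (n1 + n2 + 1) / 2)) >=
                abs(W - (n1 * (n1 + n2 + 1) / 2)) - 1e-9)
    return(list(U = U, p.value = p, direction = direction, exact = TRUE))
  }
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(list(U = U, p.value = 1, direction = "tied",
                             exact = FALSE))
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p.value = 2 * pnorm(-abs(z)), direction = direction,
       exact = FALSE)
}

#' Pooled two-proportion z-test
#'
#' Compares two binomial proportions x1/n1 and x2/n2 with the pooled
#' standard error (the classical "proportion comparison test"). Reports the
#' signed z (positive when the first proportion is larger) and the two-sided
#' normal p-value; a Fisher exact p on the same table is included for small
#' counts.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `p1`, `p2`, `z`, `p.value`, `p.fisher`.
#' @export
proportionTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
  list(p1 = p1, p2 = p2, z = z,
       p.value = 2 * pnorm(-abs(z)),
       p.fisher = stats::fisher.test(tab)$p.value)
}
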