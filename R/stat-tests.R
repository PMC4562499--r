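#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Exact conditional test: the two-sided p-value is the sum of
#' hypergeometric probabilities of tables (with the observed margins) no
#' more probable than the observed one. Degenerate margins give p = 1.
#'
#' @param table 2 x 2 matrix (or length-4 vector, filled by column) of
#'   non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  m <- matrix(as.numeric(table), nrow = 2)
  assert_that(all(m >= 0) && all(m == round(m)),
              "counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Two-sided rank-sum test for two independent groups
#'
#' Mid-ranks are used for ties. With a pooled size of at most
#' `exact_max` the p-value is exact, by enumeration of all group
#' assignments of the pooled ranks (two-sided by distance of the rank sum
#' from its null expectation); otherwise a normal approximation with tie
#' correction (no continuity correction) is used. When every pooled value
#' is identical the test is undefined and p = 1.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact_max maximum pooled size for the exact enumeration.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both groups must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  r <- rank(pooled)                       # mid-ranks
  nx <- length(x); ny <- length(y); n <- nx + ny
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  if (n <= exact_max) {
    combs <- combn(n, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    mean(abs(sums - ew) >= abs(w - ew) - 1e-9)
  } else {
    ties <- table(r)
    varw <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (varw <= 0) return(1)
    z <- (w - ew) / sqrt(varw)
    2 * pnorm(-abs(z))
  }
}

#' Upper tail of the Poisson distribution, continuously extended
#'
#' `P(X >= x)` for `X ~ Poisson(lambda)`. For integer `x` this equals the
#' exact tail sum `sum_{k >= x} e^{-lambda} lambda^k / k!`; for
#' non-integer `x` the regularized lower incomplete gamma function with
#' shape `x` and unit rate evaluated at `lambda` provides the standard
#' continuous interpolation, which is what evaluating a Poisson tail at a
#' real-valued RPKM requires. `x = 0` gives 1 by definition. With
#' `floor_x = TRUE` the statistic is floored to an integer first.
#'
#' @param x observed value(s), >= 0 (e.g. treatment RPKM).
#' @param lambda Poisson rate(s), >= 0 (e.g. control RPKM).
#' @param floor_x floor `x` to an integer before computing the tail.
#' @return tail probability, vectorised over `x` and `lambda`.
#' @export
poisson_tail <- function(x, lambda, floor_x = FALSE) {
  assert_that(all(x >= 0) && all(lambda >= 0),
              "`x` and `lambda` must be non-negative")
  if (floor_x) x <- floor(x)
  n <- max(length(x), length(lambda))
  x <- rep_len(x, n); lambda <- rep_len(lambda, n)
  p <- ifelse(x == 0, 1, pgamma(lambda, shape = x, lower.tail = TRUE))
  ## lambda = 0 with positive x: no events possible
  p[lambda == 0 & x > 0] <- 0
  p
}
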