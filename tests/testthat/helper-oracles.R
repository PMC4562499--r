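## Independent brute-force oracles used to freeze expected values.

## Two-sided Fisher p by direct hypergeometric enumeration over all
## tables with the observed margins (standard relative-error guard when
## comparing probabilities).
oracle_fisher <- function(m) {
  m <- matrix(as.numeric(m), nrow = 2)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  d <- dhyper(k, r1, n - r1, c1)
  sum(d[d <= dhyper(m[1, 1], r1, n - r1, c1) * (1 + 1e-7)])
}

## Exact two-sided rank-sum p by complete enumeration of group
## assignments of the pooled mid-ranks.
oracle_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  r <- rank(pooled)
  nx <- length(x); n <- length(pooled)
  ew <- nx * (n + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - ew)
  sums <- colSums(matrix(r[utils::combn(n, nx)], nrow = nx))
  mean(abs(sums - ew) >= obs - 1e-9)
}

## Poisson upper tail by direct series summation of P(X = k) for k >= x
## (in log space, so the far tail keeps full relative accuracy).
oracle_poisson_tail <- function(x, lambda) {
  if (x == 0) return(1)
  if (lambda == 0) return(0)
  k <- x:(x + 2000)
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

## Pearson chi-square statistic from the definition.
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

## Exhaustive nearest-feature scan with the declared tie-break.
oracle_nearest <- function(features, chrom, start, end) {
  best_id <- NA_character_; best_d <- Inf; best_start <- Inf
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != chrom) next
    d <- max(0, features$start[i] - end, start - features$end[i])
    if (d < best_d || (d == best_d && features$start[i] < best_start)) {
      best_d <- d; best_id <- features$gene_id[i]
      best_start <- features$start[i]
    }
  }
  list(gene_id = best_id,
       distance = if (is.infinite(best_d)) NA_integer_ else best_d)
}

## Does either mate share a k-mer with any reference sequence (either
## strand)? Direct substring scan, no index.
oracle_pair_mapped <- function(seq1, seq2, refs, k) {
  refs_both <- c(refs, orphanrna::revcomp(refs))
  for (s in c(seq1, seq2)) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("N", km, fixed = TRUE)) next
      if (any(grepl(km, refs_both, fixed = TRUE))) return(TRUE)
    }
  }
  FALSE
}

## Deterministic tiling reads over a template (exact coverage of both
## ends), packaged as read pairs for the assembler.
tiling_pairs <- function(template, read_len = 100, step = 50) {
  L <- nchar(template)
  starts <- unique(c(seq(1, L - read_len + 1, by = step), L - read_len + 1))
  reads <- substring(template, starts, starts + read_len - 1)
  q <- strrep("I", read_len)  # phred 40
  tibble::tibble(
    pair_id = sprintf("t:%04d", seq_along(starts)),
    seq1 = reads,
    seq2 = orphanrna::revcomp(reads),
    qual1 = q, qual2 = q
  )
}

## Small deterministic read-pair tibble builder for filter tests.
pair_row <- function(id, s1, s2, q1 = NULL, q2 = NULL) {
  q1 <- q1 %||% strrep("I", nchar(s1))
  q2 <- q2 %||% strrep("I", nchar(s2))
  tibble::tibble(pair_id = id, seq1 = s1, seq2 = s2, qual1 = q1, qual2 = q2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
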