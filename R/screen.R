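#' Build a strand-symmetric k-mer index over reference tiers
#'
#' Stand-in for a seed-based read aligner: a read "maps" to a tier when it
#' shares at least one exact k-mer (on either strand) with that tier. The
#' default seed length of 28 mirrors the seed length commonly used when
#' screening reads against genome, transcriptome, abundant-sequence and
#' bacterial/viral tiers.
#'
#' @param tiers named list; each element a named character vector of
#'   reference sequences (or a single FASTA path) forming one screening
#'   tier.
#' @param k seed length.
#' @return object of class `kmer_index`.
#' @export
kmer_index <- function(tiers, k = 28) {
  assert_that(length(tiers) > 0, "at least one reference tier is required")
  if (is.null(names(tiers)) || any(names(tiers) == "")) {
    names(tiers) <- paste0("tier", seq_along(tiers))
  }
  sets <- purrr::map(tiers, function(ref) {
    if (is.character(ref) && length(ref) == 1 && file.exists(ref)) {
      ref <- read_fasta(ref)
    }
    unique(unlist(lapply(c(ref, revcomp(ref)), seq_kmers, k = k),
                  use.names = FALSE))
  })
  structure(list(k = as.integer(k), tiers = sets), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "\n")
  for (nm in names(x$tiers)) {
    cat("  ", nm, ": ", length(x$tiers[[nm]]), " k-mers\n", sep = "")
  }
  invisible(x)
}

#' Sliding-window quality filter for read pairs
#'
#' A pair is kept only if neither mate contains an uncalled base (`N`) and
#' no sliding window of `ceiling(window_frac * read_len)` bases has mean
#' phred quality below `phred_threshold` in either mate. Defaults mirror
#' the conventional short-read cleaning parameters (window 15% of the read,
#' score 17).
#'
#' @param pairs read-pair tibble (`seq1`, `seq2`, `qual1`, `qual2`).
#' @param window_frac window length as a fraction of read length.
#' @param phred_threshold minimum acceptable window mean phred score.
#' @return logical vector, `TRUE` for pairs to keep.
#' @export
quality_filter <- function(pairs, window_frac = 0.15, phred_threshold = 17) {
  assert_that(window_frac > 0 && window_frac <= 1,
              "`window_frac` must lie in (0, 1]")
  mate_ok <- function(seq, qual) {
    purrr::map2_lgl(seq, qual, function(s, q) {
      n <- nchar(s)
      if (n == 0) stop("empty read sequence", call. = FALSE)
      if (grepl("N", s, fixed = TRUE)) return(FALSE)
      w <- ceiling(window_frac * n)
      qv <- phred_to_int(q)
      if (w >= n) return(mean(qv) >= phred_threshold)
      cs <- cumsum(c(0L, qv))
      wins <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
      min(wins) >= phred_threshold
    })
  }
  mate_ok(pairs$seq1, pairs$qual1) & mate_ok(pairs$seq2, pairs$qual2)
}

#' Remove PCR clones, keeping one representative per distinct pair
#'
#' Uniqueness is on the (seq1, seq2) pair of mate sequences; the
#' first-seen representative is kept and input order preserved.
#'
#' @param pairs read-pair tibble.
#' @return the deduplicated tibble.
#' @export
clone_filter <- function(pairs) {
  dplyr::distinct(pairs, .data$seq1, .data$seq2, .keep_all = TRUE)
}

#' Classify read pairs against a k-mer index
#'
#' A pair is `mapped` when either mate shares at least one exact k-mer
#' (either strand) with any tier; only pairs with both ends unmapped
#' survive screening. Mates shorter than `k` contribute no k-mers and
#' trigger a warning.
#'
#' @param pairs read-pair tibble.
#' @param index a [kmer_index()].
#' @return tibble with columns `pair_id`, `status` (`mapped`/`unmapped`)
#'   and `tier` (first tier hit, `NA` if unmapped).
#' @export
classify_pairs <- function(pairs, index) {
  assert_that(inherits(index, "kmer_index"), "`index` must be a kmer_index")
  k <- index$k
  if (nrow(pairs) == 0) {
    return(tibble(pair_id = character(0), status = character(0),
                  tier = character(0)))
  }
  if (any(nchar(pairs$seq1) < k | nchar(pairs$seq2) < k)) {
    warning("some mates are shorter than k = ", k,
            " and contribute no k-mers", call. = FALSE)
  }
  hit_tier <- function(s1, s2) {
    km <- c(seq_kmers(s1, k), seq_kmers(s2, k))
    for (nm in names(index$tiers)) {
      if (any(km %in% index$tiers[[nm]])) return(nm)
    }
    NA_character_
  }
  tier <- unname(purrr::map2_chr(unname(pairs$seq1), unname(pairs$seq2),
                                 hit_tier))
  tibble(pair_id = unname(pairs$pair_id),
         status = ifelse(is.na(tier), "unmapped", "mapped"),
         tier = tier)
}

#' Run the full screening cascade on a read library
#'
#' Applies, in order: the sliding-window quality filter, PCR-clone
#' removal, and the both-ends-unmapped rule against the k-mer index.
#' Returns the retained pairs plus per-stage accounting that always
#' satisfies `input = retained + removed`.
#'
#' @param pairs read-pair tibble.
#' @param index a [kmer_index()].
#' @inheritParams quality_filter
#' @return list with `retained` (read-pair tibble) and `stats` (tibble
#'   `stage`, `count`: input, low_quality, clones, mapped_<tier>, retained).
#' @export
screen_library <- function(pairs, index, window_frac = 0.15,
                           phred_threshold = 17) {
  n_input <- nrow(pairs)
  if (n_input == 0) {
    stats <- tibble(stage = c("input", "low_quality", "clones", "retained"),
                    count = 0L)
    return(list(retained = pairs, stats = stats))
  }
  keep_q <- quality_filter(pairs, window_frac, phred_threshold)
  hq <- pairs[keep_q, , drop = FALSE]
  uq <- clone_filter(hq)
  cls <- classify_pairs(uq, index)
  retained <- uq[cls$status == "unmapped", , drop = FALSE]
  tier_counts <- cls %>%
    filter(.data$status == "mapped") %>%
    count(.data$tier) %>%
    mutate(stage = paste0("mapped_", .data$tier)) %>%
    dplyr::select("stage", count = "n")
  stats <- dplyr::bind_rows(
    tibble(stage = "input", count = n_input),
    tibble(stage = "low_quality", count = n_input - nrow(hq)),
    tibble(stage = "clones", count = nrow(hq) - nrow(uq)),
    tier_counts,
    tibble(stage = "retained", count = nrow(retained))
  ) %>% mutate(count = as.integer(.data$count))
  list(retained = retained, stats = stats)
}
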