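#' Greedy overlap assembly of screened read pairs
#'
#' A deterministic greedy maximal-overlap assembler over the mates of the
#' retained pairs, considering both strands. Reads are deduplicated and
#' processed in canonical order (lexicographic by sequence, ties by pair
#' id); each seed read is extended right and left by the unused read with
#' the longest exact suffix-prefix overlap of at least `min_overlap`
#' bases. Reads containing `N` are ignored (exact overlaps only). Only
#' contigs strictly longer than `min_len` are returned, per the long
#' noncoding RNA length convention.
#'
#' @param pairs read-pair tibble.
#' @param min_overlap minimum exact overlap in bases (>= 16).
#' @param min_len contigs must be strictly longer than this.
#' @return transcript tibble with columns `id` (`asm|<n>`), `seq`,
#'   `length`, `members` (list-column; the contig's own id for initial
#'   assemblies).
#' @export
greedy_assemble <- function(pairs, min_overlap = 31, min_len = 200) {
  assert_that(min_overlap >= 16, "`min_overlap` must be >= 16")
  empty <- tibble(id = character(0), seq = character(0),
                  length = integer(0), members = list())
  if (nrow(pairs) == 0) return(empty)

  reads <- tibble(
    seq = c(pairs$seq1, pairs$seq2),
    pid = rep(pairs$pair_id, 2L)
  ) %>%
    filter(!stringr::str_detect(.data$seq, "N")) %>%
    group_by(.data$seq) %>%
    summarise(pid = min(.data$pid), .groups = "drop") %>%
    arrange(.data$seq, .data$pid)
  if (nrow(reads) == 0) return(empty)

  n <- nrow(reads)
  seqs <- reads$seq
  rcs <- revcomp(seqs)
  used <- rep(FALSE, n)
  mo <- as.integer(min_overlap)

  ## prefix index: first `mo` bases of each oriented read -> read indices
  pref <- new.env(hash = TRUE, parent = emptyenv())
  add_pref <- function(key, val) {
    cur <- get0(key, envir = pref, ifnotfound = NULL)
    assign(key, c(cur, val), envir = pref)
  }
  for (i in seq_len(n)) {
    if (nchar(seqs[i]) >= mo) {
      add_pref(substr(seqs[i], 1L, mo), i)          # forward: +i
      add_pref(substr(rcs[i], 1L, mo), -i)          # reverse: -i
    }
  }
  oriented <- function(j) if (j > 0) seqs[j] else rcs[-j]

  max_rl <- max(nchar(seqs))

  extend_right <- function(contig) {
    repeat {
      len <- nchar(contig)
      p_lo <- max(1L, len - max_rl + 1L)
      p_hi <- len - mo + 1L
      if (p_hi < p_lo) break
      extended <- FALSE
      for (p in p_lo:p_hi) {           # ascending p = longest overlap first
        key <- substr(contig, p, p + mo - 1L)
        cand <- get0(key, envir = pref, ifnotfound = NULL)
        if (is.null(cand)) next
        cand <- cand[!used[abs(cand)]]
        if (length(cand) == 0) next
        o <- len - p + 1L
        ok <- vapply(cand, function(j) {
          s <- oriented(j)
          nchar(s) >= o && substr(s, 1L, o) == substr(contig, p, len)
        }, logical(1))
        cand <- cand[ok]
        if (length(cand) == 0) next
        cseq <- vapply(cand, oriented, character(1))
        grows <- nchar(cseq) > o
        ## reads fully contained in the contig are consumed
        if (any(!grows)) used[abs(cand[!grows])] <<- TRUE
        if (!any(grows)) next
        ord <- order(cseq[grows], abs(cand[grows]))
        pick <- cand[grows][ord[1]]
        s <- oriented(pick)
        contig <- paste0(contig, substr(s, o + 1L, nchar(s)))
        used[abs(pick)] <<- TRUE
        extended <- TRUE
        break
      }
      if (!extended) break
    }
    contig
  }

  contigs <- character(0)
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    contig <- extend_right(seqs[i])
    contig <- revcomp(extend_right(revcomp(contig)))
    ## sweep reads contained in the finished contig
    un <- which(!used)
    if (length(un) > 0) {
      inside <- stringr::str_detect(contig, stringr::fixed(seqs[un])) |
        stringr::str_detect(contig, stringr::fixed(rcs[un]))
      used[un[inside]] <- TRUE
    }
    contigs <- c(contigs, contig)
  }

  contigs <- contigs[nchar(contigs) > min_len]
  if (length(contigs) == 0) return(empty)
  ## canonical strand and deterministic ids
  rc <- revcomp(contigs)
  contigs <- ifelse(contigs <= rc, contigs, rc)
  contigs <- sort(unique(contigs))
  tibble(id = sprintf("asm|%d", seq_along(contigs)),
         seq = contigs,
         length = nchar(contigs),
         members = as.list(sprintf("asm|%d", seq_along(contigs))))
}
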