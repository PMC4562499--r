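#' Extract both-ends-unmapped read pairs from a SAM file
#'
#' Reads a text SAM file and returns the pairs in which both mates carry
#' the unmapped flag (0x4) with a consistent mate-unmapped flag (0x8).
#' Mates stored on the reverse strand (0x10) are reverse-complemented
#' (and their quality strings reversed) back to the original read
#' orientation. Orphan records whose mate is missing are dropped with a
#' warning; lines with fewer than 11 fields are an error.
#'
#' @param path path to a SAM file.
#' @return read-pair tibble (`pair_id`, `seq1`, `seq2`, `qual1`, `qual2`).
#' @export
ingest_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  empty <- tibble(pair_id = character(0), seq1 = character(0),
                  seq2 = character(0), qual1 = character(0),
                  qual2 = character(0))
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0) {
    stop("malformed SAM record at line ", bad[1], call. = FALSE)
  }
  rec <- tibble(
    qname = vapply(fields, `[[`, "", 1L),
    flag = as.integer(vapply(fields, `[[`, "", 2L)),
    seq = vapply(fields, `[[`, "", 10L),
    qual = vapply(fields, `[[`, "", 11L)
  )
  if (any(is.na(rec$flag))) stop("non-numeric SAM FLAG field", call. = FALSE)
  rec <- rec %>%
    mutate(paired = bitwAnd(.data$flag, 1L) > 0L,
           unmapped = bitwAnd(.data$flag, 4L) > 0L,
           mate_unmapped = bitwAnd(.data$flag, 8L) > 0L,
           reverse = bitwAnd(.data$flag, 16L) > 0L,
           first = bitwAnd(.data$flag, 64L) > 0L,
           second = bitwAnd(.data$flag, 128L) > 0L) %>%
    filter(.data$paired)
  ## restore original read orientation
  rev_idx <- rec$reverse
  rec$seq[rev_idx] <- revcomp(rec$seq[rev_idx])
  rec$qual[rev_idx] <- stringi::stri_reverse(rec$qual[rev_idx])

  m1 <- rec %>% filter(.data$first)
  m2 <- rec %>% filter(.data$second)
  common <- intersect(m1$qname, m2$qname)
  orphans <- setdiff(union(m1$qname, m2$qname), common)
  if (length(orphans) > 0) {
    warning(length(orphans), " orphan SAM record(s) dropped", call. = FALSE)
  }
  m1 <- m1[match(common, m1$qname), , drop = FALSE]
  m2 <- m2[match(common, m2$qname), , drop = FALSE]
  both_unmapped <- m1$unmapped & m2$unmapped &
    m1$mate_unmapped & m2$mate_unmapped
  tibble(pair_id = common,
         seq1 = m1$seq, seq2 = m2$seq,
         qual1 = m1$qual, qual2 = m2$qual)[both_unmapped, , drop = FALSE]
}
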