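#' GC content of nucleotide sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from both
#' numerator and denominator. Invariant under reverse complement.
#'
#' @param seq character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(seq) {
  assert_that(all(nchar(seq) > 0), "empty sequence")
  gc <- stringr::str_count(seq, "[GC]")
  acgt <- stringr::str_count(seq, "[ACGT]")
  if (any(acgt == 0)) stop("sequence contains no called bases", call. = FALSE)
  gc / acgt
}

#' Partition transcripts at a GC-content cutoff
#'
#' The split is inclusive on the low side: GC content exactly at the
#' cutoff (65% by default) falls in the low-GC set.
#'
#' @param transcripts transcript tibble (`id`, `seq`).
#' @param cutoff GC fraction boundary.
#' @return list with character vectors `low` (GC <= cutoff) and `high`.
#' @export
split_by_gc <- function(transcripts, cutoff = 0.65) {
  if (nrow(transcripts) == 0) return(list(low = character(0),
                                          high = character(0)))
  gc <- gc_content(transcripts$seq)
  list(low = transcripts$id[gc <= cutoff], high = transcripts$id[gc > cutoff])
}

#' Chi-square homogeneity test on a GC-class by taxonomy table
#'
#' Pearson chi-square without continuity correction on a 2 x 4 table
#' (GC <= 65% / > 65% by primate, bacteria, other eukaryote, other),
#' with 3 degrees of freedom.
#'
#' @param table 2 x 4 numeric matrix of counts.
#' @return tibble with `chi2`, `df`, `p_value`.
#' @export
taxonomy_chisq <- function(table) {
  table <- as.matrix(table)
  assert_that(all(table >= 0), "counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in taxonomy table", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Read and write PSL (BLAT tabular) alignments
#'
#' Parses the 21-column PSL format into one row per alignment with the
#' per-block structure kept in list-columns. Coordinates are 0-based
#' half-open as in the format itself.
#'
#' @param path PSL file path (no header line expected; `psLayout` headers
#'   are skipped).
#' @param x alignment tibble as produced by `read_psl()`.
#' @return `read_psl()` returns a tibble with columns `matches`,
#'   `mismatches`, `strand`, `qname`, `qsize`, `qstart`, `qend`, `tname`,
#'   `tsize`, `tstart`, `tend`, `block_sizes`, `qstarts`, `tstarts`
#'   (last three are integer list-columns) and `identity`.
#' @export
read_psl <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  skip <- grepl("^(psLayout|match|\\s*-+\\s*$|\\s*$)", lines)
  lines <- lines[!skip]
  if (length(lines) == 0) {
    return(tibble(matches = integer(0), mismatches = integer(0),
                  strand = character(0), qname = character(0),
                  qsize = integer(0), qstart = integer(0), qend = integer(0),
                  tname = character(0), tsize = integer(0),
                  tstart = integer(0), tend = integer(0),
                  block_sizes = list(), qstarts = list(), tstarts = list(),
                  identity = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 21L)
  if (length(bad) > 0) {
    stop("malformed PSL line ", bad[1], ": expected 21 fields, got ",
         lengths(fields)[bad[1]], call. = FALSE)
  }
  fi <- function(j) as.integer(vapply(fields, `[[`, "", j))
  fc <- function(j) vapply(fields, `[[`, "", j)
  ilist <- function(j) {
    lapply(fields, function(f) {
      as.integer(strsplit(sub(",$", "", f[[j]]), ",", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(
    matches = fi(1), mismatches = fi(2), strand = fc(9),
    qname = fc(10), qsize = fi(11), qstart = fi(12), qend = fi(13),
    tname = fc(14), tsize = fi(15), tstart = fi(16), tend = fi(17),
    block_sizes = ilist(19), qstarts = ilist(20), tstarts = ilist(21)
  )
  out$identity <- out$matches / pmax(1L, out$matches + out$mismatches)
  out
}

#' @rdname read_psl
#' @param path output path for `write_psl()`.
#' @export
write_psl <- function(x, path) {
  comma <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(x$matches[i], x$mismatches[i], 0L, 0L, 0L, 0L, 0L, 0L,
          x$strand[i], x$qname[i], x$qsize[i], x$qstart[i], x$qend[i],
          x$tname[i], x$tsize[i], x$tstart[i], x$tend[i],
          length(x$block_sizes[[i]]),
          comma(x$block_sizes[[i]]), comma(x$qstarts[[i]]),
          comma(x$tstarts[[i]]), sep = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Best alignment per query by match score
#'
#' Keeps, for each query, the alignment maximizing `matches - mismatches`;
#' ties break deterministically by target name, then target start.
#'
#' @param alignments tibble from [read_psl()].
#' @return tibble with one row per `qname`.
#' @export
best_alignment <- function(alignments) {
  alignments %>%
    mutate(score = .data$matches - .data$mismatches) %>%
    arrange(.data$qname, dplyr::desc(.data$score), .data$tname,
            .data$tstart) %>%
    group_by(.data$qname) %>%
    slice(1) %>%
    ungroup()
}

#' Does an alignment split into discontinuous target blocks?
#'
#' `TRUE` when the alignment has at least two blocks separated by a
#' target-side gap of `min_gap` bases or more — the signature of exons
#' interrupted by introns.
#'
#' @param alignment one row of an alignment tibble (or a tibble; then a
#'   logical vector is returned).
#' @param min_gap minimum target gap in bases to call a discontinuity.
#' @return logical.
#' @export
is_multiblock <- function(alignment, min_gap = 30) {
  vapply(seq_len(nrow(alignment)), function(i) {
    ts <- alignment$tstarts[[i]]
    bs <- alignment$block_sizes[[i]]
    if (length(ts) < 2) return(FALSE)
    gaps <- ts[-1] - (ts[-length(ts)] + bs[-length(bs)])
    any(gaps >= min_gap)
  }, logical(1))
}
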