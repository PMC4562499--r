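## File-format plumbing. Sequence formats go through Biostrings; tabular
## formats through readr. Everything written here is plain text.

#' Read and write FASTA as named character vectors
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Read and write paired-end reads as two FASTQ files
#'
#' Pairs are kept in a tibble with one row per fragment: `pair_id`,
#' `seq1`, `seq2`, `qual1`, `qual2` (phred+33 strings of the same length
#' as the sequences). Mate files use the `/1` and `/2` read-name suffix
#' convention.
#'
#' @param pairs tibble of read pairs.
#' @param path1,path2 mate FASTQ paths.
#' @return `read_pairs_fastq()` returns the pairs tibble;
#'   `write_pairs_fastq()` returns the two paths invisibly.
#' @export
write_pairs_fastq <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, path) {
    s <- Biostrings::DNAStringSet(seqs)
    names(s) <- ids
    Biostrings::writeXStringSet(s, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$seq1, pairs$qual1, paste0(pairs$pair_id, "/1"), path1)
  write_one(pairs$seq2, pairs$qual2, paste0(pairs$pair_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' @rdname write_pairs_fastq
#' @export
read_pairs_fastq <- function(path1, path2) {
  rd <- function(path) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    tibble(id = sub("/[12]$", "", names(s)),
           seq = unname(as.character(s)),
           qual = unname(as.character(S4Vectors::mcols(s)$qualities)))
  }
  m1 <- rd(path1)
  m2 <- rd(path2)
  assert_that(identical(m1$id, m2$id),
              "mate FASTQ files disagree on read ids or order")
  tibble(pair_id = m1$id, seq1 = m1$seq, seq2 = m2$seq,
         qual1 = m1$qual, qual2 = m2$qual)
}

#' Read and write BED6 interval tables
#'
#' Columns `chrom`, `start`, `end`, `gene_id` (BED "name"), `score`,
#' `strand`; coordinates 0-based half-open.
#'
#' @param x interval tibble.
#' @param path file path.
#' @return `read_bed6()` returns a tibble; `write_bed6()` returns `path`
#'   invisibly.
#' @export
write_bed6 <- function(x, path) {
  out <- dplyr::select(x, "chrom", "start", "end", "gene_id", "score", "strand")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "gene_id",
                                "score", "strand"),
                  col_types = "ciicic", progress = FALSE)
}
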