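#' Generate a synthetic two-species world with planted hidden transcripts
#'
#' Builds a seeded fixture emulating the situation in which a set of
#' transcribed loci is present in a well-assembled proxy-species genome
#' (chimp/gorilla analog) but absent from the reference assembly that
#' RNA-seq reads are screened against. The proxy chromosome interleaves
#' gene bodies, intergenic spacers and "hidden" insertions; the public
#' reference is the same chromosome with every hidden insertion removed,
#' so reads deriving from planted transcripts cannot share any k-mer with
#' it (enforced by rejection sampling, not left to chance).
#'
#' Planted truth covers the downstream statistical structure: per
#' tissue-by-condition expression frequencies, adjacent-gene effect sizes
#' (log2 shift of the nearest gene in samples expressing the transcript),
#' and ChIP enrichment folds per histone mark and cell line.
#'
#' @param seed integer seed; the world is a pure function of its arguments.
#' @param n_genes number of genes on the chromosome (per species).
#' @param n_novel number of planted hidden transcripts (>= 1).
#' @param hidden_fraction fraction of the public reference length allotted,
#'   in total, to hidden insertions (0 < hidden_fraction < 1). Hidden
#'   regions are never shorter than the planted transcript plus flanks.
#' @param gene_len,intergenic_len base-pair sizes of gene bodies and
#'   intergenic spacers.
#' @param transcript_len_range planted transcript length range (all > 200).
#' @param tissues tissue labels used for the planted expression design.
#' @param k screening seed length used for the k-mer exclusion invariant.
#' @return An object of class `synthetic_world`: a list with elements
#'   `public_reference`, `hidden_regions`, `transcripts` (named character
#'   vectors of sequences), `annotations` (tibble of BED-style intervals
#'   for both species), `homologs` (proxy/human gene-id bijection), and
#'   `truth` (list of tibbles: `transcripts`, `frequencies`,
#'   `adjacent_effects`, `chip`), plus `seed` and `k`.
#' @examples
#' w <- make_world(seed = 1, n_genes = 10, n_novel = 2)
#' w$truth$transcripts
#' @export
make_world <- function(seed, n_genes = 20, n_novel = 5, hidden_fraction = 0.1,
                       gene_len = 800, intergenic_len = 400,
                       transcript_len_range = c(250, 600),
                       tissues = c("adrenal", "prostate", "lung"),
                       k = 28) {
  assert_that(is.numeric(hidden_fraction) && hidden_fraction > 0 &&
                hidden_fraction < 1,
              "`hidden_fraction` must lie strictly between 0 and 1")
  assert_that(n_novel >= 1, "`n_novel` must be >= 1")
  assert_that(n_genes >= 2, "`n_genes` must be >= 2")
  assert_that(min(transcript_len_range) > 200,
              "planted transcripts must be longer than 200 bases")

  with_seed(derive_seed(seed, "world"), {
    genes <- random_dna(rep(gene_len, n_genes))
    ## variable spacer lengths so nearest-neighbor relations are never
    ## decided by ties
    spacer_len <- floor(runif(n_genes + 1, 0.6 * intergenic_len,
                              1.5 * intergenic_len))
    spacers <- random_dna(spacer_len)

    ## Public (human-like) chromosome: spacer, gene, spacer, gene, ...
    public_chrom <- paste0(spacers[1],
                           paste0(genes, spacers[-1], collapse = ""))
    public_len <- nchar(public_chrom)
    pub_kmers <- unique(c(seq_kmers(public_chrom, k),
                          seq_kmers(revcomp(public_chrom), k)))

    tx_len <- floor(runif(n_novel, transcript_len_range[1],
                          transcript_len_range[2] + 1))
    flank <- 50L
    hid_len <- pmax(tx_len + 2L * flank,
                    round(hidden_fraction * public_len / n_novel))

    ## Rejection-sample hidden regions sharing no k-mer with the public
    ## reference (either strand).
    hidden <- character(n_novel)
    for (i in seq_len(n_novel)) {
      repeat {
        cand <- random_dna(hid_len[i])
        km <- c(seq_kmers(cand, k), seq_kmers(revcomp(cand), k))
        if (!any(km %in% pub_kmers)) {
          hidden[i] <- cand
          break
        }
      }
    }
    names(hidden) <- sprintf("hidden_%02d", seq_len(n_novel))

    tx_start_in_hidden <- flank
    transcripts <- substr(hidden, tx_start_in_hidden + 1L,
                          tx_start_in_hidden + tx_len)
    names(transcripts) <- sprintf("novel_%02d", seq_len(n_novel))

    ## Proxy chromosome: insert each hidden region mid-spacer after gene
    ## `slot_i`; human chromosome lacks the insertions.
    slots <- sort(sample(seq_len(n_genes - 1), n_novel, replace = FALSE))
    gene_start_pub <- cumsum(spacer_len)[seq_len(n_genes)] +
      (seq_len(n_genes) - 1L) * gene_len

    proxy_parts <- spacers[1]
    pos <- spacer_len[1]
    proxy_gene_start <- integer(n_genes)
    hidden_start_proxy <- integer(n_novel)
    for (g in seq_len(n_genes)) {
      proxy_gene_start[g] <- pos
      proxy_parts <- c(proxy_parts, genes[g])
      pos <- pos + gene_len
      sp <- spacers[g + 1]
      sp_len <- spacer_len[g + 1]
      hit <- which(slots == g)
      if (length(hit) == 1) {
        half <- sp_len %/% 2L
        proxy_parts <- c(proxy_parts, substr(sp, 1, half))
        pos <- pos + half
        hidden_start_proxy[hit] <- pos
        proxy_parts <- c(proxy_parts, hidden[hit])
        pos <- pos + nchar(hidden[hit])
        proxy_parts <- c(proxy_parts, substr(sp, half + 1, sp_len))
        pos <- pos + (sp_len - half)
      } else {
        proxy_parts <- c(proxy_parts, sp)
        pos <- pos + sp_len
      }
    }
    proxy_chrom <- paste(proxy_parts, collapse = "")

    gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    annotations <- dplyr::bind_rows(
      tibble(species = "proxy", chrom = "chrP",
             start = proxy_gene_start, end = proxy_gene_start + gene_len,
             gene_id = sprintf("pg%03d", seq_len(n_genes)),
             score = 0L, strand = gene_strand),
      tibble(species = "human", chrom = "chrH",
             start = gene_start_pub, end = gene_start_pub + gene_len,
             gene_id = sprintf("hg%03d", seq_len(n_genes)),
             score = 0L, strand = gene_strand)
    )
    homologs <- tibble(proxy_gene = sprintf("pg%03d", seq_len(n_genes)),
                       human_gene = sprintf("hg%03d", seq_len(n_genes)))

    tx_start_proxy <- hidden_start_proxy + tx_start_in_hidden
    ## Planted transcripts sit just downstream of gene `slots`; that gene is
    ## the nearest feature by construction (insertion is mid-spacer).
    nearest_proxy <- sprintf("pg%03d", slots)
    truth_tx <- tibble(
      transcript = names(transcripts),
      hidden_region = names(hidden),
      chrom = "chrP",
      start = tx_start_proxy,
      end = tx_start_proxy + tx_len,
      strand = "+",
      length = tx_len,
      nearest_gene_proxy = nearest_proxy,
      nearest_gene_human = sprintf("hg%03d", slots)
    )

    ## Planted expression patterns cycle through the four association
    ## categories the classifier distinguishes.
    patterns <- c("cancer_up", "normal_up", "similar", "infrequent")
    pat <- patterns[(seq_len(n_novel) - 1L) %% 4L + 1L]
    freq_for <- function(p, cond) {
      switch(p,
             cancer_up  = if (cond == "cancer") 0.5 else 0.05,
             normal_up  = if (cond == "cancer") 0.05 else 0.5,
             similar    = 0.30,
             infrequent = 0.02)
    }
    freqs <- tidyr::expand_grid(transcript = names(transcripts),
                                tissue = tissues,
                                condition = c("cancer", "normal")) %>%
      mutate(pattern = pat[match(.data$transcript, names(transcripts))],
             rate = purrr::map2_dbl(.data$pattern, .data$condition, freq_for))

    adj <- tibble(
      transcript = names(transcripts),
      gene = truth_tx$nearest_gene_human,
      pattern = pat,
      shift_cancer = ifelse(pat == "cancer_up", 1.5,
                            ifelse(pat == "similar", 1.5, 0)),
      shift_normal = ifelse(pat == "normal_up", 1.5,
                            ifelse(pat == "similar", 1.5, 0))
    )

    cell_lines <- tibble(cell_line = paste0(tissues, "_line"),
                         tissue = tissues)
    chip <- tidyr::expand_grid(transcript = names(transcripts),
                               cell_line = cell_lines$cell_line,
                               mark = c("H3K4me3", "H3K27ac")) %>%
      left_join(cell_lines, by = "cell_line") %>%
      mutate(pattern = pat[match(.data$transcript, names(transcripts))],
             ## marks planted in the first tissue's cell line for every
             ## frequently expressed pattern; H3K27ac-dominant as in
             ## enhancer RNAs
             fold = ifelse(.data$tissue == tissues[1] &
                             .data$pattern != "infrequent" &
                             (.data$mark == "H3K27ac" |
                                .data$pattern == "cancer_up"),
                           20, 1))

    structure(list(
      public_reference = c(chrH = public_chrom),
      proxy_genome = c(chrP = proxy_chrom),
      hidden_regions = hidden,
      transcripts = transcripts,
      annotations = annotations,
      homologs = homologs,
      cell_lines = cell_lines,
      tissues = tissues,
      truth = list(transcripts = truth_tx, frequencies = freqs,
                   adjacent_effects = adj, chip = chip),
      seed = as.integer(seed),
      k = as.integer(k)
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>\n")
  cat("  public reference:", nchar(x$public_reference), "bp;",
      "proxy genome:", nchar(x$proxy_genome), "bp\n")
  cat("  planted transcripts:", length(x$transcripts),
      sprintf("(%d-%d bp)", min(nchar(x$transcripts)),
              max(nchar(x$transcripts))), "\n")
  cat("  genes per species:", nrow(x$homologs),
      " tissues:", paste(x$tissues, collapse = ", "), "\n")
  cat("  seed:", x$seed, " k:", x$k, "\n")
  invisible(x)
}

#' Write a synthetic world to disk as plain-text fixtures
#'
#' Sequences go to FASTA, annotations to BED6 (0-based half-open), homologs
#' and truth tables to TSV with headers. File content is byte-deterministic
#' for a fixed world.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  write_fasta(world$public_reference, f("public_reference.fa"))
  write_fasta(world$proxy_genome, f("proxy_genome.fa"))
  write_fasta(world$hidden_regions, f("hidden_regions.fa"))
  write_fasta(world$transcripts, f("planted_transcripts.fa"))
  for (sp in unique(world$annotations$species)) {
    ann <- dplyr::filter(world$annotations, .data$species == sp)
    write_bed6(dplyr::select(ann, -"species"), f(paste0("genes_", sp, ".bed")))
  }
  readr::write_tsv(world$homologs, f("homologs.tsv"))
  readr::write_tsv(world$truth$transcripts, f("truth_transcripts.tsv"))
  readr::write_tsv(world$truth$frequencies, f("truth_frequencies.tsv"))
  readr::write_tsv(world$truth$adjacent_effects, f("truth_adjacent_effects.tsv"))
  readr::write_tsv(world$truth$chip, f("truth_chip.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
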