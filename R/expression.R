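#' Reads per kilobase of transcript per million library reads
#'
#' `RPKM = (1e9 * C) / (N * L)` with `C` the number of unique
#' high-quality reads mapped to the transcript, `N` the total number of
#' unique high-quality reads in the library, and `L` the transcript
#' length in bases.
#'
#' @param C mapped read count (>= 0).
#' @param N library size in unique high-quality reads (> 0).
#' @param L transcript length in bases (> 0).
#' @return RPKM value(s), vectorised.
#' @export
rpkm <- function(C, N, L) {
  assert_that(all(N > 0), "`N` must be positive")
  assert_that(all(L > 0), "`L` must be positive")
  assert_that(all(C >= 0), "`C` must be non-negative")
  (1e9 * C) / (N * L)
}

#' Quantify one library against a transcript set
#'
#' Counts uniquely best-placed reads per transcript by exact shared
#' k-mers: each mate counts separately, and a read whose k-mers hit more
#' than one transcript contributes to none. `N` is the total number of
#' reads in the (already screened, hence unique high-quality) library.
#'
#' @param pairs retained read-pair tibble for one library.
#' @param transcripts transcript tibble (`id`, `seq`).
#' @param k seed length.
#' @param sample sample label attached to the output column.
#' @return tibble `transcript`, `sample`, `count`, `n_library`, `length`,
#'   `rpkm`.
#' @export
quantify <- function(pairs, transcripts, k = 28, sample = "sample") {
  assert_that(nrow(transcripts) > 0, "`transcripts` must be non-empty")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, val) {
    cur <- get0(key, envir = idx, ifnotfound = NULL)
    assign(key, c(cur, val), envir = idx)
  }
  for (i in seq_len(nrow(transcripts))) {
    for (km in unique(c(seq_kmers(transcripts$seq[i], k),
                        seq_kmers(revcomp(transcripts$seq[i]), k)))) {
      add(km, i)
    }
  }
  reads <- c(pairs$seq1, pairs$seq2)
  n_lib <- length(reads)
  counts <- integer(nrow(transcripts))
  for (s in reads) {
    hits <- unique(unlist(lapply(seq_kmers(s, k), get0, envir = idx,
                                 ifnotfound = NULL), use.names = FALSE))
    if (length(hits) == 1) counts[hits] <- counts[hits] + 1L
  }
  tibble(transcript = transcripts$id, sample = sample, count = counts,
         n_library = n_lib, length = nchar(transcripts$seq),
         rpkm = if (n_lib > 0) rpkm(counts, n_lib, nchar(transcripts$seq))
                else 0)
}

#' Per tissue-by-condition expression frequency
#'
#' A sample expresses a transcript when its RPKM exceeds
#' `positive_threshold` (any uniquely mapped read, at the default of 0).
#'
#' @param expr long expression tibble (`transcript`, `sample`, `rpkm`).
#' @param meta sample metadata (`sample`, `tissue`, `condition`).
#' @param positive_threshold RPKM above which a sample counts as
#'   expressing.
#' @return frequency tibble: `transcript`, `tissue`, `condition`,
#'   `n_expressing`, `n_total`, `frequency`.
#' @export
expression_frequency <- function(expr, meta, positive_threshold = 0) {
  missing_meta <- setdiff(unique(expr$sample), meta$sample)
  if (length(missing_meta) > 0) {
    warning(length(missing_meta), " sample(s) without metadata dropped",
            call. = FALSE)
  }
  expr %>%
    inner_join(meta, by = "sample") %>%
    group_by(.data$transcript, .data$tissue, .data$condition) %>%
    summarise(n_expressing = sum(.data$rpkm > positive_threshold),
              n_total = dplyr::n(), .groups = "drop") %>%
    mutate(frequency = .data$n_expressing / .data$n_total)
}

#' Frequently expressed transcripts
#'
#' A transcript is frequently expressed when it is expressed in strictly
#' more than `freq_cutoff` (10% by default) of the samples of at least
#' one tissue-by-condition cell.
#'
#' @param records frequency tibble from [expression_frequency()].
#' @param freq_cutoff frequency that must be strictly exceeded.
#' @return character vector of frequent transcript ids.
#' @export
classify_frequent <- function(records, freq_cutoff = 0.10) {
  records %>%
    filter(.data$frequency > freq_cutoff) %>%
    pull(.data$transcript) %>%
    unique() %>%
    sort()
}

#' Classify cancer/normal association of expression frequency
#'
#' For each frequent transcript and each tissue with both conditions
#' present, the expressing-by-condition 2 x 2 table is tested with a
#' two-sided Fisher's exact test; per-tissue p-values are
#' Bonferroni-adjusted across the tissues tested and a tissue is
#' significant when the adjusted p is strictly below `alpha`. Categories:
#' `cancer_up` when every significant tissue favors cancer, `normal_up`
#' when every one favors normal, `mixed` when both directions occur, and
#' `similar` when no tissue is significant. `similar` transcripts
#' frequent in at most `max_tissues` tissues are flagged tissue-specific.
#' A two-sample rank-sum test comparing the per-tissue cancer and normal
#' frequencies is reported as a secondary statistic.
#'
#' @param frequent character vector of frequent transcript ids.
#' @param records frequency tibble from [expression_frequency()].
#' @param alpha significance level on the Bonferroni-adjusted per-tissue
#'   Fisher p-value (strict `<`).
#' @param freq_cutoff frequency cutoff defining "frequent in a tissue"
#'   for the tissue-specific flag.
#' @param max_tissues a `similar` transcript frequent in at most this
#'   many tissues is tissue-specific.
#' @return tibble with one row per transcript: `transcript`, `category`,
#'   `tissue_specific`, `p_global` (minimum adjusted Fisher p),
#'   `p_rank_sum`, `n_tissues_tested`, `n_tissues_significant`, and a
#'   `per_tissue` list-column of the underlying per-tissue tables.
#' @export
classify_association <- function(frequent, records, alpha = 1e-4,
                                 freq_cutoff = 0.10, max_tissues = 3) {
  recs <- records %>% filter(.data$transcript %in% frequent)
  if (nrow(recs) == 0) {
    return(tibble(transcript = character(0), category = character(0),
                  tissue_specific = logical(0), p_global = numeric(0),
                  p_rank_sum = numeric(0), n_tissues_tested = integer(0),
                  n_tissues_significant = integer(0), per_tissue = list()))
  }
  wide <- recs %>%
    tidyr::pivot_wider(id_cols = c("transcript", "tissue"),
                       names_from = "condition",
                       values_from = c("n_expressing", "n_total",
                                       "frequency"))
  need <- c("n_expressing_cancer", "n_expressing_normal",
            "n_total_cancer", "n_total_normal")
  for (col in c(need, "frequency_cancer", "frequency_normal")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  incomplete <- !complete.cases(wide[, need])
  if (any(incomplete)) {
    message(sum(incomplete),
            " transcript-tissue combination(s) lack one condition; excluded")
    wide <- wide[!incomplete, , drop = FALSE]
  }

  if (nrow(wide) == 0) {
    return(tibble(transcript = character(0), category = character(0),
                  tissue_specific = logical(0), p_global = numeric(0),
                  p_rank_sum = numeric(0), n_tissues_tested = integer(0),
                  n_tissues_significant = integer(0), per_tissue = list()))
  }

  per <- wide %>%
    mutate(p_fisher = purrr::pmap_dbl(
      list(.data$n_expressing_cancer, .data$n_total_cancer,
           .data$n_expressing_normal, .data$n_total_normal),
      function(ec, tc, en, tn) {
        fisher_2x2(matrix(c(ec, tc - ec, en, tn - en), nrow = 2))
      }),
      direction = dplyr::case_when(
        .data$frequency_cancer > .data$frequency_normal ~ "cancer",
        .data$frequency_cancer < .data$frequency_normal ~ "normal",
        TRUE ~ "none"))

  per %>%
    group_by(.data$transcript) %>%
    summarise(per_tissue = list(dplyr::pick(dplyr::everything())),
              n_tissues_tested = dplyr::n(),
              p_global = min(pmin(1, .data$p_fisher * dplyr::n())),
              p_rank_sum = if (dplyr::n() >= 1)
                rank_sum_test(.data$frequency_cancer, .data$frequency_normal)
              else NA_real_,
              n_tissues_significant =
                sum(pmin(1, .data$p_fisher * dplyr::n()) < alpha),
              n_sig_cancer = sum(pmin(1, .data$p_fisher * dplyr::n()) < alpha &
                                   .data$direction == "cancer"),
              n_sig_normal = sum(pmin(1, .data$p_fisher * dplyr::n()) < alpha &
                                   .data$direction == "normal"),
              n_frequent_tissues =
                dplyr::n_distinct(.data$tissue[.data$frequency_cancer > freq_cutoff |
                                                 .data$frequency_normal > freq_cutoff]),
              .groups = "drop") %>%
    mutate(category = dplyr::case_when(
      .data$n_tissues_significant == 0 ~ "similar",
      .data$n_sig_cancer > 0 & .data$n_sig_normal > 0 ~ "mixed",
      .data$n_sig_cancer > 0 ~ "cancer_up",
      TRUE ~ "normal_up"),
      tissue_specific = .data$category == "similar" &
        .data$n_frequent_tissues <= max_tissues &
        .data$n_frequent_tissues >= 1) %>%
    dplyr::select("transcript", "category", "tissue_specific", "p_global",
                  "p_rank_sum", "n_tissues_tested", "n_tissues_significant",
                  "per_tissue")
}
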