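#' Effective length of a transcript under histone-mark coverage
#'
#' The number of positions covered by at least one read in any of the
#' histone-mark libraries (the input/control library is excluded from the
#' union). This is the `L` used for ChIP RPKM values.
#'
#' @param coverages list (or matrix, libraries in rows) of per-base
#'   coverage vectors of equal length.
#' @return integer effective length.
#' @export
effective_length <- function(coverages) {
  if (is.matrix(coverages)) {
    coverages <- split(coverages, row(coverages))
  }
  assert_that(length(coverages) > 0, "at least one library is required")
  lens <- lengths(coverages)
  assert_that(length(unique(lens)) == 1,
              "coverage vectors must have equal length")
  covered <- Reduce(`+`, lapply(coverages, function(v) as.integer(v >= 1)))
  sum(covered >= 1L)
}

#' Call histone-mark enrichment with a Poisson tail statistic
#'
#' For each transcript, cell line and mark, treatment and control RPKM
#' are computed over the effective length and the enrichment p-value is
#' `1 - F_Poisson(x; lambda)` evaluated as [poisson_tail()], with
#' `lambda` the control RPKM and `x` the treatment RPKM. A mark is
#' significant when `p <= cutoff` (inclusive). Per transcript and cell
#' line the two marks combine into a pattern: `K4_only`, `K27_only`,
#' `both`, or `none`; a missing mark is treated as not significant (with
#' a message).
#'
#' @param signals histone signal tibble (`transcript`, `cell_line`,
#'   `mark`, `treatment_count`, `control_count`, `n_treatment`,
#'   `n_control`, `effective_len`), e.g. from [simulate_chip()].
#' @param cutoff significance cutoff on the Poisson p-value (inclusive).
#' @param floor_x passed to [poisson_tail()].
#' @return list with `signals` (input plus `x`, `lambda`, `p_value`,
#'   `significant`) and `calls` (one row per transcript-by-cell-line:
#'   `pattern`, per-mark p-values).
#' @export
call_marks <- function(signals, cutoff = 1e-4, floor_x = FALSE) {
  sg <- signals %>%
    mutate(
      x = ifelse(.data$effective_len > 0,
                 rpkm(.data$treatment_count, .data$n_treatment,
                      pmax(1L, .data$effective_len)), 0),
      lambda = ifelse(.data$effective_len > 0,
                      rpkm(.data$control_count, .data$n_control,
                           pmax(1L, .data$effective_len)), 0),
      p_value = poisson_tail(.data$x, .data$lambda, floor_x = floor_x),
      significant = .data$p_value <= cutoff)
  marks <- c("H3K4me3", "H3K27ac")
  missing <- sg %>%
    count(.data$transcript, .data$cell_line) %>%
    filter(.data$n < length(marks))
  if (nrow(missing) > 0) {
    message(nrow(missing), " transcript-cell line pair(s) missing a mark; ",
            "treated as not significant")
  }
  calls <- sg %>%
    dplyr::select("transcript", "cell_line", "mark", "p_value",
                  "significant") %>%
    tidyr::pivot_wider(names_from = "mark",
                       values_from = c("p_value", "significant"))
  for (col in paste0("significant_", marks)) {
    if (!col %in% names(calls)) calls[[col]] <- NA
  }
  for (col in paste0("p_value_", marks)) {
    if (!col %in% names(calls)) calls[[col]] <- NA_real_
  }
  calls <- calls %>%
    mutate(
      sig_k4 = dplyr::coalesce(.data[["significant_H3K4me3"]], FALSE),
      sig_k27 = dplyr::coalesce(.data[["significant_H3K27ac"]], FALSE),
      pattern = dplyr::case_when(
        .data$sig_k4 & .data$sig_k27 ~ "both",
        .data$sig_k4 ~ "K4_only",
        .data$sig_k27 ~ "K27_only",
        TRUE ~ "none"))
  list(signals = sg, calls = calls)
}

#' Enrichment of histone marks in the matching expressing tissue
#'
#' Builds a 2 x 2 table over transcript-by-profiled-tissue combinations —
#' (has a significant mark in a cell line of that tissue) versus (is
#' frequently expressed in that tissue) — and tests it with the
#' two-sided Fisher's exact test. A positive association means marks
#' concentrate in the tissues where the transcript is expressed.
#'
#' @param calls call tibble from [call_marks()]`$calls`.
#' @param frequent_tissues tibble `transcript`, `tissue` listing where
#'   each transcript is frequently expressed.
#' @param cell_line_tissue tibble `cell_line`, `tissue`; every cell line
#'   appearing in `calls` must be mapped.
#' @return list with `table` (2 x 2 matrix) and `p_value`.
#' @export
tissue_match_enrichment <- function(calls, frequent_tissues,
                                    cell_line_tissue) {
  unmapped <- setdiff(unique(calls$cell_line), cell_line_tissue$cell_line)
  assert_that(length(unmapped) == 0,
              paste("unmapped cell line(s):", paste(unmapped, collapse = ", ")))
  ## unit of the table: transcript-by-tissue combinations over profiled
  ## tissues — marked in that tissue's cell line(s) vs frequently
  ## expressed in that tissue
  per_unit <- calls %>%
    left_join(cell_line_tissue, by = "cell_line") %>%
    group_by(.data$transcript, .data$tissue) %>%
    summarise(marked = any(.data$pattern != "none"), .groups = "drop") %>%
    left_join(frequent_tissues %>% mutate(frequent = TRUE),
              by = c("transcript", "tissue")) %>%
    mutate(frequent = dplyr::coalesce(.data$frequent, FALSE))
  tab <- with(per_unit, table(factor(marked, c(TRUE, FALSE)),
                              factor(frequent, c(TRUE, FALSE))))
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(mark_in_matching_tissue = c("yes", "no"),
                              frequently_expressed = c("yes", "no")))
  list(table = m, p_value = fisher_2x2(m))
}
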