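#' Nearest feature to a query interval
#'
#' Minimal genomic distance between 0-based half-open intervals: 0 when
#' they overlap, otherwise `max(0, startB - endA)` in either direction.
#' Equidistant features break ties toward the smaller start coordinate;
#' strand is ignored. Queries on a sequence with no features return the
#' sentinel `NA` feature.
#'
#' @param features interval tibble (`chrom`, `start`, `end`, `gene_id`).
#' @param chrom,start,end the query interval.
#' @return tibble with `gene_id` and `distance` (one row; `gene_id` `NA`
#'   when the query's sequence carries no features).
#' @export
nearest_feature <- function(features, chrom, start, end) {
  f <- features %>% filter(.data$chrom == !!chrom)
  if (nrow(f) == 0) return(tibble(gene_id = NA_character_,
                                  distance = NA_integer_))
  d <- pmax(0L, pmax(f$start - end, start - f$end))
  best <- which(d == min(d))
  best <- best[order(f$start[best])][1]
  tibble(gene_id = f$gene_id[best], distance = as.integer(d[best]))
}

#' Assign each transcript its adjacent human gene through proxy synteny
#'
#' Takes each transcript's best alignment to a proxy-species genome,
#' finds the nearest proxy gene at the aligned locus, and maps it to its
#' human homolog. When alignments to several proxy species are supplied
#' the species carrying the higher best-alignment score wins. Transcripts
#' without an alignment, a neighboring gene, or a homolog are returned
#' unassigned.
#'
#' @param alignments alignment tibble ([read_psl()] layout) of
#'   transcripts against proxy genomes; an optional `species` column
#'   separates multiple proxies.
#' @param annotations proxy gene intervals (`chrom`, `start`, `end`,
#'   `gene_id`; optional `species`).
#' @param homologs tibble `proxy_gene`, `human_gene` (one-to-one).
#' @return tibble `transcript`, `proxy_gene`, `human_gene`, `distance`,
#'   `assigned`.
#' @export
assign_adjacent_gene <- function(alignments, annotations, homologs) {
  assert_that(!any(duplicated(homologs$proxy_gene)) &&
                !any(duplicated(homologs$human_gene)),
              "homolog table must be one-to-one")
  if (!"species" %in% names(alignments)) alignments$species <- "proxy"
  if (!"species" %in% names(annotations)) annotations$species <- "proxy"
  best <- alignments %>%
    mutate(score = .data$matches - .data$mismatches) %>%
    arrange(.data$qname, dplyr::desc(.data$score), .data$species,
            .data$tname, .data$tstart) %>%
    group_by(.data$qname) %>%
    slice(1) %>%
    ungroup()
  rows <- purrr::map(seq_len(nrow(best)), function(i) {
    sp_ann <- annotations %>% filter(.data$species == best$species[i])
    nf <- nearest_feature(sp_ann, best$tname[i], best$tstart[i], best$tend[i])
    tibble(transcript = best$qname[i], proxy_gene = nf$gene_id,
           distance = nf$distance)
  })
  dplyr::bind_rows(rows) %>%
    left_join(homologs, by = "proxy_gene") %>%
    mutate(assigned = !is.na(.data$human_gene)) %>%
    dplyr::select("transcript", "proxy_gene", "human_gene", "distance",
                  "assigned")
}

#' Fraction of conserved gene neighborhoods between two annotations
#'
#' For every gene present (through the homolog map) in both species, the
#' neighborhood is conserved when its nearest neighbor in A maps to that
#' gene's nearest neighbor in B. Genes absent from B are excluded from
#' the denominator. Symmetric in (A, B) when the homolog map is a
#' bijection and both annotations are complete.
#'
#' @param annot_a,annot_b interval tibbles (`chrom`, `start`, `end`,
#'   `gene_id`) for species A and B.
#' @param homologs tibble `proxy_gene` (ids in A), `human_gene` (ids in
#'   B).
#' @return fraction in `[0, 1]`.
#' @export
neighborhood_conservation <- function(annot_a, annot_b, homologs) {
  assert_that(nrow(homologs) > 0, "empty homolog map")
  a2b <- setNames(homologs$human_gene, homologs$proxy_gene)
  nearest_of <- function(ann, g) {
    row <- ann[ann$gene_id == g, , drop = FALSE]
    others <- ann[ann$gene_id != g, , drop = FALSE]
    if (nrow(row) == 0 || nrow(others) == 0) return(NA_character_)
    nearest_feature(others, row$chrom[1], row$start[1], row$end[1])$gene_id
  }
  genes_a <- intersect(annot_a$gene_id, names(a2b))
  conserved <- logical(0)
  excluded <- 0L
  for (g in genes_a) {
    gb <- a2b[[g]]
    if (!gb %in% annot_b$gene_id) { excluded <- excluded + 1L; next }
    na_ <- nearest_of(annot_a, g)
    nb_ <- nearest_of(annot_b, gb)
    if (is.na(na_) || is.na(nb_)) { excluded <- excluded + 1L; next }
    conserved <- c(conserved, identical(unname(a2b[[na_]]), nb_))
  }
  if (excluded > 0) {
    message(excluded, " gene(s) excluded from conservation denominator")
  }
  assert_that(length(conserved) > 0,
              "no comparable genes; conservation undefined")
  mean(conserved)
}

#' Adjacent-gene expression association per condition stratum
#'
#' Within cancer samples and within normal samples separately, the
#' expression of a transcript's assigned adjacent gene is compared
#' between samples expressing and not expressing the transcript with the
#' two-sided rank-sum test. Categories record which strata pass `alpha`:
#' `cancer_only`, `normal_only`, `both`, `none`. Strata with fewer than
#' `min_group` samples on either side are untested.
#'
#' @param expr transcript expression tibble (`transcript`, `sample`,
#'   `rpkm`).
#' @param gene_expr adjacent-gene expression tibble (`gene`, `sample`,
#'   `value`).
#' @param assignment tibble `transcript`, `human_gene` from
#'   [assign_adjacent_gene()].
#' @param meta sample metadata (`sample`, `tissue`, `condition`).
#' @param alpha per-stratum significance level (strict `<`).
#' @param positive_threshold RPKM above which a sample expresses the
#'   transcript.
#' @param min_group minimum samples per group for a stratum to be tested.
#' @return tibble `transcript`, `human_gene`, `p_cancer`, `p_normal`,
#'   `category`.
#' @export
adjacent_gene_association <- function(expr, gene_expr, assignment, meta,
                                      alpha = 1e-4, positive_threshold = 0,
                                      min_group = 3) {
  asn <- if ("assigned" %in% names(assignment)) {
    assignment %>% filter(.data$assigned)
  } else {
    assignment %>% filter(!is.na(.data$human_gene))
  }
  rows <- purrr::map(seq_len(nrow(asn)), function(i) {
    tid <- asn$transcript[i]
    gid <- asn$human_gene[i]
    tx <- expr %>% filter(.data$transcript == tid) %>%
      inner_join(meta, by = "sample")
    ge <- gene_expr %>% filter(.data$gene == gid)
    dat <- tx %>% inner_join(ge, by = "sample") %>%
      mutate(expressing = .data$rpkm > positive_threshold)
    p_for <- function(cond) {
      d <- dat %>% filter(.data$condition == cond)
      a <- d$value[d$expressing]
      b <- d$value[!d$expressing]
      if (length(a) < min_group || length(b) < min_group) return(NA_real_)
      rank_sum_test(a, b)
    }
    pc <- p_for("cancer")
    pn <- p_for("normal")
    sig <- function(p) !is.na(p) && p < alpha
    tibble(transcript = tid, human_gene = gid,
           p_cancer = pc, p_normal = pn,
           category = dplyr::case_when(
             sig(pc) & sig(pn) ~ "both",
             sig(pc) ~ "cancer_only",
             sig(pn) ~ "normal_only",
             TRUE ~ "none"))
  })
  dplyr::bind_rows(rows)
}
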