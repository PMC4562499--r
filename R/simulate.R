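#' Simulate paired-end reads from a planted transcript or the reference
#'
#' Fragments of length `fragment_len` are drawn uniformly along the source
#' sequence; mate 1 is the fragment's 5' end read forward, mate 2 the 3'
#' end read on the opposite strand (FR orientation). Substitution errors
#' are injected per base with probability `error_rate`; error positions
#' get phred quality 10, all other positions quality 40, so downstream
#' quality filters have deterministic signal.
#'
#' @param world a `synthetic_world`.
#' @param id name of a planted transcript, hidden region, or public
#'   reference sequence to draw fragments from.
#' @param depth target mean per-base coverage; the number of pairs is
#'   `round(depth * L / (2 * read_len))`.
#' @param fragment_len,read_len fragment and read lengths in bases.
#' @param error_rate per-base substitution probability (0 <= e < 0.1).
#' @param seed integer seed.
#' @return tibble with columns `pair_id`, `seq1`, `seq2`, `qual1`, `qual2`,
#'   `source`.
#' @export
simulate_read_pairs <- function(world, id, depth = 30, fragment_len = 300,
                                read_len = 100, error_rate = 0, seed = 0) {
  src <- c(world$transcripts, world$hidden_regions,
           world$public_reference, world$proxy_genome)
  assert_that(id %in% names(src), paste0("unknown sequence id: ", id))
  assert_that(error_rate >= 0 && error_rate < 0.1,
              "`error_rate` must lie in [0, 0.1)")
  assert_that(fragment_len >= read_len,
              "`fragment_len` must be >= `read_len`")
  tpl <- src[[id]]
  L <- nchar(tpl)
  if (L < fragment_len) {
    stop("sequence '", id, "' (", L, " bp) is shorter than fragment_len (",
         fragment_len, " bp)", call. = FALSE)
  }
  n_pairs <- round(depth * L / (2 * read_len))
  if (n_pairs == 0) {
    return(tibble(pair_id = character(0), seq1 = character(0),
                  seq2 = character(0), qual1 = character(0),
                  qual2 = character(0), source = character(0)))
  }
  with_seed(derive_seed(seed, paste0("reads:", id)), {
    starts <- sample.int(L - fragment_len + 1L, n_pairs, replace = TRUE)
    frag <- substring(tpl, starts, starts + fragment_len - 1L)
    seq1 <- substr(frag, 1L, read_len)
    seq2 <- revcomp(substr(frag, fragment_len - read_len + 1L, fragment_len))
    q40 <- strrep(int_to_phred(40L), read_len)
    inject <- function(s) {
      if (error_rate == 0) return(list(seq = s, qual = rep(q40, length(s))))
      mat <- matrix(runif(length(s) * read_len) < error_rate,
                    nrow = length(s))
      qual <- rep(q40, length(s))
      hit <- which(rowSums(mat) > 0)
      for (i in hit) {
        ch <- strsplit(s[i], "")[[1]]
        qv <- rep(40L, read_len)
        for (p in which(mat[i, ])) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          qv[p] <- 10L
        }
        s[i] <- paste(ch, collapse = "")
        qual[i] <- int_to_phred(qv)
      }
      list(seq = s, qual = qual)
    }
    m1 <- inject(seq1)
    m2 <- inject(seq2)
    tibble(pair_id = sprintf("%s:%05d", id, seq_len(n_pairs)),
           seq1 = m1$seq, seq2 = m2$seq,
           qual1 = m1$qual, qual2 = m2$qual,
           source = id)
  })
}

#' Simulate a tissue-by-condition expression design with planted effects
#'
#' Each planted transcript is expressed (RPKM > 0) in each sample with its
#' planted tissue-by-condition probability; when expressed, its RPKM is
#' log-normal. Nearest-gene expression is log-normal per gene, multiplied
#' by `2^shift` in samples that express the paired transcript, within the
#' strata the truth table plants the shift in.
#'
#' @param world a `synthetic_world`.
#' @param design tibble with columns `tissue`, `condition`, `n_samples`.
#' @param positive_rate optional tibble `transcript`, `tissue`,
#'   `condition`, `rate` overriding the world's planted frequencies.
#' @param seed integer seed.
#' @return list of class `expression_sim`: `expr` (long tibble
#'   `transcript`, `sample`, `rpkm`), `gene_expr` (long tibble `gene`,
#'   `sample`, `value`), `meta` (`sample`, `tissue`, `condition`), and the
#'   truth tables used.
#' @export
simulate_expression <- function(world, design = NULL, positive_rate = NULL,
                                seed = 0) {
  if (is.null(design)) {
    design <- tidyr::expand_grid(tissue = world$tissues,
                                 condition = c("cancer", "normal")) %>%
      mutate(n_samples = 50L)
  }
  assert_that(all(c("tissue", "condition", "n_samples") %in% names(design)),
              "`design` needs columns tissue, condition, n_samples")
  rates <- positive_rate %||% world$truth$frequencies
  assert_that(all(rates$rate >= 0 & rates$rate <= 1),
              "planted rates must lie in [0, 1]")

  with_seed(derive_seed(seed, "expression"), {
    meta <- design %>%
      dplyr::rowwise() %>%
      dplyr::reframe(tissue = .data$tissue, condition = .data$condition,
                     sample = sprintf("%s_%s_%02d", .data$tissue,
                                      substr(.data$condition, 1, 1),
                                      seq_len(.data$n_samples))) %>%
      dplyr::select("sample", "tissue", "condition")

    grid <- tidyr::expand_grid(transcript = unique(rates$transcript),
                               sample = meta$sample) %>%
      left_join(meta, by = "sample") %>%
      left_join(rates, by = c("transcript", "tissue", "condition")) %>%
      mutate(rate = dplyr::coalesce(.data$rate, 0))
    grid <- grid %>%
      mutate(expressed = rbinom(dplyr::n(), 1L, .data$rate) == 1L,
             rpkm = ifelse(.data$expressed,
                           rlnorm(dplyr::n(), meanlog = log(5), sdlog = 1),
                           0))
    expr <- dplyr::select(grid, "transcript", "sample", "rpkm")

    adj <- world$truth$adjacent_effects
    gene_expr <- NULL
    if (!is.null(adj) && nrow(adj) > 0) {
      ge <- tidyr::expand_grid(gene = unique(adj$gene), sample = meta$sample) %>%
        left_join(meta, by = "sample") %>%
        mutate(value = rlnorm(dplyr::n(), meanlog = log(20), sdlog = 0.5))
      shifts <- grid %>%
        dplyr::select("transcript", "sample", "condition", "expressed") %>%
        inner_join(adj, by = "transcript",
                   relationship = "many-to-many") %>%
        mutate(shift = ifelse(.data$condition == "cancer",
                              .data$shift_cancer, .data$shift_normal)) %>%
        filter(.data$expressed, .data$shift != 0) %>%
        dplyr::select("gene", "sample", "shift")
      ge <- ge %>%
        left_join(shifts, by = c("gene", "sample")) %>%
        mutate(value = .data$value * 2^dplyr::coalesce(.data$shift, 0))
      gene_expr <- dplyr::select(ge, "gene", "sample", "value")
    }

    structure(list(expr = expr, gene_expr = gene_expr, meta = meta,
                   rates = rates, adjacent_effects = adj, seed = seed),
              class = "expression_sim")
  })
}

#' Simulate histone-mark ChIP read counts over planted transcripts
#'
#' Control (input) counts are Poisson with rate
#' `control_scale * base_depth * L / read_len`; treatment counts are
#' Poisson with rate `fold * base_depth * L / read_len` for enriched
#' (transcript, cell line, mark) entries and `base_depth * L / read_len`
#' otherwise. The deep-input default (`control_scale = 50`) reflects the
#' Poisson caller's modeling assumption that the control rate is known
#' rather than estimated; set `control_scale = 1` for a matched-depth
#' control. Library sizes default to `1e9 / mean(L)` for treatment so one
#' read on an average-length transcript corresponds to one RPKM unit, and
#' `control_scale` times that for the control.
#'
#' @param world a `synthetic_world`.
#' @param enriched tibble `transcript`, `cell_line`, `mark` of planted
#'   enrichment (default: the world's truth ChIP table entries with
#'   fold > 1).
#' @param fold enrichment fold for planted entries (>= 1).
#' @param base_depth mean per-base background coverage.
#' @param read_len read length used for the count model.
#' @param control_scale control depth multiplier (>= 1).
#' @param n_treatment,n_control library sizes; defaults described above.
#' @param seed integer seed.
#' @return tibble of histone signals: `transcript`, `cell_line`, `mark`,
#'   `treatment_count`, `control_count`, `n_treatment`, `n_control`,
#'   `effective_len`, `enriched`.
#' @export
simulate_chip <- function(world, enriched = NULL, fold = 20, base_depth = 30,
                          read_len = 100, control_scale = 50,
                          n_treatment = NULL, n_control = NULL, seed = 0) {
  assert_that(fold >= 1, "`fold` must be >= 1")
  assert_that(control_scale >= 1, "`control_scale` must be >= 1")
  chip <- world$truth$chip
  if (is.null(enriched)) {
    enriched <- chip %>% filter(.data$fold > 1) %>%
      dplyr::select("transcript", "cell_line", "mark")
  }
  L <- nchar(world$transcripts)
  n_treatment <- n_treatment %||% round(1e9 / mean(L))
  n_control <- n_control %||% round(control_scale * n_treatment)

  grid <- tidyr::expand_grid(transcript = names(world$transcripts),
                             cell_line = world$cell_lines$cell_line,
                             mark = c("H3K4me3", "H3K27ac")) %>%
    mutate(effective_len = L[.data$transcript],
           enriched = paste(.data$transcript, .data$cell_line, .data$mark) %in%
             paste(enriched$transcript, enriched$cell_line, enriched$mark))

  with_seed(derive_seed(seed, "chip"), {
    base_rate <- base_depth * grid$effective_len / read_len
    grid %>%
      mutate(control_count = rpois(dplyr::n(), control_scale * base_rate),
             treatment_count = rpois(dplyr::n(),
                                     ifelse(.data$enriched, fold, 1) * base_rate),
             n_treatment = n_treatment,
             n_control = n_control) %>%
      dplyr::select("transcript", "cell_line", "mark", "treatment_count",
                    "control_count", "n_treatment", "n_control",
                    "effective_len", "enriched")
  })
}

#' Build a seeded re-assembly fixture with planted transcript chains
#'
#' Creates a set of "long transcripts" in which some planted full-length
#' transcripts have been fragmented into two or three contiguous members,
#' together with read pairs bridging each junction (mate 1 just upstream,
#' mate 2 reverse-complemented just downstream). Joining with sufficient
#' support should reunite every chain; with support below the threshold no
#' join may form.
#'
#' @param seed integer seed.
#' @param n_single,n_two,n_three planted transcripts left whole, split in
#'   two, and split in three.
#' @param support bridging read pairs generated per junction.
#' @param member_len approximate fragment length (every member > 200 bp).
#' @param read_len bridging read length.
#' @return list with `transcripts` (tibble `id`, `seq` of fragments),
#'   `pairs` (bridging read pairs), and `truth` (tibble `planted_id`,
#'   `seq`, `members` list-column in order).
#' @export
make_join_fixture <- function(seed = 0, n_single = 12, n_two = 5, n_three = 3,
                              support = 6, member_len = 400, read_len = 100) {
  with_seed(derive_seed(seed, "join_fixture"), {
    n_members <- c(rep(1L, n_single), rep(2L, n_two), rep(3L, n_three))
    n_planted <- length(n_members)
    planted_id <- sprintf("planted_%02d", seq_len(n_planted))
    frag_rows <- list()
    pair_rows <- list()
    truth_members <- vector("list", n_planted)
    seqs <- character(n_planted)
    for (i in seq_len(n_planted)) {
      m <- n_members[i]
      lens <- member_len + sample.int(50L, m)  # all > 200
      full <- random_dna(sum(lens))
      seqs[i] <- full
      off <- cumsum(c(0L, lens))
      ids <- sprintf("%s.f%d", planted_id[i], seq_len(m))
      truth_members[[i]] <- ids
      frag_rows[[i]] <- tibble(
        id = ids,
        seq = substring(full, off[seq_len(m)] + 1L, off[seq_len(m) + 1L])
      )
      if (m > 1 && support > 0) {
        q40 <- strrep(int_to_phred(40L), read_len)
        for (j in seq_len(m - 1)) {
          cut <- off[j + 1L]
          ## mate1 ends `d` bases before the junction, mate2 starts `d`
          ## bases after it; both sit wholly inside their member.
          d <- seq_len(support) + 4L
          s1 <- substring(full, cut - d - read_len + 1L, cut - d)
          s2 <- revcomp(substring(full, cut + d, cut + d + read_len - 1L))
          pair_rows[[length(pair_rows) + 1L]] <- tibble(
            pair_id = sprintf("%s.j%d:%03d", planted_id[i], j, seq_len(support)),
            seq1 = s1, seq2 = s2, qual1 = q40, qual2 = q40,
            source = planted_id[i])
        }
      }
    }
    list(transcripts = dplyr::bind_rows(frag_rows),
         pairs = dplyr::bind_rows(pair_rows),
         truth = tibble(planted_id = planted_id, seq = seqs,
                        members = truth_members))
  })
}
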