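test_that("world generation is deterministic, seed-sensitive, and honors invariants", {
  w1 <- make_world(seed = 0, n_genes = 12, n_novel = 5, hidden_fraction = 0.1)
  w2 <- make_world(seed = 0, n_genes = 12, n_novel = 5, hidden_fraction = 0.1)
  w3 <- make_world(seed = 1, n_genes = 12, n_novel = 5, hidden_fraction = 0.1)

  expect_identical(w1$hidden_regions, w2$hidden_regions)
  expect_identical(w1$truth$frequencies, w2$truth$frequencies)
  expect_false(identical(w1$hidden_regions, w3$hidden_regions))

  ## planted transcripts: 5 of them, all > 200, inside hidden regions
  expect_length(w1$transcripts, 5)
  expect_true(all(nchar(w1$transcripts) > 200))
  expect_true(all(mapply(grepl, w1$transcripts,
                         w1$hidden_regions[w1$truth$transcripts$hidden_region],
                         fixed = TRUE)))

  ## screening invariant: no hidden k-mer occurs in the public reference
  pub <- c(w1$public_reference, revcomp(w1$public_reference))
  for (h in w1$hidden_regions) {
    kms <- substring(h, 1:(nchar(h) - w1$k + 1), w1$k:nchar(h))
    expect_false(any(vapply(kms[c(1, length(kms) %/% 2, length(kms))],
                            function(km) any(grepl(km, pub, fixed = TRUE)),
                            logical(1))))
  }

  ## homolog table is a bijection
  expect_false(any(duplicated(w1$homologs$proxy_gene)))
  expect_false(any(duplicated(w1$homologs$human_gene)))

  expect_error(make_world(seed = 0, hidden_fraction = 0), "hidden_fraction")
  expect_error(make_world(seed = 0, n_novel = 0), "n_novel")
})

test_that("world fixtures round-trip to disk byte-identically", {
  w <- make_world(seed = 4, n_genes = 10, n_novel = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w, d1)
  write_world(w, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ## truth table round-trip is lossless
  tr <- readr::read_tsv(file.path(d1, "truth_transcripts.tsv"),
                        show_col_types = FALSE)
  expect_equal(as.data.frame(tr), as.data.frame(w$truth$transcripts))
  ## FASTA round-trip
  expect_identical(read_fasta(file.path(d1, "planted_transcripts.fa")),
                   w$transcripts)
  ## BED round-trip
  bed <- read_bed6(file.path(d1, "genes_proxy.bed"))
  prox <- dplyr::filter(w$annotations, species == "proxy")
  expect_equal(bed$start, prox$start)
  expect_equal(bed$gene_id, prox$gene_id)
})

test_that("simulated read pairs honor the fragment model", {
  w <- make_world(seed = 2, n_genes = 10, n_novel = 2,
                  transcript_len_range = c(300, 301))
  tx <- w$transcripts[["novel_01"]]

  ## zero error: every mate is an exact substring of the transcript strand
  p <- simulate_read_pairs(w, "novel_01", depth = 30, fragment_len = 250,
                           read_len = 100, error_rate = 0, seed = 1)
  expect_gt(nrow(p), 0)
  expect_true(all(vapply(p$seq1, grepl, logical(1), x = tx, fixed = TRUE)))
  expect_true(all(vapply(revcomp(p$seq2), grepl, logical(1), x = tx,
                         fixed = TRUE)))
  expect_equal(nrow(p), round(30 * nchar(tx) / (2 * 100)))

  ## depth 0 gives an empty set
  expect_equal(nrow(simulate_read_pairs(w, "novel_01", depth = 0, seed = 1)), 0)

  ## determinism and FASTQ round-trip
  p2 <- simulate_read_pairs(w, "novel_01", depth = 30, fragment_len = 250,
                            read_len = 100, error_rate = 0, seed = 1)
  expect_identical(p, p2)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_pairs_fastq(p, f1, f2)
  back <- read_pairs_fastq(f1, f2)
  expect_equal(back$seq1, p$seq1)
  expect_equal(back$qual2, p$qual2)

  ## fragment longer than the transcript names the transcript
  expect_error(simulate_read_pairs(w, "novel_01", fragment_len = 10000),
               "novel_01")
})

test_that("injected sequencing errors match the stated rate and mark quality", {
  w <- make_world(seed = 2, n_genes = 10, n_novel = 1,
                  transcript_len_range = c(500, 501))
  tx <- w$transcripts[[1]]
  rate <- 0.01
  p <- simulate_read_pairs(w, names(w$transcripts)[1], depth = 40,
                           fragment_len = 300, read_len = 100,
                           error_rate = rate, seed = 7)
  ## count mismatches of mate1 against the template via the error-free twin
  p0 <- simulate_read_pairs(w, names(w$transcripts)[1], depth = 40,
                            fragment_len = 300, read_len = 100,
                            error_rate = 0, seed = 7)
  mism <- sum(mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, p$seq1, p0$seq1))
  n_bases <- sum(nchar(p$seq1))
  expect_lt(abs(mism / n_bases - rate), 3 * sqrt(rate * (1 - rate) / n_bases))
  ## error positions carry phred 10, clean positions phred 40
  qv <- utf8ToInt(p$qual1[1]) - 33L
  expect_true(all(qv %in% c(10L, 40L)))
  expect_error(simulate_read_pairs(w, names(w$transcripts)[1],
                                   error_rate = 0.5), "error_rate")
})

test_that("simulated expression reproduces planted frequencies", {
  w <- make_world(seed = 5, n_genes = 10, n_novel = 4)
  design <- tibble::tibble(tissue = rep(w$tissues[1:2], each = 2),
                           condition = rep(c("cancer", "normal"), 2),
                           n_samples = 100L)

  ## planted rate 0 everywhere gives an all-zero column
  rates0 <- w$truth$frequencies |> dplyr::mutate(rate = 0)
  sim0 <- simulate_expression(w, design, positive_rate = rates0, seed = 1)
  expect_true(all(sim0$expr$rpkm == 0))

  ## planted 0.5 cancer / 0.1 normal recovered within 3 binomial SD
  rates <- w$truth$frequencies |>
    dplyr::mutate(rate = ifelse(condition == "cancer", 0.5, 0.1))
  sim <- simulate_expression(w, design, positive_rate = rates, seed = 2)
  obs <- sim$expr |>
    dplyr::inner_join(sim$meta, by = "sample") |>
    dplyr::group_by(condition) |>
    dplyr::summarise(f = mean(rpkm > 0), n = dplyr::n(), .groups = "drop")
  for (i in seq_len(nrow(obs))) {
    p0 <- if (obs$condition[i] == "cancer") 0.5 else 0.1
    expect_lt(abs(obs$f[i] - p0), 3 * sqrt(p0 * (1 - p0) / obs$n[i]))
  }

  ## invalid probabilities are rejected
  bad <- dplyr::mutate(rates, rate = 1.5)
  expect_error(simulate_expression(w, design, positive_rate = bad), "rates")
})

test_that("simulated ChIP counts follow the planted fold structure", {
  w <- make_world(seed = 6, n_genes = 10, n_novel = 3,
                  transcript_len_range = c(400, 401))
  expect_error(simulate_chip(w, fold = 0.5), "fold")

  ## base_depth 0: both channels zero, caller returns p = 1
  chip0 <- simulate_chip(w, base_depth = 0, seed = 1)
  expect_true(all(chip0$treatment_count == 0))
  expect_true(all(chip0$control_count == 0))
  mc0 <- call_marks(chip0)
  expect_true(all(mc0$signals$p_value == 1))

  ## enriched entries have visibly higher treatment counts
  chip <- simulate_chip(w, fold = 20, base_depth = 30, seed = 2)
  agg <- chip |> dplyr::group_by(enriched) |>
    dplyr::summarise(m = mean(treatment_count), .groups = "drop")
  expect_gt(agg$m[agg$enriched], 5 * agg$m[!agg$enriched])
  ## control channel is blind to enrichment
  expect_lt(abs(mean(chip$control_count[chip$enriched]) /
                  mean(chip$control_count[!chip$enriched]) - 1), 0.2)
})
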