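make_q <- function(vals) intToUtf8(vals + 33L)

test_that("sliding-window quality filter applies the window-mean and N rules", {
  good <- pair_row("p1", strrep("A", 100), strrep("C", 100))
  expect_true(quality_filter(good))

  ## any uncalled base fails the pair
  with_n <- pair_row("p2", paste0(strrep("A", 50), "N", strrep("A", 49)),
                     strrep("C", 100))
  expect_false(quality_filter(with_n))

  ## 100-base read, qualities 40 except positions 1-15 at 10:
  ## the first window of 15 has mean 10 < 17
  qbad <- make_q(c(rep(10L, 15), rep(40L, 85)))
  low <- pair_row("p3", strrep("A", 100), strrep("C", 100), q1 = qbad)
  expect_false(quality_filter(low))

  ## a single low base inside an otherwise high window survives
  qone <- make_q(c(10L, rep(40L, 99)))
  one <- pair_row("p4", strrep("A", 100), strrep("C", 100), q1 = qone)
  expect_true(quality_filter(one))

  expect_error(quality_filter(pair_row("p5", "", "A", q1 = "", q2 = "I")),
               "empty")
  expect_error(quality_filter(good, window_frac = 0), "window_frac")
})

test_that("clone filter keeps one first-seen representative per distinct pair", {
  pairs <- dplyr::bind_rows(
    pair_row("a", "ACGTACGT", "TTTTAAAA"),
    pair_row("b", "ACGTACGT", "TTTTAAAA"),   # exact clone of a
    pair_row("c", "ACGTACGT", "GGGGCCCC"),   # same seq1 only
    pair_row("d", "TTTTTTTT", "TTTTAAAA")    # same seq2 only
  )
  out <- clone_filter(pairs)
  expect_equal(out$pair_id, c("a", "c", "d"))
  ## idempotence
  expect_identical(clone_filter(out), out)
})

test_that("pair classification requires both ends unmapped", {
  ref <- c(chr = random_dna(500))
  idx <- kmer_index(list(genome = ref), k = 28)

  inside <- substr(ref, 101, 200)           # maps forward
  inside_rc <- revcomp(substr(ref, 301, 400))  # maps via reverse strand
  away <- strrep("AC", 50)                  # shares no 28-mer whp? force:
  away <- paste0(strrep("A", 60), strrep("C", 40))

  both_in <- pair_row("m", inside, inside_rc)
  half_in <- pair_row("h", away, inside)
  both_out <- pair_row("u", away, revcomp(away))

  cls <- classify_pairs(dplyr::bind_rows(both_in, half_in, both_out), idx)
  expect_equal(cls$status, c("mapped", "mapped", "unmapped"))

  ## mates shorter than k cannot map, with a warning
  short <- pair_row("s", "ACGT", "TTGG")
  expect_warning(cs <- classify_pairs(short, idx), "shorter than k")
  expect_equal(cs$status, "unmapped")
})

test_that("classification agrees with a brute-force substring oracle", {
  set.seed(11)
  refs <- setNames(random_dna(c(400, 300)), c("r1", "r2"))
  idx <- kmer_index(list(genome = refs), k = 28)
  pairs <- dplyr::bind_rows(lapply(1:30, function(i) {
    mk <- function() {
      if (runif(1) < 0.5) {
        r <- refs[[sample(2, 1)]]
        st <- sample(nchar(r) - 60, 1)
        s <- substr(r, st, st + 59)
        if (runif(1) < 0.5) s <- revcomp(s)
        s
      } else random_dna(60)
    }
    pair_row(sprintf("p%02d", i), mk(), mk())
  }))
  cls <- classify_pairs(pairs, idx)
  want <- vapply(seq_len(nrow(pairs)), function(i) {
    oracle_pair_mapped(pairs$seq1[i], pairs$seq2[i], unname(refs), 28)
  }, logical(1))
  expect_equal(cls$status == "mapped", want)
})

test_that("screen_library retains hidden-region reads, removes reference reads, and accounts exactly", {
  w <- make_world(seed = 8, n_genes = 10, n_novel = 3)
  idx <- kmer_index(list(genome = w$public_reference), k = w$k)

  hid <- dplyr::bind_rows(lapply(names(w$transcripts), function(id) {
    simulate_read_pairs(w, id, depth = 10, fragment_len = 250, seed = 3)
  }))
  ref <- simulate_read_pairs(w, "chrH", depth = 1, fragment_len = 250,
                             seed = 3)

  s_hid <- screen_library(hid, idx)
  expect_equal(nrow(s_hid$retained), nrow(clone_filter(hid)))

  s_ref <- screen_library(ref, idx)
  expect_equal(nrow(s_ref$retained), 0)

  ## accounting invariant: input = retained + sum(removed)
  st <- screen_library(dplyr::bind_rows(hid, ref), idx)$stats
  input <- st$count[st$stage == "input"]
  retained <- st$count[st$stage == "retained"]
  removed <- sum(st$count[!st$stage %in% c("input", "retained")])
  expect_equal(input, retained + removed)
  expect_true(all(st$count >= 0))

  ## empty library
  s0 <- screen_library(hid[0, ], idx)
  expect_equal(nrow(s0$retained), 0)
  expect_true(all(s0$stats$count == 0))
})

test_that("screening is monotone in the index and order-invariant in the retained set", {
  w <- make_world(seed = 9, n_genes = 8, n_novel = 2)
  pairs <- dplyr::bind_rows(
    simulate_read_pairs(w, "novel_01", depth = 8, fragment_len = 250, seed = 1),
    simulate_read_pairs(w, "chrH", depth = 0.5, fragment_len = 250, seed = 1)
  )
  idx1 <- kmer_index(list(genome = w$public_reference), k = w$k)
  idx2 <- kmer_index(list(genome = w$public_reference,
                          extra = w$hidden_regions[1]), k = w$k)
  r1 <- screen_library(pairs, idx1)$retained
  r2 <- screen_library(pairs, idx2)$retained
  expect_true(all(r2$pair_id %in% r1$pair_id))
  expect_lt(nrow(r2), nrow(r1))

  ## permuting the input leaves the retained set equal (canonical order)
  set.seed(1)
  perm <- pairs[sample(nrow(pairs)), ]
  rp <- screen_library(perm, idx1)$retained
  expect_setequal(paste(rp$seq1, rp$seq2), paste(r1$seq1, r1$seq2))
})

test_that("SAM ingestion keeps both-ends-unmapped pairs and restores orientation", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:1000",
    ## pair q1: both unmapped (77 = paired+unmapped+mate-unmapped+first,
    ## 141 = paired+unmapped+mate-unmapped+second)
    "q1\t77\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "q1\t141\t*\t0\t0\t*\t*\t0\t0\tGGGGCCCCAA\tJJJJJJJJJJ",
    ## pair q2: mate1 mapped (99), mate2 unmapped -> dropped
    "q2\t99\tchr1\t100\t60\t10M\t=\t200\t100\tTTTTTTTTTT\tIIIIIIIIII",
    "q2\t181\t*\t0\t0\t*\t*\t0\t0\tCCCCCCCCCC\tIIIIIIIIII",
    ## pair q3: both unmapped, mate2 stored reverse (flag 141+16=157)
    "q3\t77\t*\t0\t0\t*\t*\t0\t0\tAAAACCCGGT\tIIIIIIIIII",
    "q3\t157\t*\t0\t0\t*\t*\t0\t0\tAATTGGCCTT\tABCDEFGHIJ"
  )
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  out <- ingest_sam(f)
  expect_equal(sort(out$pair_id), c("q1", "q3"))
  expect_equal(out$seq1[out$pair_id == "q1"], "ACGTACGTAC")
  ## reverse-flagged mate comes back reverse-complemented, quality reversed
  expect_equal(out$seq2[out$pair_id == "q3"], revcomp("AATTGGCCTT"))
  expect_equal(out$qual2[out$pair_id == "q3"], "JIHGFEDCBA")

  ## orphan record warns and is dropped
  f2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam[c(1, 3)], f2)
  expect_warning(o2 <- ingest_sam(f2), "orphan")
  expect_equal(nrow(o2), 0)

  ## header-only SAM gives an empty set; malformed line errors
  f3 <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam[1:2], f3)
  expect_equal(nrow(ingest_sam(f3)), 0)
  f4 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam[1], "broken\t77\tonly-three-fields"), f4)
  expect_error(ingest_sam(f4), "malformed")
})
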