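test_that("greedy assembly reconstructs a tiled template exactly", {
  set.seed(21)
  template <- random_dna(400)
  pairs <- tiling_pairs(template, read_len = 100, step = 50)
  out <- greedy_assemble(pairs)
  expect_equal(nrow(out), 1)
  expect_true(out$seq %in% c(template, revcomp(template)))

  ## two disjoint templates give two contigs
  t2 <- random_dna(450)
  out2 <- greedy_assemble(dplyr::bind_rows(tiling_pairs(template),
                                           tiling_pairs(t2)))
  expect_equal(nrow(out2), 2)
  canon <- function(s) pmin(s, revcomp(s))
  expect_setequal(canon(out2$seq), canon(c(template, t2)))

  ## empty input
  expect_equal(nrow(greedy_assemble(pairs[0, ])), 0)
})

test_that("the long-transcript length cutoff is strict", {
  set.seed(22)
  t200 <- random_dna(200)
  t201 <- random_dna(201)
  out <- greedy_assemble(dplyr::bind_rows(tiling_pairs(t200, step = 25),
                                          tiling_pairs(t201, step = 25)))
  expect_equal(nrow(out), 1)
  expect_equal(out$length, 201L)
})

test_that("assembly output is invariant to read order", {
  set.seed(23)
  template <- random_dna(500)
  pairs <- tiling_pairs(template, step = 40)
  perm <- pairs[sample(nrow(pairs)), ]
  perm$pair_id <- sprintf("renamed:%03d", seq_len(nrow(perm)))
  expect_identical(greedy_assemble(pairs)$seq, greedy_assemble(perm)$seq)
})

test_that("pair mapping emits links only for two-transcript bridges", {
  jf <- make_join_fixture(seed = 1, n_single = 2, n_two = 2, n_three = 1,
                          support = 6)
  links <- map_pairs_to_transcripts(jf$pairs, jf$transcripts)
  ## every bridging pair links two distinct members of the same chain
  expect_true(all(links$transcript_a != links$transcript_b))
  expect_equal(nrow(links), nrow(jf$pairs))
  expect_equal(attr(links, "ambiguous"), 0L)

  ## a pair wholly inside one transcript yields no link
  t1 <- jf$transcripts$seq[1]
  inside <- pair_row("in", substr(t1, 1, 100),
                     revcomp(substr(t1, 150, 249)))
  l0 <- map_pairs_to_transcripts(inside, jf$transcripts)
  expect_equal(nrow(l0), 0)

  ## a pair matching nothing yields no link
  set.seed(3)
  none <- pair_row("out", random_dna(100), random_dna(100))
  expect_equal(nrow(map_pairs_to_transcripts(none, jf$transcripts)), 0)

  ## a mate shared between two transcripts is ambiguous and skipped
  dup <- dplyr::bind_rows(jf$transcripts,
                          tibble::tibble(id = "copy",
                                         seq = jf$transcripts$seq[1],
                                         members = list("copy")))
  amb <- map_pairs_to_transcripts(inside, dup)
  expect_equal(nrow(amb), 0)
  expect_equal(attr(amb, "ambiguous"), 1L)
})

test_that("join support is strictly greater-than and orientation ties drop edges", {
  jf6 <- make_join_fixture(seed = 2, n_single = 0, n_two = 1, n_three = 0,
                           support = 6)
  g6 <- build_join_graph(map_pairs_to_transcripts(jf6$pairs, jf6$transcripts),
                         min_support = 5)
  expect_equal(nrow(g6), 1)
  expect_equal(g6$support, 6L)

  jf5 <- make_join_fixture(seed = 2, n_single = 0, n_two = 1, n_three = 0,
                           support = 5)
  g5 <- build_join_graph(map_pairs_to_transcripts(jf5$pairs, jf5$transcripts),
                         min_support = 5)
  expect_equal(nrow(g5), 0)

  ## monotonicity in min_support
  links <- map_pairs_to_transcripts(jf6$pairs, jf6$transcripts)
  for (ms in c(0, 2, 5)) {
    expect_gte(nrow(build_join_graph(links, min_support = ms)),
               nrow(build_join_graph(links, min_support = ms + 1)))
  }

  ## contradictory orientations in equal numbers drop the edge
  flip <- links
  half <- seq_len(nrow(flip)) <= nrow(flip) / 2
  flip$end_a[half] <- ifelse(flip$end_a[half] == "3'", "5'", "3'")
  expect_message(gt <- build_join_graph(flip, min_support = 5), "tied")
  expect_equal(nrow(gt), 0)
})

test_that("path components join in order, branches and cycles do not", {
  seqs <- setNames(random_dna(rep(300, 4)), c("a", "b", "c", "d"))
  tx <- tibble::tibble(id = names(seqs), seq = unname(seqs))

  path <- tibble::tibble(a = c("a", "b"), b = c("b", "c"),
                         support = 6L, end_a = "3'", end_b = "5'")
  out <- join_transcripts(path, tx)
  joined <- out[lengths(out$members) > 1, ]
  expect_equal(nrow(joined), 1)
  expect_equal(joined$members[[1]], c("a", "b", "c"))
  expect_equal(joined$id, "a:b:c")
  ## members concatenated in order with a 50-N spacer
  expect_equal(joined$seq, paste(seqs[c("a", "b", "c")],
                                 collapse = strrep("N", 50)))
  ## d passes through untouched
  expect_true("d" %in% out$id)

  ## empty graph is the identity
  empty <- path[0, ]
  expect_equal(join_transcripts(empty, tx)$id, tx$id)

  ## star (branch at a) refuses to join
  star <- tibble::tibble(a = c("a", "a", "a"), b = c("b", "c", "d"),
                         support = 6L, end_a = "3'", end_b = "5'")
  expect_message(so <- join_transcripts(star, tx), "unjoined")
  expect_true(all(lengths(so$members) == 1))

  ## cycle refuses to join
  cyc <- tibble::tibble(a = c("a", "b", "a"), b = c("b", "c", "c"),
                        support = 6L, end_a = "3'", end_b = "5'")
  expect_message(co <- join_transcripts(cyc, tx), "unjoined")
  expect_true(all(lengths(co$members) == 1))
})

test_that("orientation evidence flips reverse-stored members", {
  jf <- make_join_fixture(seed = 5, n_single = 0, n_two = 1, n_three = 0,
                          support = 8)
  ## store the second member reverse-complemented, as an assembler might
  tx <- jf$transcripts
  tx$seq[2] <- revcomp(tx$seq[2])
  joined <- join_until_stable(jf$pairs, tx)
  expect_equal(sum(lengths(joined$members) > 1), 1)
  ## the joined sequence still reconstitutes the planted transcript
  expect_equal(validate_joins(joined, jf$truth), 1.0)
})

test_that("joining reaches a fixed point and validates against planted truth", {
  jf <- make_join_fixture(seed = 3, n_single = 4, n_two = 2, n_three = 2,
                          support = 7)
  j1 <- join_until_stable(jf$pairs, jf$transcripts)
  expect_equal(sum(lengths(j1$members) > 1), 4)
  expect_equal(validate_joins(j1, jf$truth), 1.0)

  ## re-application changes nothing
  j2 <- join_until_stable(jf$pairs, j1)
  expect_identical(j1$id, j2$id)

  ## id relabeling does not change the join structure
  relab <- jf$transcripts
  relab$id <- sprintf("zz%02d", rev(seq_len(nrow(relab))))
  relab$members <- as.list(relab$id)
  jr <- join_until_stable(jf$pairs, relab)
  expect_equal(sum(lengths(jr$members) > 1), 4)
  expect_equal(sort(lengths(jr$members)[lengths(jr$members) > 1]),
               sort(lengths(j1$members)[lengths(j1$members) > 1]))

  ## a deliberately shuffled member order is counted incorrect
  bad <- j1[lengths(j1$members) > 1, ][1, ]
  blocks <- strsplit(bad$seq, "N+")[[1]]
  bad$seq <- paste(rev(blocks), collapse = strrep("N", 50))
  expect_equal(validate_joins(bad, jf$truth), 0.0)

  ## no joined transcripts: vacuous 1.0 with a message
  singles <- j1[lengths(j1$members) == 1, ]
  expect_message(v <- validate_joins(singles, jf$truth), "vacuous")
  expect_equal(v, 1.0)
})
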