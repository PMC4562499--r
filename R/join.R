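#' Map read pairs onto assembled transcripts to find bridging evidence
#'
#' Each mate is placed by exact shared k-mers against the transcript set;
#' a mate "maps" when all its k-mer hits fall on exactly one transcript
#' (ambiguous mates void the pair, counted in the `ambiguous` attribute).
#' A link record is emitted when the two mates of a pair map to two
#' different transcripts. The transcript end facing the partner follows
#' from the mapped strand of an FR pair: a forward-mapped mate faces the
#' 3' end, a reverse-mapped mate the 5' end.
#'
#' @param pairs read-pair tibble.
#' @param transcripts transcript tibble (`id`, `seq`).
#' @param k seed length.
#' @return link tibble: `pair_id`, `transcript_a`, `transcript_b`,
#'   `strand_a`, `strand_b`, `end_a`, `end_b`; attribute `ambiguous`
#'   counts pairs skipped for ambiguous placement.
#' @export
map_pairs_to_transcripts <- function(pairs, transcripts, k = 28) {
  assert_that(nrow(transcripts) > 0, "`transcripts` must be non-empty")
  idx <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, val) {
    cur <- get0(key, envir = idx, ifnotfound = NULL)
    assign(key, c(cur, val), envir = idx)
  }
  for (i in seq_len(nrow(transcripts))) {
    for (km in unique(seq_kmers(transcripts$seq[i], k))) add(km, i)
    for (km in unique(seq_kmers(revcomp(transcripts$seq[i]), k))) add(km, -i)
  }
  place <- function(s) {
    hits <- unlist(lapply(seq_kmers(s, k), get0, envir = idx,
                          ifnotfound = NULL), use.names = FALSE)
    if (is.null(hits) || length(hits) == 0) return(NULL)
    tx <- unique(abs(hits))
    if (length(tx) > 1) return(NA)  # ambiguous across transcripts
    strands <- unique(sign(hits))
    if (length(strands) > 1) return(NA)
    list(tx = tx, strand = if (strands > 0) "+" else "-")
  }
  links <- vector("list", nrow(pairs))
  ambiguous <- 0L
  for (r in seq_len(nrow(pairs))) {
    p1 <- place(pairs$seq1[r])
    p2 <- place(pairs$seq2[r])
    if (is.null(p1) || is.null(p2)) next
    if (identical(p1, NA) || identical(p2, NA)) {
      ambiguous <- ambiguous + 1L
      next
    }
    if (p1$tx == p2$tx) next
    links[[r]] <- tibble(
      pair_id = pairs$pair_id[r],
      transcript_a = transcripts$id[p1$tx],
      transcript_b = transcripts$id[p2$tx],
      strand_a = p1$strand, strand_b = p2$strand,
      end_a = ifelse(p1$strand == "+", "3'", "5'"),
      end_b = ifelse(p2$strand == "+", "3'", "5'")
    )
  }
  out <- dplyr::bind_rows(links)
  if (nrow(out) == 0) {
    out <- tibble(pair_id = character(0), transcript_a = character(0),
                  transcript_b = character(0), strand_a = character(0),
                  strand_b = character(0), end_a = character(0),
                  end_b = character(0))
  }
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Build the join graph from link records
#'
#' An undirected edge between two transcripts exists only when strictly
#' more than `min_support` distinct read pairs bridge them ("more than
#' five reads" at the default). The edge's end orientation is the
#' majority (end_a, end_b) combination over its supporting links; a tied
#' majority drops the edge with a message.
#'
#' @param links link tibble from [map_pairs_to_transcripts()].
#' @param min_support edges require support strictly greater than this.
#' @return edge tibble: `a`, `b` (a < b), `support`, `end_a`, `end_b`.
#' @export
build_join_graph <- function(links, min_support = 5) {
  assert_that(min_support >= 0, "`min_support` must be >= 0")
  empty <- tibble(a = character(0), b = character(0), support = integer(0),
                  end_a = character(0), end_b = character(0))
  if (nrow(links) == 0) return(empty)
  canon <- links %>%
    distinct(.data$pair_id, .keep_all = TRUE) %>%
    mutate(swap = .data$transcript_a > .data$transcript_b,
           a = ifelse(.data$swap, .data$transcript_b, .data$transcript_a),
           b = ifelse(.data$swap, .data$transcript_a, .data$transcript_b),
           ea = ifelse(.data$swap, .data$end_b, .data$end_a),
           eb = ifelse(.data$swap, .data$end_a, .data$end_b))
  edges <- canon %>%
    group_by(.data$a, .data$b) %>%
    summarise(support = dplyr::n_distinct(.data$pair_id),
              orient = {
        tab <- sort(table(paste(.data$ea, .data$eb)), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_character_
        else names(tab)[1]
      }, .groups = "drop") %>%
    filter(.data$support > min_support)
  tied <- is.na(edges$orient)
  if (any(tied)) {
    message(sum(tied), " edge(s) dropped for tied orientation")
    edges <- edges[!tied, , drop = FALSE]
  }
  if (nrow(edges) == 0) return(empty)
  or <- stringr::str_split_fixed(edges$orient, " ", 2)
  tibble(a = edges$a, b = edges$b, support = as.integer(edges$support),
         end_a = or[, 1], end_b = or[, 2])
}

#' Join transcripts along simple paths of the join graph
#'
#' Connected components that form simple, orientation-consistent paths
#' are concatenated in path order with a spacer of `gap` `N` characters
#' between members, mirroring the 50 bp N-gap concatenation convention;
#' the joined id records the members as `a:b:c`. Components containing a
#' branch (degree > 2), a cycle, or contradictory end orientations are
#' left unjoined and reported via a message — chain joins are the only
#' order the read evidence defines.
#'
#' @param graph edge tibble from [build_join_graph()].
#' @param transcripts transcript tibble (`id`, `seq`, optionally
#'   `members`).
#' @param gap number of `N` characters inserted between joined members.
#' @return transcript tibble in which each joined path replaces its
#'   members; `members` lists constituent ids in path order and
#'   `member_strand` their orientations.
#' @export
join_transcripts <- function(graph, transcripts, gap = 50) {
  if (!"members" %in% names(transcripts)) {
    transcripts$members <- as.list(transcripts$id)
  }
  if (!"member_strand" %in% names(transcripts)) {
    transcripts$member_strand <- purrr::map(transcripts$members,
                                            ~rep("+", length(.x)))
  }
  if (nrow(graph) == 0) return(transcripts)
  assert_that(all(c(graph$a, graph$b) %in% transcripts$id),
              "graph nodes must be a subset of transcript ids")

  nodes <- sort(unique(c(graph$a, graph$b)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(graph))) {
    adj[[graph$a[r]]] <- c(adj[[graph$a[r]]], graph$b[r])
    adj[[graph$b[r]]] <- c(adj[[graph$b[r]]], graph$a[r])
  }
  edge_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  ends <- setNames(purrr::map(seq_len(nrow(graph)),
                              ~c(graph$end_a[.x], graph$end_b[.x])),
                   edge_key(graph$a, graph$b))
  ## end facing the partner, for node x on edge (x, y)
  facing <- function(x, y) {
    e <- ends[[edge_key(x, y)]]
    if (x <= y) e[1] else e[2]
  }

  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  components <- list()
  for (nd in nodes) {
    if (seen[nd]) next
    comp <- character(0)
    queue <- nd
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      if (seen[cur]) next
      seen[cur] <- TRUE
      comp <- c(comp, cur)
      queue <- c(queue, adj[[cur]][!seen[adj[[cur]]]])
    }
    components[[length(components) + 1L]] <- sort(comp)
  }

  tx_seq <- setNames(transcripts$seq, transcripts$id)
  spacer <- strrep("N", gap)
  joined_rows <- list()
  consumed <- character(0)
  skipped <- 0L

  for (comp in components) {
    deg <- lengths(adj[comp])
    n_edges <- sum(deg) / 2
    if (any(deg > 2) || n_edges != length(comp) - 1) {
      skipped <- skipped + 1L  # branch or cycle: evidence defines no order
      next
    }
    endpoints <- comp[deg[comp] == 1]
    start <- min(endpoints)
    path <- start
    prev <- NA_character_
    cur <- start
    while (TRUE) {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0) break
      path <- c(path, nxt)
      prev <- cur
      cur <- nxt
    }
    ## orientation propagation: the end facing the next member must be 3'
    ## in oriented coordinates, the end facing the previous member 5'.
    ok <- TRUE
    strand <- character(length(path))
    strand[1] <- if (facing(path[1], path[2]) == "3'") "+" else "-"
    for (i in 2:length(path)) {
      lead <- facing(path[i], path[i - 1])
      strand[i] <- if (lead == "5'") "+" else "-"
      if (i < length(path)) {
        trail <- facing(path[i], path[i + 1])
        expected <- if (strand[i] == "+") "3'" else "5'"
        if (trail != expected) { ok <- FALSE; break }
      }
    }
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    oriented <- ifelse(strand == "+", tx_seq[path], revcomp(tx_seq[path]))
    joined_rows[[length(joined_rows) + 1L]] <- tibble(
      id = paste(path, collapse = ":"),
      seq = paste(oriented, collapse = spacer),
      length = sum(nchar(oriented)) + (length(path) - 1L) * gap,
      members = list(path),
      member_strand = list(strand)
    )
    consumed <- c(consumed, path)
  }
  if (skipped > 0) {
    message(skipped, " component(s) left unjoined (branch, cycle, or ",
            "orientation conflict)")
  }
  keep <- transcripts[!transcripts$id %in% consumed, , drop = FALSE]
  dplyr::bind_rows(keep, dplyr::bind_rows(joined_rows)) %>%
    arrange(.data$id)
}

#' Iterate mapping, graph building and joining to a fixed point
#'
#' Higher-order chains (`a:b` with `b:c` giving `a:b:c`) emerge from the
#' path structure of the join graph; this wrapper re-maps the read pairs
#' to the joined set and repeats until no further edge forms.
#'
#' @inheritParams map_pairs_to_transcripts
#' @inheritParams build_join_graph
#' @inheritParams join_transcripts
#' @param max_iter safety bound on rounds.
#' @return joined transcript tibble.
#' @export
join_until_stable <- function(pairs, transcripts, k = 28, min_support = 5,
                              gap = 50, max_iter = 10) {
  for (i in seq_len(max_iter)) {
    links <- map_pairs_to_transcripts(pairs, transcripts, k = k)
    graph <- build_join_graph(links, min_support = min_support)
    if (nrow(graph) == 0) break
    transcripts <- join_transcripts(graph, transcripts, gap = gap)
  }
  transcripts
}

#' Validate joins against planted full-length truth
#'
#' A joined transcript is correct when its members, in recorded order and
#' orientation, map to contiguous, consistently oriented, non-overlapping
#' blocks of a single planted transcript. With no joined transcripts the
#' fraction is defined as 1.0 (reported via a message).
#'
#' @param joined transcript tibble from [join_transcripts()].
#' @param truth tibble with a `seq` column of planted full-length
#'   sequences.
#' @param max_gap maximum tolerated gap between consecutive blocks on the
#'   planted sequence.
#' @return fraction of joined transcripts that are correctly re-assembled.
#' @export
validate_joins <- function(joined, truth, max_gap = 100) {
  multi <- joined[lengths(joined$members) > 1, , drop = FALSE]
  if (nrow(multi) == 0) {
    message("no joined transcripts; correctness vacuously 1.0")
    return(1.0)
  }
  blocks_of <- function(seq) strsplit(seq, "N+")[[1]]
  ordered_in <- function(blocks, target) {
    pos <- 1L
    for (b in blocks) {
      m <- regexpr(b, substr(target, pos, nchar(target)), fixed = TRUE)
      if (m == -1) return(FALSE)
      st <- pos + as.integer(m) - 1L
      if (st > pos + max_gap && pos > 1L) return(FALSE)
      pos <- st + nchar(b)
    }
    TRUE
  }
  correct <- vapply(seq_len(nrow(multi)), function(i) {
    blocks <- blocks_of(multi$seq[i])
    any(vapply(truth$seq, function(t) {
      ordered_in(blocks, t) || ordered_in(revcomp(rev(blocks)), t)
    }, logical(1)))
  }, logical(1))
  mean(correct)
}
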