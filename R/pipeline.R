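#' Run the full discovery pipeline on a synthetic world
#'
#' Executes, in order: fixture generation (`simulate`), read screening
#' (`screen`), assembly (`assemble`), paired-end joining (`join`),
#' sequence annotation (`annotate`), expression-frequency association
#' (`associate`), nearest-gene assignment and adjacent-gene association
#' (`neighbors`), histone-mark calling (`histone`), and
#' discovery-saturation fitting (`saturate`). Intermediate tables are
#' written under `out_dir` and a JSON manifest captures inputs,
#' parameters, seeds, per-stage record counts and per-file MD5 digests,
#' enough to verify byte-identical reruns.
#'
#' @param config list of parameters; see [pipeline_config()] for defaults.
#' @return the manifest, invisibly, as a list; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t0 <- Sys.time()
  note <- function(...) message("[orphanrna] ", ...)

  ## --- simulate -------------------------------------------------------
  note("stage simulate")
  world <- make_world(seed = cfg$seed, n_genes = cfg$n_genes,
                      n_novel = cfg$n_novel,
                      hidden_fraction = cfg$hidden_fraction)
  write_world(world, file.path(cfg$out_dir, "world"))
  design <- tidyr::expand_grid(tissue = world$tissues,
                               condition = c("cancer", "normal")) %>%
    mutate(n_samples = cfg$n_samples_per_cell)
  stages$simulate <- list(n_transcripts = length(world$transcripts),
                          n_genes = nrow(world$homologs))

  ## --- screen ---------------------------------------------------------
  note("stage screen")
  pairs_novel <- purrr::map_dfr(names(world$transcripts), function(id) {
    simulate_read_pairs(world, id, depth = cfg$depth,
                        fragment_len = cfg$fragment_len,
                        read_len = cfg$read_len, error_rate = 0,
                        seed = cfg$seed)
  })
  pairs_ref <- simulate_read_pairs(world, names(world$public_reference)[1],
                                   depth = 2, fragment_len = cfg$fragment_len,
                                   read_len = cfg$read_len, error_rate = 0,
                                   seed = cfg$seed)
  idx <- kmer_index(list(genome = world$public_reference), k = world$k)
  scr <- screen_library(dplyr::bind_rows(pairs_novel, pairs_ref), idx)
  readr::write_tsv(scr$stats, file.path(cfg$out_dir, "screen_stats.tsv"))
  stages$screen <- list(input = nrow(pairs_novel) + nrow(pairs_ref),
                        retained = nrow(scr$retained))

  ## --- assemble -------------------------------------------------------
  note("stage assemble")
  contigs <- greedy_assemble(scr$retained, min_overlap = cfg$min_overlap,
                             min_len = cfg$min_len)
  write_fasta(setNames(contigs$seq, contigs$id),
              file.path(cfg$out_dir, "assembled.fa"))
  stages$assemble <- list(n_contigs = nrow(contigs))

  ## --- join -----------------------------------------------------------
  note("stage join")
  jf <- make_join_fixture(seed = cfg$seed, support = cfg$join_support)
  joined <- join_until_stable(jf$pairs, jf$transcripts, k = world$k,
                              min_support = cfg$min_support, gap = cfg$gap)
  join_frac <- validate_joins(joined, jf$truth)
  write_fasta(setNames(joined$seq, joined$id),
              file.path(cfg$out_dir, "joined.fa"))
  stages$join <- list(n_transcripts = nrow(joined),
                      n_joined = sum(lengths(joined$members) > 1),
                      correct_fraction = join_frac)

  ## --- annotate -------------------------------------------------------
  note("stage annotate")
  gc_split <- split_by_gc(contigs, cutoff = cfg$gc_cutoff)
  stages$annotate <- list(n_low_gc = length(gc_split$low),
                          n_high_gc = length(gc_split$high))

  ## --- associate ------------------------------------------------------
  note("stage associate")
  sim <- simulate_expression(world, design = design, seed = cfg$seed)
  freq <- expression_frequency(sim$expr, sim$meta)
  frequent <- classify_frequent(freq, freq_cutoff = cfg$freq_cutoff)
  assoc <- classify_association(frequent, freq, alpha = cfg$alpha)
  readr::write_tsv(dplyr::select(assoc, -"per_tissue"),
                   file.path(cfg$out_dir, "association.tsv"))
  stages$associate <- list(n_frequent = length(frequent),
                           categories = as.list(table(assoc$category)))

  ## --- neighbors ------------------------------------------------------
  note("stage neighbors")
  truth_tx <- world$truth$transcripts
  aln <- tibble(matches = truth_tx$length, mismatches = 0L, strand = "+",
                qname = truth_tx$transcript, qsize = truth_tx$length,
                qstart = 0L, qend = truth_tx$length,
                tname = truth_tx$chrom, tsize = nchar(world$proxy_genome),
                tstart = truth_tx$start, tend = truth_tx$end,
                block_sizes = as.list(truth_tx$length),
                qstarts = as.list(0L), tstarts = as.list(truth_tx$start))
  prox_ann <- world$annotations %>% filter(.data$species == "proxy")
  assign <- assign_adjacent_gene(aln, prox_ann, world$homologs)
  hum_ann <- world$annotations %>% filter(.data$species == "human")
  conservation <- neighborhood_conservation(prox_ann, hum_ann,
                                            world$homologs)
  adj <- adjacent_gene_association(sim$expr, sim$gene_expr, assign,
                                   sim$meta, alpha = cfg$alpha)
  readr::write_tsv(assign, file.path(cfg$out_dir, "adjacent_genes.tsv"))
  stages$neighbors <- list(n_assigned = sum(assign$assigned),
                           conservation = conservation,
                           categories = as.list(table(adj$category)))

  ## --- histone --------------------------------------------------------
  note("stage histone")
  chip <- simulate_chip(world, base_depth = cfg$chip_depth, seed = cfg$seed)
  marks <- call_marks(chip, cutoff = cfg$mark_cutoff)
  freq_tissues <- freq %>%
    filter(.data$frequency > cfg$freq_cutoff) %>%
    distinct(.data$transcript, .data$tissue)
  tme <- tissue_match_enrichment(marks$calls, freq_tissues,
                                 world$cell_lines)
  readr::write_tsv(marks$calls %>%
                     dplyr::select(dplyr::where(~!is.list(.x))),
                   file.path(cfg$out_dir, "mark_calls.tsv"))
  stages$histone <- list(n_significant =
                           sum(marks$calls$pattern != "none"),
                         tissue_match_p = tme$p_value)

  ## --- saturate -------------------------------------------------------
  note("stage saturate")
  det <- sim$expr %>%
    mutate(count = as.integer(.data$rpkm > 0)) %>%
    dplyr::select("transcript", library = "sample", "count")
  n_lib <- dplyr::n_distinct(det$library)
  sizes <- unique(pmax(1, round(seq(1, n_lib, length.out = 8))))
  disc <- subsample_discovery(det, sizes, n_rep = cfg$n_rep,
                              seed = cfg$seed)
  curve <- disc %>% group_by(.data$size) %>%
    summarise(mean_discovered = mean(.data$discovered), .groups = "drop")
  fit <- fit_one_site(curve$size, curve$mean_discovered)
  readr::write_tsv(disc, file.path(cfg$out_dir, "saturation.tsv"))
  stages$saturate <- list(Bmax = fit$Bmax, Kd = fit$Kd,
                          degenerate = fit$degenerate)

  ## --- manifest -------------------------------------------------------
  files <- sort(list.files(cfg$out_dir, recursive = TRUE,
                           full.names = TRUE))
  files <- files[!basename(files) == "manifest.json"]
  digests <- tools::md5sum(files)
  manifest <- list(
    package = "orphanrna",
    version = as.character(utils::packageVersion("orphanrna")),
    parameters = cfg,
    stages = stages,
    files = setNames(as.list(unname(digests)),
                     sub(paste0("^", cfg$out_dir, "/?"), "", files)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest[names(manifest) != "elapsed_s"],
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Default pipeline configuration
#'
#' All thresholds default to the method's printed values: seed length 28,
#' join support strictly greater than 5, long-transcript length strictly
#' greater than 200, frequent expression strictly above 10%, association
#' alpha 1e-4 (strict), histone cutoff 1e-4 (inclusive), GC split at 65%.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 0L,
    out_dir = file.path(tempdir(), "orphanrna_run"),
    n_genes = 20L, n_novel = 8L, hidden_fraction = 0.1,
    depth = 30, fragment_len = 200, read_len = 100,
    min_overlap = 31L, min_len = 200L,
    min_support = 5L, join_support = 6L, gap = 50L,
    gc_cutoff = 0.65,
    n_samples_per_cell = 50L,
    freq_cutoff = 0.10, alpha = 1e-4,
    chip_depth = 30, mark_cutoff = 1e-4,
    n_rep = 10L
  )
  utils::modifyList(cfg, list(...))
}
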