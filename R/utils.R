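#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join anti_join distinct n rename count pull
#'   row_number across slice first if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats median pnorm pgamma rpois rbinom runif rnorm rlnorm
#'   setNames chisq.test fisher.test dhyper complete.cases coef resid predict
#' @importFrom utils head tail combn
NULL

#' Reverse complement of nucleotide strings
#'
#' Vectorised over a character vector; `N` is preserved.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

## All k-mers of one sequence; sequences shorter than k yield character(0).
## N-containing k-mers are dropped (ambiguous bases never seed a match).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  km[!stringr::str_detect(km, "N")]
}

## Deterministic derived seed: one user-facing integer seed per call, split
## per stage by hashing the stage label. Keeps every stream below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 1000003L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Random DNA of given lengths (vectorised)
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(v) intToUtf8(v + 33L)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
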