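# shared small helpers; coordinates are 0-based half-open everywhere

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate an in-frame nucleotide string; returns NA_character_ if the
# length is not a multiple of 3
translate_nt <- function(nt) {
  if (is.na(nt) || nchar(nt) == 0L || nchar(nt) %% 3L != 0L) return(NA_character_)
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic nucleotide string for the bundled toy reference; a local
# seeded draw leaves the caller's RNG stream untouched
toy_nt <- function(n, seed) {
  with_local_seed(seed,
                  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
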