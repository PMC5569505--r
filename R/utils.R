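#' Derive a named substream seed from a top-level seed
#'
#' All stages of the synthetic community (genomes, fragmentation, reads,
#' markers, annotations, ...) draw their randomness from substreams derived
#' deterministically from one top-level seed, so any stage can be regenerated
#' independently of the others.
#'
#' @param seed integer top-level seed.
#' @param stream character name of the substream.
#' @return an integer seed suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L, nchar(stream) > 0)
  codes <- utf8ToInt(stream)
  h <- sum(codes * (seq_along(codes) %% 97 + 1))
  as.integer((abs(as.numeric(seed)) * 10007 + h * 131) %% 2147483629)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

BASES <- c("A", "C", "G", "T")

#' GC fraction of a DNA sequence
#' @param x character string or [Biostrings::DNAString].
#' @return fraction of G+C among A/C/G/T symbols.
#' @export
gc_fraction <- function(x) {
  x <- Biostrings::DNAString(as.character(x))
  f <- Biostrings::alphabetFrequency(x)[BASES]
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f["G"] + f["C"]) / tot)
}

#' Reverse complement of a DNA string
#' @param x character string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# write.table with fixed options so outputs are byte-stable across runs
write_tsv_stable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_stable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
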