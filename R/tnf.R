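# Canonical tetranucleotide machinery. The 256 4-mers collapse to 136
# strand-independent classes: 16 palindromes plus 120 reverse-complement
# pairs, each class named by the lexicographically smaller member.

all_tetramers <- function() {
  b <- BASES
  apply(expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1], 1, paste,
        collapse = "")
}

#' Canonical tetranucleotide classes
#'
#' @return named character vector mapping each of the 256 tetramers to its
#'   canonical class (the lexicographic minimum of the tetramer and its
#'   reverse complement); 136 distinct classes.
#' @export
canonical_tetramer_map <- function() {
  km <- all_tetramers()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  setNames(pmin(km, rc), km)
}

.tnf_env <- new.env(parent = emptyenv())

#' Names of the tetranucleotide frequency classes
#' @param canonical canonical (136 classes) or raw (256 tetramers).
#' @return sorted character vector of class names.
#' @export
tnf_class_names <- function(canonical = TRUE) {
  if (!canonical) return(sort(all_tetramers()))
  if (is.null(.tnf_env$classes136))
    .tnf_env$classes136 <- sort(unique(canonical_tetramer_map()))
  .tnf_env$classes136
}

#' Tetranucleotide frequency profile of a sequence
#'
#' Counts every overlapping 4-mer window (positions 1..L-3); windows
#' containing a non-ACGT symbol are skipped. With `canonical = TRUE`
#' (default) each tetramer is pooled with its reverse complement, giving a
#' 136-dimensional strand-independent profile; otherwise the raw
#' 256-dimensional profile is returned. Frequencies are normalized by the
#' number of valid windows.
#'
#' @param sequence character string, [Biostrings::DNAString], or one-element
#'   DNAStringSet.
#' @param canonical pool reverse complements (default TRUE).
#' @return object of class `tnf`: list with `values` (named frequency
#'   vector, length 136 or 256), `n_windows` (valid windows counted) and
#'   `empty` (TRUE when no valid window exists; values are then all NA).
#' @export
tetranucleotide_frequencies <- function(sequence, canonical = TRUE) {
  seq <- Biostrings::DNAString(as.character(sequence)[[1]])
  if (length(seq) < 4)
    stop("sequence shorter than 4 bases has no tetranucleotide windows")
  counts <- Biostrings::oligonucleotideFrequency(seq, width = 4, step = 1)
  n_valid <- sum(counts)
  cls <- tnf_class_names(canonical)
  if (canonical) {
    map <- canonical_tetramer_map()
    pooled <- rowsum(as.numeric(counts), map[names(counts)])
    counts <- setNames(pooled[, 1], rownames(pooled))[cls]
    counts[is.na(counts)] <- 0
    names(counts) <- cls
  } else {
    counts <- counts[cls]
  }
  if (n_valid == 0) {
    return(structure(list(values = setNames(rep(NA_real_, length(cls)), cls),
                          n_windows = 0L, empty = TRUE), class = "tnf"))
  }
  structure(list(values = counts / n_valid, n_windows = as.integer(n_valid),
                 empty = FALSE), class = "tnf")
}

#' @export
print.tnf <- function(x, ...) {
  cat(sprintf("<tnf: %d classes, %d valid windows%s>\n", length(x$values),
              x$n_windows, if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

#' Windowed tetranucleotide profiles of binnable scaffolds
#'
#' Scaffolds shorter than `min_scaffold` (default 5000 bp) are excluded from
#' binning. Longer scaffolds are cut into non-overlapping windows of
#' `window_len`; a trailing partial window shorter than `window_len / 2` is
#' merged into the previous window, so every emitted window has at least
#' `window_len / 2` bases (scaffolds at most `window_len` long yield a
#' single profile).
#'
#' @param scaffolds named [Biostrings::DNAStringSet] (or named character).
#' @param window_len window length in bases (default 10000).
#' @param min_scaffold minimum scaffold length admitted to binning
#'   (default 5000 bp).
#' @param canonical pool reverse complements (default TRUE).
#' @return list with `profiles` (numeric matrix, one row per window,
#'   rownames `scaffold.window`), and `windows` (data.frame scaffold_id,
#'   window_index, start, end, n_windows_valid). Scaffolds below the length
#'   gate are absent; empty-profile windows are dropped with a warning.
#' @export
window_profiles <- function(scaffolds, window_len = 10000,
                            min_scaffold = 5000, canonical = TRUE) {
  scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (is.null(names(scaffolds))) stop("scaffolds must be named")
  keep <- Biostrings::width(scaffolds) >= min_scaffold
  scaffolds <- scaffolds[keep]
  if (length(scaffolds) == 0)
    stop("no scaffold passes the minimum length gate")
  rows <- list(); meta <- list()
  for (i in seq_along(scaffolds)) {
    sid <- names(scaffolds)[i]
    L <- Biostrings::width(scaffolds)[i]
    n_full <- L %/% window_len
    rem <- L - n_full * window_len
    if (n_full == 0) {
      starts <- 0; ends <- L
    } else if (rem == 0) {
      starts <- (seq_len(n_full) - 1) * window_len
      ends <- starts + window_len
    } else if (rem < window_len / 2) {
      starts <- (seq_len(n_full) - 1) * window_len
      ends <- c(starts[-n_full] + window_len, L)  # tail merged into last
    } else {
      starts <- c((seq_len(n_full) - 1) * window_len, n_full * window_len)
      ends <- c(seq_len(n_full) * window_len, L)
    }
    for (w in seq_along(starts)) {
      sub <- Biostrings::subseq(scaffolds[[i]], starts[w] + 1, ends[w])
      p <- tetranucleotide_frequencies(sub, canonical = canonical)
      key <- sprintf("%s.w%03d", sid, w)
      if (p$empty) {
        warning(sprintf("window %s has no valid tetranucleotide window; dropped",
                        key))
        next
      }
      rows[[key]] <- p$values
      meta[[key]] <- data.frame(scaffold_id = sid, window_index = w,
                                start = starts[w], end = ends[w],
                                stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, rows)
  list(profiles = profiles, windows = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
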