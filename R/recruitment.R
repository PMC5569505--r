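# Exact full-length read recruitment. A read is recruited to a MAG iff its
# complete sequence occurs as an exact substring of one of the MAG's
# scaffolds, on either strand. This implements the full-length-match filter
# directly; relative abundance then normalizes recruited reads by genome
# size and sampling depth and scales by 1e6.

#' Recruit reads to MAGs by exact full-length matching
#'
#' Reads must have the configured fixed length; reads of any other length
#' are rejected (counted, never matched) because the full-length criterion
#' is length-specific. Reads containing non-ACGT symbols can never match
#' and are tallied as unmatchable. Each mate is counted independently. A
#' read matching several scaffolds of one MAG counts once for that MAG; a
#' read matching several MAGs counts once per MAG and is listed in the
#' ambiguity report.
#'
#' @param reads [Biostrings::DNAStringSet] (or named character vector), or a
#'   path to a FASTQ file.
#' @param scaffolds [Biostrings::DNAStringSet] of all scaffolds.
#' @param bins data.frame with columns scaffold_id, bin_id mapping member
#'   scaffolds to MAGs.
#' @param read_length required read length (default 125).
#' @param sample_id label stored in the counts table.
#' @return object of class `recruitment`: list with `counts` (data.frame
#'   mag_id, sample_id, reads, genome_size, sample_total), `per_read`
#'   (logical matrix reads x MAGs), `ambiguous` (read ids matching > 1 MAG),
#'   `unmatchable` and `bad_length` tallies.
#' @export
recruit_reads <- function(reads, scaffolds, bins, read_length = 125,
                          sample_id = "sample") {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  scaffolds <- Biostrings::DNAStringSet(scaffolds)
  stopifnot(all(c("scaffold_id", "bin_id") %in% names(bins)))
  missing_scaf <- setdiff(bins$scaffold_id, names(scaffolds))
  if (length(missing_scaf))
    stop("bin table references unknown scaffolds: ",
         paste(head(missing_scaf, 3), collapse = ", "))

  n_total <- length(reads)
  len_ok <- Biostrings::width(reads) == read_length
  acgt <- Biostrings::alphabetFrequency(reads)[, c("A", "C", "G", "T"),
                                               drop = FALSE]
  clean <- rowSums(acgt) == Biostrings::width(reads)
  usable <- len_ok & clean
  mags <- sort(unique(bins$bin_id))
  hit <- matrix(FALSE, sum(usable), length(mags),
                dimnames = list(names(reads)[usable], mags))
  if (sum(usable) > 0) {
    pd <- Biostrings::PDict(reads[usable])
    for (m in mags) {
      scafs <- scaffolds[bins$scaffold_id[bins$bin_id == m]]
      fwd <- Biostrings::vcountPDict(pd, scafs)
      rev <- Biostrings::vcountPDict(pd, Biostrings::reverseComplement(scafs))
      hit[, m] <- rowSums(fwd) + rowSums(rev) > 0
    }
  }
  genome_size <- vapply(mags, function(m)
    sum(Biostrings::width(scaffolds[bins$scaffold_id[bins$bin_id == m]])), 0)
  counts <- data.frame(mag_id = mags, sample_id = sample_id,
                       reads = unname(colSums(hit)),
                       genome_size = unname(genome_size),
                       sample_total = n_total, stringsAsFactors = FALSE)
  structure(list(counts = counts, per_read = hit,
                 ambiguous = rownames(hit)[rowSums(hit) > 1],
                 unmatchable = sum(len_ok & !clean),
                 bad_length = sum(!len_ok)),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("<recruitment: %d MAGs, %d/%d reads recruited, %d ambiguous>\n",
              nrow(x$counts), sum(rowSums(x$per_read) > 0),
              x$counts$sample_total[1], length(x$ambiguous)))
  invisible(x)
}

#' Genome-size- and depth-normalized relative abundance
#'
#' abundance(m, s) = (reads(m, s) / genome_size(m)) / sample_total(s) * 1e6:
#' recruited reads are normalized by MAG genome size, corrected for the
#' sequencing depth of the sample, and scaled by one million.
#'
#' @param counts data.frame with columns mag_id, sample_id, reads,
#'   genome_size, sample_total (as produced by [recruit_reads()], possibly
#'   row-bound over samples).
#' @return the same table with an `abundance` column.
#' @export
relative_abundance <- function(counts) {
  need <- c("mag_id", "sample_id", "reads", "genome_size", "sample_total")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$genome_size <= 0)) stop("genome sizes must be positive")
  if (any(counts$sample_total <= 0)) stop("sample totals must be positive")
  if (any(counts$reads < 0)) stop("read counts must be non-negative")
  counts$abundance <- (counts$reads / counts$genome_size) /
    counts$sample_total * 1e6
  counts
}
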