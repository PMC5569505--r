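# Paired-end read simulation: 2 x `read_len` bp reads with inserts drawn
# uniformly from a configured range, mates on opposite strands, per-base
# substitution errors, constant base quality. Genome share of read pairs is
# proportional to depth_weight x genome_length.

#' Simulate paired-end reads from a set of genomes
#'
#' @param genomes named [Biostrings::DNAStringSet] of genome sequences.
#' @param depth_weights named positive weights (expected coverage weight per
#'   genome); pair counts are multinomial with probabilities proportional to
#'   `depth_weights * genome_length`.
#' @param n_pairs number of read pairs (> 0).
#' @param read_len read length (default 125).
#' @param error_rate per-base substitution probability (default 0).
#' @param insert_range inclusive insert-size range (default c(360, 420)).
#' @param seed integer seed.
#' @param quality_char constant Phred+33 quality symbol (default "I", Q40).
#' @return list: `r1`, `r2` ([Biostrings::QualityScaledDNAStringSet], mate 1
#'   forward, mate 2 reverse-complement strand), `truth` (data.frame
#'   read_id, genome_id, start_r1, start_r2, insert).
#' @export
simulate_reads <- function(genomes, depth_weights = NULL, n_pairs,
                           read_len = 125, error_rate = 0,
                           insert_range = c(360, 420), seed = 1L,
                           quality_char = "I") {
  genomes <- Biostrings::DNAStringSet(genomes)
  if (is.null(names(genomes))) stop("genomes must be named")
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  glen <- Biostrings::width(genomes)
  if (any(glen < max(insert_range)))
    stop("every genome must be at least one insert long")
  if (is.null(depth_weights))
    depth_weights <- setNames(rep(1, length(genomes)), names(genomes))
  depth_weights <- depth_weights[names(genomes)]
  if (any(is.na(depth_weights) | depth_weights <= 0))
    stop("depth_weights must be positive for every genome")
  probs <- depth_weights * glen
  probs <- probs / sum(probs)
  with_seed(seed, {
    src <- sample.int(length(genomes), n_pairs, replace = TRUE, prob = probs)
    insert <- sample(seq(insert_range[1], insert_range[2]), n_pairs,
                     replace = TRUE)
    start <- floor(runif(n_pairs) * (glen[src] - insert)) + 1L
    gseq <- as.character(genomes)
    r1 <- substring(gseq[src], start, start + read_len - 1L)
    r2_start <- start + insert - read_len
    r2_fwd <- substring(gseq[src], r2_start, r2_start + read_len - 1L)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(r2_fwd)))
    if (error_rate > 0) {
      r1 <- mutate_reads(r1, error_rate)
      r2 <- mutate_reads(r2, error_rate)
    }
    ids <- sprintf("read_%06d", seq_len(n_pairs))
    truth <- data.frame(read_id = ids, genome_id = names(genomes)[src],
                        start_r1 = start - 1L, start_r2 = r2_start - 1L,
                        insert = insert, stringsAsFactors = FALSE)
    q <- Biostrings::PhredQuality(strrep(quality_char, read_len))
    mk <- function(x, suffix) {
      xs <- Biostrings::DNAStringSet(x)
      names(xs) <- paste0(ids, suffix)
      Biostrings::QualityScaledDNAStringSet(
        xs, Biostrings::PhredQuality(rep(as.character(q), length(xs))))
    }
    list(r1 = mk(r1, "/1"), r2 = mk(r2, "/2"), truth = truth)
  })
}

# substitution errors: each base flips to a uniformly chosen different base
mutate_reads <- function(reads, error_rate) {
  chars <- strsplit(reads, "")
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(runif(length(flat)) < error_rate & flat %in% BASES)
  if (length(hit)) {
    repl <- vapply(flat[hit], function(b) sample(setdiff(BASES, b), 1), "")
    flat[hit] <- repl
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, "", collapse = "")
}

#' Write paired reads as FASTQ (Phred+33)
#' @param sim output of [simulate_reads()].
#' @param prefix path prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return the two paths, invisibly.
#' @export
write_read_pair <- function(sim, prefix) {
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  Biostrings::writeQualityScaledXStringSet(sim$r1, p1)
  Biostrings::writeQualityScaledXStringSet(sim$r2, p2)
  invisible(c(p1, p2))
}
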