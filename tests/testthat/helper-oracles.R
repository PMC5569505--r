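# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's code paths: plain substring loops, grepl scans, and
# brute-force enumeration.

# reverse complement without Biostrings
rc_chartr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# naive overlapping 4-mer counter with non-ACGT masking
naive_tnf <- function(seq, canonical = TRUE) {
  classes <- synmag::tnf_class_names(canonical)
  counts <- setNames(rep(0, length(classes)), classes)
  n <- nchar(seq)
  valid <- 0
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      w <- substr(seq, i, i + 3)
      if (grepl("[^ACGT]", w)) next
      key <- if (canonical) min(w, rc_chartr(w)) else w
      counts[key] <- counts[key] + 1
      valid <- valid + 1
    }
  }
  if (valid == 0) return(list(values = counts * NA, n_windows = 0L))
  list(values = counts / valid, n_windows = valid)
}

# exact-substring scan over scaffolds and their reverse complements
naive_recruit <- function(reads, scaffolds, bins) {
  mags <- sort(unique(bins$bin_id))
  out <- matrix(FALSE, length(reads), length(mags),
                dimnames = list(names(reads), mags))
  scaf_chr <- as.character(scaffolds)
  for (m in mags) {
    seqs <- scaf_chr[bins$scaffold_id[bins$bin_id == m]]
    both <- c(seqs, vapply(seqs, rc_chartr, ""))
    for (i in seq_along(reads)) {
      r <- as.character(reads[[i]])
      if (grepl("[^ACGT]", r) || any(is.na(r))) next
      out[i, m] <- any(vapply(both, function(s) grepl(r, s, fixed = TRUE),
                              TRUE))
    }
  }
  out
}

# brute-force two-sided Mann-Whitney by enumeration of all group splits;
# U computed by direct pair counting (not ranks)
enum_mw <- function(x, y) {
  u_pairs <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_pairs(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_pairs(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# shared mid-sized community fixture (built once per test run)
.fix <- new.env()
test_community <- function() {
  if (is.null(.fix$comm))
    .fix$comm <- simulate_community(
      community_config(seed = 11, n_pairs = 400, genome_length = 1e6))
  .fix$comm
}

# a small additive distance matrix from an explicit tree, by hand:
# ((A:1,B:2):1.5,(C:0.5,D:3):1);  path lengths between tips
additive_4taxon <- function() {
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 1 + 2
  D["A", "C"] <- D["C", "A"] <- 1 + 1.5 + 1 + 0.5
  D["A", "D"] <- D["D", "A"] <- 1 + 1.5 + 1 + 3
  D["B", "C"] <- D["C", "B"] <- 2 + 1.5 + 1 + 0.5
  D["B", "D"] <- D["D", "B"] <- 2 + 1.5 + 1 + 3
  D["C", "D"] <- D["D", "C"] <- 0.5 + 3
  D
}
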