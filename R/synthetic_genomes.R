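#' Specify a synthetic source genome
#'
#' A genome is sampled from an order-`markov_order` Markov chain over
#' A/C/G/T whose transition table is drawn per genome (Dirichlet-perturbed)
#' and then exponentially tilted so the chain's stationary GC matches
#' `gc_target`. Distinct seeds give distinct transition tables and hence
#' distinct tetranucleotide profiles, which is what downstream compositional
#' binning relies on.
#'
#' @param genome_id identifier string.
#' @param length genome length in bases (>= 50000 for binnable genomes).
#' @param gc_target target GC fraction; must lie inside `gc_band`.
#' @param markov_order non-negative integer order of the chain (default 3,
#'   which captures tetranucleotide structure directly).
#' @param relative_depth positive expected sequencing-coverage weight.
#' @param seed integer seed for this genome's transition table and sequence.
#' @param gc_band admissible band for `gc_target` (default (0.2, 0.8)).
#' @param dirichlet_alpha concentration of the per-context Dirichlet draw;
#'   smaller values give more compositionally distinct genomes.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(genome_id, length, gc_target, markov_order = 3L,
                        relative_depth = 1, seed = 1L,
                        gc_band = c(0.2, 0.8), dirichlet_alpha = 2) {
  if (!is.numeric(length) || length(length) != 1L || length < 50000)
    stop("genome length must be a single number >= 50000")
  if (!is.numeric(gc_target) || gc_target <= gc_band[1] || gc_target >= gc_band[2])
    stop(sprintf("gc_target %.3f outside the configured (%.2f, %.2f) band",
                 gc_target, gc_band[1], gc_band[2]))
  if (markov_order < 0 || markov_order != round(markov_order))
    stop("markov_order must be a non-negative integer")
  if (relative_depth <= 0) stop("relative_depth must be positive")
  structure(list(genome_id = as.character(genome_id),
                 length = as.integer(length), gc_target = gc_target,
                 markov_order = as.integer(markov_order),
                 relative_depth = relative_depth, seed = as.integer(seed),
                 dirichlet_alpha = dirichlet_alpha),
            class = "genome_spec")
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# Per-genome transition table: 4^k x 4 row-stochastic, Dirichlet rows
draw_transition_table <- function(k, alpha, seed) {
  n_ctx <- 4L^k
  with_seed(seed, {
    t(vapply(seq_len(n_ctx), function(i) rdirichlet1(rep(alpha, 4)),
             numeric(4)))
  })
}

# Stationary distribution over the 4^k contexts of an order-k chain,
# by power iteration on the context-level transition operator.
context_stationary <- function(trans, k) {
  n_ctx <- nrow(trans)
  mask <- n_ctx / 4L
  pi0 <- rep(1 / n_ctx, n_ctx)
  nxt <- outer((seq_len(n_ctx) - 1L) %% mask, 0:3,
               function(c, b) c * 4L + b) + 1L  # n_ctx x 4 successor index
  for (it in 1:200) {
    flow <- pi0 * trans               # n_ctx x 4
    pi1 <- numeric(n_ctx)
    for (b in 1:4) pi1 <- pi1 + accumulate_at(flow[, b], nxt[, b], n_ctx)
    if (max(abs(pi1 - pi0)) < 1e-12) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  pi0
}

accumulate_at <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Expected emitted GC of the chain at stationarity
chain_gc <- function(trans, k) {
  pi <- context_stationary(trans, k)
  sum(pi * (trans[, 2] + trans[, 3]))  # columns C and G
}

# Tilt columns C/G by factor t and renormalize rows
tilt_gc <- function(trans, t) {
  w <- trans %*% diag(c(1, t, t, 1))
  w / rowSums(w)
}

# Solve for the tilt that brings stationary GC to target (bisection)
calibrate_gc <- function(trans, k, gc_target, tol = 1e-4) {
  lo <- 1e-3; hi <- 1e3
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    g <- chain_gc(tilt_gc(trans, mid), k)
    if (abs(g - gc_target) < tol) return(tilt_gc(trans, mid))
    if (g < gc_target) lo <- mid else hi <- mid
  }
  tilt_gc(trans, sqrt(lo * hi))
}

#' Generate a genome sequence from its spec
#'
#' @param spec a [genome_spec()].
#' @return a single-element [Biostrings::DNAStringSet] named by `genome_id`;
#'   the realized GC is within about 0.02 of `gc_target` for lengths
#'   at least 100 kb. Identical specs give identical sequences.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  k <- spec$markov_order
  trans <- draw_transition_table(k, spec$dirichlet_alpha,
                                 substream_seed(spec$seed, "transition"))
  trans <- calibrate_gc(trans, k, spec$gc_target)
  seq <- with_seed(substream_seed(spec$seed, "sequence"), {
    n_ctx <- 4L^k
    ctx0 <- sample.int(n_ctx, 1L) - 1L
    u <- runif(spec$length)
    codes <- markov_sample_codes(spec$length, k, trans, ctx0, u)
    paste(BASES[codes + 1L], collapse = "")
  })
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- spec$genome_id
  out
}

#' Fragment a genome into assembly-like scaffolds
#'
#' Scaffold lengths are drawn from a log-normal distribution truncated to
#' `[min_len, max_len]`, emulating the length range of a short-read
#' assembly; the sub-5 kb tail is deliberate so the binning length gate has
#' something to exclude. Scaffolds tile the genome without overlap and their
#' lengths sum exactly to the genome length.
#'
#' @param sequence single-element DNAStringSet (or character) genome.
#' @param genome_id identifier used in truth records.
#' @param min_len,max_len truncation bounds (defaults 200 and 177401 bp).
#' @param meanlog,sdlog log-normal parameters of the untruncated length law.
#' @param seed integer seed.
#' @return list with `scaffolds` (DNAStringSet) and `truth` (data.frame of
#'   scaffold_id, genome_id, start, end half-open 0-based, length, gc).
#' @export
fragment_genome <- function(sequence, genome_id, min_len = 200,
                            max_len = 177401, meanlog = log(9000),
                            sdlog = 0.9, seed = 1L) {
  if (min_len < 200) stop("min_len must be >= 200")
  if (min_len > max_len) stop("min_len must not exceed max_len")
  seq <- as.character(sequence)[[1]]
  L <- nchar(seq)
  lens <- with_seed(seed, {
    out <- integer(0); total <- 0
    while (total < L) {
      l <- round(rlnorm(1, meanlog, sdlog))
      if (l < min_len || l > max_len) next
      l <- min(l, L - total)
      out <- c(out, l); total <- total + l
    }
    # a trailing stub shorter than min_len is merged into its predecessor
    n <- length(out)
    if (n > 1 && out[n] < min_len) {
      out[n - 1] <- out[n - 1] + out[n]
      out <- out[-n]
    }
    out
  })
  ends <- cumsum(lens)
  starts <- ends - lens
  ids <- sprintf("%s_s%04d", genome_id, seq_along(lens))
  scaf <- Biostrings::DNAStringSet(substring(seq, starts + 1, ends))
  names(scaf) <- ids
  gc <- Biostrings::letterFrequency(scaf, "GC", as.prob = TRUE)[, 1]
  truth <- data.frame(scaffold_id = ids, genome_id = genome_id,
                      start = starts, end = ends, length = lens,
                      gc = unname(gc), stringsAsFactors = FALSE)
  list(scaffolds = scaf, truth = truth)
}

#' Inject cross-bin contaminant scaffolds into a truth table
#'
#' Relabels a fraction of each recipient bin's scaffolds as coming from a
#' donor genome: the scaffold keeps the donor's sequence (it is drawn from
#' the donor's scaffold pool) but is assigned to the recipient bin, and the
#' truth table records its real origin. This creates exactly the cases the
#' decontamination rules (taxonomy, GC, confidence deviation) must catch.
#'
#' @param truth scaffold truth table from [fragment_genome()] rows bound
#'   together, with a `bin_id` column (initially = genome_id).
#' @param rate fraction of each recipient bin's scaffolds replaced by
#'   contaminants, in \[0, 0.5).
#' @param policy donor-choice policy: `"gc_extreme"` picks, for each
#'   recipient, the donor genome with the largest GC offset (requiring
#'   at least `min_gc_offset`); `"any"` picks uniformly among other genomes.
#' @param genome_gc named vector of genome-level GC fractions.
#' @param min_gc_offset minimum donor-recipient GC offset under
#'   `"gc_extreme"` (default 0.30).
#' @param seed integer seed.
#' @return the truth table with `bin_id` rewritten for injected scaffolds
#'   and a logical `is_contaminant` plus `contaminant_in` column.
#' @export
inject_contaminants <- function(truth, rate, policy = c("gc_extreme", "any"),
                                genome_gc = NULL, min_gc_offset = 0.30,
                                seed = 1L) {
  policy <- match.arg(policy)
  if (rate < 0 || rate >= 0.5) stop("contamination rate must be in [0, 0.5)")
  genomes <- unique(truth$genome_id)
  if (length(genomes) < 2) stop("need >= 2 genomes to inject contaminants")
  if (is.null(truth$bin_id)) truth$bin_id <- truth$genome_id
  truth$is_contaminant <- FALSE
  truth$contaminant_in <- NA_character_
  if (rate == 0) return(truth)
  if (is.null(genome_gc)) {
    genome_gc <- vapply(split(truth$gc * truth$length, truth$genome_id), sum,
                        0) /
      vapply(split(truth$length, truth$genome_id), sum, 0)
  }
  with_seed(seed, {
    for (g in genomes) {
      if (policy == "gc_extreme") {
        off <- abs(genome_gc[setdiff(genomes, g)] - genome_gc[[g]])
        donor <- names(off)[which.max(off)]
        if (off[[donor]] < min_gc_offset) next  # no admissible donor
      } else {
        donor <- sample(setdiff(genomes, g), 1)
      }
      rec_rows <- which(truth$genome_id == g & !truth$is_contaminant)
      n_inject <- round(rate * length(rec_rows))
      if (n_inject == 0) next
      donor_rows <- which(truth$genome_id == donor & truth$bin_id == donor &
                            !truth$is_contaminant)
      n_inject <- min(n_inject, length(donor_rows))
      pick <- sample(donor_rows, n_inject)
      truth$bin_id[pick] <- g
      truth$is_contaminant[pick] <- TRUE
      truth$contaminant_in[pick] <- g
    }
  })
  truth
}
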