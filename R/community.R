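# Top-level synthetic community: ties the genome, fragmentation,
# contamination, read, marker, annotation and evidence generators together
# under one seed, and asserts at generation time that the genomes are
# compositionally separable (so binning benchmarks are well-posed).

#' Default synthetic community configuration
#'
#' Five genomes with distinct Markov transition tables and GC targets
#' spanning 0.32-0.68, long enough to yield about 200 binnable (>= 5 kb)
#' scaffolds each plus a deliberate sub-5 kb tail; uneven sequencing depth;
#' 10% cross-bin contamination from the most GC-distant donor; per-genome
#' marker completeness/duplication settings that straddle the quality
#' gates; two annotation databases.
#'
#' @param seed top-level seed; every stage derives a named substream from
#'   it.
#' @param n_pairs read pairs to simulate (default 20000).
#' @param genome_length per-genome length in bases (default 3.2e6).
#' @param error_rate per-base read substitution rate (default 0.002).
#' @param contamination_rate fraction of each bin's scaffolds replaced by
#'   contaminants (default 0.1).
#' @return a list of class `community_config`.
#' @export
community_config <- function(seed = 1L, n_pairs = 20000,
                             genome_length = 3.2e6, error_rate = 0.002,
                             contamination_rate = 0.1) {
  n <- 5
  structure(list(
    seed = as.integer(seed),
    genome_ids = sprintf("g%02d", seq_len(n)),
    genome_length = rep(genome_length, n),
    gc_targets = c(0.32, 0.42, 0.50, 0.58, 0.68),
    markov_order = 3L,
    dirichlet_alpha = 2,
    relative_depth = c(3, 1.5, 1, 0.75, 0.5),
    taxa = setNames(paste0("phylum_", LETTERS[seq_len(n)]),
                    sprintf("g%02d", seq_len(n))),
    domains = setNames(c("archaea", "archaea", "bacteria", "bacteria",
                         "bacteria"), sprintf("g%02d", seq_len(n))),
    conf_mean = setNames(c(88, 86, 85, 87, 84), sprintf("g%02d", seq_len(n))),
    scaffold_meanlog = log(9000), scaffold_sdlog = 0.9,
    min_scaffold = 200, max_scaffold = 177401,
    contamination_rate = contamination_rate,
    n_pairs = n_pairs, read_len = 125L, error_rate = error_rate,
    insert_range = c(360, 420),
    marker_completeness = setNames(c(1, 14 / 15, 12 / 15, 9 / 15, 6 / 15),
                                   sprintf("g%02d", seq_len(n))),
    marker_duplication = setNames(c(0, 0, 2 / 15, 1 / 15, 0),
                                  sprintf("g%02d", seq_len(n))),
    databases = c("blast_kegg", "hmm_custom"),
    detection_prob = 0.95, false_positive_rate = 0.02,
    tnf_separation_floor = 0.02
  ), class = "community_config")
}

#' Generate a full ground-truthed synthetic community
#'
#' Runs every generator stage under named substreams of the configured
#' seed. Asserts that all genome pairs are separated in canonical
#' tetranucleotide space by at least `tnf_separation_floor` (Euclidean), so
#' that downstream compositional binning is well-posed.
#'
#' @param config a [community_config()].
#' @return list of class `community`: genomes, scaffolds, truth (scaffold
#'   truth incl. bin_id / contamination), reads (r1, r2, truth), markers,
#'   marker_params, annotations, pathway_truth, evidence, taxa, domains,
#'   genome_tnf, config.
#' @export
simulate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  n <- length(config$genome_ids)
  genomes <- Biostrings::DNAStringSet()
  for (i in seq_len(n)) {
    sp <- genome_spec(config$genome_ids[i], config$genome_length[i],
                      config$gc_targets[i],
                      markov_order = config$markov_order,
                      relative_depth = config$relative_depth[i],
                      seed = substream_seed(config$seed,
                                            paste0("genome_", i)),
                      dirichlet_alpha = config$dirichlet_alpha)
    genomes <- c(genomes, generate_genome(sp))
  }
  # generation-time separability assertion
  tnf <- t(vapply(seq_len(n), function(i)
    tetranucleotide_frequencies(genomes[[i]])$values, numeric(136)))
  rownames(tnf) <- config$genome_ids
  dmat <- as.matrix(stats::dist(tnf))
  min_sep <- min(dmat[upper.tri(dmat)])
  if (min_sep < config$tnf_separation_floor)
    stop(sprintf(paste0("genome pair separation %.4f below the configured ",
                        "TNF floor %.4f; community is not binnable"),
                 min_sep, config$tnf_separation_floor))

  scaffolds <- Biostrings::DNAStringSet()
  truth <- list()
  for (i in seq_len(n)) {
    fr <- fragment_genome(genomes[i], config$genome_ids[i],
                          min_len = config$min_scaffold,
                          max_len = config$max_scaffold,
                          meanlog = config$scaffold_meanlog,
                          sdlog = config$scaffold_sdlog,
                          seed = substream_seed(config$seed,
                                                paste0("fragment_", i)))
    scaffolds <- c(scaffolds, fr$scaffolds)
    truth[[i]] <- fr$truth
  }
  truth <- do.call(rbind, truth)
  truth$bin_id <- truth$genome_id
  truth <- inject_contaminants(truth, config$contamination_rate,
                               policy = "gc_extreme",
                               seed = substream_seed(config$seed,
                                                     "contaminants"))

  reads <- simulate_reads(genomes,
                          depth_weights = setNames(config$relative_depth,
                                                   config$genome_ids),
                          n_pairs = config$n_pairs,
                          read_len = config$read_len,
                          error_rate = config$error_rate,
                          insert_range = config$insert_range,
                          seed = substream_seed(config$seed, "reads"))

  markers <- list()
  for (i in seq_len(n)) {
    g <- config$genome_ids[i]
    scafs <- truth$scaffold_id[truth$genome_id == g & !truth$is_contaminant]
    markers[[i]] <- place_markers(
      g, scafs, marker_catalog("set15"),
      completeness = config$marker_completeness[[g]],
      duplication = config$marker_duplication[[g]],
      seed = substream_seed(config$seed, paste0("markers_", i)))
  }
  markers <- do.call(rbind, markers)

  definitions <- default_pathways()
  pathway_truth <- with_seed(substream_seed(config$seed, "pathway_truth"), {
    setNames(lapply(seq_len(n), function(i) {
      # every genome encodes 2-4 of the starter processes
      k <- sample(2:4, 1)
      sort(sample(names(definitions), k))
    }), config$genome_ids)
  })
  annotations <- simulate_annotations(
    pathway_truth, definitions, databases = config$databases,
    detection_prob = config$detection_prob,
    false_positive_rate = config$false_positive_rate,
    seed = substream_seed(config$seed, "annotations"))

  evidence <- simulate_scaffold_evidence(
    truth, config$taxa, config$conf_mean,
    seed = substream_seed(config$seed, "evidence"))

  structure(list(genomes = genomes, scaffolds = scaffolds, truth = truth,
                 reads = reads, markers = markers,
                 marker_params = data.frame(
                   genome_id = config$genome_ids,
                   completeness = unname(config$marker_completeness),
                   duplication = unname(config$marker_duplication)),
                 annotations = annotations, pathway_truth = pathway_truth,
                 pathway_definitions = definitions,
                 evidence = evidence, taxa = config$taxa,
                 domains = config$domains, genome_tnf = tnf,
                 min_tnf_separation = min_sep, config = config),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf(paste0("<community: %d genomes, %d scaffolds (%d contaminant),",
                     " %d read pairs, min TNF separation %.3f>\n"),
              length(x$genomes), nrow(x$truth), sum(x$truth$is_contaminant),
              nrow(x$reads$truth), x$min_tnf_separation))
  invisible(x)
}

#' Write a community to disk (FASTA / FASTQ / TSV)
#'
#' @param community a [simulate_community()] result.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    scaffolds = file.path(outdir, "scaffolds.fasta"),
    truth = file.path(outdir, "scaffold_truth.tsv"),
    markers = file.path(outdir, "marker_hits.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    evidence = file.path(outdir, "scaffold_evidence.tsv"),
    read_truth = file.path(outdir, "read_truth.tsv"))
  Biostrings::writeXStringSet(community$scaffolds, paths["scaffolds"])
  write_tsv_stable(community$truth, paths["truth"])
  write_tsv_stable(community$markers, paths["markers"])
  write_tsv_stable(community$annotations, paths["annotations"])
  write_tsv_stable(community$evidence, paths["evidence"])
  write_tsv_stable(community$reads$truth, paths["read_truth"])
  rp <- write_read_pair(community$reads, file.path(outdir, "reads"))
  invisible(c(paths, r1 = rp[1], r2 = rp[2]))
}
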