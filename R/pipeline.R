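# End-to-end driver: from a synthetic community through binning, QC,
# decontamination, recruitment, functional profiling and phylogeny, with
# evaluation against the community's truth tables. This is what the
# numbered analysis scripts and the acceptance script call.

#' Evaluate a scaffold bin assignment against the truth table
#'
#' @param assignment data.frame scaffold_id, bin_id (from
#'   [scaffold_bin_vote()]).
#' @param truth community truth table (scaffold_id, genome_id).
#' @return list: `ari` (adjusted Rand index over binned scaffolds),
#'   `ari_all` (unbinned treated as its own cluster), `purity` (per-bin
#'   majority-genome fraction), `n_pure_bins` (purity >= 0.9),
#'   `n_genomes_recovered` (genomes that are the majority of some pure
#'   bin), `unbinned_fraction`, `table` (bin x genome contingency).
#' @export
evaluate_binning <- function(assignment, truth) {
  m <- merge(assignment, truth[, c("scaffold_id", "genome_id")],
             by = "scaffold_id")
  binned <- m[m$bin_id != "unbinned", ]
  ari <- mclust::adjustedRandIndex(binned$bin_id, binned$genome_id)
  ari_all <- mclust::adjustedRandIndex(m$bin_id, m$genome_id)
  tab <- table(binned$bin_id, binned$genome_id)
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  top_genome <- colnames(tab)[apply(tab, 1, which.max)]
  pure <- purity >= 0.9
  list(ari = ari, ari_all = ari_all, purity = purity,
       n_pure_bins = sum(pure),
       n_genomes_recovered = length(unique(top_genome[pure])),
       unbinned_fraction = mean(m$bin_id == "unbinned"), table = tab)
}

#' Run the full workflow on a synthetic community
#'
#' Stages: (1) windowed canonical TNF profiles of scaffolds >= 5 kb, SOM
#' training, U-matrix bin delineation and per-scaffold majority vote;
#' (2) marker-based completeness/duplication QC of the truth bins and the
#' completeness/duplication gates; (3) one-pass decontamination of the
#' contaminated truth bins; (4) exact full-length recruitment of a read
#' subset and genome-size/depth-normalized abundance; (5) annotation
#' filtering, cross-database consensus and pathway presence calls compared
#' to the pathway truth; (6) domain-level gene-family Mann-Whitney
#' contrasts on a simulated family matrix; (7) marker blocks simulated down
#' a known genome tree, supermatrix, NJ tree and bootstrap support.
#'
#' @param community a [simulate_community()] result.
#' @param outdir if non-NULL, write all tables/sequences below this
#'   directory.
#' @param n_recruit number of mate-1 reads recruited (default 2000; a
#'   subset keeps the exact-match scan fast without changing semantics).
#' @param som_epochs SOM epochs (default 20).
#' @param u_percentile U-matrix delineation percentile, or "auto"
#'   (default) for the Otsu split (see [delineate_bins()]).
#' @param bootstrap_replicates bootstrap replicates for the marker tree
#'   (default 100).
#' @return list with per-stage results (binning, qc, decontamination,
#'   recruitment, functional, families, phylogeny).
#' @export
run_pipeline <- function(community, outdir = NULL, n_recruit = 2000,
                         som_epochs = 20, u_percentile = "auto",
                         bootstrap_replicates = 100) {
  stopifnot(inherits(community, "community"))
  cfg <- community$config
  seed <- cfg$seed

  ## 1. compositional binning ------------------------------------------
  wp <- window_profiles(community$scaffolds)
  som <- train_som(wp$profiles, epochs = som_epochs,
                   seed = substream_seed(seed, "som"))
  del <- delineate_bins(som, wp$profiles, u_percentile = u_percentile)
  wa <- data.frame(scaffold_id = wp$windows$scaffold_id,
                   bin_id = del$assignment$bin_id, stringsAsFactors = FALSE)
  votes <- scaffold_bin_vote(wa)
  bin_eval <- evaluate_binning(votes, community$truth)

  ## 2. marker QC + gates on the truth bins ----------------------------
  qc <- do.call(rbind, lapply(split(community$markers,
                                    community$markers$genome_id),
                              function(d) estimate_completeness(
                                d, marker_catalog("set15"),
                                bin_id = d$genome_id[1])))
  rownames(qc) <- NULL
  gates <- gate_bins(qc)

  ## 3. decontamination of the contaminated truth bins ------------------
  decon_bins <- split(community$truth$scaffold_id, community$truth$bin_id)
  big_enough <- community$truth$length >= 5000
  decon <- lapply(names(decon_bins), function(b) {
    members <- community$truth$scaffold_id[community$truth$bin_id == b &
                                             big_enough]
    decontaminate(members, community$evidence)
  })
  names(decon) <- names(decon_bins)
  removed <- unlist(lapply(decon, function(d) d$removed$scaffold_id))
  is_cont <- community$truth$scaffold_id[community$truth$is_contaminant &
                                           big_enough]
  native <- setdiff(community$truth$scaffold_id[big_enough], is_cont)
  decon_eval <- list(
    sensitivity = if (length(is_cont)) mean(is_cont %in% removed) else NA,
    false_removals = sum(native %in% removed),
    n_contaminants = length(is_cont))

  ## 4. recruitment + abundance -----------------------------------------
  sub <- community$reads$r1[seq_len(min(n_recruit,
                                        length(community$reads$r1)))]
  bins_tbl <- data.frame(scaffold_id = community$truth$scaffold_id,
                         bin_id = community$truth$bin_id,
                         stringsAsFactors = FALSE)
  rec <- recruit_reads(sub, community$scaffolds, bins_tbl,
                       read_length = cfg$read_len)
  abund <- relative_abundance(rec$counts)
  read_truth <- community$reads$truth
  src <- setNames(read_truth$genome_id, paste0(read_truth$read_id, "/1"))
  hits_src <- rep(FALSE, nrow(rec$per_read))
  for (i in seq_len(nrow(rec$per_read))) {
    g <- src[[rownames(rec$per_read)[i]]]
    hits_src[i] <- rec$per_read[i, g]
  }
  recruit_eval <- list(
    recruited_fraction = mean(rowSums(rec$per_read) > 0),
    source_fraction = mean(hits_src),
    expected_errorfree = (1 - cfg$error_rate)^cfg$read_len)

  ## 5. functional profiling --------------------------------------------
  filt <- filter_records(community$annotations)
  cons <- consensus_enzymes(filt)
  calls <- call_pathways(cons, community$pathway_definitions)
  truth_mat <- matrix(FALSE, nrow(calls), ncol(calls),
                      dimnames = dimnames(calls))
  for (g in rownames(calls))
    truth_mat[g, community$pathway_truth[[g]]] <- TRUE
  func_eval <- list(
    sensitivity = mean(calls[truth_mat]),
    specificity = mean(!calls[!truth_mat]),
    calls = calls, truth = truth_mat)

  ## 6. domain-level gene-family statistics ------------------------------
  # domain contrasts need a community-scale MAG panel (the five synthetic
  # genomes alone cannot power a rank test); 34 archaeal vs 77 bacterial
  # MAGs mirrors a realistic deep-sediment recovery
  panel <- setNames(c(rep("archaea", 34), rep("bacteria", 77)),
                    sprintf("mag_%03d", 1:111))
  fam <- simulate_family_counts(panel, n_families = 20, n_effect = 5,
                                seed = substream_seed(seed, "families"))
  fam_test <- domain_comparison_test(fam$counts, fam$groups)
  fam_means <- family_abundance(fam$counts, fam$groups)
  fam_eval <- list(
    test = fam_test, means = fam_means,
    effect_detected = sum(fam_test$significant &
                            fam_test$family_id %in% fam$effect_families),
    null_rejections = sum(fam_test$significant &
                            !fam_test$family_id %in% fam$effect_families),
    n_effect = length(fam$effect_families))

  ## 7. marker phylogeny --------------------------------------------------
  ref_ids <- c("ref01", "ref02", "ref03")
  taxa <- c(cfg$genome_ids, ref_ids)
  gtree <- with_seed(substream_seed(seed, "tree"), {
    tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
    tr
  })
  cat15 <- marker_catalog("set15")
  presence <- matrix(TRUE, length(taxa), length(cat15),
                     dimnames = list(taxa, cat15))
  for (g in cfg$genome_ids) {
    have <- unique(community$markers$marker[community$markers$genome_id == g])
    presence[g, ] <- cat15 %in% have
  }
  blocks <- lapply(seq_along(cat15), function(j) {
    aln <- simulate_marker_block(gtree, n_sites = 60,
                                 seed = substream_seed(seed,
                                                       paste0("block_", j)))
    aln[presence[, j][names(aln)]]
  })
  names(blocks) <- cat15
  sm <- concatenate_markers(blocks, cat15, min_markers = 8)
  pd <- pairwise_distances(sm)
  tree <- nj_tree(pd$D)
  bs <- bootstrap_support(sm, n_replicates = bootstrap_replicates,
                          seed = substream_seed(seed, "bootstrap"))
  true_pruned <- ape::keep.tip(gtree, sm$taxa)
  topo_ok <- setequal(tree_splits(tree), tree_splits(true_pruned))
  phylo_eval <- list(supermatrix = sm, tree = tree, bootstrap = bs,
                     generating_tree = gtree,
                     topology_recovered = topo_ok,
                     mean_support = mean(bs$support),
                     excluded_taxa = sm$excluded)

  res <- list(binning = list(windows = wp$windows, som = som,
                             delineation = del, votes = votes,
                             eval = bin_eval),
              qc = list(reports = qc, gates = gates),
              decontamination = list(per_bin = decon, eval = decon_eval),
              recruitment = list(result = rec, abundance = abund,
                                 eval = recruit_eval),
              functional = func_eval, families = fam_eval,
              phylogeny = phylo_eval)
  if (!is.null(outdir)) write_pipeline_outputs(community, res, outdir)
  res
}

# serialize the pipeline outputs; stable formatting so identical seeds give
# byte-identical files
write_pipeline_outputs <- function(community, res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_community(community, file.path(outdir, "community"))
  write_tsv_stable(res$binning$votes, file.path(outdir, "bin_assignment.tsv"))
  write_tsv_stable(res$qc$reports, file.path(outdir, "qc_reports.tsv"))
  removed <- do.call(rbind, lapply(names(res$decontamination$per_bin),
                                   function(b) {
    d <- res$decontamination$per_bin[[b]]$removed
    if (nrow(d)) cbind(bin_id = b, d) else NULL
  }))
  if (is.null(removed))
    removed <- data.frame(bin_id = character(), scaffold_id = character(),
                          reasons = character())
  write_tsv_stable(removed, file.path(outdir, "removal_log.tsv"))
  write_tsv_stable(res$recruitment$abundance,
                   file.path(outdir, "abundance.tsv"))
  calls <- as.data.frame(res$functional$calls)
  calls <- cbind(mag_id = rownames(calls), calls)
  write_tsv_stable(calls, file.path(outdir, "pathway_calls.tsv"))
  write_tsv_stable(res$families$test, file.path(outdir, "family_tests.tsv"))
  aln <- res$phylogeny$supermatrix$alignment
  writeLines(paste0(">", names(aln), "\n", aln),
             file.path(outdir, "supermatrix.fasta"))
  write_tsv_stable(res$phylogeny$supermatrix$partitions,
                   file.path(outdir, "partitions.tsv"))
  tree <- res$phylogeny$bootstrap$tree
  ape::write.tree(tree, file.path(outdir, "marker_tree.nwk"))
  supp <- data.frame(split = res$phylogeny$bootstrap$splits,
                     support = unname(res$phylogeny$bootstrap$support))
  write_tsv_stable(supp, file.path(outdir, "bootstrap_support.tsv"))
  invisible(outdir)
}
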