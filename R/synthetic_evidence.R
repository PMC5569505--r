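# Ground-truthed marker placements and multi-database annotation records
# for synthetic genomes: the inputs the QC estimator and the consensus
# pathway caller are exercised against.

#' Place single-copy markers on a genome's scaffolds at controlled
#' completeness and duplication
#'
#' Exactly `round(completeness * |markers|)` distinct markers are present;
#' `round(duplication * |markers|)` of the present markers appear twice.
#' Markers are assigned to scaffolds uniformly at random.
#'
#' @param genome_id identifier recorded per row.
#' @param scaffold_ids scaffolds available to carry markers.
#' @param marker_list character vector of markers (default set15 catalog).
#' @param completeness fraction in \[0, 1\].
#' @param duplication fraction in \[0, 1\]; must not exceed completeness.
#' @param seed integer seed.
#' @return data.frame: genome_id, marker, scaffold_id, copy.
#' @export
place_markers <- function(genome_id, scaffold_ids,
                          marker_list = marker_catalog("set15"),
                          completeness = 1, duplication = 0, seed = 1L) {
  if (completeness < 0 || completeness > 1)
    stop("completeness must be in [0, 1]")
  if (duplication < 0 || duplication > 1)
    stop("duplication must be in [0, 1]")
  if (duplication > completeness)
    stop("duplication cannot exceed completeness")
  M <- length(marker_list)
  n_present <- round(completeness * M)
  n_dup <- round(duplication * M)
  with_seed(seed, {
    present <- sort(sample(marker_list, n_present))
    doubled <- if (n_dup > 0) sort(sample(present, n_dup)) else character(0)
    markers <- c(present, doubled)
    if (length(markers) == 0)
      return(data.frame(genome_id = character(), marker = character(),
                        scaffold_id = character(), copy = integer(),
                        stringsAsFactors = FALSE))
    copy <- c(rep(1L, length(present)),
              rep(2L, length(doubled)))
    scafs <- sample(scaffold_ids, length(markers), replace = TRUE)
    data.frame(genome_id = genome_id, marker = markers, scaffold_id = scafs,
               copy = copy, stringsAsFactors = FALSE)[order(markers, copy), ]
  })
}

#' Simulate multi-database annotation records against a pathway ground truth
#'
#' Every enzyme truly present in a genome yields, per database, a record
#' with probability `detection_prob`; enzymes absent from the genome appear
#' per database with probability `false_positive_rate`. True records are
#' given e-values at or below 1e-20 by construction so the downstream score
#' gate passes them; false positives draw from a wider range and may be
#' gated out.
#'
#' @param pathway_truth named list: genome_id -> character vector of
#'   pathway ids truly encoded by that genome.
#' @param definitions named list of [pathway_definition()]s.
#' @param databases character vector (>= 2) of database names.
#' @param detection_prob per-database detection probability for true
#'   enzymes.
#' @param false_positive_rate per-database probability of a spurious enzyme
#'   record.
#' @param seed integer seed.
#' @return data.frame of annotation records: gene_id, mag_id, database,
#'   enzyme_id, score, score_type, is_true.
#' @export
simulate_annotations <- function(pathway_truth, definitions,
                                 databases = c("blast_kegg", "hmm_custom"),
                                 detection_prob = 0.9,
                                 false_positive_rate = 0.02, seed = 1L) {
  if (length(databases) < 2)
    stop("need >= 2 databases to exercise consensus calling")
  if (detection_prob < 0 || detection_prob > 1 ||
      false_positive_rate < 0 || false_positive_rate > 1)
    stop("probabilities must be in [0, 1]")
  all_enzymes <- sort(unique(unlist(lapply(definitions, `[[`, "components"))))
  rows <- list()
  with_seed(seed, {
    for (g in names(pathway_truth)) {
      true_enz <- sort(unique(unlist(lapply(
        definitions[pathway_truth[[g]]], `[[`, "components"))))
      for (db in databases) {
        det <- true_enz[runif(length(true_enz)) < detection_prob]
        fp_pool <- setdiff(all_enzymes, true_enz)
        fp <- fp_pool[runif(length(fp_pool)) < false_positive_rate]
        enz <- c(det, fp)
        if (length(enz) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = sprintf("%s_%s_%s", g, db, enz),
          mag_id = g, database = db, enzyme_id = enz,
          score = 10^-(runif(length(enz),
                             ifelse(enz %in% det, 21, 10),
                             ifelse(enz %in% det, 60, 40))),
          score_type = "evalue",
          is_true = enz %in% det, stringsAsFactors = FALSE)
      }
    }
  })
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), mag_id = character(),
                      database = character(), enzyme_id = character(),
                      score = numeric(), score_type = character(),
                      is_true = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene taxonomy/confidence evidence for scaffolds
#'
#' Emulates the per-gene taxonomic assignments the decontamination rules
#' consume: every scaffold carries `genes_per_scaffold` genes labeled with
#' its true source genome's taxon at the configured rank, with confidence
#' scores around the genome's mean. Contaminant scaffolds therefore carry
#' the donor's taxonomy and GC, which is exactly what the deviation rules
#' must detect.
#'
#' @param truth scaffold truth table (scaffold_id, genome_id, gc columns).
#' @param taxa named character vector: genome_id -> taxon label.
#' @param conf_mean named numeric: genome_id -> mean confidence (0-100).
#' @param genes_per_scaffold genes per scaffold (default 3).
#' @param conf_sd confidence score spread (default 3).
#' @param seed integer seed.
#' @return data.frame: scaffold_id, gene_id, gc, taxonomy, confidence.
#' @export
simulate_scaffold_evidence <- function(truth, taxa, conf_mean,
                                       genes_per_scaffold = 3, conf_sd = 3,
                                       seed = 1L) {
  stopifnot(all(truth$genome_id %in% names(taxa)),
            all(truth$genome_id %in% names(conf_mean)))
  n <- nrow(truth)
  with_seed(seed, {
    idx <- rep(seq_len(n), each = genes_per_scaffold)
    conf <- pmin(100, pmax(0, stats::rnorm(length(idx),
                                           conf_mean[truth$genome_id[idx]],
                                           conf_sd)))
    data.frame(scaffold_id = truth$scaffold_id[idx],
               gene_id = sprintf("%s_g%d", truth$scaffold_id[idx],
                                 rep(seq_len(genes_per_scaffold), times = n)),
               gc = truth$gc[idx],
               taxonomy = unname(taxa[truth$genome_id[idx]]),
               confidence = round(conf, 1), stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-family count matrix with known domain effects
#'
#' Counts are Poisson per MAG and family. Families listed in
#' `effect_families` have different means in archaea and bacteria
#' (`base_mean` vs `base_mean * effect_size`); all other families share
#' `base_mean` across domains, so any detection on them is a false
#' positive.
#'
#' @param domains named character vector mag_id -> "archaea"/"bacteria".
#' @param n_families total number of families.
#' @param n_effect number of families with a true domain effect.
#' @param base_mean Poisson mean for null families (default 2).
#' @param effect_size multiplicative enrichment in bacteria for effect
#'   families (default 4).
#' @param seed integer seed.
#' @return list: `counts` (data.frame mag_id, family_id, count), `groups`
#'   (data.frame mag_id, domain), `effect_families`.
#' @export
simulate_family_counts <- function(domains, n_families = 20, n_effect = 5,
                                   base_mean = 2, effect_size = 4,
                                   seed = 1L) {
  mags <- names(domains)
  fams <- sprintf("fam_%03d", seq_len(n_families))
  eff <- fams[seq_len(n_effect)]
  with_seed(seed, {
    grid <- expand.grid(mag_id = mags, family_id = fams,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- ifelse(grid$family_id %in% eff &
                   domains[grid$mag_id] == "bacteria",
                 base_mean * effect_size, base_mean)
    grid$count <- stats::rpois(nrow(grid), mu)
    list(counts = grid,
         groups = data.frame(mag_id = mags, domain = unname(domains),
                             stringsAsFactors = FALSE),
         effect_families = eff)
  })
}
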