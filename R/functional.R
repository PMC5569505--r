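# Multi-database functional profiling: score gates, cross-database
# consensus, and pathway presence calls. A metabolic process is called
# present in a MAG only when its key enzymes are confirmed by at least two
# databases AND strictly more than half of the pathway components are
# detected.

#' Filter annotation records by score gates
#'
#' E-value-scored records are kept when the e-value is at or below
#' `evalue_max` (default 1e-20, inclusive). Bit-score records are kept when
#' the score reaches the per-enzyme minimum bit score in `bit_thresholds`
#' (falling back to `default_bit_min`). Records with an unknown score type
#' are dropped with a warning.
#'
#' @param records data.frame: gene_id, mag_id, database, enzyme_id, score,
#'   score_type ("evalue" or "bitscore").
#' @param evalue_max inclusive e-value ceiling (default 1e-20).
#' @param bit_thresholds named numeric vector of per-enzyme minimum bit
#'   scores.
#' @param default_bit_min bit-score floor for enzymes without a custom
#'   threshold (default 50).
#' @return the kept records.
#' @export
filter_records <- function(records, evalue_max = 1e-20,
                           bit_thresholds = numeric(0),
                           default_bit_min = 50) {
  need <- c("gene_id", "mag_id", "database", "enzyme_id", "score", "score_type")
  stopifnot(all(need %in% names(records)))
  if (any(records$score_type == "evalue" & records$score <= 0))
    stop("e-values must be positive")
  known <- records$score_type %in% c("evalue", "bitscore")
  if (any(!known))
    warning(sum(!known), " record(s) with unknown score type dropped")
  records <- records[known, , drop = FALSE]
  thr <- bit_thresholds[records$enzyme_id]
  thr[is.na(thr)] <- default_bit_min
  keep <- ifelse(records$score_type == "evalue",
                 records$score <= evalue_max,
                 records$score >= thr)
  records[keep, , drop = FALSE]
}

#' Cross-database consensus over filtered annotation records
#'
#' An enzyme is confirmed for a MAG when at least `min_databases` distinct
#' databases report it; enzymes seen in fewer databases are retained
#' separately as unconfirmed (they still count toward pathway component
#' fractions, but cannot serve as key-enzyme evidence).
#'
#' @param records filtered annotation records (see [filter_records()]).
#' @param min_databases minimum distinct databases for confirmation
#'   (default 2).
#' @return data.frame: mag_id, enzyme_id, n_databases, confirmed (logical).
#' @export
consensus_enzymes <- function(records, min_databases = 2) {
  if (nrow(records) == 0)
    return(data.frame(mag_id = character(), enzyme_id = character(),
                      n_databases = integer(), confirmed = logical(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(database ~ mag_id + enzyme_id, data = records,
                          FUN = function(d) length(unique(d)))
  names(agg)[3] <- "n_databases"
  agg$confirmed <- agg$n_databases >= min_databases
  agg[order(agg$mag_id, agg$enzyme_id), , drop = FALSE]
}

#' Define a metabolic pathway
#'
#' @param pathway_id identifier.
#' @param components character vector of component enzyme ids (non-empty).
#' @param keys character vector of key enzyme ids (subset of components).
#' @param name human-readable name.
#' @param min_component_fraction strict lower bound on the detected
#'   component fraction (default 0.5).
#' @return object of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, components, keys,
                               name = pathway_id,
                               min_component_fraction = 0.5) {
  components <- unique(as.character(components))
  keys <- unique(as.character(keys))
  if (length(components) == 0) stop("pathway needs at least one component")
  if (!all(keys %in% components))
    stop("key enzymes must be a subset of the components")
  structure(list(pathway_id = pathway_id, name = name,
                 components = components, keys = keys,
                 min_component_fraction = min_component_fraction),
            class = "pathway_definition")
}

#' Parse pathway definitions from structured text
#'
#' One pathway per block, blocks separated by blank lines:
#' ```
#' pathway: reverse_methanogenesis
#' name: Reverse methanogenesis
#' components: mcrA mcrB mcrG mtrA mer mtd mch ftr fwdA
#' keys: mcrA
#' ```
#' @param path file path.
#' @return named list of [pathway_definition()] objects.
#' @export
read_pathway_definitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(lines == ""))
  out <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (length(b) == 0) next
    kv <- regmatches(b, regexec("^([a-z_]+):\\s*(.*)$", b))
    fields <- setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
    if (!"pathway" %in% names(fields))
      stop("pathway block without a 'pathway:' line")
    def <- pathway_definition(
      pathway_id = fields[["pathway"]],
      components = strsplit(fields[["components"]], "[[:space:],]+")[[1]],
      keys = strsplit(fields[["keys"]], "[[:space:],]+")[[1]],
      name = if ("name" %in% names(fields)) fields[["name"]]
             else fields[["pathway"]])
    out[[def$pathway_id]] <- def
  }
  out
}

#' Starter pathway definition set
#'
#' Exemplar anaerobic sediment processes: reverse methanogenesis (key mcrA),
#' dissimilatory sulfate reduction (key dsrAB), lipid beta-oxidation (the
#' four named steps), denitrification (key napA), and fumarate-addition
#' hydrocarbon activation (keys bssA/assA). The shipped file is editable
#' structured text; this returns its parsed form.
#' @return named list of `pathway_definition`s.
#' @export
default_pathways <- function() {
  read_pathway_definitions(system.file("extdata", "pathways.txt",
                                       package = "synmag", mustWork = TRUE))
}

#' Call a pathway present or absent in one MAG
#'
#' Present iff every key enzyme is in the confirmed set AND strictly more
#' than `min_component_fraction` of the components are detected. Detection
#' for the component fraction counts both confirmed and unconfirmed
#' enzymes; key enzymes must be confirmed (multi-database) evidence.
#'
#' @param confirmed character vector of confirmed enzyme ids for the MAG.
#' @param unconfirmed character vector of single-database enzyme ids.
#' @param definition a [pathway_definition()].
#' @return list: present (logical), n_detected, n_components, fraction,
#'   keys_confirmed (logical), detected_components, missing_components.
#' @export
call_pathway <- function(confirmed, unconfirmed, definition) {
  stopifnot(inherits(definition, "pathway_definition"))
  detected <- intersect(definition$components, union(confirmed, unconfirmed))
  frac <- length(detected) / length(definition$components)
  keys_ok <- all(definition$keys %in% confirmed)
  list(present = keys_ok && frac > definition$min_component_fraction,
       n_detected = length(detected),
       n_components = length(definition$components),
       fraction = frac, keys_confirmed = keys_ok,
       detected_components = detected,
       missing_components = setdiff(definition$components, detected))
}

#' Pathway presence matrix over MAGs
#'
#' @param consensus output of [consensus_enzymes()].
#' @param definitions named list of pathway definitions.
#' @return logical matrix MAGs x pathways.
#' @export
call_pathways <- function(consensus, definitions) {
  mags <- sort(unique(consensus$mag_id))
  out <- matrix(FALSE, length(mags), length(definitions),
                dimnames = list(mags, names(definitions)))
  for (m in mags) {
    rows <- consensus[consensus$mag_id == m, ]
    conf <- rows$enzyme_id[rows$confirmed]
    unconf <- rows$enzyme_id[!rows$confirmed]
    for (p in names(definitions))
      out[m, p] <- call_pathway(conf, unconf, definitions[[p]])$present
  }
  out
}

#' Per-domain mean gene-family counts
#'
#' For each gene family, the total gene count in a domain divided by the
#' number of MAGs in that domain (every MAG counts in the denominator,
#' including MAGs without the family). Grouping by another column (e.g.
#' phylum) gives the per-phylum variant.
#'
#' @param counts data.frame: mag_id, family_id, count.
#' @param groups data.frame: mag_id plus the grouping column.
#' @param group_col name of the grouping column (default "domain").
#' @return data.frame family_id x group means, long format: family_id,
#'   group, mean_per_mag, n_mags.
#' @export
family_abundance <- function(counts, groups, group_col = "domain") {
  stopifnot(all(c("mag_id", "family_id", "count") %in% names(counts)),
            all(c("mag_id", group_col) %in% names(groups)))
  groups <- groups[!duplicated(groups$mag_id), ]
  glev <- sort(unique(groups[[group_col]]))
  n_mags <- vapply(glev, function(g) sum(groups[[group_col]] == g), 0)
  if (any(n_mags == 0)) stop("empty group")
  fams <- sort(unique(counts$family_id))
  counts$group <- groups[[group_col]][match(counts$mag_id, groups$mag_id)]
  if (any(is.na(counts$group))) stop("MAG without a group label")
  out <- expand.grid(family_id = fams, group = glev,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tot <- stats::aggregate(count ~ family_id + group, data = counts, FUN = sum)
  out <- merge(out, tot, all.x = TRUE)
  out$count[is.na(out$count)] <- 0
  out$n_mags <- n_mags[out$group]
  out$mean_per_mag <- out$count / out$n_mags
  out[order(out$family_id, out$group),
      c("family_id", "group", "mean_per_mag", "n_mags")]
}
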