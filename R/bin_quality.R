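# Marker-based bin QC. Completeness and duplication are simple single-copy
# marker statistics over a configurable marker list (defaults to the 15
# ribosomal proteins); decontamination applies three one-pass deviation
# rules (taxonomy, GC, annotation confidence) with bin means frozen at the
# initial membership.

#' Estimate bin completeness and single-gene duplication
#'
#' Completeness is the percentage of the marker list present at least once
#' in the bin; duplication is the percentage of the marker list present two
#' or more times.
#'
#' @param marker_hits data.frame with a `marker` column (one row per marker
#'   hit in the bin; repeated rows are extra copies), optionally
#'   `scaffold_id`.
#' @param marker_list character vector of expected single-copy markers.
#' @param bin_id identifier recorded in the report.
#' @return one-row data.frame: bin_id, completeness, duplication,
#'   n_markers_present, n_markers_duplicated.
#' @export
estimate_completeness <- function(marker_hits, marker_list,
                                  bin_id = "bin") {
  if (length(marker_list) == 0) stop("marker_list must be non-empty")
  hits <- marker_hits$marker
  unknown <- setdiff(unique(hits), marker_list)
  if (length(unknown) > 0)
    stop("unknown marker(s) not in marker_list: ",
         paste(unknown, collapse = ", "))
  tab <- table(factor(hits, levels = marker_list))
  n_present <- sum(tab >= 1)
  n_dup <- sum(tab >= 2)
  data.frame(bin_id = bin_id,
             completeness = 100 * n_present / length(marker_list),
             duplication = 100 * n_dup / length(marker_list),
             n_markers_present = n_present, n_markers_duplicated = n_dup,
             stringsAsFactors = FALSE)
}

#' Apply completeness/duplication quality gates to QC reports
#'
#' A bin is kept iff completeness is strictly above `min_completeness` and
#' duplication is at most `max_duplication` (inclusive). The boundary
#' semantics matter: a bin at exactly 50% completeness is rejected, a bin at
#' exactly 10% duplication is kept.
#'
#' @param reports data.frame with columns bin_id, completeness, duplication.
#' @param min_completeness percent, strict lower bound (default 50).
#' @param max_duplication percent, inclusive upper bound (default 10).
#' @return list with `kept` and `rejected` data.frames; `rejected` gains a
#'   `reason` column.
#' @export
gate_bins <- function(reports, min_completeness = 50, max_duplication = 10) {
  ok_c <- reports$completeness > min_completeness
  ok_d <- reports$duplication <= max_duplication
  keep <- ok_c & ok_d
  reason <- character(nrow(reports))
  reason[!ok_c] <- "low_completeness"
  reason[!ok_d] <- ifelse(reason[!ok_d] == "", "high_duplication",
                          "low_completeness;high_duplication")
  rejected <- reports[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  list(kept = reports[keep, , drop = FALSE], rejected = rejected)
}

# majority label with ties resolved to NA (conservative: no removal)
majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) NA_character_ else top
}

#' Remove contaminant scaffolds from a bin by deviation rules
#'
#' One-pass evaluation against bin means computed on the initial
#' membership (means are frozen; removing one scaffold never changes
#' another's verdict within the pass). A scaffold is removed when any of:
#'
#' * `gc`: its GC differs from the bin mean GC by more than `gc_delta`
#'   (absolute, fraction scale; default 0.25);
#' * `taxonomy`: the majority taxonomy of its genes differs from the bin's
#'   majority gene taxonomy (ties in either majority break toward
#'   retention);
#' * `confidence`: its mean gene confidence differs from the bin mean by
#'   more than `conf_delta` percentage points (default 25).
#'
#' Bins with fewer than 3 scaffolds pass through unfiltered with a warning
#' (deviation from the mean of fewer than 3 items is ill-posed). Scaffolds
#' without evidence rows are retained and flagged "unevaluated".
#'
#' @param members character vector of scaffold ids in the bin.
#' @param evidence data.frame with one row per gene: scaffold_id, gc (per
#'   scaffold, repeated across its genes), taxonomy (label at the configured
#'   rank), confidence (0-100).
#' @param gc_delta,conf_delta removal thresholds.
#' @return list: `kept` (scaffold ids), `removed` (data.frame scaffold_id,
#'   reasons, gc, bin_gc, taxonomy, bin_taxonomy, confidence,
#'   bin_confidence), `unevaluated` (scaffold ids without evidence).
#' @export
decontaminate <- function(members, evidence, gc_delta = 0.25,
                          conf_delta = 25) {
  members <- unique(as.character(members))
  ev <- evidence[evidence$scaffold_id %in% members, , drop = FALSE]
  have <- intersect(members, unique(ev$scaffold_id))
  unev <- setdiff(members, have)
  empty_removed <- data.frame(scaffold_id = character(), reasons = character(),
                              gc = numeric(), bin_gc = numeric(),
                              taxonomy = character(), bin_taxonomy = character(),
                              confidence = numeric(), bin_confidence = numeric(),
                              stringsAsFactors = FALSE)
  if (length(members) < 3) {
    warning("bin has fewer than 3 scaffolds; passed through unfiltered")
    return(list(kept = members, removed = empty_removed, unevaluated = unev))
  }
  per_scaf <- lapply(split(ev, ev$scaffold_id), function(d) {
    list(gc = d$gc[1], tax = majority_label(d$taxonomy),
         conf = mean(d$confidence, na.rm = TRUE))
  })
  # bin means frozen on the initial membership
  bin_gc <- mean(vapply(per_scaf, `[[`, 0, "gc"))
  bin_conf <- mean(vapply(per_scaf, `[[`, 0, "conf"))
  bin_tax <- majority_label(ev$taxonomy)
  removed <- list()
  kept <- character(0)
  for (sid in members) {
    if (!sid %in% have) { kept <- c(kept, sid); next }
    s <- per_scaf[[sid]]
    reasons <- character(0)
    if (abs(s$gc - bin_gc) > gc_delta) reasons <- c(reasons, "gc")
    if (!is.na(bin_tax) && !is.na(s$tax) && s$tax != bin_tax)
      reasons <- c(reasons, "taxonomy")
    if (is.finite(s$conf) && is.finite(bin_conf) &&
        abs(s$conf - bin_conf) > conf_delta)
      reasons <- c(reasons, "confidence")
    if (length(reasons)) {
      removed[[sid]] <- data.frame(
        scaffold_id = sid, reasons = paste(reasons, collapse = ";"),
        gc = s$gc, bin_gc = bin_gc, taxonomy = ifelse(is.na(s$tax), "", s$tax),
        bin_taxonomy = ifelse(is.na(bin_tax), "", bin_tax),
        confidence = s$conf, bin_confidence = bin_conf,
        stringsAsFactors = FALSE)
    } else kept <- c(kept, sid)
  }
  removed <- if (length(removed)) do.call(rbind, c(removed, list(make.row.names = FALSE)))
             else empty_removed
  list(kept = kept, removed = removed, unevaluated = unev)
}
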