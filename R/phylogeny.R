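# Concatenated marker-gene phylogenetics: table-driven marker extraction,
# supermatrix assembly with the >= 8-marker inclusion rule, pairwise-deletion
# p-distances, an in-repo neighbor-joining implementation, and
# column-resampling bootstrap support. Trees are returned as ape "phylo"
# objects and serialized as Newick.

#' Marker-gene catalogs
#'
#' `set15`: the 15 syntenic ribosomal proteins (rpL2, 3, 4, 5, 6, 14, 15,
#' 18, 22, 24; rpS3, 8, 10, 17, 19). `set37`: the extended single-copy
#' marker list used for more robust placements (ribosomal proteins plus
#' IF-2, both phenylalanyl-tRNA synthetase subunits, tRNA pseudouridine
#' synthase B, porphobilinogen deaminase, and ribonuclease HII).
#'
#' @param set "set15" or "set37".
#' @return character vector of marker names (catalog order).
#' @export
marker_catalog <- function(set = c("set15", "set37")) {
  set <- match.arg(set)
  set15 <- c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15",
             "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17",
             "rpS19")
  if (set == "set15") return(set15)
  c("rpS2", "rpS3", "rpS5", "rpS7", "rpS8", "rpS9", "rpS10", "rpS11",
    "rpS12", "rpS13", "rpS15P", "rpS17", "rpS19", "rpL1", "rpL2", "rpL3",
    "rpL4", "rpL5", "rpL6", "rpL11", "rpL13", "rpL14b", "rpL15", "rpL16",
    "rpL18P", "rpL22", "rpL24", "rpL25", "rpL29", "IF-2", "pheRS_alpha",
    "pheRS_beta", "truB", "hemC", "rnhB")
}

#' Extract one sequence per (taxon, marker) from marker annotations
#'
#' When a taxon carries several copies of a marker, the longest sequence is
#' kept and the duplication is logged. Taxa with fewer than `min_markers`
#' markers are still extracted but flagged below the inclusion threshold.
#'
#' @param annotations data.frame: taxon, marker, sequence.
#' @param catalog character vector of marker names (defines order).
#' @param min_markers inclusion threshold used for flagging (default 8).
#' @return list: `markers` (named list per marker of named character
#'   vectors), `presence` (logical matrix taxa x markers), `below_threshold`
#'   (taxa with < min_markers), `duplications` (log data.frame).
#' @export
extract_markers <- function(annotations, catalog = marker_catalog("set15"),
                            min_markers = 8) {
  stopifnot(all(c("taxon", "marker", "sequence") %in% names(annotations)))
  ann <- annotations[annotations$marker %in% catalog, , drop = FALSE]
  dups <- list()
  per_marker <- lapply(catalog, function(m) {
    rows <- ann[ann$marker == m, , drop = FALSE]
    if (nrow(rows) == 0) return(character(0))
    out <- vapply(split(rows, rows$taxon), function(d) {
      if (nrow(d) > 1) {
        keep <- which.max(nchar(d$sequence))
        dups[[length(dups) + 1]] <<- data.frame(
          taxon = d$taxon[1], marker = m, n_copies = nrow(d),
          kept_length = nchar(d$sequence)[keep], stringsAsFactors = FALSE)
        d$sequence[keep]
      } else d$sequence
    }, "")
    out
  })
  names(per_marker) <- catalog
  taxa <- sort(unique(ann$taxon))
  presence <- vapply(per_marker, function(v) taxa %in% names(v),
                     logical(length(taxa)))
  if (length(taxa) == 1) presence <- matrix(presence, nrow = 1)
  dimnames(presence) <- list(taxa, catalog)
  n_mark <- rowSums(presence)
  list(markers = per_marker, presence = presence,
       below_threshold = taxa[n_mark < min_markers],
       duplications = if (length(dups)) do.call(rbind, dups) else
         data.frame(taxon = character(), marker = character(),
                    n_copies = integer(), kept_length = integer()))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Gene blocks follow catalog order; a taxon missing a gene gets a full
#' block of gap characters. Taxa with fewer than `min_markers` present
#' blocks are excluded (the inclusion rule is >= `min_markers`, i.e. a
#' taxon with exactly `min_markers` markers is included, one marker fewer
#' is excluded).
#'
#' @param blocks named list (marker -> named character vector of aligned
#'   sequences, equal width within a block).
#' @param catalog marker order; defaults to the names of `blocks`.
#' @param min_markers inclusion threshold (default 8).
#' @param gap_char gap fill character (default "-").
#' @return object of class `supermatrix`: list with `alignment` (named
#'   character vector), `partitions` (data.frame marker, start, end,
#'   1-based inclusive), `presence` (logical matrix), `taxa`, `excluded`.
#' @export
concatenate_markers <- function(blocks, catalog = names(blocks),
                                min_markers = 8, gap_char = "-") {
  blocks <- blocks[catalog[catalog %in% names(blocks)]]
  blocks <- Filter(function(b) length(b) > 0, blocks)
  if (length(blocks) == 0) stop("no non-empty gene blocks")
  widths <- vapply(blocks, function(b) {
    w <- unique(nchar(b))
    if (length(w) != 1) stop("gene block with unequal row lengths")
    w
  }, 0)
  taxa <- sort(unique(unlist(lapply(blocks, names))))
  presence <- vapply(blocks, function(b) taxa %in% names(b),
                     logical(length(taxa)))
  if (length(taxa) == 1) presence <- matrix(presence, nrow = 1)
  dimnames(presence) <- list(taxa, names(blocks))
  n_mark <- rowSums(presence)
  keep <- taxa[n_mark >= min_markers]
  excluded <- taxa[n_mark < min_markers]
  if (length(keep) == 0) stop("no taxon reaches the marker inclusion threshold")
  rows <- setNames(rep("", length(keep)), keep)
  parts <- data.frame(marker = names(blocks), start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
  pos <- 0L
  for (j in seq_along(blocks)) {
    b <- blocks[[j]]; w <- widths[j]
    gaps <- strrep(gap_char, w)
    add <- ifelse(keep %in% names(b), b[keep], gaps)
    rows <- paste0(rows, add)
    parts$start[j] <- pos + 1L
    parts$end[j] <- pos + w
    pos <- pos + w
  }
  names(rows) <- keep
  structure(list(alignment = rows, partitions = parts,
                 presence = presence[keep, , drop = FALSE], taxa = keep,
                 excluded = excluded, gap_char = gap_char),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix: %d taxa, %d blocks, %d columns (%d excluded taxa)>\n",
              length(x$taxa), nrow(x$partitions),
              max(x$partitions$end), length(x$excluded)))
  invisible(x)
}

# character matrix (taxa x columns) from a supermatrix or named vector
alignment_matrix <- function(x) {
  aln <- if (inherits(x, "supermatrix")) x$alignment else x
  do.call(rbind, strsplit(aln, ""))
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' For each pair of rows, the proportion of differing sites among columns
#' where both taxa are non-gap. Pairs sharing fewer than `min_shared`
#' columns are flagged unreliable; a pair with zero shared columns is an
#' error. Optional Poisson correction -ln(1 - p).
#'
#' @param x a `supermatrix` or named character vector of equal-length rows.
#' @param min_shared reliability floor on shared columns (default 50).
#' @param correction "none" (p-distance, default) or "poisson".
#' @param gap_chars characters treated as missing (default "-", ".", "?",
#'   "X").
#' @return list: `D` (symmetric matrix, zero diagonal), `shared` (matrix of
#'   shared-column counts), `unreliable` (data.frame of flagged pairs).
#' @export
pairwise_distances <- function(x, min_shared = 50,
                               correction = c("none", "poisson"),
                               gap_chars = c("-", ".", "?", "X")) {
  correction <- match.arg(correction)
  M <- alignment_matrix(x)
  taxa <- if (inherits(x, "supermatrix")) x$taxa else names(x)
  rownames(M) <- taxa
  if (length(taxa) < 3) stop("need >= 3 taxa")
  n <- length(taxa)
  ok <- !matrix(M %in% gap_chars, n)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  S <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  bad <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- ok[i, ] & ok[j, ]
    ns <- sum(sh)
    if (ns == 0)
      stop(sprintf("taxa %s and %s share no aligned columns", taxa[i], taxa[j]))
    p <- sum(M[i, sh] != M[j, sh]) / ns
    if (correction == "poisson") p <- -log(max(1e-12, 1 - p))
    D[i, j] <- D[j, i] <- p
    S[i, j] <- S[j, i] <- ns
    if (ns < min_shared)
      bad[[length(bad) + 1]] <- data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                                           shared = ns)
  }
  list(D = D, shared = S,
       unreliable = if (length(bad)) do.call(rbind, bad) else
         data.frame(taxon_a = character(), taxon_b = character(),
                    shared = integer()))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. Ties in the minimum Q criterion break to the
#' lexicographically smallest taxon pair. Negative pendant branch lengths
#' are clamped to zero with the deficit moved to the sister branch (their
#' sum is preserved). Exact on additive matrices: the output tree's path
#' lengths reproduce the input distances.
#'
#' @param D symmetric numeric matrix with zero diagonal and row/col names.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix must have taxon names")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (nrow(D) < 3) stop("need >= 3 taxa")
  labels <- rownames(D)
  newick <- labels  # growing subtree strings per active cluster
  active <- seq_along(labels)
  while (length(active) > 3) {
    n <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_names <- apply(cand, 1, function(ij)
      paste(sort(c(newick[active[ij[1]]], newick[active[ij[2]]])),
            collapse = "\r"))
    pick <- cand[order(pair_names)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (r[pick[1]] - r[pick[2]]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    # distances from the new node to the remaining clusters
    others <- setdiff(active, c(i, j))
    dnew <- (D[i, others] + D[j, others] - dij) / 2
    dnew[dnew < 0] <- 0
    D[i, others] <- D[others, i] <- dnew
    D[i, i] <- 0
    newick[i] <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], li, newick[j], lj)
    active <- setdiff(active, j)
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", newick[a[1]], l1,
                 newick[a[2]], l2, newick[a[3]], l3)
  ape::read.tree(text = txt)
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as
# sorted "|"-joined strings of the side not containing the reference tip.
tree_splits <- function(phy) {
  phy <- ape::unroot(phy)
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  n_tip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  clade <- vector("list", n_tip + phy$Nnode)
  for (t in seq_len(n_tip)) clade[[t]] <- phy$tip.label[t]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }
  splits <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch <= n_tip) next  # pendant edge: trivial split
    side <- clade[[ch]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2 || length(side) > n_tip - 2) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Bootstrap support for supermatrix NJ splits
#'
#' Resamples supermatrix columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal split of the original tree the
#' fraction of replicates containing it. Deterministic for a fixed seed.
#'
#' @param supermatrix a `supermatrix`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param min_shared passed to [pairwise_distances()] (default 1 for
#'   resampled replicates).
#' @return list: `tree` (original NJ tree), `support` (named numeric vector
#'   per split), `splits` (split strings).
#' @export
bootstrap_support <- function(supermatrix, n_replicates = 100, seed = 1L,
                              min_shared = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  M <- alignment_matrix(supermatrix)
  rownames(M) <- supermatrix$taxa
  base_tree <- nj_tree(pairwise_distances(supermatrix,
                                          min_shared = min_shared)$D)
  base_splits <- tree_splits(base_tree)
  hits <- setNames(numeric(length(base_splits)), base_splits)
  ncol_aln <- ncol(M)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      Mb <- M[, cols, drop = FALSE]
      rows <- setNames(apply(Mb, 1, paste, collapse = ""), rownames(M))
      Db <- pairwise_distances(rows, min_shared = min_shared)$D
      sp <- tree_splits(nj_tree(Db))
      hits[base_splits %in% sp] <- hits[base_splits %in% sp] + 1
    }
  })
  list(tree = base_tree, support = hits / n_replicates, splits = base_splits)
}

#' Simulate aligned marker blocks down a known tree
#'
#' Sites evolve independently: along each branch a site substitutes with
#' probability `1 - exp(-branch_length)` to a uniformly chosen different
#' residue. This produces already-aligned blocks (no indels) whose pairwise
#' p-distances grow with path length, so distance methods should recover
#' the generating topology given enough sites.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param n_sites alignment columns per block.
#' @param seed integer seed.
#' @param alphabet residue alphabet (default the 20 amino acids).
#' @return named character vector of aligned sequences (one per tip).
#' @export
simulate_marker_block <- function(tree, n_sites, seed = 1L,
                                  alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                      "")[[1]]) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  with_seed(seed, {
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(alphabet, n_sites, replace = TRUE)
    # preorder: parents before children
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      s <- seqs[[p]]
      mut <- runif(n_sites) < (1 - exp(-bl))
      if (any(mut)) {
        cur <- s[mut]
        repl <- vapply(cur, function(a)
          sample(setdiff(alphabet, a), 1), "")
        s[mut] <- repl
      }
      seqs[[ch]] <- s
    }
    setNames(vapply(seqs[seq_len(n_tip)], paste, "", collapse = ""),
             tree$tip.label)
  })
}
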