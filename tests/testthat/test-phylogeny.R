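# Marker extraction, supermatrix, distances, NJ, bootstrap.

test_that("marker catalogs carry the expected ribosomal protein sets", {
  s15 <- marker_catalog("set15")
  expect_length(s15, 15)
  expect_true(all(c("rpL2", "rpS3", "rpS19") %in% s15))
  s37 <- marker_catalog("set37")
  expect_gt(length(s37), length(s15))
  expect_true(all(c("IF-2", "truB", "hemC", "rnhB") %in% s37))
  expect_equal(anyDuplicated(s37), 0)
})

test_that("extraction keeps one longest sequence per taxon and marker", {
  ann <- data.frame(
    taxon = c("t1", "t1", "t1", "t2"),
    marker = c("rpS3", "rpS3", "rpL2", "rpS3"),
    sequence = c(strrep("M", 180), strrep("M", 120), strrep("K", 90),
                 strrep("R", 100)))
  ex <- extract_markers(ann)
  expect_equal(nchar(ex$markers$rpS3[["t1"]]), 180)
  expect_equal(ex$duplications$n_copies, 2)
  # both taxa have < 8 markers: flagged, not dropped
  expect_setequal(ex$below_threshold, c("t1", "t2"))
  expect_true("t1" %in% rownames(ex$presence))
})

test_that("concatenation gap-fills and enforces the 8-marker rule", {
  blocks <- list(gene1 = c(a = "MKLV", b = "MKIV", c = "MRLV"),
                 gene2 = c(a = "DDEEG", b = "DDQEG"))
  sm <- concatenate_markers(blocks, min_markers = 1)
  expect_equal(unname(nchar(sm$alignment)), rep(9, 3))
  expect_equal(unname(substr(sm$alignment[["c"]], 5, 9)), "-----")
  expect_equal(sm$partitions$start, c(1, 5))
  expect_equal(sm$partitions$end, c(4, 9))

  # 15 genes; taxon "low" has exactly 7, taxon "edge" exactly 8
  cat15 <- marker_catalog("set15")
  blocks15 <- setNames(lapply(seq_along(cat15), function(j) {
    out <- c(full = strrep("A", 10), edge = strrep("C", 10),
             low = strrep("D", 10))
    if (j > 8) out <- out[names(out) != "edge"]
    if (j > 7) out <- out[names(out) != "low"]
    out
  }), cat15)
  sm15 <- concatenate_markers(blocks15, cat15, min_markers = 8)
  expect_true("edge" %in% sm15$taxa)      # 8 markers: included
  expect_false("low" %in% sm15$taxa)      # 7 markers: excluded
  expect_equal(sm15$excluded, "low")

  bad <- list(gene1 = c(a = "MKLV", b = "MK"))
  expect_error(concatenate_markers(bad, min_markers = 1), "unequal")
})

test_that("p-distances match a column-by-column counting oracle", {
  aln <- c(a = "AAAA", b = "AAAT", c = "TTTT")
  pd <- pairwise_distances(aln, min_shared = 1)
  expect_equal(pd$D["a", "b"], 0.25)
  expect_equal(pd$D["a", "a"], 0)
  expect_equal(pd$D["a", "c"], 1)

  set.seed(8)
  rows <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 80, replace = TRUE,
                 prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = ""), "")
  names(rows) <- sprintf("t%d", 1:6)
  pd2 <- pairwise_distances(rows, min_shared = 1)
  for (i in 1:5) for (j in (i + 1):6) {
    ci <- strsplit(rows[i], "")[[1]]; cj <- strsplit(rows[j], "")[[1]]
    ok <- ci != "-" & cj != "-"
    expect_equal(pd2$D[i, j], sum(ci[ok] != cj[ok]) / sum(ok))
  }
  # pairs with few shared columns are flagged; none shared is an error
  expect_gt(nrow(pairwise_distances(rows, min_shared = 100)$unreliable), 0)
  gappy <- c(a = "AA--", b = "AA--", c = "--CC")
  expect_error(pairwise_distances(gappy, min_shared = 1), "share no")
})

test_that("three taxa solve the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "taxon names|3 taxa")
  D2 <- D; D2[1, 2] <- 9
  dimnames(D2) <- dimnames(D)
  expect_error(nj_tree(D2), "symmetric")
})

test_that("additive matrices reconstruct their generating tree exactly", {
  D <- additive_4taxon()
  tr <- nj_tree(D)
  # correct split: {A,B} vs {C,D}
  expect_equal(synmag:::tree_splits(tr), "C|D")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # random 5-taxon trees: topology and path lengths recovered
  for (s in 1:15) {
    set.seed(s)
    gen <- ape::rtree(5, tip.label = c("a", "b", "c", "d", "e"))
    gen$edge.length <- runif(nrow(gen$edge), 0.5, 3)
    D5 <- ape::cophenetic.phylo(ape::unroot(gen))
    D5 <- D5[order(rownames(D5)), order(colnames(D5))]
    tr5 <- nj_tree(D5)
    expect_setequal(synmag:::tree_splits(tr5),
                    synmag:::tree_splits(gen))
    expect_equal(ape::cophenetic.phylo(tr5)[rownames(D5), colnames(D5)],
                 D5, tolerance = 1e-8)
  }
})

test_that("our neighbor joining agrees with the reference implementation", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(n * 4), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    ours <- nj_tree(D)
    ref <- ape::nj(D)
    expect_equal(sort(synmag:::tree_splits(ours)),
                 sort(synmag:::tree_splits(ref)))
  }
})

test_that("bootstrap support is deterministic and bounded by design", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.08,(c:0.1,d:0.1):0.08,(e:0.1,f:0.1):0.08);")
  blocks <- lapply(1:5, function(j)
    simulate_marker_block(tree, 120, seed = j))
  names(blocks) <- sprintf("gene%d", 1:5)
  sm <- concatenate_markers(blocks, min_markers = 1)

  one <- bootstrap_support(sm, n_replicates = 1, seed = 4)
  expect_true(all(one$support %in% c(0, 1)))

  b1 <- bootstrap_support(sm, n_replicates = 30, seed = 9)
  b2 <- bootstrap_support(sm, n_replicates = 30, seed = 9)
  expect_identical(b1$support, b2$support)
  # long clean alignment: true splits close to full support
  expect_gte(mean(b1$support), 0.9)
  expect_error(bootstrap_support(sm, n_replicates = 0), "replicates")
})

test_that("markers simulated down a known tree recover its topology", {
  tree <- ape::read.tree(text = paste0(
    "(((t1:0.1,t2:0.1):0.07,(t3:0.1,t4:0.1):0.07):0.05,",
    "((t5:0.1,t6:0.1):0.07,(t7:0.1,t8:0.1):0.07):0.05);"))
  hits <- 0
  n_seed <- 10
  for (s in seq_len(n_seed)) {
    blocks <- lapply(1:8, function(j)
      simulate_marker_block(tree, 250, seed = s * 100 + j))
    names(blocks) <- sprintf("gene%d", 1:8)
    sm <- concatenate_markers(blocks, min_markers = 1)
    tr <- nj_tree(pairwise_distances(sm, min_shared = 1)$D)
    if (setequal(synmag:::tree_splits(tr),
                 synmag:::tree_splits(ape::unroot(tree)))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
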