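# Score gates, database consensus, pathway calls, family means.

toy_records <- function() {
  data.frame(
    gene_id = sprintf("g%02d", 1:10), mag_id = "m1",
    database = rep(c("dbA", "dbB"), 5),
    enzyme_id = sprintf("e%02d", 1:10),
    score = c(1e-21, 1e-19, 1e-20, 1e-25, 1e-5,
              55, 45, 80, 1e-30, 1e-22),
    score_type = c(rep("evalue", 5), rep("bitscore", 3), "evalue", "evalue"),
    stringsAsFactors = FALSE)
}

test_that("the e-value gate is inclusive at 1e-20 and strict above", {
  rec <- toy_records()
  kept <- filter_records(rec)
  expect_true("g01" %in% kept$gene_id)    # 1e-21 kept
  expect_false("g02" %in% kept$gene_id)   # 1e-19 removed
  expect_true("g03" %in% kept$gene_id)    # exactly 1e-20 kept (inclusive)
  expect_false("g05" %in% kept$gene_id)
  # bit scores against the default floor of 50
  expect_true("g06" %in% kept$gene_id)    # 55 >= 50
  expect_false("g07" %in% kept$gene_id)   # 45 < 50
  # hand count of the whole toy table: e-values pass {1,3,4,9,10},
  # bit scores pass {6,8}
  expect_equal(nrow(kept), 7)
  # per-enzyme custom bit thresholds override the default
  kept2 <- filter_records(rec, bit_thresholds = c(e06 = 60))
  expect_false("g06" %in% kept2$gene_id)
  expect_error(filter_records(transform(rec, score = -score)), "positive")
  rec$score_type[1] <- "mystery"
  expect_warning(filter_records(rec), "unknown score type")
})

test_that("consensus requires at least two distinct databases", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    mag_id = "m1",
                    database = c("dbA", "dbB", "dbA", "dbA"),
                    enzyme_id = c("mcrA", "mcrA", "dsrA", "dsrA"),
                    score = 1e-30, score_type = "evalue")
  cons <- consensus_enzymes(rec)
  expect_true(cons$confirmed[cons$enzyme_id == "mcrA"])
  # same database twice is not multiple databases
  expect_false(cons$confirmed[cons$enzyme_id == "dsrA"])
  expect_equal(cons$n_databases[cons$enzyme_id == "dsrA"], 1)
})

test_that("pathway calls enforce strict >50% and confirmed keys", {
  def <- pathway_definition("p", c("k", "c2", "c3", "c4"), keys = "k")
  # 3 of 4 detected, key confirmed -> present
  expect_true(call_pathway("k", c("c2", "c3"), def)$present)
  # exactly 2 of 4 is not > 50%
  expect_false(call_pathway("k", "c2", def)$present)
  # all four detected but key only single-database -> absent
  expect_false(call_pathway(character(0), c("k", "c2", "c3", "c4"),
                            def)$present)
  expect_error(pathway_definition("p", c("a", "b"), keys = "zzz"), "subset")

  # boundary at exactly 50% for component totals 2, 4, 10
  for (n in c(2, 4, 10)) {
    comps <- c("key", sprintf("c%d", seq_len(n - 1)))
    d <- pathway_definition("p", comps, keys = "key")
    half <- comps[seq_len(n / 2)]
    more <- comps[seq_len(n / 2 + 1)]
    expect_false(call_pathway("key", setdiff(half, "key"), d)$present)
    expect_true(call_pathway("key", setdiff(more, "key"), d)$present)
  }
})

test_that("pathway calls are monotone under added evidence", {
  defs <- default_pathways()
  set.seed(77)
  for (i in 1:50) {
    def <- defs[[sample(length(defs), 1)]]
    pool <- def$components
    conf <- sample(pool, sample(0:length(pool), 1))
    unconf <- sample(setdiff(pool, conf),
                     sample(0:length(setdiff(pool, conf)), 1))
    before <- call_pathway(conf, unconf, def)$present
    # add one detected component or promote one unconfirmed enzyme
    extra <- setdiff(pool, union(conf, unconf))
    after1 <- if (length(extra))
      call_pathway(conf, c(unconf, extra[1]), def)$present else before
    after2 <- if (length(unconf))
      call_pathway(c(conf, unconf[1]), setdiff(unconf, unconf[1]),
                   def)$present else before
    expect_false(before && !after1)
    expect_false(before && !after2)
  }
})

test_that("the shipped pathway set parses and matches its text form", {
  defs <- default_pathways()
  expect_length(defs, 5)
  expect_true(all(vapply(defs, function(d) all(d$keys %in% d$components),
                         TRUE)))
  expect_equal(defs$reverse_methanogenesis$keys, "mcrA")
  expect_setequal(defs$fumarate_addition$keys, c("bssA", "assA"))
  expect_setequal(defs$beta_oxidation$components,
                  c("acd", "ech", "hbd", "atoB"))
})

test_that("family means are per-MAG averages with full denominators", {
  counts <- data.frame(mag_id = c("a1", "a2", "b1"),
                       family_id = "F",
                       count = c(30, 38, 5))
  groups <- data.frame(mag_id = c(sprintf("a%d", 1:34),
                                  sprintf("b%d", 1:77)),
                       domain = rep(c("archaea", "bacteria"), c(34, 77)))
  fa <- family_abundance(counts, groups)
  expect_equal(fa$mean_per_mag[fa$group == "archaea"], 68 / 34)
  expect_equal(fa$mean_per_mag[fa$group == "bacteria"], 5 / 77)

  # absent family -> zero everywhere
  counts2 <- rbind(counts, data.frame(mag_id = "a1", family_id = "G",
                                      count = 0))
  fa2 <- family_abundance(counts2, groups)
  expect_equal(fa2$mean_per_mag[fa2$family_id == "G"], c(0, 0))

  # 5-MAG toy vs hand sums
  counts3 <- data.frame(mag_id = c("m1", "m2", "m3", "m4", "m5"),
                        family_id = c("F", "F", "F", "G", "G"),
                        count = c(1, 2, 3, 4, 5))
  groups3 <- data.frame(mag_id = sprintf("m%d", 1:5),
                        domain = c("archaea", "archaea", "bacteria",
                                   "bacteria", "bacteria"))
  fa3 <- family_abundance(counts3, groups3)
  expect_equal(fa3$mean_per_mag[fa3$family_id == "F" &
                                  fa3$group == "archaea"], 3 / 2)
  expect_equal(fa3$mean_per_mag[fa3$family_id == "F" &
                                  fa3$group == "bacteria"], 3 / 3)
  expect_equal(fa3$mean_per_mag[fa3$family_id == "G" &
                                  fa3$group == "bacteria"], 9 / 3)
  expect_error(family_abundance(counts3, groups3[1:2, ]), "group")
})
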