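# Marker QC, gates, decontamination.

test_that("completeness and duplication are exact marker-count fractions", {
  ml <- sprintf("m%02d", 1:40)
  full <- data.frame(marker = ml)
  r <- estimate_completeness(full, ml, "b1")
  expect_equal(r$completeness, 100)
  expect_equal(r$duplication, 0)

  half <- data.frame(marker = ml[1:20])
  expect_equal(estimate_completeness(half, ml)$completeness, 50)

  dup <- data.frame(marker = c(ml[1:28], ml[1:4]))
  r2 <- estimate_completeness(dup, ml)
  expect_equal(r2$completeness, 70)
  expect_equal(r2$duplication, 10)

  expect_error(estimate_completeness(data.frame(marker = "nope"), ml),
               "unknown marker")
  expect_error(estimate_completeness(full, character(0)), "non-empty")
})

test_that("QC estimates round-trip the generating parameters exactly", {
  ml <- marker_catalog("set15")
  M <- length(ml)
  set.seed(99)
  for (i in 1:100) {
    comp <- sample(0:M, 1) / M
    dup <- if (comp > 0) sample(0:round(comp * M), 1) / M else 0
    tab <- place_markers("g", sprintf("s%d", 1:5), ml,
                         completeness = comp, duplication = dup, seed = i)
    r <- estimate_completeness(tab, ml)
    expect_equal(r$completeness, 100 * round(comp * M) / M)
    expect_equal(r$duplication, 100 * round(dup * M) / M)
  }
})

test_that("quality gates are strict above 50 and inclusive at 10", {
  reports <- data.frame(
    bin_id = c("exactly50", "ok", "dup_at_10", "dup_11", "both_bad"),
    completeness = c(50, 70, 90, 90, 40),
    duplication = c(0, 5, 10, 11, 20))
  g <- gate_bins(reports)
  expect_setequal(g$kept$bin_id, c("ok", "dup_at_10"))
  expect_true("exactly50" %in% g$rejected$bin_id)        # 50.0 is rejected
  expect_true("dup_11" %in% g$rejected$bin_id)
  expect_equal(g$rejected$reason[g$rejected$bin_id == "both_bad"],
               "low_completeness;high_duplication")
  # just above the boundary is kept
  g2 <- gate_bins(data.frame(bin_id = "x", completeness = 50.1,
                             duplication = 10.0))
  expect_equal(g2$kept$bin_id, "x")
})

make_evidence <- function(ids, gc, tax, conf) {
  do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(scaffold_id = ids[i], gene_id = paste0(ids[i], "_g", 1:3),
               gc = gc[i], taxonomy = tax[i], confidence = conf[i])))
}

test_that("deviant scaffolds are removed for the stated reason", {
  # nine scaffolds near 0.50 plus one at 0.80: frozen bin mean 0.53, the
  # outlier deviates by 0.27 > 0.25 while the natives stay within 0.03
  ids <- sprintf("s%02d", 1:10)
  ev <- make_evidence(ids, gc = c(rep(0.50, 9), 0.80),
                      tax = rep("phylum_A", 10), conf = rep(85, 10))
  d <- decontaminate(ids, ev)
  expect_equal(d$removed$scaffold_id, "s10")
  expect_match(d$removed$reasons, "gc")
  expect_setequal(d$kept, ids[1:9])

  # matching scaffold is retained
  ev2 <- make_evidence(c("s1", "s2", "s3"), gc = c(0.5, 0.5, 0.5),
                       tax = rep("phylum_A", 3), conf = c(85, 85, 85))
  d2 <- decontaminate(c("s1", "s2", "s3"), ev2)
  expect_length(d2$removed$scaffold_id, 0)

  # taxonomy and confidence rules (s4: |20 - 72| = 52 > 25 points)
  ev3 <- make_evidence(c("s1", "s2", "s3", "s4", "s5"),
                       gc = rep(0.5, 5),
                       tax = c(rep("phylum_A", 4), "phylum_B"),
                       conf = c(85, 85, 85, 20, 85))
  d3 <- decontaminate(sprintf("s%d", 1:5), ev3)
  expect_match(d3$removed$reasons[d3$removed$scaffold_id == "s5"], "taxonomy")
  expect_match(d3$removed$reasons[d3$removed$scaffold_id == "s4"],
               "confidence")
})

test_that("bin means are frozen: removals never cascade within one pass", {
  # with frozen means (mean GC 0.56) only s5 (|0.80-0.56| = 0.24 < 0.25 --
  # no; set up so s5 is removed but s4 is evaluated against the SAME mean)
  ev <- make_evidence(c("s1", "s2", "s3", "s4", "s5"),
                      gc = c(0.50, 0.50, 0.50, 0.70, 0.95),
                      tax = rep("phylum_A", 5), conf = rep(85, 5))
  d <- decontaminate(sprintf("s%d", 1:5), ev)
  frozen_mean <- mean(c(0.50, 0.50, 0.50, 0.70, 0.95))
  # s5 deviates by 0.32 -> removed; s4 by 0.07 -> kept, even though
  # recomputing the mean without s5 (0.55) would still keep s4, the point
  # is the verdict must use the initial mean for every scaffold
  expect_equal(d$removed$scaffold_id, "s5")
  expect_equal(unique(d$removed$bin_gc), frozen_mean)
  expect_true("s4" %in% d$kept)
  # a second, explicit pass may remove more (means shift after filtering)
  d2 <- decontaminate(d$kept, ev)
  expect_true(all(d2$removed$bin_gc != frozen_mean) || nrow(d2$removed) == 0)
})

test_that("small bins pass through and missing evidence is flagged", {
  ev <- make_evidence(c("s1", "s2"), gc = c(0.3, 0.8),
                      tax = c("phylum_A", "phylum_B"), conf = c(85, 20))
  expect_warning(d <- decontaminate(c("s1", "s2"), ev), "fewer than 3")
  expect_setequal(d$kept, c("s1", "s2"))

  ev3 <- make_evidence(c("s1", "s2", "s3"), gc = rep(0.5, 3),
                       tax = rep("phylum_A", 3), conf = rep(85, 3))
  d3 <- decontaminate(c("s1", "s2", "s3", "s_no_evidence"), ev3)
  expect_equal(d3$unevaluated, "s_no_evidence")
  expect_true("s_no_evidence" %in% d3$kept)
})

test_that("injected contaminants are recovered from the community bins", {
  comm <- test_community()
  truth <- comm$truth
  big <- truth$length >= 5000
  removed_all <- character(0)
  for (b in unique(truth$bin_id)) {
    members <- truth$scaffold_id[truth$bin_id == b & big]
    d <- decontaminate(members, comm$evidence)
    removed_all <- c(removed_all, d$removed$scaffold_id)
  }
  contaminants <- truth$scaffold_id[truth$is_contaminant & big]
  native <- setdiff(truth$scaffold_id[big], contaminants)
  expect_gt(length(contaminants), 0)
  expect_true(all(contaminants %in% removed_all))
  expect_equal(sum(native %in% removed_all), 0)
})
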