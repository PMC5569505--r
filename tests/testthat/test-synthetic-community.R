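# Generators: genomes, scaffolds, contaminants, reads, markers, annotations.

test_that("generated genomes hit their GC target and are reproducible", {
  sp <- genome_spec("gA", 100000, 0.5, seed = 21)
  g <- generate_genome(sp)
  expect_equal(Biostrings::width(g), 100000)
  expect_gt(gc_fraction(g[[1]]), 0.48)
  expect_lt(gc_fraction(g[[1]]), 0.52)
  expect_identical(as.character(generate_genome(sp)), as.character(g))

  low <- generate_genome(genome_spec("gB", 100000, 0.32, seed = 5))
  expect_lt(abs(gc_fraction(low[[1]]) - 0.32), 0.02)
})

test_that("genome specs outside the admissible band are rejected", {
  expect_error(genome_spec("g", 100000, 0.99), "band")
  expect_error(genome_spec("g", 100000, 0.15), "band")
  expect_error(genome_spec("g", 10000, 0.5), "50000")
  expect_error(genome_spec("g", 100000, 0.5, relative_depth = 0), "positive")
})

test_that("distinct seeds give distinct tetranucleotide profiles", {
  g1 <- generate_genome(genome_spec("g1", 80000, 0.5, seed = 1))
  g2 <- generate_genome(genome_spec("g2", 80000, 0.5, seed = 2))
  t1 <- tetranucleotide_frequencies(g1[[1]])$values
  t2 <- tetranucleotide_frequencies(g2[[1]])$values
  expect_gt(sqrt(sum((t1 - t2)^2)), 0.01)
})

test_that("fragmentation tiles the genome exactly", {
  g <- generate_genome(genome_spec("gA", 60000, 0.45, seed = 3))
  fr <- fragment_genome(g, "gA", seed = 9)
  expect_equal(sum(fr$truth$length), 60000)
  # concatenating the scaffolds in order reconstructs the genome
  expect_identical(paste(as.character(fr$scaffolds), collapse = ""),
                   as.character(g[[1]]))
  # half-open 0-based coordinates: end - start = length, no overlap
  expect_equal(fr$truth$end - fr$truth$start, fr$truth$length)
  expect_equal(fr$truth$start[-1], fr$truth$end[-nrow(fr$truth)])
  expect_true(all(fr$truth$length >= 200))
  expect_error(fragment_genome(g, "gA", min_len = 5000, max_len = 400),
               "exceed")
})

test_that("the scaffold length law keeps a deliberate sub-5 kb tail", {
  comm <- test_community()
  expect_gt(sum(comm$truth$length < 5000), 0)
  expect_gt(sum(comm$truth$length >= 5000), 0)
  expect_true(all(comm$truth$length <= 177401))
})

test_that("contaminant injection relabels the right number of scaffolds", {
  comm <- test_community()
  truth0 <- comm$truth
  truth0$bin_id <- truth0$genome_id
  truth0$is_contaminant <- NULL
  truth0$contaminant_in <- NULL

  unchanged <- inject_contaminants(truth0, rate = 0, seed = 1)
  expect_identical(unchanged$bin_id, truth0$genome_id)
  expect_false(any(unchanged$is_contaminant))

  expect_error(inject_contaminants(truth0, rate = 0.5), "rate")

  inj <- inject_contaminants(truth0, rate = 0.1, seed = 1)
  cont <- inj[inj$is_contaminant, ]
  expect_gt(nrow(cont), 0)
  # every contaminant sits in a bin it does not originate from
  expect_true(all(cont$bin_id != cont$genome_id))
  # gc_extreme policy: injected scaffold GC far from recipient bin mean GC
  for (b in unique(cont$bin_id)) {
    native_gc <- mean(inj$gc[inj$genome_id == b & inj$bin_id == b])
    expect_true(all(abs(cont$gc[cont$bin_id == b] - native_gc) > 0.25))
  }
})

test_that("error-free reads are exact genome substrings on either strand", {
  g <- generate_genome(genome_spec("gA", 60000, 0.5, seed = 4))
  sim <- simulate_reads(g, n_pairs = 50, error_rate = 0, seed = 2)
  gseq <- as.character(g[[1]])
  for (i in seq_len(10)) {
    r1 <- as.character(sim$r1[[i]])
    r2 <- as.character(sim$r2[[i]])
    expect_true(grepl(r1, gseq, fixed = TRUE))
    expect_true(grepl(rc_chartr(r2), gseq, fixed = TRUE))
  }
  # insert size bookkeeping
  expect_true(all(sim$truth$insert >= 360 & sim$truth$insert <= 420))
  expect_error(simulate_reads(g, n_pairs = 0), "positive")
})

test_that("read counts split by depth weight times genome length", {
  g <- c(generate_genome(genome_spec("gA", 60000, 0.45, seed = 5)),
         generate_genome(genome_spec("gB", 60000, 0.55, seed = 6)))
  sim <- simulate_reads(g, setNames(c(1, 1), names(g)), n_pairs = 10000,
                        seed = 3)
  nA <- sum(sim$truth$genome_id == "gA")
  # binomial 99% interval around 5000
  expect_true(abs(nA - 5000) < 2.576 * sqrt(10000 * 0.25))
})

test_that("identical seeds give byte-identical FASTQ", {
  g <- generate_genome(genome_spec("gA", 60000, 0.5, seed = 4))
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  s1 <- simulate_reads(g, n_pairs = 30, error_rate = 0.01, seed = 11)
  s2 <- simulate_reads(g, n_pairs = 30, error_rate = 0.01, seed = 11)
  write_read_pair(s1, file.path(d1, "r"))
  write_read_pair(s2, file.path(d2, "r"))
  expect_identical(readLines(file.path(d1, "r_R1.fastq")),
                   readLines(file.path(d2, "r_R1.fastq")))
  expect_identical(readLines(file.path(d1, "r_R2.fastq")),
                   readLines(file.path(d2, "r_R2.fastq")))
})

test_that("marker placement yields exact presence and duplication counts", {
  ml <- sprintf("m%02d", 1:40)
  tab <- place_markers("g", sprintf("s%d", 1:10), ml,
                       completeness = 1, duplication = 0, seed = 1)
  expect_equal(sort(unique(tab$marker)), ml)
  expect_true(all(table(tab$marker) == 1))

  tab2 <- place_markers("g", sprintf("s%d", 1:10), ml,
                        completeness = 0.5, duplication = 0, seed = 2)
  expect_equal(length(unique(tab2$marker)), 20)

  tab3 <- place_markers("g", sprintf("s%d", 1:10), ml,
                        completeness = 0.7, duplication = 0.1, seed = 3)
  expect_equal(length(unique(tab3$marker)), 28)
  expect_equal(sum(table(tab3$marker) == 2), 4)

  expect_error(place_markers("g", "s1", ml, completeness = 0.3,
                             duplication = 0.4), "exceed")
})

test_that("annotation simulation respects detection and consensus rates", {
  defs <- default_pathways()
  truth <- list(g1 = names(defs))
  all_enz <- sort(unique(unlist(lapply(defs, `[[`, "components"))))

  full <- simulate_annotations(truth, defs, detection_prob = 1,
                               false_positive_rate = 0, seed = 1)
  expect_equal(nrow(full), 2 * length(all_enz))
  expect_true(all(full$score <= 1e-20))

  none <- simulate_annotations(truth, defs, detection_prob = 0,
                               false_positive_rate = 0, seed = 1)
  expect_equal(sum(none$is_true), 0)

  expect_error(simulate_annotations(truth, defs, databases = "only_one"),
               "databases")
  expect_error(simulate_annotations(truth, defs, detection_prob = 1.2),
               "probabilities")

  # with detection 0.9 over 2 databases, P(enzyme in both) = 0.81
  many <- lapply(1:30, function(s)
    simulate_annotations(truth, defs, detection_prob = 0.9,
                         false_positive_rate = 0, seed = s))
  frac2 <- vapply(many, function(a) {
    cons <- consensus_enzymes(a, min_databases = 2)
    sum(cons$confirmed) / length(all_enz)
  }, 0)
  n_total <- 30 * length(all_enz)
  expect_lt(abs(mean(frac2) - 0.81), 3 * sqrt(0.81 * 0.19 / n_total))
})

test_that("the community's truth tables cover every record exactly once", {
  comm <- test_community()
  expect_equal(anyDuplicated(comm$truth$scaffold_id), 0)
  expect_setequal(comm$truth$scaffold_id, names(comm$scaffolds))
  expect_equal(anyDuplicated(comm$reads$truth$read_id), 0)
  expect_equal(nrow(comm$reads$truth), length(comm$reads$r1))
  # pairwise genome TNF separation above the configured floor
  expect_gte(comm$min_tnf_separation, comm$config$tnf_separation_floor)
})
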