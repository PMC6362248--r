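test_that("zero mutation rates reproduce the ancestor with an empty log", {
  set.seed(91)
  anc <- random_dna(300)
  mc <- mutate_copy(anc, p_sub = 0, p_indel = 0)
  expect_identical(mc$sequence, anc)
  expect_equal(nrow(mc$log), 0)
})

test_that("in the kappa limit every substitution is a transition", {
  set.seed(92)
  anc <- random_dna(500)
  mc <- mutate_copy(anc, p_sub = 1, kappa = Inf)
  expect_equal(nrow(mc$log), 500)
  tr <- c(A = "G", G = "A", C = "T", T = "C")
  expect_identical(mc$log$alt, unname(tr[mc$log$ref]))
})

test_that("mean copy identity to the ancestor matches the substitution rate", {
  set.seed(93)
  anc <- random_dna(500)
  p_sub <- 0.05
  n <- 100
  mism <- vapply(seq_len(n), function(i) {
    mc <- mutate_copy(anc, p_sub = p_sub)
    mapply(function(a, b) sum(a != b),
           strsplit(anc, ""), strsplit(mc$sequence, ""))
  }, numeric(1))
  total_sites <- n * 500
  expect_lt(abs(sum(mism) / total_sites - p_sub),
            3 * sqrt(p_sub * (1 - p_sub) / total_sites))
})

test_that("mutation logs replay exactly, including indels", {
  set.seed(94)
  anc <- random_dna(400)
  for (i in 1:10) {
    mc <- mutate_copy(anc, p_sub = 0.05, p_indel = 0.02, indel_mean = 2)
    expect_identical(replay_mutations(anc, mc$log), mc$sequence)
  }
})

test_that("generation is fully deterministic under a fixed seed", {
  m <- tiny_model()
  p <- sim_params(genome_length = 2e4, n_copies = 6, p_sub = 0.03,
                  n_decoys = 2, p_indel = 0.005, truncation_prob = 0.3,
                  seed = 95)
  g1 <- generate_genome(m, p)
  g2 <- generate_genome(m, p)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$copies, g2$truth$copies)
  expect_identical(g1$truth$mutation_logs, g2$truth$mutation_logs)
  # and FASTA bytes are identical too
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_fasta(g1$genome, t1); write_fasta(g2$genome, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("planted copies sit at their recorded coordinates", {
  m <- tiny_model()
  p <- sim_params(genome_length = 3e4, n_copies = 8, p_sub = 0.04,
                  n_decoys = 3, seed = 96)
  g <- generate_genome(m, p)
  tr <- g$truth$copies
  # intervals are non-overlapping
  iv <- tr[order(tr$start), ]
  expect_true(all(iv$end[-nrow(iv)] < iv$start[-1]))
  for (i in seq_len(nrow(tr))) {
    s <- substr(g$genome[["chr1"]], tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") s <- unname(reverse_complement(s))
    expect_identical(s, unname(g$truth$copy_sequences[tr$id[i]]))
  }
  # replaying each log reproduces each planted copy
  for (id in tr$id) {
    expect_identical(
      replay_mutations(g$truth$ancestors[[id]], g$truth$mutation_logs[[id]]),
      unname(g$truth$copy_sequences[id]))
  }
})

test_that("variant planting hits an exact carrier count", {
  anc <- strrep("A", 50)
  copies <- rep(anc, 50)
  got <- plant_variant_site(copies, 10, "G", 0.40)
  expect_equal(sum(substr(got, 10, 10) == "G"), 20)
  got2 <- plant_variant_site(copies, 10, "G", 0.50)
  expect_equal(sum(substr(got2, 10, 10) == "G"), 25)
  expect_identical(plant_variant_site(copies, 10, "G", 0), copies)
})

test_that("an empty simulation yields background only and zero hits", {
  m <- tiny_model()
  p <- sim_params(genome_length = 1e4, n_copies = 0, n_decoys = 0, seed = 97)
  g <- generate_genome(m, p)
  expect_equal(nchar(g$genome[["chr1"]]), 1e4)
  h <- filter_by_length(find_hits(g$genome, m$sequence, tiny_search()),
                        m$length)
  expect_equal(nrow(h), 0)
})

test_that("impossible packing and missing seeds are rejected", {
  m <- tiny_model()
  expect_error(sim_params(genome_length = 100, n_copies = 5),
               "seed")
  p <- sim_params(genome_length = 2, n_copies = 5, seed = 98)
  expect_error(generate_genome(m, p), "packing")
})

test_that("truncated copies are shorter and flagged in the truth table", {
  m <- tiny_model()
  p <- sim_params(genome_length = 3e4, n_copies = 10, p_sub = 0,
                  truncation_prob = 1, truncation_range = c(0.4, 0.6),
                  seed = 99)
  g <- generate_genome(m, p)
  expect_true(all(g$truth$copies$truncated))
  lens <- g$truth$copies$end - g$truth$copies$start + 1
  expect_true(all(lens >= 0.3 * m$length & lens <= 0.7 * m$length))
})

test_that("the truth table TSV lists copies and decoys", {
  m <- tiny_model()
  p <- sim_params(genome_length = 2e4, n_copies = 3, n_decoys = 2, seed = 100)
  g <- generate_genome(m, p)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(g$truth, tf)
  back <- utils::read.table(tf, sep = "\t", header = TRUE)
  expect_equal(sum(back$type == "copy"), 3)
  expect_equal(sum(back$type == "decoy"), 2)
})
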