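test_that("an exact planted copy yields one full-length perfect hit", {
  set.seed(21)
  q <- random_dna(200)
  pg <- plant_genome(q, background_len = 4000)
  h <- find_hits(pg$genome, q, tiny_search())
  h <- filter_by_length(h, nchar(q))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1.0)
  expect_equal(h$end - h$start + 1, nchar(q))
  expect_equal(h$start, pg$starts)
  expect_equal(h$strand, "+")
})

test_that("a minus-strand copy is found and extracts back in query orientation", {
  set.seed(22)
  q <- random_dna(200)
  pg <- plant_genome(q, strands = "-", background_len = 4000)
  h <- filter_by_length(find_hits(pg$genome, q, tiny_search()), nchar(q))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_identical(unname(extract_hit_sequences(pg$genome, h)), q)
})

test_that("diverged copies are all recovered with identity above 90%", {
  m <- sb_like_model()
  p <- sim_params(genome_length = 5e4, n_copies = 10, p_sub = 0.03,
                  seed = 23)
  g <- generate_genome(m, p)
  h <- filter_by_length(find_hits(g$genome, m$sequence, search_params()),
                        m$length)
  expect_equal(nrow(h), 10)
  expect_true(all(h$identity >= 0.90))
  # every truth interval is recovered (within a few clipped terminal bases)
  tr <- g$truth$copies[order(g$truth$copies$start), ]
  h <- h[order(h$start), ]
  expect_true(all(abs(h$start - tr$start) <= 10))
  expect_true(all(abs(h$end - tr$end) <= 10))
  expect_identical(h$strand, tr$strand)
})

test_that("extracted hit sequences match the simulator truth", {
  m <- tiny_model()
  p <- sim_params(genome_length = 2e4, n_copies = 6, p_sub = 0.02,
                  seed = 31)
  g <- generate_genome(m, p)
  tr <- g$truth$copies
  hits <- data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                     strand = tr$strand, stringsAsFactors = FALSE)
  got <- extract_hit_sequences(g$genome, hits)
  expect_identical(unname(got), unname(g$truth$copy_sequences))
})

test_that("length filter applies the strict more-than-10-percent rule", {
  hits <- rbind(fake_hit(start = 1, end = 1638),
                fake_hit(start = 2000, end = 2000 + 1474),  # length 1475
                fake_hit(start = 5000, end = 5000 + 1473))  # length 1474
  kept <- filter_by_length(hits, 1638)
  expect_equal(kept$end - kept$start + 1, c(1638, 1475))
})

test_that("identity filter is inclusive at the threshold", {
  hits <- rbind(fake_hit(start = 1, end = 100, identity = 0.90),
                fake_hit(start = 200, end = 300, identity = 0.899),
                fake_hit(start = 400, end = 500, identity = 1.0))
  expect_equal(filter_by_identity(hits, 0.90)$start, c(1, 400))
  expect_identical(filter_by_identity(hits, 0), hits)
})

test_that("filters preserve order and commute", {
  set.seed(24)
  hits <- do.call(rbind, lapply(1:20, function(i)
    fake_hit(start = i * 500, end = i * 500 + sample(80:120, 1),
             identity = stats::runif(1, 0.7, 1))))
  a <- filter_by_identity(filter_by_length(hits, 100), 0.85)
  b <- filter_by_length(filter_by_identity(hits, 0.85), 100)
  expect_identical(a, b)
  expect_true(all(diff(a$start) > 0))
})

test_that("sequence duplicates collapse to the lowest-coordinate copy", {
  set.seed(25)
  q <- random_dna(150)
  mut <- q
  substr(mut, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, 75, 75))[1]
  pg <- plant_genome(c(q, q, mut), background_len = 4000)
  h <- filter_by_length(find_hits(pg$genome, q, tiny_search()), nchar(q))
  expect_equal(nrow(h), 3)
  d <- dedupe_hits(h, pg$genome)
  expect_equal(nrow(d), 2)
  expect_equal(min(d$start), min(h$start))
  expect_identical(dedupe_hits(d, pg$genome), d)
})

test_that("searching the reverse-complemented genome swaps strands only", {
  set.seed(26)
  q <- random_dna(180)
  pg <- plant_genome(c(q, q), strands = c("+", "-"), background_len = 5000)
  rc_genome <- c(chr1 = unname(reverse_complement(pg$genome)))
  h1 <- filter_by_length(find_hits(pg$genome, q, tiny_search()), nchar(q))
  h2 <- filter_by_length(find_hits(rc_genome, q, tiny_search()), nchar(q))
  expect_equal(nrow(h1), 2)
  expect_equal(nrow(h2), 2)
  expect_setequal(h1$strand, c("+", "-"))
  expect_setequal(h2$strand, c("+", "-"))
  expect_setequal(unname(extract_hit_sequences(pg$genome, h1)),
                  unname(extract_hit_sequences(rc_genome, h2)))
})

test_that("PSL files round trip and tolerate the standard header", {
  set.seed(27)
  q <- random_dna(150)
  pg <- plant_genome(c(q, q), strands = c("+", "-"), background_len = 3000)
  h <- filter_by_length(find_hits(pg$genome, q, tiny_search()), nchar(q))
  tf <- withr::local_tempfile(fileext = ".psl")
  write_psl(h, tf, query_name = "q", query_len = nchar(q),
            genome = pg$genome, header = TRUE)
  got <- read_psl(tf)
  cols <- c("chrom", "start", "end", "strand", "matches", "aligned_len",
            "identity", "qstart", "qend")
  expect_equal(got[cols], h[cols])
  expect_true(any(got$strand == "-"))
  # reading is idempotent through a second write
  tf2 <- withr::local_tempfile(fileext = ".psl")
  write_psl(got, tf2, query_name = "q", query_len = nchar(q), header = FALSE)
  expect_identical(read_psl(tf2), got)
})

test_that("malformed PSL lines are reported with their line number", {
  tf <- withr::local_tempfile(fileext = ".psl")
  writeLines(c("150\t0\t0\t0", "irrelevant"), tf)
  expect_error(read_psl(tf), "line 1")
})

test_that("an empty genome yields an empty hit list", {
  expect_equal(nrow(find_hits(character(), "ACGTACGTACGTACGT",
                              tiny_search())), 0)
})
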