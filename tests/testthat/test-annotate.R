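# model whose CDS begins AAA CGA AAG ATC ... so the reported third-position
# substitutions can be checked codon by codon
codon_model <- function() {
  set.seed(71)
  left <- random_dna(30)
  cds <- paste0("AAACGAAAGATC", random_dna(108))
  full <- paste0(left, random_dna(10), cds, random_dna(10),
                 unname(reverse_complement(left)))
  transposon_model("codon", full, left_itr = c(1, 30),
                   right_itr = c(171, 200), cds = c(41, 160), cds_frame = 0)
}

test_that("third-position substitutions classify as synonymous", {
  m <- codon_model()
  e1 <- codon_effect(m, 3, "A", "G")    # AAA -> AAG, Lys
  expect_equal(e1$effect, "synonymous")
  expect_equal(e1$aa_ref, "K")
  expect_equal(e1$codon_position, 3)
  e2 <- codon_effect(m, 6, "A", "C")    # CGA -> CGC, Arg
  expect_equal(e2$effect, "synonymous")
  expect_equal(e2$aa_ref, "R")
  e3 <- codon_effect(m, 9, "G", "A")    # AAG -> AAA, Lys
  expect_equal(e3$effect, "synonymous")
  expect_equal(e3$aa_ref, "K")
  e4 <- codon_effect(m, 12, "C", "A")   # ATC -> ATA, Ile
  expect_equal(e4$effect, "synonymous")
  expect_equal(e4$aa_ref, "I")
})

test_that("first-position changes and N substitutions classify correctly", {
  m <- codon_model()
  e <- codon_effect(m, 1, "A", "G")     # AAA -> GAA, K -> E
  expect_equal(e$effect, "nonsynonymous")
  expect_equal(e$aa_new, "E")
  expect_equal(e$codon_position, 1)
  expect_equal(codon_effect(m, 4, "C", "N")$effect, "ambiguous")
})

test_that("codon effects honour a nonzero reading frame", {
  m <- codon_model()
  m2 <- transposon_model("f1", m$sequence, m$left_itr, m$right_itr, m$cds,
                         cds_frame = 1)
  # CDS position 1 precedes the frame start: no codon effect
  expect_equal(codon_effect(m2, 1, "A", "G")$effect, "none")
  # with frame 1 the first codon is CDS positions 2-4 (AAC...)
  e <- codon_effect(m2, 2, "A", "G")
  expect_equal(e$codon_position, 1)
})

test_that("codon classification agrees with a whole-CDS translation oracle", {
  set.seed(72)
  cds <- paste0("ATG", random_dna(96))
  full <- paste0(random_dna(30), random_dna(10), cds, random_dna(10),
                 random_dna(30))
  left <- c(1, 30); right <- c(150, 179)
  m <- transposon_model("oracle", substr(full, 1, 179), left, right,
                        c(41, 139), cds_frame = 0)
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, 99)), no.init.codon = TRUE))
  for (pos in seq_len(99)) {
    ref_base <- substr(cds, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
      mut <- cds
      substr(mut, pos, pos) <- alt
      mut_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(mut, 1, 99)), no.init.codon = TRUE))
      want <- if (mut_aa == ref_aa) "synonymous" else "nonsynonymous"
      expect_equal(codon_effect(m, pos, ref_base, alt)$effect, want,
                   info = sprintf("pos %d %s>%s", pos, ref_base, alt))
    }
  }
})

test_that("indel effects depend on length and location", {
  expect_equal(indel_effect(1, in_cds = TRUE), "frameshift")
  expect_equal(indel_effect(3, in_cds = TRUE), "in-frame")
  expect_equal(indel_effect(1, in_cds = FALSE), "none")
})

test_that("binding-region classification uses the configured spans", {
  m <- tiny_model()  # left ITR box spans positions 2-9
  expect_true(classify_binding_region(m, "left_itr", 5))
  expect_false(classify_binding_region(m, "left_itr", 10))  # 1 past the end
  expect_false(classify_binding_region(m, "left_itr", 20))
  m0 <- tiny_model(binding = FALSE)
  expect_true(is.na(classify_binding_region(m0, "left_itr", 5)))
})

test_that("an identical consensus yields an empty difference list", {
  m <- tiny_model()
  set.seed(73)
  copies <- stats::setNames(rep(m$sequence, 5), paste0("c", 1:5))
  aln <- align_sequences(copies, reference = m$sequence)
  res <- map_to_reference(call_consensus(column_frequencies(aln)), aln, m)
  d <- diff_consensus(res, m)
  expect_equal(nrow(d), 0)
  expect_match(render_report(d)[2], "zero differences")
})

test_that("planted ITR substitutions are reported at their feature positions", {
  m <- tiny_model()
  # ancestor differing from the model at 4 left-ITR sites outside the
  # binding box (box is positions 2-9)
  anc <- m$sequence
  sites <- c(12, 15, 21, 28)
  for (s in sites) {
    cur <- substr(anc, s, s)
    substr(anc, s, s) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  copies <- stats::setNames(rep(anc, 6), paste0("c", 1:6))
  aln <- align_sequences(copies, reference = m$sequence)
  res <- map_to_reference(call_consensus(column_frequencies(aln)), aln, m)
  d <- diff_consensus(res, m)
  expect_equal(nrow(d), 4)
  expect_true(all(d$feature == "left_itr"))
  expect_equal(d$position, sites)
  expect_true(all(d$kind == "substitution"))
  expect_true(all(d$in_binding_region == FALSE))
})

test_that("variable columns carry their frequency vectors in the report", {
  m <- tiny_model()
  anc <- m$sequence
  copies <- rep(anc, 10)
  # split site 50 (inside the CDS) between two bases 50/50
  alt <- setdiff(c("A", "C", "G", "T"), substr(anc, 50, 50))[1]
  for (i in 1:5) substr(copies[i], 50, 50) <- alt
  names(copies) <- paste0("c", 1:10)
  aln <- align_sequences(copies, reference = m$sequence)
  res <- map_to_reference(call_consensus(column_frequencies(aln)), aln, m)
  d <- diff_consensus(res, m)
  expect_equal(nrow(d), 1)
  expect_equal(d$kind, "variable")
  expect_equal(d$feature, "cds")
  expect_equal(d$position, 10)  # CDS starts at offset 41
  freqs <- unlist(d[1, c("freq_A", "freq_C", "freq_G", "freq_T")])
  expect_equal(sort(unname(freqs), decreasing = TRUE)[1:2], c(0.5, 0.5))
  expect_equal(d$effect, "ambiguous")
})

test_that("a CDS insertion in all copies is reported as a frameshift", {
  m <- tiny_model()
  anc <- m$sequence
  with_ins <- paste0(substr(anc, 1, 100), "A", substr(anc, 101, 200))
  copies <- stats::setNames(rep(with_ins, 6), paste0("c", 1:6))
  aln <- align_sequences(copies, reference = m$sequence)
  res <- map_to_reference(call_consensus(column_frequencies(aln)), aln, m)
  d <- diff_consensus(res, m)
  ins <- d[d$kind == "insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$feature, "cds")
  expect_identical(ins$alt, "A")
  expect_equal(ins$effect, "frameshift")
})

test_that("the difference TSV re-parses to the identical record list", {
  m <- tiny_model()
  anc <- m$sequence
  substr(anc, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(anc, 12, 12))[1]
  substr(anc, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(anc, 50, 50))[1]
  copies <- stats::setNames(rep(anc, 5), paste0("c", 1:5))
  aln <- align_sequences(copies, reference = m$sequence)
  res <- map_to_reference(call_consensus(column_frequencies(aln)), aln, m)
  d <- diff_consensus(res, m)
  tf <- withr::local_tempfile(fileext = ".tsv")
  render_report(d, path = tf, metadata = c(run = "test"))
  back <- read_diff_tsv(tf)
  expect_equal(back, d)
})
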