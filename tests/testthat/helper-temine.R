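# Shared fixtures: all built in code at test time.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small transposon model with true inverted terminal repeats: 30-nt ITRs,
# 120-nt CDS, 200 nt total. Fast enough for end-to-end unit tests.
tiny_model <- function(seed = 7, binding = TRUE) {
  set.seed(seed)
  left <- random_dna(30)
  cds <- paste0("ATG", random_dna(117))
  right <- unname(reverse_complement(left))
  seqn <- paste0(left, random_dna(10), cds, random_dna(10), right)
  br <- if (binding)
    data.frame(itr = c("left_itr", "right_itr"), start = c(2L, 192L),
               end = c(9L, 199L), stringsAsFactors = FALSE)
  else NULL
  transposon_model("tiny", seqn, left_itr = c(1, 30), right_itr = c(171, 200),
                   cds = c(41, 160), cds_frame = 0, binding_regions = br)
}

# search settings scaled to the tiny model (few sampled seeds per feature)
tiny_search <- function(...) search_params(word_size = 11, step = 3, ...)

# fabricate a hit row without running a search
fake_hit <- function(chrom = "chr1", start, end, strand = "+",
                     identity = 1, qstart = 1, qend = end - start + 1,
                     score = end - start + 1) {
  alen <- end - start + 1L
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, matches = as.integer(round(identity * alen)),
             aligned_len = as.integer(alen), identity = identity,
             qstart = as.integer(qstart), qend = as.integer(qend),
             score = score, stringsAsFactors = FALSE)
}

# plant given sequences at fixed, well-separated positions in a random
# background; returns list(genome, starts, ends)
plant_genome <- function(seqs, strands = rep("+", length(seqs)),
                         background_len = 5000, spacing = NULL) {
  n <- length(seqs)
  if (is.null(spacing)) spacing <- floor(background_len / (n + 1))
  bg <- random_dna(background_len)
  pieces <- character(0)
  prev <- 0
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    bp <- i * spacing
    s <- if (strands[i] == "-") unname(reverse_complement(seqs[i])) else seqs[i]
    pieces <- c(pieces, substr(bg, prev + 1, bp), s)
    starts[i] <- sum(nchar(pieces)) - nchar(s) + 1L
    ends[i] <- sum(nchar(pieces))
    prev <- bp
  }
  pieces <- c(pieces, substr(bg, prev + 1, background_len))
  list(genome = c(chr1 = paste(pieces, collapse = "")),
       starts = starts, ends = ends)
}

# simple star-phylogeny copy set (substitutions only) for consensus tests
diverged_copies <- function(ancestor, n, p_sub, kappa = 2) {
  vapply(seq_len(n), function(i)
    mutate_copy(ancestor, p_sub = p_sub, kappa = kappa)$sequence,
    character(1))
}
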