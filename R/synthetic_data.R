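# Synthetic genome generator with full ground truth: background sequence
# with planted transposon copies diverged independently from one ancestor
# (star phylogeny, the neutral model under which the majority consensus
# recovers the ancestral sequence), plus truncated copies and ITR-less
# transposase-like decoys.

#' Simulation parameters
#'
#' @param genome_length Background genome length, nt.
#' @param gc_content Background GC fraction.
#' @param n_copies Number of planted full-length copies.
#' @param p_sub Per-site substitution probability per copy.
#' @param kappa Transition/transversion rate ratio (`Inf` = transitions
#'   only).
#' @param p_indel Per-site indel probability per copy.
#' @param indel_mean Mean indel length (geometric).
#' @param truncation_prob Probability a copy is truncated from one end.
#' @param truncation_range Fraction of the copy removed when truncated,
#'   `c(min, max)` of a uniform draw.
#' @param n_decoys Number of ITR-less transposase-like decoys (the model
#'   CDS, diverged like a copy) planted alongside.
#' @param strand_prob Probability a planted sequence is inserted
#'   reverse-complemented.
#' @param variant_site Optional `list(position, base, carrier_fraction)`
#'   planting a fixed variant in an exact fraction of copies before random
#'   divergence (threshold-boundary experiments).
#' @param subfamily_divergence Optional substitution divergence of two
#'   sub-ancestors; copies then split half-and-half between two subfamilies
#'   instead of the default star phylogeny.
#' @param seed Mandatory RNG seed driving all randomness.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 2e6, gc_content = 0.40, n_copies = 50,
                       p_sub = 0.03, kappa = 2, p_indel = 0,
                       indel_mean = 1.5, truncation_prob = 0,
                       truncation_range = c(0.3, 0.7), n_decoys = 0,
                       strand_prob = 0.5, variant_site = NULL,
                       subfamily_divergence = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(genome_length >= 0, gc_content >= 0, gc_content <= 1,
            n_copies >= 0, p_sub >= 0, p_sub <= 1, kappa > 0,
            p_indel >= 0, p_indel <= 1, truncation_prob >= 0,
            truncation_prob <= 1, n_decoys >= 0, strand_prob >= 0,
            strand_prob <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_copies = as.integer(n_copies),
                 p_sub = p_sub, kappa = kappa, p_indel = p_indel,
                 indel_mean = indel_mean, truncation_prob = truncation_prob,
                 truncation_range = truncation_range,
                 n_decoys = as.integer(n_decoys), strand_prob = strand_prob,
                 variant_site = variant_site,
                 subfamily_divergence = subfamily_divergence,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# deterministic per-item substream seeds, all below 2^31
.substream <- function(seed, i, offset = 0) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * offset) %% 2147483629)
}

.random_dna <- function(n, gc) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Mutate one copy of an ancestor sequence
#'
#' Independent per-site substitution with probability `p_sub`; the
#' alternative base is the transition with weight `kappa` against weight 1
#' for each transversion. Indels occur with per-site probability `p_indel`
#' (insertion or deletion equally likely, geometric length of mean
#' `indel_mean`). The returned mutation log replays exactly: applying it to
#' the ancestor with [replay_mutations()] reproduces the mutated sequence.
#'
#' Uses the R RNG in its current state; seed before calling for
#' reproducibility.
#'
#' @param ancestor Ancestral nucleotide sequence.
#' @param p_sub,kappa,p_indel,indel_mean See [sim_params()].
#' @return `list(sequence, log)` where `log` is
#'   `data.frame(position, ref, alt, type)` with positions in ancestor
#'   coordinates.
#' @export
mutate_copy <- function(ancestor, p_sub = 0.03, kappa = 2, p_indel = 0,
                        indel_mean = 1.5) {
  ch <- strsplit(ancestor, "")[[1]]
  L <- length(ch)
  log <- data.frame(position = integer(), ref = character(),
                    alt = character(), type = character(),
                    stringsAsFactors = FALSE)
  if (p_sub > 0) {
    sites <- which(stats::runif(L) < p_sub & ch %in% names(TRANSITION))
    for (s in sites) {
      base <- ch[s]
      if (is.infinite(kappa)) {
        alt <- TRANSITION[[base]]
      } else {
        pool <- c(TRANSITION[[base]], TRANSVERSIONS[[base]])
        alt <- sample(pool, 1, prob = c(kappa, 1, 1))
      }
      log <- rbind(log, data.frame(position = s, ref = base, alt = alt,
                                   type = "sub", stringsAsFactors = FALSE))
      ch[s] <- alt
    }
  }
  if (p_indel > 0) {
    sites <- which(stats::runif(L) < p_indel)
    for (s in sort(sites, decreasing = TRUE)) {
      len <- stats::rgeom(1, 1 / indel_mean) + 1L
      if (stats::runif(1) < 0.5) {  # insertion after position s
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        log <- rbind(log, data.frame(position = s, ref = "",
                                     alt = ins, type = "ins",
                                     stringsAsFactors = FALSE))
        ch <- append(ch, strsplit(ins, "")[[1]], after = s)
      } else {                       # deletion starting at position s
        to <- min(length(ch), s + len - 1L)
        log <- rbind(log, data.frame(position = s,
                                     ref = paste(ch[s:to], collapse = ""),
                                     alt = "", type = "del",
                                     stringsAsFactors = FALSE))
        ch <- ch[-(s:to)]
      }
    }
  }
  list(sequence = paste(ch, collapse = ""), log = log)
}

#' Replay a mutation log
#'
#' @param ancestor Ancestral sequence.
#' @param log Mutation log from [mutate_copy()].
#' @return Mutated sequence, byte-identical to the generated copy.
#' @export
replay_mutations <- function(ancestor, log) {
  ch <- strsplit(ancestor, "")[[1]]
  subs <- log[log$type == "sub", , drop = FALSE]
  for (i in seq_len(nrow(subs))) ch[subs$position[i]] <- subs$alt[i]
  indels <- log[log$type != "sub", , drop = FALSE]
  if (nrow(indels)) {
    indels <- indels[order(indels$position, decreasing = TRUE), ,
                     drop = FALSE]
    for (i in seq_len(nrow(indels))) {
      s <- indels$position[i]
      if (indels$type[i] == "ins") {
        ch <- append(ch, strsplit(indels$alt[i], "")[[1]], after = s)
      } else {
        ch <- ch[-(s:(s + nchar(indels$ref[i]) - 1L))]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Plant a fixed variant in an exact fraction of copies
#'
#' Exactly `round(carrier_fraction * length(copies))` copies (the first k,
#' by construction) receive `base` at `position`. Intended to run before
#' random divergence, enabling exact threshold-boundary experiments.
#'
#' @param copies Character vector of copy sequences.
#' @param position 1-based position.
#' @param base Variant base.
#' @param carrier_fraction Fraction of copies carrying the variant, in
#'   `[0, 1]`.
#' @return Modified copy vector.
#' @export
plant_variant_site <- function(copies, position, base, carrier_fraction) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1,
            position >= 1, all(position <= nchar(copies)))
  k <- round(carrier_fraction * length(copies))
  if (k > 0) {
    for (i in seq_len(k)) substr(copies[i], position, position) <- base
  }
  copies
}

#' Generate a synthetic genome with planted transposon copies
#'
#' Background sequence of i.i.d. composition at the requested GC content;
#' `n_copies` independently diverged copies of the model sequence and
#' `n_decoys` ITR-less CDS decoys are inserted at uniformly drawn,
#' necessarily non-overlapping breakpoints, each reverse-complemented with
#' probability `strand_prob`. Fully deterministic under the seed:
#' identical FASTA bytes and truth tables on every run.
#'
#' @param model A `transposon_model` (the ancestor).
#' @param params A [sim_params()] object.
#' @return `list(genome, truth)`: `genome` is a named character vector
#'   (single chromosome `chr1`); `truth` (class `synthetic_truth`) carries
#'   per-copy intervals, strands, planted sequences, mutation logs, decoy
#'   intervals, the ancestor model and the parameters.
#' @export
generate_genome <- function(model, params) {
  stopifnot(inherits(model, "transposon_model"),
            inherits(params, "sim_params"))
  n_items <- params$n_copies + params$n_decoys
  if (n_items > params$genome_length + 1)
    stop("infeasible packing: more insertions than breakpoints available")
  set.seed(params$seed)
  background <- .random_dna(params$genome_length, params$gc_content)

  ancestor <- model$sequence
  ancestors <- rep(ancestor, params$n_copies)
  subfam <- rep(0L, params$n_copies)
  if (!is.null(params$subfamily_divergence) && params$n_copies > 0) {
    set.seed(.substream(params$seed, 0, 1))
    subA <- mutate_copy(ancestor, p_sub = params$subfamily_divergence,
                        kappa = params$kappa)$sequence
    set.seed(.substream(params$seed, 0, 2))
    subB <- mutate_copy(ancestor, p_sub = params$subfamily_divergence,
                        kappa = params$kappa)$sequence
    half <- ceiling(params$n_copies / 2)
    ancestors <- c(rep(subA, half), rep(subB, params$n_copies - half))
    subfam <- c(rep(1L, half), rep(2L, params$n_copies - half))
  }
  if (!is.null(params$variant_site)) {
    vs <- params$variant_site
    ancestors <- plant_variant_site(ancestors, vs$position, vs$base,
                                    vs$carrier_fraction)
  }

  copies <- vector("list", params$n_copies)
  for (i in seq_len(params$n_copies)) {
    set.seed(.substream(params$seed, i, 3))
    mc <- mutate_copy(ancestors[i], params$p_sub, params$kappa,
                      params$p_indel, params$indel_mean)
    truncated <- FALSE
    if (params$truncation_prob > 0 &&
        stats::runif(1) < params$truncation_prob) {
      frac <- stats::runif(1, params$truncation_range[1],
                           params$truncation_range[2])
      cut <- floor(frac * nchar(mc$sequence))
      if (cut >= 1 && cut < nchar(mc$sequence)) {
        if (stats::runif(1) < 0.5) {
          mc$sequence <- substr(mc$sequence, cut + 1, nchar(mc$sequence))
        } else {
          mc$sequence <- substr(mc$sequence, 1, nchar(mc$sequence) - cut)
        }
        truncated <- TRUE
      }
    }
    copies[[i]] <- list(seq = mc$sequence, log = mc$log,
                        truncated = truncated, subfamily = subfam[i])
  }
  decoy_seq <- model_feature_seq(model, "cds")
  decoys <- vector("list", params$n_decoys)
  for (j in seq_len(params$n_decoys)) {
    set.seed(.substream(params$seed, j, 4))
    decoys[[j]] <- mutate_copy(decoy_seq, params$p_sub, params$kappa,
                               params$p_indel, params$indel_mean)$sequence
  }

  set.seed(.substream(params$seed, 0, 5))
  items <- c(lapply(copies, `[[`, "seq"), decoys)
  types <- c(rep("copy", params$n_copies), rep("decoy", params$n_decoys))
  strands <- ifelse(stats::runif(n_items) < params$strand_prob, "-", "+")
  breakpoints <- sort(sample.int(params$genome_length + 1L, n_items) - 1L)
  order_in <- sample.int(n_items)  # which item lands at which breakpoint

  pieces <- character(0)
  prev <- 0L
  starts <- integer(n_items); ends <- integer(n_items)
  for (k in seq_len(n_items)) {
    it <- order_in[k]
    s <- items[[it]]
    if (strands[it] == "-") s <- unname(reverse_complement(s))
    pieces <- c(pieces, substr(background, prev + 1L, breakpoints[k]), s)
    offset <- sum(nchar(pieces)) - nchar(s)
    starts[it] <- offset + 1L
    ends[it] <- offset + nchar(s)
    prev <- breakpoints[k]
  }
  pieces <- c(pieces, substr(background, prev + 1L, params$genome_length))
  genome <- c(chr1 = paste(pieces, collapse = ""))

  copy_idx <- which(types == "copy")
  truth_copies <- data.frame(
    id = if (params$n_copies) paste0("copy", seq_len(params$n_copies))
         else character(),
    chrom = rep("chr1", params$n_copies),
    start = starts[copy_idx], end = ends[copy_idx],
    strand = strands[copy_idx],
    n_subs = vapply(copies, function(x) sum(x$log$type == "sub"),
                    integer(1)),
    n_indels = vapply(copies, function(x) sum(x$log$type != "sub"),
                      integer(1)),
    truncated = vapply(copies, `[[`, logical(1), "truncated"),
    subfamily = vapply(copies, `[[`, integer(1), "subfamily"),
    stringsAsFactors = FALSE)
  decoy_idx <- which(types == "decoy")
  truth_decoys <- data.frame(
    id = if (params$n_decoys) paste0("decoy", seq_len(params$n_decoys))
         else character(),
    chrom = rep("chr1", params$n_decoys),
    start = starts[decoy_idx], end = ends[decoy_idx],
    strand = strands[decoy_idx], stringsAsFactors = FALSE)
  truth <- structure(list(
    copies = truth_copies,
    copy_sequences = stats::setNames(vapply(copies, `[[`, character(1),
                                            "seq"), truth_copies$id),
    mutation_logs = stats::setNames(lapply(copies, `[[`, "log"),
                                    truth_copies$id),
    ancestors = stats::setNames(if (params$n_copies) ancestors
                                else character(), truth_copies$id),
    decoys = truth_decoys,
    model = model, params = params), class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d copies, %d decoys, seed %d\n",
              nrow(x$copies), nrow(x$decoys), x$params$seed))
  invisible(x)
}

#' Write the simulation truth table as TSV
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- truth$copies
  if (nrow(truth$decoys)) {
    dd <- truth$decoys
    dd$n_subs <- NA_integer_; dd$n_indels <- NA_integer_
    dd$truncated <- NA; dd$subfamily <- NA_integer_
    df$type <- "copy"; dd$type <- "decoy"
    df <- rbind(df, dd[, names(df)])
  } else {
    df$type <- "copy"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
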