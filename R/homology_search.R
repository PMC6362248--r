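# Permissive seed-and-extend homology search, hit filters and PSL
# interoperability.
#
# The search mirrors the permissive external-tool settings used for
# transposon mining: short seeds sampled every `step` nt along the query,
# one seed mismatch tolerated, chained within a diagonal band and extended
# by local alignment. It is deterministic and dependency-free; precomputed
# PSL hits from an external tool can be substituted via read_psl().

#' Search parameters
#'
#' @param word_size Seed length in nt (>= 4).
#' @param step Stride between sampled query seeds, nt.
#' @param allow_one_mismatch Tolerate one mismatch per seed (mirrors the
#'   permissive one-off seeding of genome search tools).
#' @param xdrop Margin, in nt per query length fraction, added around a
#'   chained seed cluster before extension (controls how far extension may
#'   reach beyond the seeded diagonal band).
#' @param min_identity Minimum hit identity (fraction) retained.
#' @param min_seeds Minimum seed matches a diagonal chain needs before it
#'   is extended (capped at the number of sampled seeds, so very short
#'   queries still search); filters isolated random seed matches.
#' @param match,mismatch,gap Alignment scores (gap is the linear per-base
#'   penalty).
#' @return Object of class `search_params`.
#' @export
search_params <- function(word_size = 11, step = 5, allow_one_mismatch = TRUE,
                          xdrop = 0.10, min_identity = 0, min_seeds = 4,
                          match = 1, mismatch = -1, gap = -2) {
  stopifnot(word_size >= 4, step >= 1, min_identity >= 0, min_identity <= 1,
            min_seeds >= 1, match > 0, mismatch < 0, gap < 0)
  structure(list(word_size = as.integer(word_size), step = as.integer(step),
                 allow_one_mismatch = isTRUE(allow_one_mismatch),
                 xdrop = xdrop, min_identity = min_identity,
                 min_seeds = as.integer(min_seeds),
                 match = match, mismatch = mismatch, gap = gap),
            class = "search_params")
}

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), matches = integer(),
             aligned_len = integer(), identity = numeric(),
             qstart = integer(), qend = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

.subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = FALSE)
}

# All 1-mismatch variants of a seed string (including the seed itself).
.seed_neighborhood <- function(seed) {
  w <- nchar(seed)
  bases <- c("A", "C", "G", "T")
  out <- seed
  for (i in seq_len(w)) {
    for (b in setdiff(bases, substr(seed, i, i))) {
      v <- seed
      substr(v, i, i) <- b
      out <- c(out, v)
    }
  }
  out
}

# Seed match positions of query q in one chromosome sequence.
# Returns data.frame(qstart, tstart).
.seed_matches <- function(q, chrom_seq, params) {
  w <- params$word_size
  qlen <- nchar(q)
  if (nchar(chrom_seq) < w || qlen < w) {
    return(data.frame(qstart = integer(), tstart = integer()))
  }
  starts <- seq.int(1L, qlen - w + 1L, by = params$step)
  seeds <- substring(q, starts, starts + w - 1L)
  ok <- !grepl("[^ACGT]", seeds)
  starts <- starts[ok]
  seeds <- seeds[ok]
  if (!length(seeds)) return(data.frame(qstart = integer(), tstart = integer()))
  if (params$allow_one_mismatch) {
    pats <- lapply(seeds, .seed_neighborhood)
    qs <- rep(starts, lengths(pats))
    pats <- unlist(pats, use.names = FALSE)
  } else {
    pats <- seeds
    qs <- starts
  }
  # collapse duplicate patterns, keep the map back to query starts
  u <- unique(pats)
  idx <- match(pats, u)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(u))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(chrom_seq))
  si <- Biostrings::startIndex(m)
  nh <- lengths(si)
  if (!sum(nh)) return(data.frame(qstart = integer(), tstart = integer()))
  hit_u <- rep(seq_along(u), nh)
  tstart_u <- unlist(si, use.names = FALSE)
  # expand back: each occurrence of pattern u[k] applies to every query
  # start that produced it
  res_q <- integer(0)
  res_t <- integer(0)
  occ <- split(tstart_u, hit_u)
  for (k in names(occ)) {
    kk <- as.integer(k)
    qsk <- qs[idx == kk]
    tk <- occ[[k]]
    res_q <- c(res_q, rep(qsk, each = length(tk)))
    res_t <- c(res_t, rep(tk, times = length(qsk)))
  }
  unique(data.frame(qstart = res_q, tstart = res_t))
}

# Cluster seed matches into candidate windows by diagonal band and genomic
# proximity. Returns data.frame(wstart, wend) of candidate windows.
.chain_seeds <- function(sm, qlen, clen, params) {
  if (!nrow(sm)) return(data.frame(wstart = integer(), wend = integer()))
  band <- ceiling(params$xdrop * qlen)
  w <- params$word_size
  sm$diag <- sm$tstart - sm$qstart
  sm <- sm[order(sm$diag, sm$tstart), ]
  cl <- integer(nrow(sm))
  cur <- 1L
  cl[1] <- cur
  base_diag <- sm$diag[1]
  for (i in seq_len(nrow(sm))[-1]) {
    if (sm$diag[i] - base_diag > band) {
      cur <- cur + 1L
      base_diag <- sm$diag[i]
    }
    cl[i] <- cur
  }
  # split diagonal clusters by genomic distance (distinct copies can share
  # a diagonal), then drop chains with too few seeds (isolated random
  # matches); windows from distinct chains are kept separate so nearby
  # copies each get their own extension
  n_seeds_sampled <- length(unique(sm$qstart))
  need <- min(params$min_seeds, n_seeds_sampled)
  out <- list()
  for (g in split(sm, cl)) {
    g <- g[order(g$tstart), ]
    brk <- cumsum(c(1L, as.integer(diff(g$tstart) > qlen + band)))
    for (h in split(g, brk)) {
      if (nrow(h) < need) next
      ws <- min(h$tstart - (h$qstart - 1L)) - band
      we <- max(h$tstart + w - 1L + (qlen - (h$qstart + w - 1L))) + band
      out[[length(out) + 1L]] <- c(max(1L, ws), min(clen, we))
    }
  }
  if (!length(out)) return(data.frame(wstart = integer(), wend = integer()))
  wins <- do.call(rbind, out)
  unique(data.frame(wstart = wins[, 1], wend = wins[, 2]))
}

#' Find genomic copies of a query sequence
#'
#' Seed-and-extend search over both strands of every genome record. Seeds
#' are exact (or one-mismatch) `word_size`-mers sampled every `step` nt of
#' the query; seeds are chained within a diagonal band of ±`xdrop` × query
#' length and each chained cluster is extended by local alignment with the
#' configured scores. Overlapping hits on the same chromosome and strand
#' are resolved by higher score, then leftmost start. Output is ordered by
#' chromosome, start, strand.
#'
#' A minus-strand hit means the reverse complement of the query matches the
#' forward genomic span; [extract_hit_sequences()] returns all hits in
#' query orientation.
#'
#' @param genome Named character vector of chromosome sequences (or a FASTA
#'   path).
#' @param query Query nucleotide sequence.
#' @param params A [search_params()] object.
#' @return `data.frame` of hits with columns `chrom, start, end, strand,
#'   matches, aligned_len, identity, qstart, qend, score`.
#' @export
find_hits <- function(genome, query, params = search_params()) {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen < params$word_size)
    stop("query shorter than word_size")
  if (!length(genome)) return(empty_hits())
  submat <- .subst_matrix(params)
  rows <- list()
  for (chrom in names(genome)) {
    cseq <- genome[[chrom]]
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else unname(reverse_complement(query))
      sm <- .seed_matches(q, cseq, params)
      wins <- .chain_seeds(sm, qlen, clen, params)
      if (!nrow(wins)) next
      for (i in seq_len(nrow(wins))) {
        ws <- wins$wstart[i]; we <- wins$wend[i]
        aln <- Biostrings::pairwiseAlignment(
          pattern = Biostrings::DNAString(q),
          subject = Biostrings::DNAString(substr(cseq, ws, we)),
          type = "local", substitutionMatrix = submat,
          gapOpening = 0, gapExtension = abs(params$gap))
        pat <- Biostrings::alignedPattern(aln)
        alen <- nchar(as.character(pat))
        if (alen == 0) next
        nmat <- Biostrings::nmatch(aln)
        qs <- Biostrings::start(Biostrings::pattern(aln))
        qe <- Biostrings::end(Biostrings::pattern(aln))
        ts <- ws + Biostrings::start(Biostrings::subject(aln)) - 1L
        te <- ws + Biostrings::end(Biostrings::subject(aln)) - 1L
        if (strand == "-") {
          tmp <- qs
          qs <- qlen - qe + 1L
          qe <- qlen - tmp + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = as.integer(ts), end = as.integer(te),
          strand = strand, matches = as.integer(nmat),
          aligned_len = as.integer(alen), identity = nmat / alen,
          qstart = as.integer(qs), qend = as.integer(qe),
          score = Biostrings::score(aln), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- unique(hits)
  hits <- hits[hits$identity >= params$min_identity, , drop = FALSE]
  hits <- .resolve_overlaps(hits)
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Among hits overlapping by more than half the shorter span on the same
# chromosome (either strand: an inverted-repeat-bearing query produces a
# weak mirror hit over a true copy), keep the higher score, then the
# leftmost start.
.resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score, hits$chrom, hits$start, hits$strand)
  kept <- list()
  for (i in ord) {
    h <- hits[i, ]
    clash <- FALSE
    for (k in kept) {
      if (hits$chrom[k] != h$chrom) next
      ov <- min(hits$end[k], h$end) - max(hits$start[k], h$start) + 1L
      if (ov <= 0) next
      shorter <- min(hits$end[k] - hits$start[k], h$end - h$start) + 1L
      if (ov > 0.5 * shorter) { clash <- TRUE; break }
    }
    if (clash) keep[i] <- FALSE else kept[[length(kept) + 1L]] <- i
  }
  hits[keep, , drop = FALSE]
}

#' Filter hits by length deviation from the query
#'
#' Keeps a hit iff its span length deviates from the query length by no
#' more than `max_dev` × query length ("more than 10%" is strict: a
#' deviation exactly at the bound is kept).
#'
#' @param hits Hit data frame.
#' @param query_len Query length, nt.
#' @param max_dev Maximum tolerated fractional deviation.
#' @return Filtered hit data frame (order preserved).
#' @export
filter_by_length <- function(hits, query_len, max_dev = 0.10) {
  stopifnot(query_len > 0)
  if (!nrow(hits)) return(hits)
  len <- hits$end - hits$start + 1L
  hits[abs(len - query_len) <= max_dev * query_len, , drop = FALSE]
}

#' Filter hits by identity
#'
#' Keeps hits with `identity >= min_identity` (inclusive, "at least").
#'
#' @param hits Hit data frame.
#' @param min_identity Minimum identity fraction.
#' @return Filtered hit data frame (order preserved).
#' @export
filter_by_identity <- function(hits, min_identity) {
  if (!nrow(hits)) return(hits)
  hits[hits$identity >= min_identity, , drop = FALSE]
}

#' Remove sequence-duplicate hits
#'
#' Among hits whose extracted (query-oriented) sequences are identical
#' strings, exactly one representative — the lowest by chromosome, start,
#' strand — is retained. Idempotent.
#'
#' @param hits Hit data frame.
#' @param genome Named character vector of chromosome sequences.
#' @return Deduplicated hit data frame.
#' @export
dedupe_hits <- function(hits, genome) {
  if (nrow(hits) < 2) return(hits)
  seqs <- extract_hit_sequences(genome, hits)
  ord <- order(hits$chrom, hits$start, hits$strand)
  first <- ord[!duplicated(seqs[ord])]
  out <- hits[sort(first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit identifier strings
#'
#' @param hits Hit data frame.
#' @return Character vector `chrom:start-end(strand)`.
#' @export
hit_ids <- function(hits) {
  if (!nrow(hits)) return(character())
  sprintf("%s:%d-%d(%s)", hits$chrom, hits$start, hits$end, hits$strand)
}

#' Extract hit sequences in query orientation
#'
#' Minus-strand hits are reverse-complemented so every returned sequence
#' reads in the orientation of the query.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param hits Hit data frame.
#' @return Named character vector (names from [hit_ids()]).
#' @export
extract_hit_sequences <- function(genome, hits) {
  if (!nrow(hits)) return(character())
  ids <- hit_ids(hits)
  out <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cseq <- genome[[hits$chrom[i]]]
    if (is.null(cseq) || is.na(cseq))
      stop("hit on unknown chromosome: ", ids[i])
    if (hits$start[i] < 1 || hits$end[i] > nchar(cseq))
      stop("hit span out of chromosome bounds: ", ids[i])
    s <- substr(cseq, hits$start[i], hits$end[i])
    out[i] <- if (hits$strand[i] == "-") unname(reverse_complement(s)) else s
  }
  names(out) <- ids
  out
}

PSL_HEADER <- c(
  "psLayout version 3",
  "",
  "match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap\tstrand\tQ        \tQ   \tQ    \tQ  \tT        \tT   \tT    \tT  \tblock\tblockSizes \tqStarts\t tStarts",
  "     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases\t      \tname     \tsize\tstart\tend\tname     \tsize\tstart\tend\tcount",
  "---------------------------------------------------------------------------------------------------------------------------------------------------------------")

#' Write hits as PSL
#'
#' Single-block PSL per hit, 21 tab-separated columns per the UCSC layout
#' (coordinates converted to PSL's 0-based half-open convention).
#' `misMatches` is written as `aligned_len - matches`; the alignment score
#' is not representable in PSL.
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @param query_name,query_len Query metadata written to the Q columns.
#' @param genome Optional genome (named character vector) used to fill
#'   `tSize`; 0 when absent.
#' @param header Write the 5-line PSL header.
#' @return `path`, invisibly.
#' @export
write_psl <- function(hits, path, query_name = "query", query_len = NA,
                      genome = NULL, header = TRUE) {
  lines <- if (header) PSL_HEADER else character()
  if (nrow(hits)) {
    qsz <- if (is.na(query_len)) max(hits$qend) else as.integer(query_len)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      tsz <- if (!is.null(genome) && !is.null(genome[[h$chrom]]))
        nchar(genome[[h$chrom]]) else 0L
      mism <- h$aligned_len - h$matches
      lines <- c(lines, paste(
        h$matches, mism, 0L, 0L, 0L, 0L, 0L, 0L, h$strand,
        query_name, qsz, h$qstart - 1L, h$qend,
        h$chrom, tsz, h$start - 1L, h$end,
        1L, paste0(h$end - h$start + 1L, ","),
        paste0(h$qstart - 1L, ","), paste0(h$start - 1L, ","),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read hits from a PSL file
#'
#' Accepts the standard 21-column layout with or without the 5-line header.
#' `aligned_len` is reconstructed as matches + misMatches + inserted bases;
#' the score is recomputed as matches − misMatches.
#'
#' @param path PSL file path.
#' @return Hit data frame.
#' @export
read_psl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    if (!grepl("^[0-9]", line)) next  # header / separator lines
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 21)
      stop(sprintf("malformed PSL line %d: expected 21 columns, got %d",
                   ln, length(f)))
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (any(is.na(num)))
      stop(sprintf("malformed PSL line %d: non-numeric field", ln))
    matches <- as.integer(f[1]); mism <- as.integer(f[2])
    qbi <- as.integer(f[6]); tbi <- as.integer(f[8])
    strand <- f[9]
    if (!strand %in% c("+", "-"))
      stop(sprintf("malformed PSL line %d: bad strand '%s'", ln, strand))
    alen <- matches + mism + qbi + tbi
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[14], start = as.integer(f[16]) + 1L,
      end = as.integer(f[17]), strand = strand,
      matches = matches, aligned_len = alen,
      identity = if (alen > 0) matches / alen else 0,
      qstart = as.integer(f[12]) + 1L, qend = as.integer(f[13]),
      score = as.numeric(matches - mism), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write hits as TSV
#' @param hits Hit data frame.
#' @param path Output path.
#' @param comment Optional `#` header comment lines.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
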