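# Multiple sequence alignment: a deterministic built-in center-star
# progressive aligner anchored on the reference, an external MAFFT adapter,
# and rule-based curation of indel-heavy rows.

#' Construct a multiple alignment object
#'
#' @param ids Row identifiers.
#' @param seqs Gapped row sequences (equal lengths).
#' @param reference Id of the reference row, or `NA`.
#' @return Object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(ids, seqs, reference = NA) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1,
            !anyDuplicated(ids))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("alignment rows have unequal widths")
  if (!is.na(reference) && !reference %in% ids)
    stop("reference row '", reference, "' not among row ids")
  structure(list(ids = as.character(ids), seqs = unname(as.character(seqs)),
                 n_cols = unname(widths[1]), reference = reference),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns%s\n",
              length(x$ids), x$n_cols,
              if (!is.na(x$reference))
                paste0(", reference: ", x$reference) else ""))
  invisible(x)
}

#' Remove gaps from a row
#' @param aln A `multiple_alignment`.
#' @param id Row id.
#' @return Ungapped sequence.
#' @export
ungap_row <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop("no row '", id, "'")
  gsub("-", "", aln$seqs[i], fixed = TRUE)
}

# number of gap characters between consecutive center bases: slot k
# (0..L) counts gaps after center base k (slot 0 = before the first base)
.gap_slots <- function(gapped_center, L) {
  ch <- strsplit(gapped_center, "")[[1]]
  is_base <- ch != "-"
  slot <- cumsum(is_base)
  ins <- integer(L + 1)
  if (any(!is_base)) {
    t <- table(slot[!is_base])
    ins[as.integer(names(t)) + 1L] <- as.integer(t)
  }
  ins
}

# re-emit a pairwise-aligned row on the master gap scaffold: slot segments
# (insertions, left-aligned and padded to max_ins) interleaved with the
# center-aligned characters
.project_row <- function(gapped_center, gapped_row, max_ins, L) {
  chC <- strsplit(gapped_center, "")[[1]]
  chR <- strsplit(gapped_row, "")[[1]]
  is_base <- chC != "-"
  slot <- cumsum(is_base)
  bases <- chR[is_base]
  ins_str <- rep("", L + 1)
  if (any(!is_base)) {
    sp <- split(chR[!is_base], slot[!is_base])
    ins_str[as.integer(names(sp)) + 1L] <-
      vapply(sp, paste, character(1), collapse = "")
  }
  segs <- paste0(ins_str, strrep("-", max_ins - nchar(ins_str)))
  paste0(segs[1], paste(paste0(bases, segs[-1]), collapse = ""))
}

.builtin_align <- function(seqs, reference, ref_id, match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 1) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  if (!is.null(reference)) {
    center <- reference
  } else {
    center <- seqs[[which.max(nchar(seqs))]]
  }
  L <- nchar(center)
  pas <- lapply(seqs, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s),
      subject = Biostrings::DNAString(center),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    list(center = as.character(Biostrings::alignedSubject(pa)),
         row = as.character(Biostrings::alignedPattern(pa)))
  })
  ins <- lapply(pas, function(p) .gap_slots(p$center, L))
  max_ins <- Reduce(pmax, ins, integer(L + 1))
  # master center row: center bases interleaved with all-gap slots
  center_ch <- strsplit(center, "")[[1]]
  segs <- strrep("-", max_ins)
  master <- paste0(segs[1], paste(paste0(center_ch, segs[-1]), collapse = ""))
  rows <- vapply(pas, function(p)
    .project_row(p$center, p$row, max_ins, L), character(1))
  out_ids <- names(seqs)
  if (!is.null(reference)) {
    multiple_alignment(c(ref_id, out_ids), c(master, rows), reference = ref_id)
  } else {
    # the center sequence is one of the inputs; its projected row equals
    # the master scaffold
    multiple_alignment(out_ids, rows, reference = NA)
  }
}

.mafft_align <- function(seqs, reference, ref_id, mode) {
  if (Sys.which("mafft") == "")
    stop("external aligner 'mafft' requested but not found on PATH")
  input <- seqs
  if (!is.null(reference)) {
    input <- c(stats::setNames(reference, ref_id), seqs)
  }
  n <- length(input)
  if (is.null(mode)) mode <- if (n < 200) "linsi" else "fftns2"
  flags <- switch(mode,
                  fftns2 = c("--retree", "2"),
                  linsi = c("--localpair", "--maxiterate", "1000"),
                  auto = "--auto",
                  stop("unknown mafft mode: ", mode))
  tin <- tempfile(fileext = ".fa"); tout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  # protect ids from truncation/mangling by writing positional ids
  write_fasta(stats::setNames(unname(input),
                              paste0("s", seq_along(input))), tin)
  status <- system2("mafft", c(flags, "--inputorder", "--quiet", tin),
                    stdout = tout, stderr = FALSE)
  if (status != 0) stop("mafft failed with exit status ", status)
  out <- read_fasta(tout, allow_gaps = TRUE)
  out <- out[paste0("s", seq_along(input))]
  multiple_alignment(names(input), unname(out),
                     reference = if (!is.null(reference)) ref_id else NA)
}

#' Align sequences to one another (and optionally a reference)
#'
#' The built-in engine is a deterministic center-star progressive aligner:
#' every sequence is globally aligned (affine gaps) to the center — the
#' reference when given, otherwise the longest input — and the pairwise
#' gap patterns are merged onto one master scaffold. The external engine
#' invokes MAFFT (never a silent fallback: a missing binary is an error);
#' its default mode follows a documented size heuristic (L-INS-i below 200
#' sequences, FFT-NS-2 at or above) and can be forced with `mafft_mode`.
#'
#' @param seqs Named character vector of (ungapped) sequences.
#' @param reference Optional reference sequence anchoring the alignment;
#'   becomes the first row.
#' @param ref_id Row id used for the reference.
#' @param engine `"builtin"` or `"mafft"`.
#' @param mafft_mode `NULL` (size heuristic) or one of `"fftns2"`,
#'   `"linsi"`, `"auto"`.
#' @param match,mismatch,gap_open,gap_extend Built-in pairwise scores
#'   (penalties positive; a gap of length k costs `gap_open + k *
#'   gap_extend`).
#' @return A `multiple_alignment`; the reference row, when present, is
#'   flagged in `$reference`.
#' @export
align_sequences <- function(seqs, reference = NULL, ref_id = "reference",
                            engine = c("builtin", "mafft"),
                            mafft_mode = NULL, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 1) {
  engine <- match.arg(engine)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  n_total <- length(seqs) + !is.null(reference)
  if (n_total < 2) stop("need at least 2 sequences to align")
  if (!is.null(reference) && ref_id %in% names(seqs))
    stop("ref_id collides with an input sequence name")
  if (engine == "builtin") {
    .builtin_align(seqs, reference, ref_id, match, mismatch, gap_open,
                   gap_extend)
  } else {
    .mafft_align(seqs, reference, ref_id, mafft_mode)
  }
}

#' Curate an alignment by gap fraction
#'
#' Drops every non-reference row whose gap fraction exceeds
#' `max_gap_fraction` (the reproducible replacement for manual removal of
#' indel-heavy hits), then deletes any columns left all-gap. Dropped row
#' ids are attached as attribute `"dropped"`. Idempotent.
#'
#' @param aln A `multiple_alignment`.
#' @param max_gap_fraction Maximum tolerated per-row gap fraction.
#' @return Curated `multiple_alignment`.
#' @export
curate_alignment <- function(aln, max_gap_fraction = 0.10) {
  gapfrac <- vapply(aln$seqs, function(s) {
    n <- nchar(s)
    (n - nchar(gsub("-", "", s, fixed = TRUE))) / n
  }, numeric(1))
  drop <- gapfrac > max_gap_fraction & aln$ids != ifelse(is.na(aln$reference),
                                                         "", aln$reference)
  kept_ids <- aln$ids[!drop]
  kept <- aln$seqs[!drop]
  # delete all-gap columns created by the removal
  mat <- do.call(rbind, strsplit(kept, ""))
  all_gap <- colSums(mat != "-") == 0
  if (any(all_gap)) {
    mat <- mat[, !all_gap, drop = FALSE]
    kept <- apply(mat, 1, paste, collapse = "")
  }
  out <- multiple_alignment(kept_ids, kept,
                            reference = if (!is.na(aln$reference) &&
                                            aln$reference %in% kept_ids)
                              aln$reference else NA)
  attr(out, "dropped") <- aln$ids[drop]
  out
}

#' Write an alignment as aligned FASTA
#' @param aln A `multiple_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(stats::setNames(aln$seqs, aln$ids), path)
}

#' Read an aligned FASTA file
#' @param path Aligned FASTA path.
#' @param reference Optional reference row id to flag.
#' @return A `multiple_alignment`.
#' @export
read_alignment <- function(path, reference = NA) {
  seqs <- read_fasta(path, allow_gaps = TRUE)
  multiple_alignment(names(seqs), unname(seqs), reference = reference)
}
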