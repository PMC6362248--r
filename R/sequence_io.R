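# Sequence input/output and the reference transposon model.
#
# All coordinates in this package are 1-based closed intervals (the
# R/Bioconductor convention); PSL files are converted from/to their native
# 0-based half-open layout at the file boundary only.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read a multi-record FASTA file
#'
#' Reads nucleotide FASTA (wrapped or unwrapped). Sequences are uppercased;
#' IUPAC ambiguity codes are tolerated and kept as-is (they count as
#' mismatches during search). Record ids are the header up to the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Accept `-` characters (aligned FASTA).
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop("FASTA file not found: ", path)
  if (file.size(path) == 0)
    stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0)
    stop("no FASTA records in: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == ""))
    stop("FASTA record with empty id in: ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated FASTA record id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- ids[nchar(seqs) == 0]
  if (length(empty))
    stop("zero-length FASTA record(s): ", paste(empty, collapse = ", "))
  allowed <- c(IUPAC_CHARS, if (allow_gaps) c(".", "-"))
  pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- grepl(pat, seqs)
  if (any(bad)) {
    id <- ids[which(bad)[1]]
    stop(sprintf("invalid sequence character in record '%s' (line %d)",
                 id, .fasta_bad_line(path, id, pat)))
  }
  seqs
}

# Locate the first offending line of a record, for error reporting.
.fasta_bad_line <- function(path, rec_id, pat) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  this <- which(sub("\\s.*$", "", sub("^>", "", lines[hdr])) == rec_id)[1]
  from <- hdr[this] + 1
  to <- if (this < length(hdr)) hdr[this + 1] - 1 else length(lines)
  for (i in seq(from, to)) {
    if (grepl(pat, toupper(lines[i]))) return(i)
  }
  from
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), length(seqs) > 0, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' IUPAC ambiguity codes are complemented per the IUPAC table; gaps are
#' preserved.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of reverse complements (names preserved).
#' @export
reverse_complement <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
  names(out) <- names(seq)
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing partial codon is dropped; stop codons
#' render as `*`; any codon containing a non-ACGT character renders as `X`.
#'
#' @param cds_seq Nucleotide sequence.
#' @param frame Reading-frame offset 0, 1 or 2 (bases skipped before the
#'   first codon).
#' @return Amino-acid sequence, one letter per complete codon.
#' @export
translate_cds <- function(cds_seq, frame = 0) {
  stopifnot(length(cds_seq) == 1, frame %in% 0:2)
  s <- toupper(cds_seq)
  if (frame > 0) s <- substr(s, frame + 1, nchar(s))
  n <- nchar(s) %/% 3
  if (n == 0) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a transposon model
#'
#' A transposon model is the reference element used both as search query and
#' as the coordinate frame for annotation: the full nucleotide sequence plus
#' the spans of the left/right inverted terminal repeats (ITRs), the
#' transposase CDS with its reading-frame offset, and the transposase
#' binding regions nested inside the ITRs.
#'
#' All spans are 1-based closed `c(start, end)` on the full sequence and
#' must satisfy: left ITR before CDS before right ITR, all within the
#' sequence. Binding regions are optional (some outputs are then marked
#' unevaluable) and must nest inside their parent ITR.
#'
#' @param name Model label.
#' @param sequence Nucleotide sequence (uppercased).
#' @param left_itr,right_itr,cds Integer `c(start, end)` spans.
#' @param cds_frame Reading-frame offset of the CDS (0/1/2).
#' @param binding_regions `data.frame(itr, start, end)` with `itr` in
#'   `c("left_itr", "right_itr")` and full-sequence spans, or `NULL`.
#' @return Object of class `transposon_model`.
#' @export
transposon_model <- function(name, sequence, left_itr, right_itr, cds,
                             cds_frame = 0, binding_regions = NULL) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  chk_span <- function(sp, lab) {
    if (length(sp) != 2 || any(is.na(sp)) || sp[1] > sp[2] ||
        sp[1] < 1 || sp[2] > len)
      stop(sprintf("invalid %s span [%s, %s] for sequence of length %d",
                   lab, sp[1], sp[2], len))
    as.integer(sp)
  }
  left_itr <- chk_span(left_itr, "left_itr")
  right_itr <- chk_span(right_itr, "right_itr")
  cds <- chk_span(cds, "cds")
  if (!(left_itr[2] < cds[1] && cds[2] < right_itr[1]))
    stop("feature order violated: left_itr must precede cds must precede right_itr")
  stopifnot(cds_frame %in% 0:2)
  if (!is.null(binding_regions)) {
    stopifnot(is.data.frame(binding_regions),
              all(c("itr", "start", "end") %in% names(binding_regions)))
    for (i in seq_len(nrow(binding_regions))) {
      br <- binding_regions[i, ]
      parent <- switch(br$itr, left_itr = left_itr, right_itr = right_itr,
                       stop("binding region parent must be left_itr or right_itr"))
      if (br$start < parent[1] || br$end > parent[2] || br$start > br$end)
        stop(sprintf("binding region [%d, %d] not nested in its %s span",
                     br$start, br$end, br$itr))
    }
    binding_regions$start <- as.integer(binding_regions$start)
    binding_regions$end <- as.integer(binding_regions$end)
  }
  structure(list(name = name, sequence = sequence, length = len,
                 left_itr = left_itr, right_itr = right_itr, cds = cds,
                 cds_frame = as.integer(cds_frame),
                 binding_regions = binding_regions),
            class = "transposon_model")
}

#' @export
print.transposon_model <- function(x, ...) {
  cat(sprintf("<transposon_model> %s: %d nt\n", x$name, x$length))
  cat(sprintf("  left ITR  %d-%d (%d nt)\n", x$left_itr[1], x$left_itr[2],
              diff(x$left_itr) + 1))
  cat(sprintf("  CDS       %d-%d (%d nt, frame %d)\n", x$cds[1], x$cds[2],
              diff(x$cds) + 1, x$cds_frame))
  cat(sprintf("  right ITR %d-%d (%d nt)\n", x$right_itr[1], x$right_itr[2],
              diff(x$right_itr) + 1))
  if (is.null(x$binding_regions)) {
    cat("  binding regions: not configured\n")
  } else {
    cat(sprintf("  binding regions: %d configured\n", nrow(x$binding_regions)))
  }
  invisible(x)
}

#' Extract a feature sequence from a model
#'
#' @param model A `transposon_model`.
#' @param feature One of `"full"`, `"left_itr"`, `"right_itr"`, `"cds"`.
#' @return Nucleotide sequence of the feature.
#' @export
model_feature_seq <- function(model, feature = c("full", "left_itr",
                                                 "right_itr", "cds")) {
  feature <- match.arg(feature)
  if (feature == "full") return(model$sequence)
  sp <- model[[feature]]
  substr(model$sequence, sp[1], sp[2])
}

#' Load a transposon model from a YAML configuration
#'
#' The configuration carries: `name`; either `sequence` (literal) or
#' `sequence_file` (FASTA, path relative to the YAML file); `left_itr`,
#' `cds` (with `frame`), `right_itr` spans; optional `binding_regions`
#' (list of `{itr, start, end}`). Spans are 1-based closed on the full
#' sequence, so binding-region boxes are editable without touching code.
#'
#' @param path Path to the YAML configuration.
#' @return A validated `transposon_model`.
#' @export
load_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg[["sequence"]])) {
    seq <- gsub("\\s", "", cfg[["sequence"]])
  } else if (!is.null(cfg[["sequence_file"]])) {
    fp <- cfg[["sequence_file"]]
    if (!file.exists(fp)) fp <- file.path(dirname(path), cfg[["sequence_file"]])
    seq <- unname(read_fasta(fp)[1])
  } else {
    stop("model config must give 'sequence' or 'sequence_file'")
  }
  br <- NULL
  if (!is.null(cfg$binding_regions) && length(cfg$binding_regions)) {
    br <- do.call(rbind, lapply(cfg$binding_regions, function(b)
      data.frame(itr = b$itr, start = b$start, end = b$end,
                 stringsAsFactors = FALSE)))
  }
  transposon_model(
    name = if (is.null(cfg$name)) basename(path) else cfg$name,
    sequence = seq,
    left_itr = c(cfg$left_itr$start, cfg$left_itr$end),
    right_itr = c(cfg$right_itr$start, cfg$right_itr$end),
    cds = c(cfg$cds$start, cfg$cds$end),
    cds_frame = if (is.null(cfg$cds$frame)) 0 else cfg$cds$frame,
    binding_regions = br)
}

#' The packaged synthetic SB-like demonstration model
#'
#' A synthetic 1638-nt element with Sleeping-Beauty-like geometry (227-nt
#' ITRs flanking a 1022-nt transposase CDS) and two editable binding-region
#' boxes per ITR. The sequence is randomly generated, not the real SB
#' construct; substitute your own model config to analyse a real element.
#'
#' @return A `transposon_model`.
#' @export
sb_like_model <- function() {
  load_model(system.file("extdata", "synthetic_sb_like_model.yaml",
                         package = "temine", mustWork = TRUE))
}

#' Convert a feature-local position to a full-sequence position
#'
#' Feature positions are 1-based within the named feature, the convention
#' used in all reports ("position 31 in the left repeat").
#'
#' @param model A `transposon_model`.
#' @param feature `"full"`, `"left_itr"`, `"right_itr"` or `"cds"`.
#' @param position 1-based position within the feature.
#' @return 1-based position on the full sequence.
#' @export
feature_to_offset <- function(model, feature, position) {
  stopifnot(position >= 1)
  if (feature == "full") {
    if (position > model$length) stop("position beyond sequence end")
    return(as.integer(position))
  }
  sp <- model[[feature]]
  if (is.null(sp)) stop("unknown feature: ", feature)
  if (position > diff(sp) + 1)
    stop(sprintf("position %d beyond %s length %d", position, feature,
                 diff(sp) + 1))
  as.integer(sp[1] + position - 1)
}

#' Convert a full-sequence position to a feature-local position
#'
#' Positions falling in no annotated feature map to feature `"full"`.
#'
#' @param model A `transposon_model`.
#' @param offset 1-based position on the full sequence.
#' @return `list(feature, position)`.
#' @export
offset_to_feature <- function(model, offset) {
  stopifnot(offset >= 1, offset <= model$length)
  for (f in c("left_itr", "cds", "right_itr")) {
    sp <- model[[f]]
    if (offset >= sp[1] && offset <= sp[2])
      return(list(feature = f, position = as.integer(offset - sp[1] + 1)))
  }
  list(feature = "full", position = as.integer(offset))
}
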