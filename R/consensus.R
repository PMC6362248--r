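# Per-column frequency profiling, inclusive majority-rule consensus calling
# with 'N' at variable positions, and mapping of the consensus onto the
# reference coordinate frame (insertions/deletions relative to the
# reference).

CONSENSUS_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Per-column nucleotide frequencies of an alignment
#'
#' Exact counts of A, C, G, T and gap per column. Gaps count as a fifth
#' symbol in the denominator, so "conserved in at least 60% of the
#' sequences" is literal over all counted rows. The reference row is
#' excluded by default so the consensus reflects the genomic copies only.
#' Characters outside the five symbols (rare ambiguity codes) count in the
#' denominator but toward no symbol.
#'
#' @param aln A `multiple_alignment`.
#' @param include_reference Count the reference row too.
#' @return Object of class `column_profile`: list with `counts` and `freqs`
#'   (5 x n_cols matrices, rows `A,C,G,T,-`) and `n_rows`.
#' @export
column_frequencies <- function(aln, include_reference = FALSE) {
  seqs <- aln$seqs
  if (!include_reference && !is.na(aln$reference)) {
    seqs <- seqs[aln$ids != aln$reference]
  }
  if (!length(seqs)) stop("no rows to count")
  mat <- do.call(rbind, strsplit(seqs, ""))
  counts <- matrix(0, nrow = length(CONSENSUS_SYMBOLS), ncol = ncol(mat),
                   dimnames = list(CONSENSUS_SYMBOLS, NULL))
  for (s in CONSENSUS_SYMBOLS) counts[s, ] <- colSums(mat == s)
  structure(list(counts = counts, freqs = counts / length(seqs),
                 n_rows = length(seqs)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("<column_profile> %d columns over %d rows\n",
              ncol(x$counts), x$n_rows))
  invisible(x)
}

#' Call a majority-rule consensus from a column profile
#'
#' Per column: if some base reaches frequency `threshold` (inclusive — "at
#' least 60%" keeps an exact-60% majority), that base is emitted; else if
#' the gap symbol reaches `threshold` the column is a deletion column and
#' emits nothing; otherwise `N` is emitted and the column's frequency
#' vector is recorded as a variable position.
#'
#' @param profile A `column_profile`.
#' @param threshold Majority threshold in (0, 1].
#' @return Object of class `consensus_result` with fields `consensus`
#'   (sequence with possible `N`s), `column_map` (`data.frame(column,
#'   call, consensus_index)` with `call` in base/`N`/`del`), and
#'   `variable_positions` (`data.frame(column, freq_A..freq_gap)`).
#' @export
call_consensus <- function(profile, threshold = 0.60) {
  stopifnot(threshold > 0, threshold <= 1)
  fr <- profile$freqs
  ncols <- ncol(fr)
  base_fr <- fr[c("A", "C", "G", "T"), , drop = FALSE]
  top <- apply(base_fr, 2, max)
  # deterministic tie-break: alphabetically first base among maxima
  top_base <- rownames(base_fr)[apply(base_fr, 2, which.max)]
  call <- ifelse(top >= threshold, top_base,
                 ifelse(fr["-", ] >= threshold, "del", "N"))
  cons_chars <- call[call != "del"]
  consensus <- paste(ifelse(cons_chars %in% c("A", "C", "G", "T"),
                            cons_chars, "N"), collapse = "")
  consensus_index <- rep(NA_integer_, ncols)
  consensus_index[call != "del"] <- seq_len(sum(call != "del"))
  var_cols <- which(call == "N")
  variable_positions <- data.frame(column = var_cols,
                                   freq_A = fr["A", var_cols],
                                   freq_C = fr["C", var_cols],
                                   freq_G = fr["G", var_cols],
                                   freq_T = fr["T", var_cols],
                                   freq_gap = fr["-", var_cols],
                                   row.names = NULL)
  structure(list(consensus = consensus,
                 column_map = data.frame(column = seq_len(ncols),
                                         call = unname(call),
                                         consensus_index = consensus_index),
                 variable_positions = variable_positions,
                 threshold = threshold, n_rows = profile$n_rows),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d nt (%d variable, %d deletion columns)%s\n",
              nchar(x$consensus), nrow(x$variable_positions),
              sum(x$column_map$call == "del"),
              if (!is.null(x$ref_map)) ", reference-mapped" else ""))
  invisible(x)
}

#' Map a consensus onto the reference coordinate frame
#'
#' Requires the alignment to contain a reference row. Columns where the
#' reference has a gap but the consensus emits a base (or `N`) become
#' insertion records anchored to the preceding reference position
#' (consecutive such columns are merged into one record); reference
#' positions whose column was a deletion column become deletion records;
#' every other consensus column receives the reference position (reported
#' as a feature-local position via the model).
#'
#' @param result A `consensus_result`.
#' @param aln The `multiple_alignment` the profile was computed from; must
#'   carry a reference row.
#' @param model A `transposon_model` supplying the feature frame.
#' @param feature Feature the alignment reference corresponds to:
#'   `"full"` when the reference row is the whole element, else the
#'   feature name (positions are then feature-local directly).
#' @return The `consensus_result` augmented with `ref_map` (per column:
#'   `ref_pos`, `feature`, `feature_pos`), `insertions`
#'   (`data.frame(anchor_ref_pos, feature, feature_pos, bases)`) and
#'   `deletions` (`data.frame(ref_pos, feature, feature_pos)`), plus
#'   `projected` — the consensus projected onto reference positions
#'   (base/`N`/`-` per reference position).
#' @export
map_to_reference <- function(result, aln, model, feature = "full") {
  if (is.na(aln$reference))
    stop("alignment has no reference row")
  ref_row <- aln$seqs[match(aln$reference, aln$ids)]
  ch <- strsplit(ref_row, "")[[1]]
  if (length(ch) != nrow(result$column_map))
    stop("alignment and consensus result have different column counts")
  is_base <- ch != "-"
  ref_pos <- ifelse(is_base, cumsum(is_base), NA_integer_)
  anchor <- cumsum(is_base)  # preceding reference position (0 before start)
  cm <- result$column_map
  feat_of <- function(p) {
    if (feature == "full") offset_to_feature(model, p)
    else list(feature = feature, position = as.integer(p))
  }
  # per-column feature annotation for reference-aligned columns
  feats <- lapply(seq_along(ch), function(i) {
    if (!is_base[i]) return(list(feature = NA_character_,
                                 position = NA_integer_))
    feat_of(ref_pos[i])
  })
  ref_map <- data.frame(
    column = cm$column,
    ref_pos = as.integer(ref_pos),
    feature = vapply(feats, `[[`, character(1), "feature"),
    feature_pos = vapply(feats, `[[`, integer(1), "position"))
  # insertions: reference-gap columns emitting a base or N
  ins_col <- which(!is_base & cm$call != "del")
  insertions <- data.frame(anchor_ref_pos = integer(), feature = character(),
                           feature_pos = integer(), bases = character())
  if (length(ins_col)) {
    grp <- cumsum(c(1L, as.integer(diff(ins_col) > 1 |
                                     diff(anchor[ins_col]) > 0)))
    pieces <- split(ins_col, grp)
    insertions <- do.call(rbind, lapply(pieces, function(cols) {
      a <- anchor[cols[1]]
      fa <- if (a >= 1) feat_of(a) else list(feature = "full", position = 0L)
      data.frame(anchor_ref_pos = a, feature = fa$feature,
                 feature_pos = fa$position,
                 bases = paste(ifelse(cm$call[cols] == "N", "N",
                                      cm$call[cols]), collapse = ""))
    }))
    rownames(insertions) <- NULL
  }
  # deletions: reference positions in deletion columns
  del_col <- which(is_base & cm$call == "del")
  deletions <- data.frame(ref_pos = integer(), feature = character(),
                          feature_pos = integer())
  if (length(del_col)) {
    fs <- lapply(ref_pos[del_col], feat_of)
    deletions <- data.frame(ref_pos = as.integer(ref_pos[del_col]),
                            feature = vapply(fs, `[[`, character(1),
                                             "feature"),
                            feature_pos = vapply(fs, `[[`, integer(1),
                                                 "position"))
  }
  # consensus projected onto reference positions
  L <- sum(is_base)
  projected <- character(L)
  projected[ref_pos[is_base]] <- ifelse(cm$call[is_base] == "del", "-",
                                        cm$call[is_base])
  result$ref_map <- ref_map
  result$insertions <- insertions
  result$deletions <- deletions
  result$projected <- paste(projected, collapse = "")
  result$feature <- feature
  result
}

#' Consensus projected onto reference positions
#'
#' @param result A reference-mapped `consensus_result`.
#' @return Character string, one symbol (base, `N`, or `-`) per reference
#'   position.
#' @export
projected_consensus <- function(result) {
  if (is.null(result$projected))
    stop("consensus result is not reference-mapped; run map_to_reference()")
  result$projected
}

#' Write the per-column frequency table as TSV
#'
#' @param profile A `column_profile`.
#' @param result Optional `consensus_result` (adds call and reference
#'   position columns; must be reference-mapped for the latter).
#' @param path Output path.
#' @param comment Optional `#` header comment lines.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(profile, path, result = NULL,
                                comment = NULL) {
  df <- data.frame(column = seq_len(ncol(profile$counts)),
                   t(profile$counts),
                   t(round(profile$freqs, 3)))
  names(df) <- c("column", paste0("n_", c("A", "C", "G", "T", "gap")),
                 paste0("freq_", c("A", "C", "G", "T", "gap")))
  if (!is.null(result)) {
    df$call <- result$column_map$call
    if (!is.null(result$ref_map)) {
      df$ref_pos <- result$ref_map$ref_pos
      df$feature <- result$ref_map$feature
      df$feature_pos <- result$ref_map$feature_pos
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
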