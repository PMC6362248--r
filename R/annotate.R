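# Comparison of a reference-mapped consensus against the transposon model:
# one record per difference, with feature context, binding-region flags and
# synonymous/nonsynonymous/frameshift classification of CDS changes.

FEATURE_ORDER <- c("left_itr", "cds", "right_itr", "full")

#' Is a feature-local ITR position inside a transposase binding region?
#'
#' @param model A `transposon_model`.
#' @param feature `"left_itr"` or `"right_itr"`.
#' @param position 1-based position within that ITR.
#' @return `TRUE`/`FALSE`, or `NA` ("unevaluable") when the model has no
#'   binding-region spans configured.
#' @export
classify_binding_region <- function(model, feature, position) {
  stopifnot(feature %in% c("left_itr", "right_itr"))
  if (is.null(model$binding_regions)) return(NA)
  off <- feature_to_offset(model, feature, position)
  br <- model$binding_regions
  br <- br[br$itr == feature, , drop = FALSE]
  any(off >= br$start & off <= br$end)
}

#' Coding effect of a single-nucleotide substitution in the CDS
#'
#' Builds the reference codon around the position (honouring the model's
#' reading-frame offset), substitutes the single base, translates both and
#' compares — the one-substitution-at-a-time convention; compound
#' same-codon changes are classified independently. A position before the
#' frame offset, or in a trailing partial codon, has no codon effect; an
#' `N` substitute is "ambiguous".
#'
#' @param model A `transposon_model`.
#' @param cds_pos 1-based position within the CDS feature.
#' @param ref_base Reference base at the position (checked against the
#'   model).
#' @param new_base Substituted base (or `N`).
#' @return List with `effect` (`"synonymous"`, `"nonsynonymous"`,
#'   `"ambiguous"` or `"none"`), `aa_ref`, `aa_new`, `codon_ref`,
#'   `codon_new` and `codon_position` (1/2/3, `NA` when untranslated).
#' @export
codon_effect <- function(model, cds_pos, ref_base, new_base) {
  cds_seq <- model_feature_seq(model, "cds")
  cds_len <- nchar(cds_seq)
  stopifnot(cds_pos >= 1, cds_pos <= cds_len)
  model_base <- substr(cds_seq, cds_pos, cds_pos)
  if (!is.na(ref_base) && nzchar(ref_base) && model_base != ref_base)
    warning(sprintf("model CDS has %s at position %d, not %s",
                    model_base, cds_pos, ref_base))
  adj <- cds_pos - model$cds_frame
  if (adj < 1)
    return(list(effect = "none", aa_ref = NA, aa_new = NA,
                codon_ref = NA, codon_new = NA, codon_position = NA))
  codon_idx <- (adj - 1) %/% 3
  codon_position <- (adj - 1) %% 3 + 1
  cstart <- model$cds_frame + codon_idx * 3 + 1
  if (cstart + 2 > cds_len)  # trailing partial codon
    return(list(effect = "none", aa_ref = NA, aa_new = NA,
                codon_ref = NA, codon_new = NA,
                codon_position = codon_position))
  codon_ref <- substr(cds_seq, cstart, cstart + 2)
  codon_new <- codon_ref
  substr(codon_new, codon_position, codon_position) <- new_base
  if (new_base == "N" || grepl("[^ACGT]", codon_new))
    return(list(effect = "ambiguous", aa_ref = translate_cds(codon_ref),
                aa_new = "X", codon_ref = codon_ref, codon_new = codon_new,
                codon_position = codon_position))
  aa_ref <- translate_cds(codon_ref)
  aa_new <- translate_cds(codon_new)
  list(effect = if (aa_ref == aa_new) "synonymous" else "nonsynonymous",
       aa_ref = aa_ref, aa_new = aa_new, codon_ref = codon_ref,
       codon_new = codon_new, codon_position = codon_position)
}

#' Coding effect of an insertion or deletion
#'
#' @param indel_len Inserted/deleted length in nt.
#' @param in_cds Does the indel fall inside the CDS?
#' @return `"frameshift"` (length not a codon multiple, in the CDS),
#'   `"in-frame"` (codon multiple, in the CDS) or `"none"`.
#' @export
indel_effect <- function(indel_len, in_cds) {
  if (!in_cds) return("none")
  if (indel_len %% 3 != 0) "frameshift" else "in-frame"
}

.empty_diff <- function() {
  data.frame(feature = character(), position = integer(), kind = character(),
             ref = character(), alt = character(),
             in_binding_region = logical(), codon_position = integer(),
             effect = character(), freq_A = numeric(), freq_C = numeric(),
             freq_G = numeric(), freq_T = numeric(), freq_gap = numeric(),
             stringsAsFactors = FALSE)
}

#' List all differences between a consensus and the reference model
#'
#' One record per reference position where the (reference-mapped) consensus
#' differs — substitutions, variable (`N`) positions with their frequency
#' vectors, deletions — plus the insertion records. ITR records carry the
#' binding-region flag (NA when spans are unconfigured); CDS substitutions
#' carry the codon effect; CDS indels the frame effect. Sorted by feature
#' (left ITR, CDS, right ITR, unannotated) then position.
#'
#' @param result A reference-mapped `consensus_result` (see
#'   [map_to_reference()]).
#' @param model A `transposon_model`.
#' @return `data.frame` of difference records.
#' @export
diff_consensus <- function(result, model) {
  proj <- projected_consensus(result)
  feature <- if (is.null(result$feature)) "full" else result$feature
  ref_seq <- if (feature == "full") model$sequence
             else model_feature_seq(model, feature)
  if (nchar(proj) != nchar(ref_seq))
    stop("projected consensus and reference lengths differ")
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  feat_of <- function(p) {
    if (feature == "full") offset_to_feature(model, p)
    else list(feature = feature, position = as.integer(p))
  }
  br_flag <- function(fe, po) {
    if (fe %in% c("left_itr", "right_itr"))
      classify_binding_region(model, fe, po)
    else NA
  }
  # frequency vectors for variable columns, keyed by reference position
  var_freq <- NULL
  if (nrow(result$variable_positions)) {
    vp <- merge(result$variable_positions, result$ref_map, by = "column")
    var_freq <- vp[!is.na(vp$ref_pos), , drop = FALSE]
  }
  pc <- strsplit(proj, "")[[1]]
  rc <- strsplit(ref_seq, "")[[1]]
  for (p in which(pc != rc)) {
    fp <- feat_of(p)
    kind <- if (pc[p] == "N") "variable" else if (pc[p] == "-") "deletion"
            else "substitution"
    eff <- "none"; cp <- NA_integer_
    if (fp$feature == "cds" && kind != "deletion") {
      ce <- codon_effect(model, fp$position, rc[p],
                         if (kind == "variable") "N" else pc[p])
      eff <- ce$effect
      if (eff == "synonymous") eff <- paste0("synonymous(", ce$aa_ref, ")")
      if (eff == "nonsynonymous")
        eff <- paste0("nonsynonymous(", ce$aa_ref, ">", ce$aa_new, ")")
      cp <- ce$codon_position
    } else if (fp$feature == "cds" && kind == "deletion") {
      eff <- indel_effect(1, TRUE)
    }
    fq <- c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    if (kind == "variable" && !is.null(var_freq)) {
      m <- var_freq[var_freq$ref_pos == p, , drop = FALSE]
      if (nrow(m))
        fq <- as.numeric(m[1, c("freq_A", "freq_C", "freq_G", "freq_T",
                                "freq_gap")])
    }
    add(data.frame(feature = fp$feature, position = fp$position,
                   kind = kind, ref = rc[p],
                   alt = if (kind == "deletion") "-" else pc[p],
                   in_binding_region = br_flag(fp$feature, fp$position),
                   codon_position = cp, effect = eff,
                   freq_A = fq[1], freq_C = fq[2], freq_G = fq[3],
                   freq_T = fq[4], freq_gap = fq[5],
                   stringsAsFactors = FALSE))
  }
  if (nrow(result$insertions)) {
    for (i in seq_len(nrow(result$insertions))) {
      ins <- result$insertions[i, ]
      in_cds <- ins$feature == "cds"
      add(data.frame(feature = ins$feature, position = ins$feature_pos,
                     kind = "insertion", ref = "-", alt = ins$bases,
                     in_binding_region = br_flag(ins$feature,
                                                 ins$feature_pos),
                     codon_position = NA_integer_,
                     effect = indel_effect(nchar(ins$bases), in_cds),
                     freq_A = NA_real_, freq_C = NA_real_, freq_G = NA_real_,
                     freq_T = NA_real_, freq_gap = NA_real_,
                     stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) return(.empty_diff())
  out <- do.call(rbind, rows)
  out <- out[order(match(out$feature, FEATURE_ORDER), out$position,
                   out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a difference report
#'
#' Deterministic human-readable summary (per-feature counts, binding-region
#' and codon-effect breakdowns) plus a machine-readable TSV that re-parses
#' to the identical record list via [read_diff_tsv()].
#'
#' @param records Difference records from [diff_consensus()].
#' @param path Optional TSV output path.
#' @param metadata Optional named character vector echoed into the report
#'   header (e.g. run parameters, config hash).
#' @return Character vector of report lines, invisibly if `path` given.
#' @export
render_report <- function(records, path = NULL, metadata = NULL) {
  lines <- "Consensus vs reference differences"
  if (!is.null(metadata))
    lines <- c(lines, paste0("  ", names(metadata), ": ", metadata))
  if (!nrow(records)) {
    lines <- c(lines, "  zero differences: consensus identical to reference")
  } else {
    for (f in intersect(FEATURE_ORDER, unique(records$feature))) {
      r <- records[records$feature == f, , drop = FALSE]
      lines <- c(lines, sprintf(
        "  %s: %d difference(s) [%d substitution, %d variable, %d insertion, %d deletion]",
        f, nrow(r), sum(r$kind == "substitution"),
        sum(r$kind == "variable"), sum(r$kind == "insertion"),
        sum(r$kind == "deletion")))
      if (f %in% c("left_itr", "right_itr")) {
        n_in <- sum(r$in_binding_region %in% TRUE)
        n_un <- sum(is.na(r$in_binding_region))
        lines <- c(lines, sprintf(
          "    binding regions: %d inside, %d outside%s", n_in,
          nrow(r) - n_in - n_un,
          if (n_un) sprintf(", %d unevaluable", n_un) else ""))
      }
      if (f == "cds") {
        lines <- c(lines, sprintf(
          "    codon effects: %d synonymous, %d nonsynonymous, %d frameshift, %d ambiguous",
          sum(grepl("^synonymous", r$effect)),
          sum(grepl("^nonsynonymous", r$effect)),
          sum(r$effect == "frameshift"), sum(r$effect == "ambiguous")))
      }
      for (i in seq_len(nrow(r))) {
        lines <- c(lines, sprintf("    pos %d: %s %s>%s%s", r$position[i],
                                  r$kind[i], r$ref[i], r$alt[i],
                                  if (r$effect[i] != "none")
                                    paste0(" [", r$effect[i], "]") else ""))
      }
    }
  }
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(metadata))
      writeLines(paste0("# ", names(metadata), "=", metadata), con)
    utils::write.table(records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(lines))
  }
  lines
}

#' Read back a difference TSV
#' @param path TSV written by [render_report()].
#' @return Difference record `data.frame`.
#' @export
read_diff_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c(feature = "character",
                                         position = "integer",
                                         kind = "character",
                                         ref = "character",
                                         alt = "character",
                                         in_binding_region = "logical",
                                         codon_position = "integer",
                                         effect = "character",
                                         freq_A = "numeric",
                                         freq_C = "numeric",
                                         freq_G = "numeric",
                                         freq_T = "numeric",
                                         freq_gap = "numeric"),
                          stringsAsFactors = FALSE)
  df
}
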