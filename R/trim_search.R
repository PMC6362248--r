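# Two-step "transposase trim" search: a CDS hit is accepted only if both
# ITRs are detectable in its 500-nt genomic flanks, which excludes ITR-less
# transposase-homologous genes.

#' Trim-search parameters
#'
#' @param flank Flank extension in nt on each side of a CDS hit.
#' @param itr_min_identity Minimum identity of an ITR detection in a flank.
#' @param itr_min_coverage Minimum fraction of the ITR query that must be
#'   covered by the detection.
#' @return Object of class `trim_params`.
#' @export
trim_params <- function(flank = 500, itr_min_identity = 0.75,
                        itr_min_coverage = 0.80) {
  stopifnot(flank > 0, itr_min_identity >= 0, itr_min_identity <= 1,
            itr_min_coverage >= 0, itr_min_coverage <= 1)
  structure(list(flank = as.integer(flank),
                 itr_min_identity = itr_min_identity,
                 itr_min_coverage = itr_min_coverage),
            class = "trim_params")
}

# Best qualifying ITR detection in a query-oriented flank sequence, or NULL.
# The flank is already in query orientation, so only plus-strand detections
# qualify.
.detect_itr <- function(flank_seq, itr_query, params, search) {
  if (nchar(flank_seq) < search$word_size) return(NULL)
  h <- find_hits(c(flank = flank_seq), itr_query, search)
  h <- h[h$strand == "+", , drop = FALSE]
  if (!nrow(h)) return(NULL)
  cov <- (h$qend - h$qstart + 1) / nchar(itr_query)
  h <- h[h$identity >= params$itr_min_identity &
           cov >= params$itr_min_coverage, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(-h$score, h$start), , drop = FALSE]
  h[1, ]
}

#' Two-step trim search
#'
#' For each transposase (CDS) hit, the genomic flank upstream in query
#' orientation is searched for the left ITR and the downstream flank for
#' the right ITR; the hit is retained only if both are detected at the
#' configured identity and coverage. Flanks are clipped at chromosome ends;
#' a hit whose flank is fully clipped is dropped (the repeat cannot be
#' detected there). Retained hits carry the detected element span
#' (left-ITR start through right-ITR end) and the detected ITR spans;
#' sequence duplicates are removed afterwards.
#'
#' Flank assignment is strand-aware: for a minus-strand CDS hit the
#' query-upstream flank lies genomically downstream, so retention is
#' strand-invariant.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param cds_hits Hits produced with the model CDS as query.
#' @param model A `transposon_model`.
#' @param params A [trim_params()] object.
#' @param search A [search_params()] object used for the flank searches.
#' @return Retained hit data frame with extra columns `element_start`,
#'   `element_end`, `litr_start`, `litr_end`, `ritr_start`, `ritr_end`.
#' @export
trim_search <- function(genome, cds_hits, model, params = trim_params(),
                        search = search_params()) {
  left_q <- model_feature_seq(model, "left_itr")
  right_q <- model_feature_seq(model, "right_itr")
  out <- list()
  if (nrow(cds_hits)) for (i in seq_len(nrow(cds_hits))) {
    h <- cds_hits[i, ]
    clen <- nchar(genome[[h$chrom]])
    us <- max(1L, h$start - params$flank)        # genomic upstream flank
    ue <- h$start - 1L
    ds <- h$end + 1L                             # genomic downstream flank
    de <- min(clen, h$end + params$flank)
    up_len <- ue - us + 1L
    down_len <- de - ds + 1L
    if (up_len <= 0 || down_len <= 0) next
    gup <- substr(genome[[h$chrom]], us, ue)
    gdown <- substr(genome[[h$chrom]], ds, de)
    if (h$strand == "+") {
      qup <- gup; qdown <- gdown
    } else {
      qup <- unname(reverse_complement(gdown))
      qdown <- unname(reverse_complement(gup))
    }
    dl <- .detect_itr(qup, left_q, params, search)
    if (is.null(dl)) next
    dr <- .detect_itr(qdown, right_q, params, search)
    if (is.null(dr)) next
    # flank-local detection coords -> genomic coords
    if (h$strand == "+") {
      litr <- c(us + dl$start - 1L, us + dl$end - 1L)
      ritr <- c(ds + dr$start - 1L, ds + dr$end - 1L)
    } else {
      # query-upstream flank is the genomic downstream one, reverse mapped
      # (position p in the flank corresponds to genomic de - p + 1), and
      # symmetrically for the query-downstream flank
      litr <- c(de - dl$end + 1L, de - dl$start + 1L)
      ritr <- c(ue - dr$end + 1L, ue - dr$start + 1L)
    }
    h$litr_start <- min(litr); h$litr_end <- max(litr)
    h$ritr_start <- min(ritr); h$ritr_end <- max(ritr)
    h$element_start <- min(h$litr_start, h$ritr_start)
    h$element_end <- max(h$litr_end, h$ritr_end)
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) {
    e <- empty_hits()
    e$litr_start <- integer(); e$litr_end <- integer()
    e$ritr_start <- integer(); e$ritr_end <- integer()
    e$element_start <- integer(); e$element_end <- integer()
    return(e)
  }
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  # duplicate removal on the full element sequence
  el <- ret
  el$start <- ret$element_start
  el$end <- ret$element_end
  seqs <- extract_hit_sequences(genome, el)
  ord <- order(ret$chrom, ret$element_start, ret$strand)
  first <- ord[!duplicated(seqs[ord])]
  ret <- ret[sort(first), , drop = FALSE]
  rownames(ret) <- NULL
  ret
}

#' Assemble full-length elements from trim-search hits
#'
#' Extracts, in query orientation, the genomic span from the detected left
#' ITR start through the detected right ITR end for every retained hit.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param retained_hits Output of [trim_search()].
#' @param model A `transposon_model` (unused except for API symmetry; may
#'   be `NULL`).
#' @return Named character vector of element sequences, ids
#'   `chrom:start-end(strand)` over the element span.
#' @export
assemble_full_elements <- function(genome, retained_hits, model = NULL) {
  if (!nrow(retained_hits)) return(character())
  el <- retained_hits
  ov <- pmin(el$litr_end, el$ritr_end) - pmax(el$litr_start, el$ritr_start) + 1
  if (any(ov > 0)) {
    bad <- which(ov > 0)[1]
    stop("overlapping ITR detections for element ",
         sprintf("%s:%d-%d(%s)", el$chrom[bad], el$element_start[bad],
                 el$element_end[bad], el$strand[bad]))
  }
  el$start <- el$element_start
  el$end <- el$element_end
  extract_hit_sequences(genome, el)
}
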