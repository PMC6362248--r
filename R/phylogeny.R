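# Distance-based phylogenetics for the recovered element set: p-distance /
# Kimura two-parameter distances with pairwise gap deletion, neighbor
# joining with deterministic tie-breaking, and column-resampling bootstrap
# support.

#' Pairwise distances from an alignment
#'
#' Sites where either sequence has a gap or ambiguity are excluded per pair
#' (pairwise deletion), which preserves partially truncated copies. The
#' Kimura two-parameter (K2P) correction — the equal-frequency
#' simplification of HKY85 — is the default; the raw p-distance is also
#' available. Saturated pairs (logarithm of a non-positive argument) and
#' pairs with no comparable columns raise errors naming the pair.
#'
#' @param aln A `multiple_alignment` (>= 3 rows).
#' @param correction `"K2P"` or `"p"`.
#' @return Symmetric numeric matrix of distances (substitutions/site) with
#'   row/column names from the alignment ids.
#' @export
pairwise_distances <- function(aln, correction = c("K2P", "p")) {
  correction <- match.arg(correction)
  n <- length(aln$ids)
  if (n < 3) stop("need at least 3 rows for a distance matrix")
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  is_transition <- function(a, b) (a == "A" & b == "G") |
    (a == "G" & b == "A") | (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0)
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     aln$ids[i], aln$ids[j]))
      a <- mat[i, comp]; b <- mat[j, comp]
      diffs <- a != b
      if (correction == "p") {
        dij <- sum(diffs) / m
      } else {
        P <- sum(diffs & is_transition(a, b)) / m
        Q <- (sum(diffs) / m) - P
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        if (w1 <= 0 || w2 <= 0)
          stop(sprintf("K2P distance saturated between '%s' and '%s'",
                       aln$ids[i], aln$ids[j]))
        dij <- -0.5 * log(w1 * sqrt(w2))
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration with deterministic tie-breaking (the
#' lowest-index pair among equal Q criteria) and negative branch lengths
#' clamped to zero with the deficit shifted to the sister branch (their sum
#' is preserved). Exact on additive matrices.
#'
#' @param dm Symmetric distance matrix with row/column names (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 3)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(dm)))
  # quote ids unsafe for newick
  safe <- gsub("[(),:;\\s']", "_", ids, perl = TRUE)
  labs <- safe
  d <- dm
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    c(li, lj)
  }
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair (i < j, row-major) among minima
    min_q <- min(q)
    cand <- which(q - min_q <= 1e-12 * max(1, abs(min_q)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    l <- clamp(li, lj)
    new_lab <- sprintf("(%s:%s,%s:%s)", labs[i], fmt(l[1]), labs[j],
                       fmt(l[2]))
    others <- setdiff(seq_len(n), c(i, j))
    new_d <- 0.5 * (d[i, others] + d[j, others] - d[i, j])
    d2 <- d[others, others, drop = FALSE]
    d2 <- rbind(cbind(d2, new_d), c(new_d, 0))
    labs <- c(labs[others], new_lab)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  # final three-taxon star
  li <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lj <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lk <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", labs[1], fmt(li), labs[2], fmt(lj),
                 labs[3], fmt(lk))
  tr <- ape::read.tree(text = nwk)
  # restore original labels
  tr$tip.label <- ids[match(tr$tip.label, safe)]
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Columns are resampled with replacement `n_replicates` times under the
#' given seed; the support of each internal branch of the full-data NJ tree
#' is the fraction of replicate trees containing the same bipartition.
#' Supports are stored as node labels.
#'
#' @param aln A `multiple_alignment`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param correction Distance correction passed to
#'   [pairwise_distances()].
#' @return `ape::phylo` tree with node labels holding support fractions.
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed,
                              correction = "K2P") {
  stopifnot(n_replicates >= 1, !missing(seed))
  main <- neighbor_joining(pairwise_distances(aln, correction))
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  set.seed(as.integer(seed))
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    rmat <- mat[, cols, drop = FALSE]
    raln <- multiple_alignment(aln$ids,
                               apply(rmat, 1, paste, collapse = ""),
                               reference = aln$reference)
    reps[[b]] <- tryCatch(
      neighbor_joining(pairwise_distances(raln, correction)),
      error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  if (!length(reps)) {
    main$node.label <- rep("", main$Nnode)
    return(main)
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- sprintf("%.3f", counts / length(reps))
  main
}

#' Write a tree in newick format
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
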