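# End-to-end orchestration of the mining pipeline: search -> length filter
# -> (trim verification) -> dedupe -> extract -> align -> curate ->
# frequencies -> consensus -> reference mapping -> differences -> tree.
# Every stage writes its artifact so long genome-scale runs are resumable
# and reruns are byte-reproducible.

#' Pipeline run configuration
#'
#' @param genome Named character vector of chromosome sequences, or a FASTA
#'   path.
#' @param model A `transposon_model` or path to a model YAML.
#' @param strategy One of `"full"` (whole-element query), `"left_itr"`,
#'   `"right_itr"`, `"cds"` (single-feature query) or `"trim"` (CDS query
#'   verified by ITR detection in 500-nt flanks).
#' @param out_dir Output directory for stage artifacts.
#' @param search A [search_params()] object.
#' @param trim A [trim_params()] object.
#' @param max_length_dev Length-filter tolerance (strict beyond it).
#' @param min_identity Optional identity filter after the length filter
#'   (0 disables).
#' @param max_gap_fraction Curation threshold on per-row gap fraction.
#' @param consensus_threshold Majority threshold for the consensus call.
#' @param engine Alignment engine, `"builtin"` or `"mafft"`.
#' @param mafft_mode Optional MAFFT mode override.
#' @param tree Build an NJ tree of the curated alignment.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param psl_in Optional path to precomputed external-search hits in PSL
#'   format, used instead of the built-in search.
#' @param seed Seed for the stochastic stages (bootstrap).
#' @return Object of class `run_config`.
#' @export
run_config <- function(genome, model, strategy = c("full", "left_itr",
                                                   "right_itr", "cds",
                                                   "trim"),
                       out_dir, search = search_params(),
                       trim = trim_params(), max_length_dev = 0.10,
                       min_identity = 0, max_gap_fraction = 0.10,
                       consensus_threshold = 0.60,
                       engine = c("builtin", "mafft"), mafft_mode = NULL,
                       tree = TRUE, bootstrap = 0, psl_in = NULL,
                       seed = 1) {
  strategy <- match.arg(strategy)
  engine <- match.arg(engine)
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)))
    genome <- read_fasta(genome)
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "transposon_model"))
  structure(list(genome = genome, model = model, strategy = strategy,
                 out_dir = out_dir, search = search, trim = trim,
                 max_length_dev = max_length_dev,
                 min_identity = min_identity,
                 max_gap_fraction = max_gap_fraction,
                 consensus_threshold = consensus_threshold,
                 engine = engine, mafft_mode = mafft_mode, tree = tree,
                 bootstrap = as.integer(bootstrap), psl_in = psl_in,
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic hash of the configuration (genome hashed by content; the
# output directory does not influence results and is excluded so reruns
# into different directories compare equal)
config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  x$genome <- paste(names(x$genome),
                    vapply(x$genome, nchar, integer(1)),
                    substr(x$genome, 1, 1000), collapse = "|")
  txt <- paste(deparse(x[order(names(x))]), collapse = "\n")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' Run the full mining pipeline
#'
#' Executes every stage for the configured strategy and writes all
#' intermediates under `out_dir`: `hits.psl`, `hits.tsv`, `elements.fasta`,
#' `alignment.fasta`, `frequencies.tsv`, `consensus.fasta`,
#' `differences.tsv`, `report.txt`, `tree.nwk` (when requested),
#' `run_log.tsv` and `manifest.tsv`. The run log holds one row per stage
#' with input/output counts and parameters; wall times are reported on the
#' console only, so reruns with an identical configuration produce
#' byte-identical artifacts. Any stage error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return List with the per-stage objects (`hits`, `elements`,
#'   `alignment`, `profile`, `consensus`, `differences`, `tree`), the
#'   stage-count `log`, the `config_hash` and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  genome <- config$genome
  model <- config$model
  log <- list()
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, n_in, n_out, params = "") {
    log[[length(log) + 1L]] <<- data.frame(stage = name, n_in = n_in,
                                           n_out = n_out, params = params,
                                           stringsAsFactors = FALSE)
    message(sprintf("[%s] %d -> %d (%.1fs)", name, n_in, n_out,
                    proc.time()[["elapsed"]] - t_all))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  apath <- function(f) file.path(config$out_dir, f)
  paths <- c(hits_psl = apath("hits.psl"), hits_tsv = apath("hits.tsv"),
             elements = apath("elements.fasta"),
             alignment = apath("alignment.fasta"),
             frequencies = apath("frequencies.tsv"),
             consensus = apath("consensus.fasta"),
             differences = apath("differences.tsv"),
             report = apath("report.txt"), tree = apath("tree.nwk"),
             run_log = apath("run_log.tsv"), manifest = apath("manifest.tsv"))

  feature <- switch(config$strategy, full = "full", trim = "cds",
                    config$strategy)
  query <- model_feature_seq(model, feature)

  hits <- run_stage("search", {
    if (!is.null(config$psl_in)) read_psl(config$psl_in)
    else find_hits(genome, query, config$search)
  })
  stage("search", length(genome), nrow(hits),
        sprintf("strategy=%s query_len=%d", config$strategy, nchar(query)))
  write_psl(hits, paths["hits_psl"], query_name = feature,
            query_len = nchar(query), genome = genome)
  write_hits_tsv(hits, paths["hits_tsv"], comment = paste0("config=", hash))

  n0 <- nrow(hits)
  hits <- run_stage("length_filter",
                    filter_by_length(hits, nchar(query),
                                     config$max_length_dev))
  stage("length_filter", n0, nrow(hits),
        sprintf("max_dev=%g", config$max_length_dev))

  if (config$min_identity > 0) {
    n0 <- nrow(hits)
    hits <- run_stage("identity_filter",
                      filter_by_identity(hits, config$min_identity))
    stage("identity_filter", n0, nrow(hits),
          sprintf("min_identity=%g", config$min_identity))
  }

  if (config$strategy == "trim") {
    n0 <- nrow(hits)
    retained <- run_stage("trim_search",
                          trim_search(genome, hits, model, config$trim,
                                      config$search))
    stage("trim_search", n0, nrow(retained),
          sprintf("flank=%d itr_min_identity=%g itr_min_coverage=%g",
                  config$trim$flank, config$trim$itr_min_identity,
                  config$trim$itr_min_coverage))
    elements <- run_stage("extract",
                          assemble_full_elements(genome, retained, model))
    hits <- retained
    ref_feature <- "full"
    reference <- model$sequence
  } else {
    n0 <- nrow(hits)
    hits <- run_stage("dedupe", dedupe_hits(hits, genome))
    stage("dedupe", n0, nrow(hits), "")
    elements <- run_stage("extract", extract_hit_sequences(genome, hits))
    ref_feature <- feature
    reference <- query
  }
  stage("extract", nrow(hits), length(elements), "")
  if (length(elements) < 2)
    stop("pipeline stage 'extract' failed: fewer than 2 element sequences; nothing to align")
  write_fasta(elements, paths["elements"])

  aln <- run_stage("align",
                   align_sequences(elements, reference = reference,
                                   engine = config$engine,
                                   mafft_mode = config$mafft_mode))
  stage("align", length(elements), length(aln$ids),
        sprintf("engine=%s", config$engine))

  aln <- run_stage("curate", curate_alignment(aln, config$max_gap_fraction))
  stage("curate", length(elements) + 1L, length(aln$ids),
        sprintf("max_gap_fraction=%g dropped=%d",
                config$max_gap_fraction, length(attr(aln, "dropped"))))
  write_alignment(aln, paths["alignment"])

  profile <- run_stage("frequencies", column_frequencies(aln))
  cons <- run_stage("consensus",
                    call_consensus(profile, config$consensus_threshold))
  cons <- run_stage("map", map_to_reference(cons, aln, model,
                                            feature = ref_feature))
  stage("consensus", profile$n_rows, nchar(cons$consensus),
        sprintf("threshold=%g", config$consensus_threshold))
  write_frequency_tsv(profile, paths["frequencies"], result = cons,
                      comment = paste0("config=", hash))
  write_fasta(c(consensus = cons$consensus,
                consensus_on_reference = projected_consensus(cons)),
              paths["consensus"])

  diffs <- run_stage("diff", diff_consensus(cons, model))
  stage("diff", nchar(cons$consensus), nrow(diffs), "")
  report <- render_report(diffs, path = paths["differences"],
                          metadata = c(config = hash,
                                       strategy = config$strategy))
  writeLines(report, paths["report"])

  tree <- NULL
  if (isTRUE(config$tree) && length(aln$ids) >= 3) {
    tree <- run_stage("tree", {
      if (config$bootstrap > 0)
        bootstrap_support(aln, config$bootstrap, seed = config$seed)
      else neighbor_joining(pairwise_distances(aln))
    })
    stage("tree", length(aln$ids), ape::Ntip(tree),
          sprintf("bootstrap=%d seed=%d", config$bootstrap, config$seed))
    write_newick(tree, paths["tree"])
  }

  log_df <- do.call(rbind, log)
  con <- file(paths["run_log"], "w")
  writeLines(paste0("# config=", hash), con)
  utils::write.table(log_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  arts <- paths[file.exists(paths)]
  manifest <- data.frame(artifact = names(arts), file = basename(arts),
                         config = hash, stringsAsFactors = FALSE)
  utils::write.table(manifest, paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(config = config, config_hash = hash, hits = hits,
       elements = elements, alignment = aln, profile = profile,
       consensus = cons, differences = diffs, tree = tree, log = log_df,
       paths = paths)
}

#' Compare consensus sequences from several strategies
#'
#' All results must be mapped to the same reference model; agreement is the
#' per-position identity of the reference-projected consensuses (`N`
#' compared as `N`, deletions as `-`).
#'
#' @param results List of reference-mapped `consensus_result` objects
#'   (named, >= 2).
#' @return List with `agreement` (pairwise percent-identity matrix),
#'   `overall` (mean off-diagonal agreement, percent) and `n_positions`.
#' @export
compare_consensuses <- function(results) {
  stopifnot(is.list(results), length(results) >= 2)
  proj <- lapply(results, projected_consensus)
  lens <- vapply(proj, nchar, integer(1))
  if (length(unique(lens)) != 1)
    stop("consensuses map to references of different lengths: ",
         paste(lens, collapse = ", "))
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("consensus", seq_along(results))
  k <- length(proj)
  agree <- matrix(100, k, k, dimnames = list(nm, nm))
  chs <- lapply(proj, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- 100 * mean(chs[[i]] == chs[[j]])
      agree[i, j] <- agree[j, i] <- a
    }
  }
  list(agreement = agree,
       overall = mean(agree[upper.tri(agree)]),
       n_positions = lens[1])
}
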