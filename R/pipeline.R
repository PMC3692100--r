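#' Configuration for a full pipeline run
#'
#' @param pattern_path path to the phyletic pattern file.
#' @param pattern_format \code{"fasta01"} or \code{"tsv"}.
#' @param tree_path optional Newick tree path; NJ inference when NULL.
#' @param annotations_path optional annotation TSV path.
#' @param tier model tier.
#' @param K gamma category count.
#' @param correction unobservable-data correction.
#' @param alpha network significance level in (0, 1].
#' @param n_null_sims null simulation count (>= 100).
#' @param seed integer seed, recorded in the output manifest.
#' @param out_dir output directory.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(pattern_path, pattern_format = "fasta01",
                       tree_path = NULL, annotations_path = NULL,
                       tier = "gamma_invariant", K = 4L,
                       correction = "no_absent", alpha = 0.01,
                       n_null_sims = 1000L, seed = 1L, out_dir = ".") {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (n_null_sims < 100L) stop("n_null_sims must be >= 100")
  structure(list(pattern_path = pattern_path,
                 pattern_format = pattern_format,
                 tree_path = tree_path,
                 annotations_path = annotations_path,
                 tier = tier, K = as.integer(K), correction = correction,
                 alpha = alpha, n_null_sims = as.integer(n_null_sims),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full coevolution pipeline
#'
#' Reads the inputs, infers a tree by neighbor joining when none is given,
#' fits the gain/loss model, maps events, scores and tests all pairs,
#' builds the network, and writes: fitted parameters (JSON), event table
#' (TSV), pair table (TSV), network (SIF, GraphML, TSV), summary tables and
#' a manifest recording inputs, effective configuration, seed and all
#' artifact files. Reruns with the same configuration are bit-identical.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return the manifest (also written as \code{manifest.json}), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- "read inputs"
  manifest <- list(config = unclass(cfg), files = list())
  res <- tryCatch({
    pattern <- read_pattern(cfg$pattern_path, cfg$pattern_format)
    if (!is.null(cfg$annotations_path)) {
      pattern$annotations <- validate_annotations(
        read_annotations(cfg$annotations_path), pattern$characters)
    }
    tree <- if (is.null(cfg$tree_path)) NULL else {
      tr <- ape::read.tree(cfg$tree_path)
      if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
      tr
    }
    stage <- "coevolution analysis"
    cv <- coevolve(pattern, tree = tree, tier = cfg$tier,
                   correction = cfg$correction, alpha = cfg$alpha,
                   n_null_sims = cfg$n_null_sims, seed = cfg$seed,
                   K = cfg$K)
    stage <- "write outputs"
    p <- cv$fit$params
    jsonlite::write_json(
      list(tier = p$model_tier, gain = p$g, loss = p$l,
           gain_loss_ratio = p$g / p$l, alpha_shape = p$alpha,
           p_inv = p$p_inv, K = p$K,
           log_likelihood = cv$fit$fit$log_likelihood,
           correction = cfg$correction, branch_scale = cv$fit$branch_scale),
      out("fitted_params.json"), auto_unbox = TRUE, digits = NA)
    ape::write.tree(cv$tree, out("tree.nwk"))
    write_event_table(cv$em, out("events.tsv"))
    utils::write.table(cv$pairs, out("pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    export_network(cv$network, out("network.sif"), "sif")
    export_network(cv$network, out("network.graphml"), "graphml")
    export_network(cv$network, out("network.tsv"), "tsv")
    summ <- network_summaries(cv$network)
    utils::write.table(summ$degrees, out("degree_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$significance_histogram,
                       out("significance_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = names(summ$components),
                 component = as.integer(summ$components)),
      out("components.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$tree <- if (cv$tree_inferred) "inferred (NJ)" else "user-supplied"
    manifest$n_taxa <- length(pattern$taxa)
    manifest$n_characters <- length(pattern$characters)
    manifest$n_pairs_tested <- nrow(cv$pairs)
    manifest$n_edges <- nrow(cv$network$edges)
    manifest$excluded_characters <- as.list(cv$excluded)
    manifest$files <- list(
      fitted_params = "fitted_params.json", tree = "tree.nwk",
      events = "events.tsv", pairs = "pairs.tsv",
      network_sif = "network.sif", network_graphml = "network.graphml",
      network_tsv = "network.tsv",
      degree_distribution = "degree_distribution.tsv",
      significance_histogram = "significance_histogram.tsv",
      components = "components.tsv")
    manifest
  }, error = function(e) {
    manifest$error <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(res)
}
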