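# Coevolution scoring: Pearson correlation of per-branch gain/loss event
# expectation vectors, with empirical significance from parametric
# simulations stratified by event abundance and BH FDR control.

#' Event vector of one character
#'
#' Concatenation of the per-branch expected gain counts followed by the
#' per-branch expected loss counts, in fixed branch order; length is twice
#' the number of non-root nodes.
#'
#' @param em an \code{event_expectations}.
#' @param site character id.
#' @return named numeric vector \code{gain:<branch>..., loss:<branch>...}.
#' @export
event_vector <- function(em, site) {
  if (!site %in% em$sites) stop("unknown site: ", site)
  stats::setNames(c(em$e_gain[site, ], em$e_loss[site, ]),
                  c(paste0("gain:", em$branches), paste0("loss:", em$branches)))
}

event_vector_matrix <- function(em) {
  cbind(em$e_gain, em$e_loss)
}

#' Coevolution score of two event vectors
#'
#' Pearson correlation of the two characters' concatenated per-branch gain
#' and loss expectation vectors. Undefined (error) for constant vectors;
#' such characters are excluded from pair testing upstream.
#'
#' @param v1,v2 equal-length event vectors.
#' @return correlation in [-1, 1].
#' @export
coevolution_score <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("event vectors differ in length")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant event vector: score undefined")
  }
  stats::cor(v1, v2)
}

site_event_totals <- function(em) {
  rowSums(em$e_gain) + rowSums(em$e_loss)
}

# Assign abundance bins given quantile edges of the real data's totals.
abundance_bins <- function(totals, edges) {
  b <- findInterval(totals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

stratum_key <- function(b1, b2) {
  paste(pmin(b1, b2), pmax(b1, b2), sep = "_")
}

# Pool the scores of a stratum with ever-wider Chebyshev neighborhoods in
# bin space until the floor is reached.
pool_stratum <- function(scores_by_key, b1, b2, n_bins, floor) {
  pooled <- numeric(0)
  for (r in 0:(n_bins - 1L)) {
    keys <- character(0)
    for (i in max(1L, b1 - r):min(n_bins, b1 + r)) {
      for (j in max(1L, b2 - r):min(n_bins, b2 + r)) {
        if (max(abs(i - b1), abs(j - b2)) == r) {
          keys <- c(keys, stratum_key(i, j))
        }
      }
    }
    add <- unlist(scores_by_key[unique(keys)], use.names = FALSE)
    pooled <- c(pooled, add)
    if (length(pooled) >= floor) break
  }
  sort(pooled)
}

#' Simulate a stratified null score bank
#'
#' Simulates \code{n_sims} independent characters under the fitted model on
#' the same tree, maps their events, and scores every disjoint pair of
#' simulated characters. Null scores are stratified by the per-character
#' total expected event count of the two pair members, using quantile bins
#' of the real data's totals: the null distribution of the correlation
#' depends strongly on event abundance, so unmatched nulls would
#' miscalibrate p-values. Strata holding fewer than \code{stratum_floor}
#' samples are merged with their nearest bins.
#'
#' @param tree rooted \code{phylo} tree.
#' @param mix fitted \code{rate_mixture}.
#' @param em \code{event_expectations} of the real data (defines the
#'   abundance bin edges).
#' @param n_sims number of simulated null characters (>= 2).
#' @param seed integer seed; same seed gives an identical bank.
#' @param n_bins number of abundance quantile bins per axis (default 5).
#' @param stratum_floor minimal null sample count per (merged) stratum.
#' @param condition_observable simulate null characters conditioned on
#'   being observable (present somewhere). Default \code{TRUE}: real input
#'   never contains an all-absent character, so exchangeable nulls must be
#'   conditioned the same way.
#' @return object of class \code{null_score_bank} with the bin edges and a
#'   sorted pooled null-score vector per stratum.
#' @export
simulate_null_scores <- function(tree, mix, em, n_sims = 1000L, seed = 1L,
                                 n_bins = 5L, stratum_floor = 100L,
                                 condition_observable = TRUE) {
  if (n_sims < 2L) stop("n_sims must be >= 2")
  real_totals <- site_event_totals(em)
  edges <- unique(stats::quantile(real_totals,
                                  probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE))
  if (length(edges) < 2L) edges <- c(min(real_totals) - 1, max(real_totals) + 1)
  n_bins_eff <- length(edges) - 1L
  sim <- simulate_independent_sites(tree, mix, n_sims, seed = seed,
                                    prefix = "NULL",
                                    condition_observable = condition_observable)
  nfit <- corrected_log_likelihood(tree, sim$pattern, mix, "none")
  nem <- map_events(tree, sim$pattern, mix, nfit)
  V <- event_vector_matrix(nem)
  keep <- apply(V, 1L, stats::sd) > 0
  V <- V[keep, , drop = FALSE]
  if (nrow(V) < 2L) {
    stop("n_sims too small: fewer than 2 non-constant null characters; ",
         "increase n_sims")
  }
  totals <- site_event_totals(nem)[keep]
  bins <- abundance_bins(totals, edges)
  # all disjoint null pair correlations, computed block-wise so banks of
  # many thousands of simulated characters stay within memory
  Vn <- V - rowMeans(V)
  Vn <- Vn / sqrt(rowSums(Vn^2))
  nk <- nrow(Vn)
  acc <- list()
  blk <- 2000L
  for (s in seq(1L, nk - 1L, by = blk)) {
    rows <- s:min(s + blk - 1L, nk - 1L)
    Cb <- tcrossprod(Vn[rows, , drop = FALSE], Vn)
    n_per_row <- nk - rows
    idx_i <- rep.int(rows, n_per_row)
    idx_j <- unlist(lapply(rows, function(i) (i + 1L):nk), use.names = FALSE)
    sc <- Cb[cbind(rep.int(seq_along(rows), n_per_row), idx_j)]
    part <- split(sc, stratum_key(bins[idx_i], bins[idx_j]))
    for (k in names(part)) acc[[k]] <- c(acc[[k]], list(part[[k]]))
  }
  by_key <- lapply(acc, function(x) unlist(x, use.names = FALSE))
  pools <- list()
  for (b1 in seq_len(n_bins_eff)) {
    for (b2 in b1:n_bins_eff) {
      key <- stratum_key(b1, b2)
      pools[[key]] <- pool_stratum(by_key, b1, b2, n_bins_eff, stratum_floor)
      if (length(pools[[key]]) < stratum_floor) {
        stop("n_sims too small for stratum floor ", stratum_floor,
             "; increase n_sims")
      }
    }
  }
  structure(list(bin_edges = edges, n_bins = n_bins_eff, pools = pools,
                 n_sims = n_sims, seed = seed,
                 stratum_floor = stratum_floor),
            class = "null_score_bank")
}

#' Empirical p-value of a coevolution score
#'
#' Add-one empirical p: \code{p = (1 + #\{null >= score\}) / (N + 1)} within
#' the pair's abundance stratum; ties count toward the numerator, so p is
#' never 0 and is a valid finite-sample p-value. The smallest attainable p
#' is \code{1 / (N + 1)} (the add-one floor).
#'
#' @param score coevolution score.
#' @param bank a \code{null_score_bank}.
#' @param stratum integer vector \code{c(bin1, bin2)}.
#' @return empirical p in (0, 1].
#' @export
pair_pvalue <- function(score, bank, stratum) {
  pool <- bank$pools[[stratum_key(stratum[[1L]], stratum[[2L]])]]
  if (is.null(pool)) stop("unknown stratum")
  n <- length(pool)
  (1 + (n - findInterval(score, pool, left.open = TRUE))) / (n + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment (monotone-enforced, capped at 1).
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Score and test all character pairs
#'
#' Pearson coevolution scores for every pair of non-constant event vectors,
#' empirical p-values from the stratified null bank and BH q-values across
#' all tested pairs.
#'
#' @param em \code{event_expectations} of the real data.
#' @param bank matching \code{null_score_bank}.
#' @return list: \code{pairs} data frame (id1 < id2, score, pvalue, qvalue)
#'   and \code{excluded} (ids of characters with constant event vectors).
#' @export
score_all_pairs <- function(em, bank) {
  V <- event_vector_matrix(em)
  sds <- apply(V, 1L, stats::sd)
  excluded <- em$sites[sds == 0]
  if (length(excluded)) {
    warning(length(excluded),
            " character(s) with constant event vectors excluded: ",
            paste(utils::head(excluded, 5L), collapse = ", "))
  }
  keep <- sds > 0
  ids <- em$sites[keep]
  if (length(ids) < 2L) stop("fewer than 2 testable characters")
  V <- V[keep, , drop = FALSE]
  totals <- site_event_totals(em)[keep]
  bins <- abundance_bins(totals, bank$bin_edges)
  C <- stats::cor(t(V))
  ut <- upper.tri(C)
  i <- row(C)[ut]
  j <- col(C)[ut]
  score <- C[ut]
  key <- stratum_key(bins[i], bins[j])
  p <- numeric(length(score))
  for (k in unique(key)) {
    sel <- key == k
    pool <- bank$pools[[k]]
    n <- length(pool)
    p[sel] <- (1 + (n - findInterval(score[sel], pool, left.open = TRUE))) /
      (n + 1)
  }
  ida <- ids[i]
  idb <- ids[j]
  pairs <- data.frame(id1 = pmin(ida, idb), id2 = pmax(ida, idb),
                      score = score, pvalue = p,
                      qvalue = bh_adjust(p), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$id1, pairs$id2), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, excluded = excluded)
}

#' Build the coevolution network
#'
#' Nodes are the tested characters; edges are the pairs whose q-value is at
#' or below the significance level \code{alpha}.
#'
#' @param pairs data frame from \code{\link{score_all_pairs}}.
#' @param alpha significance level in (0, 1] (default 0.01).
#' @param annotations optional named character vector of node annotations.
#' @return object of class \code{coevolution_network}.
#' @export
build_network <- function(pairs, alpha = 0.01, annotations = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  nodes <- sort(unique(c(pairs$id1, pairs$id2)))
  ann <- rep(NA_character_, length(nodes))
  if (!is.null(annotations)) {
    hit <- match(nodes, names(annotations))
    ann[!is.na(hit)] <- annotations[hit[!is.na(hit)]]
  }
  edges <- pairs[pairs$qvalue <= alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(id = nodes, annotation = ann,
                                    stringsAsFactors = FALSE),
                 edges = edges, alpha = alpha),
            class = "coevolution_network")
}

#' @export
print.coevolution_network <- function(x, ...) {
  cat("Coevolution network:", nrow(x$nodes), "characters,",
      nrow(x$edges), "interactions at q <=", x$alpha, "\n")
  invisible(x)
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("id1", "id2", "score", "pvalue", "qvalue"), drop = FALSE],
    directed = FALSE, vertices = net$nodes)
}

#' Summaries of a coevolution network
#'
#' Degree distribution per node, a histogram of edge significance levels in
#' fixed p-value bins, and connected components.
#'
#' @param net a \code{coevolution_network}.
#' @param breaks p-value bin boundaries.
#' @return list: \code{degrees} (id, degree), \code{significance_histogram}
#'   (bin, count; counts sum to the edge count), \code{components}
#'   (named node -> component-id vector).
#' @export
network_summaries <- function(net,
                              breaks = c(0, 1e-5, 1e-4, 1e-3, 0.005, 0.01,
                                         0.05, 1)) {
  g <- network_igraph(net)
  deg <- igraph::degree(g)
  h <- graphics::hist(net$edges$pvalue, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  comp <- igraph::components(g)$membership
  list(degrees = data.frame(id = names(deg), degree = as.integer(deg),
                            stringsAsFactors = FALSE),
       significance_histogram = data.frame(
         bin = paste0("(", breaks[-length(breaks)], ",", breaks[-1L], "]"),
         count = h$counts),
       components = comp)
}

#' Classify taxa by the joint state of a character pair
#'
#' For projecting a pair's phyletic patterns onto the tree: each taxon is
#' labelled by presence in both ("11"), absence in both ("00"), presence in
#' the first only ("10") or in the second only ("01").
#'
#' @param pattern a \code{\link{phyletic_pattern}}.
#' @param id1,id2 character ids.
#' @return named character vector of labels, one per taxon.
#' @export
pair_state_categories <- function(pattern, id1, id2) {
  if (!id1 %in% pattern$characters || !id2 %in% pattern$characters) {
    stop("unknown character id")
  }
  x <- pattern$matrix[, id1]
  y <- pattern$matrix[, id2]
  stats::setNames(paste0(x, y), pattern$taxa)
}

#' Write the pair-projection files for tree viewers
#'
#' Writes a taxon-to-category TSV and an annotated Newick in which each
#' leaf label carries its \code{11/00/10/01} category suffix.
#'
#' @inheritParams pair_state_categories
#' @param tree rooted \code{phylo} tree over the pattern's taxa.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.nwk}.
#' @return invisibly, the category vector.
#' @export
write_pair_projection <- function(pattern, id1, id2, tree, prefix) {
  cats <- pair_state_categories(pattern, id1, id2)
  utils::write.table(
    data.frame(taxon = names(cats), category = cats),
    paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- tree
  tr$tip.label <- paste0(tr$tip.label, "|", cats[tr$tip.label])
  ape::write.tree(tr, paste0(prefix, ".nwk"))
  invisible(cats)
}

#' Full coevolution analysis of a phyletic pattern
#'
#' Fits the gain/loss model (inferring a neighbor-joining tree first when
#' none is given), maps expected events onto branches, scores all character
#' pairs, assigns simulation-based significance with abundance-matched null
#' strata, adjusts by Benjamini-Hochberg, and builds the network at level
#' \code{alpha}.
#'
#' @param pattern a \code{\link{phyletic_pattern}}.
#' @param tree optional rooted \code{phylo} tree; inferred by NJ if NULL.
#' @param tier model tier.
#' @param correction unobservable-data correction.
#' @param alpha network significance level (default 0.01).
#' @param n_null_sims number of simulated null characters (default 1000).
#' @param seed integer seed for the null simulations.
#' @param n_bins abundance bins per axis for null matching.
#' @param stratum_floor minimal null samples per stratum.
#' @param K gamma category count.
#' @return list: \code{pairs}, \code{network}, \code{excluded}, \code{fit}
#'   (from \code{\link{fit_model}}), \code{em}, \code{bank},
#'   \code{tree} and \code{tree_inferred}.
#' @export
coevolve <- function(pattern, tree = NULL,
                     tier = c("gamma_invariant", "single", "mixture"),
                     correction = c("no_absent", "none"),
                     alpha = 0.01, n_null_sims = 1000L, seed = 1L,
                     n_bins = 5L, stratum_floor = 100L, K = 4L) {
  tier <- match.arg(tier)
  correction <- match.arg(correction)
  tree_inferred <- is.null(tree)
  if (tree_inferred) tree <- infer_tree(pattern)
  fit <- fit_model(tree, pattern, tier = tier, correction = correction, K = K)
  em <- map_events(fit$tree, pattern, fit$mix, fit$fit)
  bank <- simulate_null_scores(fit$tree, fit$mix, em, n_sims = n_null_sims,
                               seed = seed, n_bins = n_bins,
                               stratum_floor = stratum_floor)
  scored <- score_all_pairs(em, bank)
  net <- build_network(scored$pairs, alpha = alpha,
                       annotations = pattern$annotations)
  list(pairs = scored$pairs, network = net, excluded = scored$excluded,
       fit = fit, em = em, bank = bank, tree = fit$tree,
       tree_inferred = tree_inferred)
}
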