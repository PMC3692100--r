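#' Stationary frequencies of a phyletic pattern by counting
#'
#' Estimates the stationary presence/absence frequencies of the two-state
#' chain as the observed fractions of 1s and 0s over all matrix cells.
#'
#' @param p a \code{\link{phyletic_pattern}}.
#' @param fallback if \code{TRUE}, an all-constant matrix returns
#'   \code{c(0.5, 0.5)} instead of an error.
#' @return numeric vector \code{c(pi0, pi1)} summing to 1.
#' @export
two_state_frequencies <- function(p, fallback = FALSE) {
  stopifnot(inherits(p, "phyletic_pattern"))
  pi1 <- mean(p$matrix)
  if (pi1 %in% c(0, 1)) {
    if (fallback) {
      return(c(pi0 = 0.5, pi1 = 0.5))
    }
    stop("degenerate frequencies: matrix is all-", pi1,
         " (use fallback = TRUE for (0.5, 0.5))")
  }
  c(pi0 = 1 - pi1, pi1 = pi1)
}

#' Maximum-likelihood two-state distance between two 0/1 sequences
#'
#' Distance between two binary sequences under the reversible two-state
#' chain with given stationary frequencies, in expected events per
#' character (the chain is scaled so one unit of time produces one expected
#' event at stationarity). The likelihood maximised over the divergence t is
#' prod_sites sum_s pi_s P_{s,x}(t/2) P_{s,y}(t/2); by reversibility this
#' equals prod_sites pi_x P_{x,y}(t), so the t/2-per-branch split is
#' immaterial. Distances are capped at \code{cap} (saturation guard, same
#' role as the infinite Jukes-Cantor distance).
#'
#' @param x,y equal-length 0/1 vectors.
#' @param freqs stationary frequencies \code{c(pi0, pi1)}.
#' @param cap maximal representable distance (default 10).
#' @return non-negative distance; \code{cap} with a warning at saturation.
#' @export
ml_pairwise_distance <- function(x, y, freqs, cap = 10) {
  if (length(x) == 0L || length(x) != length(y)) {
    stop("sequences must be non-empty and of equal length")
  }
  pi0 <- freqs[[1L]]
  pi1 <- freqs[[2L]]
  # flux-normalised rates: g + l chosen so 2*pi0*pi1*lambda... i.e. rates
  # g = pi1/(2 pi0 pi1), l = pi0/(2 pi0 pi1) give one expected event per unit t
  g <- 1 / (2 * pi0)
  l <- 1 / (2 * pi1)
  n <- c(n00 = sum(x == 0 & y == 0), n01 = sum(x == 0 & y == 1),
         n10 = sum(x == 1 & y == 0), n11 = sum(x == 1 & y == 1))
  if (n[["n01"]] + n[["n10"]] == 0L) {
    return(0)
  }
  nll <- function(t) {
    P <- transition_probability(g, l, t)
    -(n[["n00"]] * log(pi0 * P[1L, 1L]) + n[["n01"]] * log(pi0 * P[1L, 2L]) +
        n[["n10"]] * log(pi1 * P[2L, 1L]) + n[["n11"]] * log(pi1 * P[2L, 2L]))
  }
  opt <- stats::optimize(nll, interval = c(1e-9, cap), tol = 1e-8)
  t_hat <- opt$minimum
  # saturation: likelihood still improving at the cap
  if (t_hat > cap - 1e-4 || nll(cap) <= opt$objective) {
    warning("distance saturated at cap = ", cap)
    return(cap)
  }
  t_hat
}

#' All pairwise ML two-state distances of a phyletic pattern
#'
#' @param p a \code{\link{phyletic_pattern}}.
#' @param freqs stationary frequencies; counted from the pattern when
#'   missing (falling back to (0.5, 0.5) for constant matrices).
#' @param cap saturation bound passed to \code{\link{ml_pairwise_distance}}.
#' @return symmetric distance matrix with taxa as dimnames.
#' @export
ml_distance_matrix <- function(p, freqs = NULL, cap = 10) {
  stopifnot(inherits(p, "phyletic_pattern"))
  if (is.null(freqs)) freqs <- two_state_frequencies(p, fallback = TRUE)
  n <- length(p$taxa)
  d <- matrix(0, n, n, dimnames = list(p$taxa, p$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- suppressWarnings(
        ml_pairwise_distance(p$matrix[i, ], p$matrix[j, ], freqs, cap = cap))
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative estimated branch lengths
#' are clamped to zero and the unrooted result is rooted at the midpoint of
#' the longest leaf-to-leaf path. Under the reversible model the likelihood
#' is root-invariant, so rooting only fixes the direction in which mapped
#' events are reported per branch.
#'
#' @param dm symmetric distance matrix with taxon dimnames (or a
#'   \code{dist}).
#' @return rooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must carry taxon names")
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  validate_phylogeny(tr)
  tr
}

#' Estimate a phylogeny from a phyletic pattern
#'
#' ML two-state pairwise distances followed by neighbor joining; used when
#' the user supplies no tree.
#'
#' @inheritParams ml_distance_matrix
#' @return rooted \code{phylo} tree with branch lengths in expected events
#'   per character.
#' @export
infer_tree <- function(p, freqs = NULL, cap = 10) {
  neighbor_joining(ml_distance_matrix(p, freqs = freqs, cap = cap))
}

#' Validate a rooted phylogeny for use with a phyletic pattern
#'
#' @param tree a \code{phylo} object.
#' @param taxa optional taxon set that the leaf labels must equal.
#' @return the tree, invisibly.
#' @export
validate_phylogeny <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  # a basal multifurcation is accepted: the basal node serves as the root
  if (length(setdiff(tree$edge[, 1L], tree$edge[, 2L])) != 1L) {
    stop("tree must have a single root node")
  }
  if (!is.null(taxa) && !setequal(tree$tip.label, taxa)) {
    stop("tree leaf set does not match pattern taxa")
  }
  invisible(tree)
}

# Internal: preprocessed rooted tree for the likelihood/mapping engines.
# Branches are identified by their child node: tip label for terminal
# branches, "N<node>" for internal ones (root -> tip direction).
tree_prep <- function(tree, taxa = NULL) {
  validate_phylogeny(tree, taxa)
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  child <- tr$edge[, 2L]
  list(tree = tr,
       n_tip = n_tip,
       root = tr$edge[nrow(tr$edge), 1L],
       parent = tr$edge[, 1L],
       child = child,
       blen = tr$edge.length,
       branch_id = ifelse(child <= n_tip, tr$tip.label[child],
                          paste0("N", child)))
}

#' Branch identifiers of a rooted tree
#'
#' Branches are named by their child node (root-to-tip direction): the leaf
#' label for terminal branches and \code{N<node-number>} for internal ones,
#' in the tree's postorder edge order.
#'
#' @param tree rooted \code{phylo} tree.
#' @return character vector of branch ids, one per non-root node.
#' @export
branch_ids <- function(tree) {
  tree_prep(tree)$branch_id
}
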