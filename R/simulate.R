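# Character simulators along a tree. Histories are simulated by drawing the
# full jump chain on every branch (not just endpoint states), so actual
# event counts are recorded and can serve as an oracle for the analytic
# stochastic mapping.

# Evolve a vector of sites along one branch; g, l and t may be per-site.
# Returns end states and the number of gains/losses per site.
simulate_branch_states <- function(state, g, l, t) {
  n <- length(state)
  if (length(t) == 1L) t <- rep(t, n)
  gains <- integer(n)
  losses <- integer(n)
  t_rem <- t
  active <- rep(TRUE, n)
  while (any(active)) {
    rate <- ifelse(state == 0L, g, l)
    active <- active & rate > 0
    idx <- which(active)
    if (!length(idx)) break
    wait <- stats::rexp(length(idx), rate[idx])
    flips <- idx[wait < t_rem[idx]]
    active[idx[wait >= t_rem[idx]]] <- FALSE
    if (length(flips)) {
      t_rem[flips] <- t_rem[flips] - wait[wait < t_rem[idx]]
      was0 <- state[flips] == 0L
      gains[flips] <- gains[flips] + was0
      losses[flips] <- losses[flips] + !was0
      state[flips] <- 1L - state[flips]
    }
  }
  list(state = state, gains = gains, losses = losses)
}

#' Simulate independent characters along a tree
#'
#' Each character draws a rate category from the mixture, draws its root
#' state from that category's stationary frequencies, and evolves down the
#' tree by simulating the full jump process on every branch (so the actual
#' gain and loss events are recorded, not just endpoint states).
#'
#' @param tree rooted \code{phylo} tree.
#' @param mix a \code{rate_mixture}.
#' @param n_sites number of characters (>= 1).
#' @param seed integer seed; same seed gives an identical result.
#' @param prefix character-id prefix.
#' @param condition_observable reject and resimulate characters that end up
#'   absent from every taxon. An all-absent character can never be observed,
#'   so data meant to emulate real input (and null simulations compared
#'   against it under the \code{no_absent} likelihood correction) must be
#'   conditioned this way; the conditioned simulator's density is exactly
#'   the corrected likelihood. Default \code{FALSE} (the raw process).
#' @return object of class \code{simulated_sites}: \code{pattern}
#'   (a \code{\link{phyletic_pattern}}), per-site/per-branch true event-count
#'   matrices \code{gain_events} and \code{loss_events} (branches ordered as
#'   \code{\link{branch_ids}}), \code{categories} (drawn category index per
#'   site) and \code{root_states}.
#' @export
simulate_independent_sites <- function(tree, mix, n_sites, seed = NULL,
                                       prefix = "S",
                                       condition_observable = FALSE) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tp <- tree_prep(tree)
  n_node <- max(tp$parent)
  n_edge <- length(tp$child)

  sim_batch <- function(n) {
    cat_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    g <- mix$gain[cat_idx]
    l <- mix$loss[cat_idx]
    states <- matrix(NA_integer_, n_node, n)
    root_states <- stats::rbinom(n, 1L, mix$pi1[cat_idx])
    states[tp$root, ] <- root_states
    gain_ev <- matrix(0L, n, n_edge)
    loss_ev <- matrix(0L, n, n_edge)
    for (e in rev(seq_len(n_edge))) {   # preorder: parents before children
      sim <- simulate_branch_states(states[tp$parent[e], ], g, l, tp$blen[e])
      states[tp$child[e], ] <- sim$state
      gain_ev[, e] <- sim$gains
      loss_ev[, e] <- sim$losses
    }
    list(tips = t(states[seq_len(tp$n_tip), , drop = FALSE]),
         gain_ev = gain_ev, loss_ev = loss_ev,
         cat_idx = cat_idx, root_states = root_states)
  }

  b <- sim_batch(n_sites)
  if (condition_observable) {
    for (round in 1:100) {
      absent <- which(rowSums(b$tips) == 0L)
      if (!length(absent)) break
      if (round == 100L) {
        stop("could not draw observable characters; ",
             "is presence essentially impossible under this model?")
      }
      r <- sim_batch(length(absent))
      b$tips[absent, ] <- r$tips
      b$gain_ev[absent, ] <- r$gain_ev
      b$loss_ev[absent, ] <- r$loss_ev
      b$cat_idx[absent] <- r$cat_idx
      b$root_states[absent] <- r$root_states
    }
  }
  ids <- sprintf("%s%04d", prefix, seq_len(n_sites))
  m <- t(b$tips)   # taxa x sites
  rownames(m) <- tp$tree$tip.label
  colnames(m) <- ids
  gain_ev <- b$gain_ev
  loss_ev <- b$loss_ev
  dimnames(gain_ev) <- dimnames(loss_ev) <- list(ids, tp$branch_id)
  structure(list(pattern = phyletic_pattern(m),
                 gain_events = gain_ev, loss_events = loss_ev,
                 categories = b$cat_idx, root_states = b$root_states,
                 tree = tp$tree),
            class = "simulated_sites")
}

#' Joint generator of a coevolving character pair
#'
#' 4-state rate matrix over the pair states \{00, 01, 10, 11\} built from
#' the two marginal two-state generators: only one character changes at a
#' time; every rate entering a concordant state (00 or 11) is multiplied by
#' the dependency factor \code{d} and every rate leaving a concordant state
#' is divided by \code{d}. At \code{d = 1} the generator is exactly the
#' Kronecker sum of the marginals, i.e. the two characters evolve
#' independently.
#'
#' @param g1,l1 gain and loss rates of the first character.
#' @param g2,l2 gain and loss rates of the second character.
#' @param d dependency factor (>= 1).
#' @return 4x4 generator with dimnames \code{c("00","01","10","11")} and
#'   zero row sums.
#' @export
pair_generator <- function(g1, l1, g2, l2, d = 1) {
  if (d < 1) stop("dependency factor d must be >= 1 (anti-coevolution is out of scope)")
  st <- c("00", "01", "10", "11")
  Q <- matrix(0, 4L, 4L, dimnames = list(st, st))
  concordant <- c(TRUE, FALSE, FALSE, TRUE)
  for (i in 1:4) {
    x1 <- (i - 1L) %/% 2L
    x2 <- (i - 1L) %% 2L
    # flip character 1
    j <- (1L - x1) * 2L + x2 + 1L
    q <- if (x1 == 0L) g1 else l1
    if (concordant[j]) q <- q * d
    if (concordant[i]) q <- q / d
    Q[i, j] <- q
    # flip character 2
    j <- x1 * 2L + (1L - x2) + 1L
    q <- if (x2 == 0L) g2 else l2
    if (concordant[j]) q <- q * d
    if (concordant[i]) q <- q / d
    Q[i, j] <- q
  }
  diag(Q) <- -rowSums(Q)
  Q
}

pair_stationary <- function(Q) {
  A <- rbind(t(Q)[-4L, , drop = FALSE], rep(1, 4L))
  pi <- solve(A, c(0, 0, 0, 1))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Simulate one coevolving character pair along a tree
#'
#' The pair evolves as a single 4-state chain under the concordance-biased
#' joint generator of \code{\link{pair_generator}}. Each character draws its
#' own marginal rate category from the mixture; the root pair state is drawn
#' from the joint chain's stationary distribution and the full jump process
#' is simulated on every branch.
#'
#' @param tree rooted \code{phylo} tree.
#' @param mix a \code{rate_mixture}.
#' @param d dependency factor (>= 1).
#' @param seed optional integer seed.
#' @param condition_observable reject draws in which either character ends
#'   up absent from every taxon (see
#'   \code{\link{simulate_independent_sites}}).
#' @return list: \code{columns} (taxa x 2 matrix of tip states),
#'   per-character event totals \code{gains} and \code{losses}.
#' @export
simulate_coevolving_pair <- function(tree, mix, d = 16, seed = NULL,
                                     condition_observable = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (condition_observable) {
    for (try in 1:10000) {
      out <- simulate_coevolving_pair(tree, mix, d = d,
                                      condition_observable = FALSE)
      if (all(colSums(out$columns) > 0L)) return(out)
    }
    stop("could not draw an observable coevolving pair")
  }
  tp <- tree_prep(tree)
  cats <- sample.int(nrow(mix), 2L, replace = TRUE, prob = mix$weight)
  Q <- pair_generator(mix$gain[cats[1L]], mix$loss[cats[1L]],
                      mix$gain[cats[2L]], mix$loss[cats[2L]], d)
  pi <- pair_stationary(Q)
  n_node <- max(tp$parent)
  states <- integer(n_node)   # pair state index 1..4
  states[tp$root] <- sample.int(4L, 1L, prob = pi)
  gains <- c(0L, 0L)
  losses <- c(0L, 0L)
  n_edge <- length(tp$child)
  for (e in rev(seq_len(n_edge))) {
    s <- states[tp$parent[e]]
    t_rem <- tp$blen[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      wait <- stats::rexp(1L, rate)
      if (wait >= t_rem) break
      t_rem <- t_rem - wait
      s_new <- sample.int(4L, 1L, prob = pmax(Q[s, ], 0))
      x_old <- c((s - 1L) %/% 2L, (s - 1L) %% 2L)
      x_new <- c((s_new - 1L) %/% 2L, (s_new - 1L) %% 2L)
      ch <- which(x_old != x_new)
      if (x_new[ch] == 1L) gains[ch] <- gains[ch] + 1L
      else losses[ch] <- losses[ch] + 1L
      s <- s_new
    }
    states[tp$child[e]] <- s
  }
  tips <- states[seq_len(tp$n_tip)]
  cols <- cbind((tips - 1L) %/% 2L, (tips - 1L) %% 2L)
  rownames(cols) <- tp$tree$tip.label
  list(columns = cols, gains = gains, losses = losses, categories = cats)
}

#' Build a benchmark data set of coevolving and independent characters
#'
#' Simulates \code{n_pairs_coev} coevolving pairs (dependency factor
#' \code{d}) and \code{n_indep} independent characters on the same tree and
#' mixture, shuffles the column order, and records which character-id pairs
#' are truly coevolving. Each character belongs to at most one true pair.
#'
#' @param tree rooted \code{phylo} tree.
#' @param mix a \code{rate_mixture}.
#' @param n_pairs_coev number of coevolving pairs (>= 0).
#' @param n_indep number of independent characters (>= 0).
#' @param d dependency factor.
#' @param seed integer seed.
#' @param condition_observable reject all-absent characters (default
#'   \code{TRUE}: a benchmark emulating real input contains no character
#'   that is absent everywhere, matching the \code{no_absent} likelihood
#'   correction).
#' @return object of class \code{benchmark_set}: \code{pattern},
#'   \code{tree}, \code{truth} (data frame id1 < id2) and \code{params}.
#' @export
make_benchmark <- function(tree, mix, n_pairs_coev, n_indep, d = 16,
                           seed = 1L, condition_observable = TRUE) {
  if (n_pairs_coev < 0L || n_indep < 0L) stop("counts must be >= 0")
  n_total <- 2L * n_pairs_coev + n_indep
  if (n_total < 1L) stop("benchmark must contain at least one character")
  set.seed(seed)
  tp <- tree_prep(tree)
  cols <- matrix(NA_integer_, tp$n_tip, n_total)
  rownames(cols) <- tp$tree$tip.label
  truth_idx <- matrix(integer(0), ncol = 2L)
  k <- 0L
  if (n_pairs_coev > 0L) {
    for (p in seq_len(n_pairs_coev)) {
      pair <- simulate_coevolving_pair(
        tree, mix, d = d, condition_observable = condition_observable)
      cols[, k + 1L] <- pair$columns[rownames(cols), 1L]
      cols[, k + 2L] <- pair$columns[rownames(cols), 2L]
      truth_idx <- rbind(truth_idx, c(k + 1L, k + 2L))
      k <- k + 2L
    }
  }
  if (n_indep > 0L) {
    sim <- simulate_independent_sites(
      tree, mix, n_indep, condition_observable = condition_observable)
    cols[, k + seq_len(n_indep)] <- sim$pattern$matrix[rownames(cols), ,
                                                       drop = FALSE]
  }
  perm <- sample.int(n_total)
  ids <- sprintf("S%04d", seq_len(n_total))
  m <- cols[, perm, drop = FALSE]
  colnames(m) <- ids
  # position of original column j after shuffling
  pos <- match(seq_len(n_total), perm)
  truth <- if (nrow(truth_idx)) {
    a <- ids[pos[truth_idx[, 1L]]]
    b <- ids[pos[truth_idx[, 2L]]]
    data.frame(id1 = pmin(a, b), id2 = pmax(a, b),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id1 = character(0), id2 = character(0))
  }
  structure(list(pattern = phyletic_pattern(m), tree = tp$tree,
                 truth = truth,
                 params = list(n_pairs_coev = n_pairs_coev,
                               n_indep = n_indep, d = d, seed = seed,
                               condition_observable = condition_observable)),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("Benchmark set:", length(x$pattern$characters), "characters (",
      nrow(x$truth), "coevolving pairs, d =", x$params$d, ") on",
      length(x$tree$tip.label), "taxa\n")
  invisible(x)
}
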