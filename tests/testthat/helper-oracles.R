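# Independent oracles and fixture builders used across the test files.

# Exhaustive site likelihood: sum over all interior-state assignments of
# pi(root) * prod_edges P(parent -> child). Independent of the pruning code.
enum_site_likelihood <- function(tree, column, mix) {
  nt <- length(tree$tip.label)
  interior <- sort(unique(tree$edge[, 1L]))
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  total <- 0
  for (c in seq_len(nrow(mix))) {
    g <- mix$gain[c]
    l <- mix$loss[c]
    pic <- c(mix$pi0[c], mix$pi1[c])
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      if (g + l > 0) transition_probability(g, l, tree$edge.length[e]) else diag(2)
    })
    Lc <- 0
    n_int <- length(interior)
    for (code in 0:(2^n_int - 1L)) {
      st <- integer(max(tree$edge))
      st[seq_len(nt)] <- column[tree$tip.label]
      st[interior] <- bitwAnd(bitwShiftR(code, seq_len(n_int) - 1L), 1L)
      pr <- pic[st[root] + 1L]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * Ps[[e]][st[tree$edge[e, 1L]] + 1L, st[tree$edge[e, 2L]] + 1L]
      }
      Lc <- Lc + pr
    }
    total <- total + mix$weight[c] * Lc
  }
  total
}

# Monte-Carlo trajectory sampler for conditional branch event counts, by
# uniformization (Poisson number of candidate jumps, thinned walk) -- a
# different algorithm from both the analytic integral and the package's
# exponential-waiting-time simulator.
mc_branch_trajectories <- function(g, l, t, n, start) {
  lam <- max(g, l) * 1.5 + 0.1
  b01 <- g / lam
  b10 <- l / lam
  N <- stats::rpois(n, lam * t)
  state <- rep.int(as.integer(start), n)
  gains <- integer(n)
  losses <- integer(n)
  if (max(N) > 0) {
    for (k in seq_len(max(N))) {
      act <- which(N >= k)
      u <- stats::runif(length(act))
      s <- state[act]
      flip <- ifelse(s == 0L, u < b01, u < b10)
      gi <- act[flip & s == 0L]
      li <- act[flip & s == 1L]
      gains[gi] <- gains[gi] + 1L
      losses[li] <- losses[li] + 1L
      idx <- act[flip]
      state[idx] <- 1L - state[idx]
    }
  }
  data.frame(end = state, gains = gains, losses = losses)
}

# Conditional MC means and standard errors per endpoint state.
mc_conditional_expectations <- function(g, l, t, start, end, n) {
  sim <- mc_branch_trajectories(g, l, t, n, start)
  sel <- sim$end == end
  if (sum(sel) < 50L) stop("too few accepted trajectories")
  list(gain = mean(sim$gains[sel]),
       gain_se = stats::sd(sim$gains[sel]) / sqrt(sum(sel)),
       loss = mean(sim$losses[sel]),
       loss_se = stats::sd(sim$losses[sel]) / sqrt(sum(sel)),
       n_accept = sum(sel))
}

# Dense grid search of the two-sequence likelihood over t.
grid_ml_distance <- function(x, y, freqs, cap = 10, step = 1e-4) {
  pi0 <- freqs[[1L]]
  pi1 <- freqs[[2L]]
  g <- 1 / (2 * pi0)
  l <- 1 / (2 * pi1)
  ts <- seq(step, cap, by = step)
  lam <- g + l
  e <- exp(-lam * ts)
  P00 <- pi0 + pi1 * e
  P01 <- pi1 * (1 - e)
  P10 <- pi0 * (1 - e)
  P11 <- pi1 + pi0 * e
  n00 <- sum(x == 0 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n11 <- sum(x == 1 & y == 1)
  ll <- n00 * log(pi0 * P00) + n01 * log(pi0 * P01) +
    n10 * log(pi1 * P10) + n11 * log(pi1 * P11)
  ts[which.max(ll)]
}

# Random rooted tree with branch lengths, scaled to a given total length.
random_tree <- function(n_taxa, tree_length = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- phangorn::midpoint(ape::rtree(n_taxa))
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * tree_length
  tr
}

# Small random 0/1 pattern over a taxon set.
random_pattern <- function(taxa, n_chars, p1 = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rbinom(length(taxa) * n_chars, 1L, p1),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  phyletic_pattern(m)
}

single_mix <- function(g = 1, l = 1, normalize = FALSE) {
  build_rate_mixture(gain_loss_params(g, l, "single"), normalize = normalize)
}
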