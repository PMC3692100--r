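# Analytic stochastic mapping for the two-state gain/loss chain.
#
# The chain has eigenvalues 0 and -(g+l), so P_xy(s) = pi_y + (d_xy - pi_y)
# e^{-(g+l)s} and the expected number of i->j transitions on a branch of
# length t conditional on endpoint states (a, b) has a closed form:
#   E[N_ij | a,b] = q_ij / P_ab(t) * Int_0^t P_ai(s) P_jb(t-s) ds
# with the integral evaluated analytically below (expm1 keeps the small
# (g+l)t regime accurate without a separate series branch).

#' Expected gain and loss events on one branch given its endpoint states
#'
#' Posterior expected numbers of 0->1 (gain) and 1->0 (loss) transitions
#' over a branch of length \code{t}, conditional on the states at its two
#' ends, under the two-state chain with gain rate \code{g} and loss rate
#' \code{l}.
#'
#' @param g,l gain and loss rates (>= 0). Both 0 means no events.
#' @param t branch length (>= 0).
#' @param state_start,state_end endpoint states in \{0, 1\}.
#' @return named vector \code{c(gain, loss)} of conditional expectations.
#' @export
branch_conditional_expectations <- function(g, l, t, state_start, state_end) {
  if (t < 0) stop("negative branch length")
  if (!state_start %in% c(0, 1) || !state_end %in% c(0, 1)) {
    stop("endpoint states must be 0 or 1")
  }
  if (g == 0 && l == 0) {
    if (state_start != state_end) stop("impossible endpoint pair: zero rates")
    return(c(gain = 0, loss = 0))
  }
  lam <- g + l
  pii <- c(l, g) / lam
  P <- transition_probability(g, l, t)
  a <- state_start + 1L
  b <- state_end + 1L
  pab <- P[a, b]
  if (pab <= 0) {
    stop("impossible endpoint pair: P(", state_start, " -> ", state_end,
         ") = 0 at t = ", t)
  }
  # Int_0^t P_ai(s) P_jb(t-s) ds for transition i -> j
  dwell_integral <- function(i, j) {
    alpha <- (a == i + 1L) - pii[i + 1L]
    beta <- (j + 1L == b) - pii[b]
    e1 <- -expm1(-lam * t) / lam   # (1 - e^{-lam t}) / lam
    pii[i + 1L] * pii[b] * t +
      (pii[i + 1L] * beta + alpha * pii[b]) * e1 +
      alpha * beta * t * exp(-lam * t)
  }
  c(gain = g * dwell_integral(0L, 1L) / pab,
    loss = l * dwell_integral(1L, 0L) / pab)
}

# Downward (outside) partial vectors and per-edge endpoint posteriors for
# one rate category, reusing the scaled upward partials from pruning.
map_category <- function(tp, part, g, l, pi, X) {
  ns <- ncol(X)
  n_edge <- length(tp$child)
  Fp <- part$F
  Plist <- part$P
  # tip partials were not rescaled during pruning; rebuild indicators
  tipF <- function(v) {
    x <- X[v, ]
    cbind(1 - x, x)
  }
  getF <- function(v) if (v <= tp$n_tip) tipF(v) else Fp[[v]]
  M <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    M[[e]] <- getF(tp$child[e]) %*% t(Plist[[e]])
  }
  edges_of <- split(seq_len(n_edge), tp$parent)
  G <- vector("list", max(tp$parent))
  G[[tp$root]] <- matrix(rep(c(pi[[1L]], pi[[2L]]), each = ns), ns, 2L)
  e_gain <- matrix(0, ns, n_edge)
  e_loss <- matrix(0, ns, n_edge)
  for (e in rev(seq_len(n_edge))) {   # parents before children
    u <- tp$parent[e]
    v <- tp$child[e]
    Gsib <- G[[u]]
    for (e2 in edges_of[[as.character(u)]]) {
      if (e2 != e) Gsib <- Gsib * M[[e2]]
    }
    P <- Plist[[e]]
    Fv <- getF(v)
    # joint endpoint posterior over the 4 (parent, child) state pairs
    J <- cbind(Gsib[, 1L] * P[1L, 1L] * Fv[, 1L],
               Gsib[, 1L] * P[1L, 2L] * Fv[, 2L],
               Gsib[, 2L] * P[2L, 1L] * Fv[, 1L],
               Gsib[, 2L] * P[2L, 2L] * Fv[, 2L])
    tot <- rowSums(J)
    pos <- tot > 0
    J[pos, ] <- J[pos, ] / tot[pos]
    J[!pos, ] <- 0
    ab <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    for (k in 1:4) {
      Pab <- P[ab[k, 1L] + 1L, ab[k, 2L] + 1L]
      if (Pab > 0 && (g + l) > 0) {
        ex <- branch_conditional_expectations(g, l, tp$blen[e],
                                              ab[k, 1L], ab[k, 2L])
        e_gain[, e] <- e_gain[, e] + J[, k] * ex[["gain"]]
        e_loss[, e] <- e_loss[, e] + J[, k] * ex[["loss"]]
      }
    }
    if (v > tp$n_tip) {
      Gv <- Gsib %*% P
      sc <- pmax(Gv[, 1L], Gv[, 2L])
      posv <- sc > 0
      Gv[posv, ] <- Gv[posv, ] / sc[posv]
      G[[v]] <- Gv
    }
  }
  list(e_gain = e_gain, e_loss = e_loss)
}

#' Map expected gain and loss events onto branches
#'
#' Posterior expected numbers of gain (0->1) and loss (1->0) events for
#' every character on every branch of the rooted tree (stochastic mapping).
#' For each rate category, endpoint-state posteriors per branch are obtained
#' from inside/outside partial vectors and combined with the analytic
#' conditional event expectations; categories are mixed by their per-site
#' posterior weights from the fit. The zero-rate invariant category
#' contributes no events. Events are attributed to branches of the rooted
#' tree in root-to-tip direction.
#'
#' @param tree rooted \code{phylo} tree.
#' @param pattern a \code{\link{phyletic_pattern}}.
#' @param mix fitted \code{rate_mixture}.
#' @param fit matching \code{likelihood_result} (defaults to recomputing).
#' @return object of class \code{event_expectations}: matrices
#'   \code{e_gain} and \code{e_loss} (sites x branches, branch ids per
#'   \code{\link{branch_ids}}), plus \code{sites}, \code{branches} and the
#'   tree.
#' @export
map_events <- function(tree, pattern, mix, fit = NULL) {
  tp <- tree_prep(tree, pattern$taxa)
  X <- pattern_site_matrix(tp$tree, pattern)
  if (is.null(fit)) {
    fit <- corrected_log_likelihood(tree, pattern, mix, "none")
  }
  if (length(fit$per_site_log_likelihood) != ncol(X) ||
      ncol(fit$posterior_category_weights) != nrow(mix)) {
    stop("fit does not match pattern/mixture")
  }
  up <- prune_all(tp, X, mix, keep = TRUE)
  ns <- ncol(X)
  n_edge <- length(tp$child)
  e_gain <- matrix(0, ns, n_edge,
                   dimnames = list(pattern$characters, tp$branch_id))
  e_loss <- e_gain
  for (c in seq_len(nrow(mix))) {
    w <- fit$posterior_category_weights[, c]
    if (all(w == 0) || (mix$gain[c] + mix$loss[c]) == 0) next
    mc <- map_category(tp, up$partials[[c]], mix$gain[c], mix$loss[c],
                       c(mix$pi0[c], mix$pi1[c]), X)
    e_gain <- e_gain + mc$e_gain * w
    e_loss <- e_loss + mc$e_loss * w
  }
  structure(list(e_gain = e_gain, e_loss = e_loss,
                 sites = pattern$characters, branches = tp$branch_id,
                 tree = tp$tree),
            class = "event_expectations")
}

#' @export
print.event_expectations <- function(x, ...) {
  cat("Event expectations:", length(x$sites), "characters x",
      length(x$branches), "branches\n")
  cat(sprintf("  mean expected gains/site: %.4f, losses/site: %.4f\n",
              mean(rowSums(x$e_gain)), mean(rowSums(x$e_loss))))
  invisible(x)
}

#' Write event expectations as a long-format table
#'
#' Columns: site, branch, exp_gain, exp_loss.
#'
#' @param em an \code{event_expectations}.
#' @param path output TSV path (or a connection).
#' @return the long-format data frame, invisibly.
#' @export
write_event_table <- function(em, path) {
  df <- data.frame(
    site = rep(em$sites, times = length(em$branches)),
    branch = rep(em$branches, each = length(em$sites)),
    exp_gain = as.vector(em$e_gain),
    exp_loss = as.vector(em$e_loss))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
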