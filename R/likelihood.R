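# Felsenstein pruning for the two-state gain/loss chain, vectorized over
# sites, with per-node rescaling of partial likelihoods (underflow guard).

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# One rate category. X: n_tip x n_sites 0/1 matrix, rows indexed by tip
# number of tp$tree. Returns per-site log-likelihood; with keep = TRUE also
# the (scaled) upward partials F per node and the 2x2 P per edge.
prune_category <- function(tp, X, g, l, pi, keep = FALSE) {
  ns <- ncol(X)
  n_node <- max(tp$parent)
  Fp <- vector("list", n_node)
  Plist <- if (keep) vector("list", length(tp$child)) else NULL
  logscale <- numeric(ns)
  I2 <- diag(2)
  for (e in seq_along(tp$child)) {
    v <- tp$child[e]
    if (v <= tp$n_tip) {
      x <- X[v, ]
      Fv <- cbind(1 - x, x)
    } else {
      Fv <- Fp[[v]]
      sc <- pmax(Fv[, 1L], Fv[, 2L])
      pos <- sc > 0
      if (any(pos)) {
        Fv[pos, ] <- Fv[pos, ] / sc[pos]
        logscale[pos] <- logscale[pos] + log(sc[pos])
      }
      logscale[!pos] <- -Inf
      Fp[[v]] <- Fv
    }
    P <- if (g + l > 0) transition_probability(g, l, tp$blen[e]) else I2
    if (keep) Plist[[e]] <- P
    Me <- Fv %*% t(P)
    u <- tp$parent[e]
    Fp[[u]] <- if (is.null(Fp[[u]])) Me else Fp[[u]] * Me
  }
  L <- Fp[[tp$root]] %*% c(pi[[1L]], pi[[2L]])
  ll <- ifelse(L > 0, log(L) + logscale, -Inf)
  if (keep) {
    list(loglik = as.numeric(ll), F = Fp, P = Plist)
  } else {
    list(loglik = as.numeric(ll))
  }
}

# Per-site log-likelihood for every category of a mixture.
prune_all <- function(tp, X, mix, keep = FALSE) {
  K <- nrow(mix)
  out <- vector("list", K)
  cat_ll <- matrix(NA_real_, ncol(X), K)
  for (c in seq_len(K)) {
    res <- prune_category(tp, X, mix$gain[c], mix$loss[c],
                          c(mix$pi0[c], mix$pi1[c]), keep = keep)
    cat_ll[, c] <- res$loglik
    if (keep) out[[c]] <- res
  }
  list(cat_loglik = cat_ll, partials = if (keep) out else NULL)
}

pattern_site_matrix <- function(tree, pattern) {
  stopifnot(inherits(pattern, "phyletic_pattern"))
  if (!setequal(tree$tip.label, pattern$taxa)) {
    stop("tree leaf set does not match pattern taxa")
  }
  pattern$matrix[tree$tip.label, , drop = FALSE]
}

#' Likelihood of one phyletic character on a tree
#'
#' Mixture likelihood of a single 0/1 column: for every rate category the
#' pruning likelihood with root prior equal to that category's stationary
#' frequencies, mixed by category weight.
#'
#' @param tree rooted \code{phylo} tree.
#' @param column named 0/1 vector, names matching the tree's leaves.
#' @param mix a \code{rate_mixture}.
#' @return probability in (0, 1].
#' @export
site_likelihood <- function(tree, column, mix) {
  if (is.null(names(column)) || !setequal(names(column), tree$tip.label)) {
    stop("column must be named by the tree's leaf labels")
  }
  tp <- tree_prep(tree)
  X <- matrix(as.numeric(column[tp$tree$tip.label]), ncol = 1L)
  res <- prune_all(tp, X, mix)
  sum(mix$weight * exp(res$cat_loglik[1L, ]))
}

#' Log-likelihood of a phyletic pattern with unobservable-data correction
#'
#' Computes per-site mixture log-likelihoods by pruning. With
#' \code{correction = "no_absent"} each site likelihood is divided by
#' 1 - P(all-absent column) computed on the same tree and mixture: a
#' character absent from every genome is never observed, so the likelihood
#' is conditioned on observable patterns (all-present patterns remain
#' observable and are not conditioned on).
#'
#' @param tree rooted \code{phylo} tree.
#' @param pattern a \code{\link{phyletic_pattern}}.
#' @param mix a \code{rate_mixture}.
#' @param correction \code{"none"} or \code{"no_absent"}.
#' @return object of class \code{likelihood_result}: total
#'   \code{log_likelihood}, \code{per_site_log_likelihood},
#'   \code{posterior_category_weights} (sites x categories, rows sum to 1),
#'   per-category site log-likelihoods and \code{p_all_absent}.
#' @export
corrected_log_likelihood <- function(tree, pattern, mix,
                                     correction = c("no_absent", "none")) {
  correction <- match.arg(correction)
  tp <- tree_prep(tree, pattern$taxa)
  X <- pattern_site_matrix(tp$tree, pattern)
  res <- prune_all(tp, X, mix)
  lw <- log(mix$weight)
  site_ll <- logsumexp_rows(sweep(res$cat_loglik, 2L, lw, "+"))
  post <- exp(sweep(res$cat_loglik, 2L, lw, "+") - site_ll)
  p0 <- 0
  if (correction == "no_absent") {
    zero <- matrix(0, nrow(X), 1L)
    ll0 <- prune_all(tp, zero, mix)$cat_loglik[1L, ]
    p0 <- sum(mix$weight * exp(ll0))
    if (p0 >= 1 - 1e-14) {
      stop("P(all-absent) is numerically 1; correction impossible")
    }
    site_ll <- site_ll - log1p(-p0)
  }
  structure(list(log_likelihood = sum(site_ll),
                 per_site_log_likelihood = stats::setNames(site_ll,
                                                           pattern$characters),
                 posterior_category_weights = post,
                 cat_loglik = res$cat_loglik,
                 correction = correction,
                 p_all_absent = p0),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat("Log-likelihood:", format(x$log_likelihood), "over",
      length(x$per_site_log_likelihood), "characters (correction:",
      x$correction, ")\n")
  invisible(x)
}

#' Posterior mean gain and loss rate per character
#'
#' Posterior-weighted average of category rates per site, from the fitted
#' per-site category posteriors. Used to match null simulations to the
#' rate profile of the data.
#'
#' @param result a \code{likelihood_result}.
#' @param mix the \code{rate_mixture} the result was computed under.
#' @return matrix with columns \code{gain}, \code{loss}, one row per site.
#' @export
posterior_rate_per_site <- function(result, mix) {
  w <- result$posterior_category_weights
  if (ncol(w) != nrow(mix)) stop("result and mixture category counts differ")
  out <- w %*% cbind(gain = mix$gain, loss = mix$loss)
  rownames(out) <- names(result$per_site_log_likelihood)
  out
}

#' Fit a gain/loss model to a phyletic pattern by maximum likelihood
#'
#' Maximizes the (optionally corrected) log-likelihood over the model's free
#' parameters: the gain/loss ratio for all tiers, plus the gamma shape and
#' invariant proportion (tier \code{gamma_invariant}) or the two independent
#' gamma shapes (tier \code{mixture}). The overall rate scale is fixed by
#' the mixture normalization (unit mean event flux), so branch lengths stay
#' in expected events per character; input branch lengths are not
#' re-optimized, but a single global branch-scaling factor can optionally be
#' fitted. Optimization is bounded derivative-free search on transformed
#' parameters (log ratio, log shapes, logit p_inv) from a fixed list of
#' starts, so fits are deterministic.
#'
#' @param tree rooted \code{phylo} tree.
#' @param pattern a \code{\link{phyletic_pattern}}.
#' @param tier model tier.
#' @param correction unobservable-data correction mode.
#' @param K,K_gain,K_loss discretization category counts.
#' @param fit_branch_scale also fit a global branch-length multiplier.
#' @return list with \code{params} (\code{gain_loss_params}), \code{mix}
#'   (fitted \code{rate_mixture}), \code{fit} (\code{likelihood_result}),
#'   \code{branch_scale} and the possibly rescaled \code{tree}.
#' @export
fit_model <- function(tree, pattern,
                      tier = c("gamma_invariant", "single", "mixture"),
                      correction = c("no_absent", "none"),
                      K = 4L, K_gain = 3L, K_loss = 3L,
                      fit_branch_scale = FALSE) {
  tier <- match.arg(tier)
  correction <- match.arg(correction)
  validate_phylogeny(tree, pattern$taxa)

  make_params <- function(theta) {
    rho <- exp(theta[[1L]])
    switch(tier,
      single = gain_loss_params(g = rho, l = 1, tier = "single"),
      gamma_invariant = gain_loss_params(
        g = rho, l = 1, tier = "gamma_invariant",
        alpha = exp(theta[[2L]]), p_inv = stats::plogis(theta[[3L]]), K = K),
      mixture = gain_loss_params(
        g = rho, l = 1, tier = "mixture",
        alpha_gain = exp(theta[[2L]]), alpha_loss = exp(theta[[3L]]),
        K_gain = K_gain, K_loss = K_loss))
  }
  scaled_tree <- function(s) {
    if (s == 1) return(tree)
    tr <- tree
    tr$edge.length <- tr$edge.length * s
    tr
  }
  n_model <- switch(tier, single = 1L, gamma_invariant = 3L, mixture = 3L)
  objective <- function(theta) {
    s <- if (fit_branch_scale) exp(theta[[n_model + 1L]]) else 1
    ll <- tryCatch(
      corrected_log_likelihood(scaled_tree(s), pattern,
                               build_rate_mixture(make_params(theta)),
                               correction)$log_likelihood,
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- switch(tier,
    single = list(c(log(0.5)), c(0), c(log(2))),
    gamma_invariant = list(c(0, log(0.5), stats::qlogis(0.1)),
                           c(log(0.3), 0, stats::qlogis(0.05)),
                           c(log(3), log(2), stats::qlogis(0.3))),
    mixture = list(c(0, log(0.5), log(0.5)),
                   c(log(0.3), 0, 0),
                   c(log(3), log(2), log(0.7))))
  if (fit_branch_scale) starts <- lapply(starts, c, 0)

  best <- NULL
  if (n_model == 1L && !fit_branch_scale) {
    # the corrected conditional likelihood can be multimodal in the
    # gain/loss ratio on heterogeneous data: scan a coarse grid, then
    # refine around the best bracket
    grid <- seq(-8, 8, length.out = 33L)
    vals <- vapply(grid, objective, numeric(1L))
    k <- which.min(vals)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[min(length(grid), k + 1L)]
    best <- stats::optim(grid[k], objective, method = "Brent",
                         lower = lo, upper = hi)
  } else {
    for (st in starts) {
      opt <- stats::optim(st, objective, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("model fit failed to reach a finite likelihood")
  }
  theta <- best$par
  s <- if (fit_branch_scale) exp(theta[[n_model + 1L]]) else 1
  params <- make_params(theta)
  mix <- build_rate_mixture(params)
  tr <- scaled_tree(s)
  fit <- corrected_log_likelihood(tr, pattern, mix, correction)
  list(params = params, mix = mix, fit = fit, branch_scale = s, tree = tr)
}
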