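test_that("transition probabilities follow the two-state closed form", {
  expect_equal(transition_probability(1, 1, 0), diag(2), ignore_attr = TRUE)
  P <- transition_probability(1, 1, 0.5)
  expect_equal(P[1, 2], 0.5 * (1 - exp(-1)), tolerance = 1e-7)
  expect_equal(P[1, 2], 0.3160603, tolerance = 1e-6)
  Pinf <- transition_probability(2, 1, 1e6)
  expect_equal(Pinf[1, ], Pinf[2, ], tolerance = 1e-12)
  expect_equal(unname(Pinf[1, ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_error(transition_probability(1, 1, -0.1), "negative")
})

test_that("stationary frequencies solve pi Q = 0", {
  expect_equal(unname(stationary_frequencies(2, 1)), c(1 / 3, 2 / 3))
  expect_equal(unname(stationary_frequencies(3, 3)), c(0.5, 0.5))
  set.seed(8)
  for (i in 1:10) {
    g <- runif(1, 0.1, 5)
    l <- runif(1, 0.1, 5)
    expect_equal(sum(stationary_frequencies(g, l)), 1)
  }
})

test_that("Chapman-Kolmogorov and detailed balance hold", {
  set.seed(21)
  for (i in 1:50) {
    g <- runif(1, 0.05, 4)
    l <- runif(1, 0.05, 4)
    t1 <- runif(1, 0, 2)
    t2 <- runif(1, 0, 2)
    P12 <- transition_probability(g, l, t1 + t2)
    expect_equal(transition_probability(g, l, t1) %*%
                   transition_probability(g, l, t2),
                 P12, tolerance = 1e-12)
    pi <- stationary_frequencies(g, l)
    expect_equal(pi[[1]] * P12[1, 2], pi[[2]] * P12[2, 1], tolerance = 1e-12)
  }
})

test_that("rate mixtures discretize correctly and normalize to unit flux", {
  m1 <- build_rate_mixture(gain_loss_params(2, 1, "single"))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$gain / m1$loss, 2)
  expect_equal(mixture_flux(m1), 1)

  # huge shape concentrates the gamma at its mean
  mh <- build_rate_mixture(gain_loss_params(1, 1, "gamma_invariant",
                                            alpha = 1e6, p_inv = 0, K = 4),
                           normalize = FALSE)
  expect_equal(mh$gain, rep(1, 4), tolerance = 1e-3)

  mk <- build_rate_mixture(gain_loss_params(1, 2, "gamma_invariant",
                                            alpha = 0.6, p_inv = 0.2, K = 4))
  expect_equal(nrow(mk), 5L)
  expect_equal(mk$weight, rep(0.2, 5))
  expect_equal(sum(mk$weight), 1)
  expect_equal(mixture_flux(mk), 1, tolerance = 1e-12)

  mm <- build_rate_mixture(gain_loss_params(1, 1, "mixture",
                                            alpha_gain = 0.7,
                                            alpha_loss = 1.3,
                                            K_gain = 3, K_loss = 3))
  expect_equal(nrow(mm), 9L)
  expect_equal(sum(mm$weight), 1)
  expect_equal(mixture_flux(mm), 1, tolerance = 1e-12)
})

test_that("gamma quantile-bin means match numerical integration", {
  for (alpha in c(0.4, 1, 2.7)) {
    K <- 4
    r <- phylocoev:::discretize_gamma(alpha, K)
    q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
    oracle <- vapply(seq_len(K), function(k) {
      K * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                    q[k], min(q[k + 1], 1e4), rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(r, oracle, tolerance = 1e-6)
    expect_equal(mean(r), 1, tolerance = 1e-6)
  }
})

test_that("two-leaf site likelihood matches the hand expansion", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  mix <- single_mix(1, 1)
  P <- transition_probability(1, 1, 0.5)
  hand <- 0.5 * P[1, 1] * P[1, 2] + 0.5 * P[2, 1] * P[2, 2]
  expect_equal(site_likelihood(tr, c(A = 0, B = 1), mix), hand,
               tolerance = 1e-12)
  expect_equal(hand, 0.2161662, tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    tr <- random_tree(n, tree_length = runif(1, 0.5, 4))
    mix <- if (i %% 2 == 0) {
      build_rate_mixture(gain_loss_params(runif(1, 0.2, 3), runif(1, 0.2, 3),
                                          "gamma_invariant", alpha = 0.8,
                                          p_inv = 0.15, K = 2))
    } else {
      single_mix(runif(1, 0.2, 3), runif(1, 0.2, 3))
    }
    column <- stats::setNames(rbinom(n, 1, 0.5), tr$tip.label)
    expect_equal(site_likelihood(tr, column, mix),
                 enum_site_likelihood(tr, column, mix), tolerance = 1e-12)
  }
})

test_that("zero-length star tree returns the mixed stationary frequency", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  mix <- build_rate_mixture(gain_loss_params(2, 1, "gamma_invariant",
                                             alpha = 1, p_inv = 0.3, K = 3))
  expect_equal(site_likelihood(tr, c(A = 1, B = 1, C = 1), mix),
               sum(mix$weight * mix$pi1), tolerance = 1e-12)
})

test_that("unobservable-data correction matches the 2-leaf worked example", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  mix <- single_mix(1, 1)
  p <- phyletic_pattern(matrix(c(0L, 1L), 2, 1,
                               dimnames = list(c("A", "B"), "c1")))
  res <- corrected_log_likelihood(tr, p, mix, "no_absent")
  expect_lt(abs(res$p_all_absent - 0.28383), 1e-5)
  expect_lt(abs(exp(res$per_site_log_likelihood[[1]]) - 0.30184), 1e-5)
  plain <- corrected_log_likelihood(tr, p, mix, "none")
  expect_equal(exp(plain$per_site_log_likelihood[[1]]), 0.2161662,
               tolerance = 1e-6)
})

test_that("correction only increases the log-likelihood", {
  tr <- random_tree(6, seed = 4)
  p <- random_pattern(tr$tip.label, 25, seed = 5)
  mix <- build_rate_mixture(gain_loss_params(1.4, 0.9, "gamma_invariant",
                                             alpha = 0.7, p_inv = 0.1, K = 4))
  a <- corrected_log_likelihood(tr, p, mix, "none")$log_likelihood
  b <- corrected_log_likelihood(tr, p, mix, "no_absent")$log_likelihood
  expect_gt(b, a)
})

test_that("likelihood is invariant to root placement", {
  tr <- random_tree(7, tree_length = 3, seed = 11)
  p <- random_pattern(tr$tip.label, 20, seed = 12)
  mix <- build_rate_mixture(gain_loss_params(1.6, 0.8, "gamma_invariant",
                                             alpha = 1.1, p_inv = 0.2, K = 3))
  base <- corrected_log_likelihood(tr, p, mix, "no_absent")$log_likelihood
  un <- ape::unroot(tr)
  for (tip in c(1L, 4L)) {
    re <- ape::root(un, outgroup = un$tip.label[tip], resolve.root = TRUE)
    expect_equal(corrected_log_likelihood(re, p, mix,
                                          "no_absent")$log_likelihood,
                 base, tolerance = 1e-8)
  }
})

test_that("single-tier fit recovers the gain/loss ratio", {
  tr <- benchmark_tree(32, tree_length = 4, seed = 77)
  truth <- build_rate_mixture(gain_loss_params(2, 1, "single"))
  sim <- simulate_independent_sites(tr, truth, 600, seed = 42)
  fit <- fit_model(tr, sim$pattern, tier = "single", correction = "no_absent")
  ratio <- fit$params$g / fit$params$l
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 / 0.75)
  # optimality: fitted log-likelihood beats the generating parameters
  ll_true <- corrected_log_likelihood(tr, sim$pattern, truth,
                                      "no_absent")$log_likelihood
  expect_gte(fit$fit$log_likelihood, ll_true - 1e-6)
})

test_that("gamma-invariant fit on single-rate data nests the single fit", {
  tr <- benchmark_tree(16, tree_length = 4, seed = 55)
  truth <- build_rate_mixture(gain_loss_params(1.5, 1, "single"))
  sim <- simulate_independent_sites(tr, truth, 300, seed = 9)
  f1 <- fit_model(tr, sim$pattern, tier = "single", correction = "none")
  f2 <- fit_model(tr, sim$pattern, tier = "gamma_invariant",
                  correction = "none", K = 4)
  expect_gte(f2$fit$log_likelihood, f1$fit$log_likelihood - 2)
})

test_that("posterior category weights and per-site rates are coherent", {
  tr <- random_tree(8, seed = 14)
  p <- random_pattern(tr$tip.label, 30, seed = 15)
  mix <- build_rate_mixture(gain_loss_params(1, 1, "gamma_invariant",
                                             alpha = 0.5, p_inv = 0.2, K = 4))
  res <- corrected_log_likelihood(tr, p, mix, "no_absent")
  expect_equal(rowSums(res$posterior_category_weights),
               rep(1, 30), tolerance = 1e-12)
  rates <- posterior_rate_per_site(res, mix)
  expect_true(all(rates >= 0))

  ms <- single_mix(1.3, 0.7, normalize = TRUE)
  res1 <- corrected_log_likelihood(tr, p, ms, "none")
  r1 <- posterior_rate_per_site(res1, ms)
  expect_equal(unname(r1[, "gain"]), rep(ms$gain, 30))
  expect_equal(unname(r1[, "loss"]), rep(ms$loss, 30))
})

test_that("a variable site gets a higher posterior rate than a constant one", {
  tr <- random_tree(8, tree_length = 3, seed = 20)
  tips <- tr$tip.label
  m <- cbind(flippy = rep(c(0L, 1L), 4), steady = rep(1L, 8))
  # make the variable column alternate across the tree's tip order
  m[, "flippy"] <- rep(c(0L, 1L), length.out = 8)[order(tips)]
  rownames(m) <- tips
  p <- phyletic_pattern(m)
  mix <- build_rate_mixture(gain_loss_params(1, 1, "gamma_invariant",
                                             alpha = 0.5, p_inv = 0.2, K = 4))
  res <- corrected_log_likelihood(tr, p, mix, "none")
  rates <- posterior_rate_per_site(res, mix)
  tot <- rowSums(rates)
  expect_gt(tot[["flippy"]], tot[["steady"]])
})
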