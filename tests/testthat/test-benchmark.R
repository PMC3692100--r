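test_that("the joint pair generator reduces to independence at d = 1", {
  g1 <- 1.3; l1 <- 0.7; g2 <- 0.5; l2 <- 2
  Q <- pair_generator(g1, l1, g2, l2, d = 1)
  Q1 <- matrix(c(-g1, g1, l1, -l1), 2, byrow = TRUE)
  Q2 <- matrix(c(-g2, g2, l2, -l2), 2, byrow = TRUE)
  kron_sum <- kronecker(Q1, diag(2)) + kronecker(diag(2), Q2)
  expect_equal(unname(Q), kron_sum, tolerance = 1e-12)
  expect_equal(rowSums(pair_generator(2, 1, 1, 3, d = 16)), rep(0, 4),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(pair_generator(1, 1, 1, 1, d = 0.5), "d must be >= 1")
})

test_that("concordance bias moves rates in the right direction", {
  Q <- pair_generator(1, 1, 1, 1, d = 4)
  # leaving 00 is slowed, entering 11 is sped up
  expect_equal(Q["00", "01"], 1 / 4)
  expect_equal(Q["01", "11"], 4)
  expect_equal(Q["11", "01"], 1 / 4)
  expect_equal(Q["01", "00"], 4)
})

test_that("at d = 1 the two characters are independent at the tips", {
  tr <- random_tree(4, tree_length = 3, seed = 100)
  mix <- single_mix(1, 1, normalize = TRUE)
  set.seed(101)
  tip <- tr$tip.label[1]
  xs <- matrix(NA_integer_, 4000, 2)
  for (i in seq_len(nrow(xs))) {
    pr <- simulate_coevolving_pair(tr, mix, d = 1)
    xs[i, ] <- pr$columns[tip, ]
  }
  tab <- table(factor(xs[, 1], 0:1), factor(xs[, 2], 0:1))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("dependency raises extant correlation relative to independence", {
  tr <- benchmark_tree(64, tree_length = 4, seed = 110)
  mix <- single_mix(1, 1, normalize = TRUE)
  set.seed(111)
  cor_of <- function(d, n) {
    vapply(seq_len(n), function(i) {
      pr <- simulate_coevolving_pair(tr, mix, d = d)
      if (sd(pr$columns[, 1]) == 0 || sd(pr$columns[, 2]) == 0) NA_real_
      else cor(pr$columns[, 1], pr$columns[, 2])
    }, numeric(1))
  }
  c16 <- cor_of(16, 200)
  c1 <- cor_of(1, 200)
  expect_gt(mean(c16, na.rm = TRUE), mean(c1, na.rm = TRUE))
})

test_that("independent-site simulation matches stationarity and flux", {
  star <- ape::read.tree(text = "(a:50,b:50,c:50,d:50,e:50,f:50,g:50,h:50);")
  mix <- single_mix(2, 1, normalize = FALSE)
  sim <- simulate_independent_sites(star, mix, 10000, seed = 120)
  f1 <- mean(sim$pattern$matrix)
  se <- sqrt(2 / 3 * 1 / 3 / length(sim$pattern$matrix))
  expect_lt(abs(f1 - 2 / 3), 3 * se)

  tr <- benchmark_tree(32, tree_length = 3, seed = 121)
  nmix <- build_rate_mixture(gain_loss_params(1, 2, "gamma_invariant",
                                              alpha = 1, p_inv = 0.1, K = 4))
  sim2 <- simulate_independent_sites(tr, nmix, 10000, seed = 122)
  flips <- (sum(sim2$gain_events) + sum(sim2$loss_events)) / 10000
  expect_equal(flips, sum(tr$edge.length), tolerance = 0.05)

  # determinism and degenerate branch lengths
  sim3 <- simulate_independent_sites(tr, nmix, 50, seed = 9)
  sim4 <- simulate_independent_sites(tr, nmix, 50, seed = 9)
  expect_identical(sim3$pattern$matrix, sim4$pattern$matrix)
  zt <- tr
  zt$edge.length[] <- 0
  sim5 <- simulate_independent_sites(zt, nmix, 20, seed = 10)
  expect_true(all(apply(sim5$pattern$matrix, 2, sd) == 0))
  expect_error(simulate_independent_sites(tr, nmix, 0), "n_sites")
})

test_that("benchmark sets have the declared composition and valid truth", {
  tr <- random_tree(16, tree_length = 4, seed = 130)
  mix <- single_mix(1, 1, normalize = TRUE)
  b <- make_benchmark(tr, mix, n_pairs_coev = 5, n_indep = 12, d = 8,
                      seed = 131)
  expect_equal(length(b$pattern$characters), 22L)
  expect_equal(nrow(b$truth), 5L)
  expect_true(all(unlist(b$truth) %in% b$pattern$characters))
  expect_true(all(b$truth$id1 < b$truth$id2))
  # coevolving pairs disjoint
  expect_false(anyDuplicated(c(b$truth$id1, b$truth$id2)) > 0)
  b0 <- make_benchmark(tr, mix, n_pairs_coev = 0, n_indep = 5, seed = 132)
  expect_equal(nrow(b0$truth), 0L)
  # truth survives a write/read round-trip through character ids
  f <- withr::local_tempfile()
  write_pattern(b$pattern, f, "tsv")
  back <- read_pattern(f, "tsv")
  expect_identical(back$matrix[, b$truth$id1[1]],
                   b$pattern$matrix[, b$truth$id1[1]])
})

test_that("observed correlation scores extant columns", {
  m <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 0L, 1L, 1L),
             c = c(1L, 1L, 0L, 0L), d = c(0L, 1L, 0L, 1L))
  rownames(m) <- paste0("t", 1:4)
  sc <- observed_correlation_detector(phyletic_pattern(m))
  get <- function(i, j) sc$score[sc$id1 == i & sc$id2 == j]
  expect_equal(get("a", "b"), 1)
  expect_equal(get("a", "c"), -1)
  expect_equal(get("a", "d"), 0)
})

test_that("average precision matches hand computations", {
  truth <- data.frame(id1 = c("A", "C"), id2 = c("B", "D"))
  perfect <- data.frame(id1 = c("A", "C", "E"), id2 = c("B", "D", "F"),
                        score = c(3, 2, 1))
  expect_equal(average_precision(perfect, truth), 1)
  mixed <- data.frame(id1 = c("A", "E", "C"), id2 = c("B", "F", "D"),
                      score = c(3, 2, 1))
  expect_equal(average_precision(mixed, truth), (1 / 1 + 2 / 3) / 2)
  expect_equal(average_precision(mixed, truth), 0.8333, tolerance = 1e-4)
  # invariant under strictly monotone score transforms
  mixed2 <- mixed
  mixed2$score <- exp(mixed2$score) + 5
  expect_equal(average_precision(mixed2, truth),
               average_precision(mixed, truth))
  expect_error(average_precision(mixed, truth[0, ]), "empty truth")
})

test_that("random scores score near prevalence", {
  set.seed(140)
  n <- 40
  ids <- sprintf("X%02d", 1:n)
  grid <- t(combn(ids, 2))
  truth <- data.frame(id1 = grid[1:30, 1], id2 = grid[1:30, 2])
  prevalence <- 30 / nrow(grid)
  ap <- replicate(50, {
    sc <- data.frame(id1 = grid[, 1], id2 = grid[, 2],
                     score = runif(nrow(grid)))
    average_precision(sc, truth)
  })
  expect_equal(mean(ap), prevalence, tolerance = 0.25)
})

test_that("run_benchmark reports one AUPR per detector, order-independent", {
  tr <- random_tree(16, tree_length = 4, seed = 150)
  mix <- single_mix(1, 1, normalize = TRUE)
  b <- make_benchmark(tr, mix, n_pairs_coev = 3, n_indep = 10, d = 16,
                      seed = 151)
  oracle_detector <- function(pattern, tree, ...) {
    grid <- t(combn(sort(pattern$characters), 2))
    key <- paste(grid[, 1], grid[, 2])
    tkey <- paste(b$truth$id1, b$truth$id2)
    data.frame(id1 = grid[, 1], id2 = grid[, 2],
               score = as.numeric(key %in% tkey))
  }
  res <- run_benchmark(b, list(oracle = oracle_detector,
                               observed = observed_correlation_detector))
  expect_equal(res$aupr[res$detector == "oracle"], 1)
  res2 <- run_benchmark(b, list(observed = observed_correlation_detector,
                                oracle = oracle_detector))
  expect_equal(sort(res$aupr), sort(res2$aupr))
  expect_error(run_benchmark(b, list(oracle_detector)), "named")
})
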