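
# build a response table (one trial per stimulus) from tuning matrices
tuning_table <- function(gmat, pmat) {
  do.call(rbind, lapply(seq_len(nrow(gmat)), function(i) {
    mean_table(gmat[i, ], pmat[i, ], id = sprintf("n%02d", i))
  }))
}

test_that("pairwise similarity hits its closed-form cases", {
  g <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
  p <- rbind(c(2, 1, 4, 3), c(2, 1, 4, 3), c(5, 5, 1, 1))
  tab <- tuning_table(g, p)
  sim <- pairwise_similarity(tab, ss4)
  expect_equal(nrow(sim), 3)  # C(3, 2) unordered pairs, no self-pairs
  r12 <- sim[sim$cell_i == "n01" & sim$cell_j == "n02", ]
  expect_equal(r12$r_g, 1)    # identical tuning
  expect_equal(r12$r_p, 1)
  r13 <- sim[sim$cell_i == "n01" & sim$cell_j == "n03", ]
  expect_equal(r13$r_g, -1)   # mirrored tuning
  expect_true(all(sim$r_g >= -1 & sim$r_g <= 1))
})

test_that("pair count is quadratic and zero-variance cells are dropped", {
  set.seed(50)
  g <- matrix(stats::rnorm(40), 10)
  p <- matrix(stats::rnorm(40), 10)
  g[4, ] <- 2  # flat cell: undefined correlation
  tab <- tuning_table(g, p)
  expect_message(sim <- pairwise_similarity(tab, ss4), "zero-variance")
  expect_equal(nrow(sim), choose(9, 2))
})

test_that("similarity is invariant to positive affine transforms", {
  set.seed(51)
  g <- matrix(stats::rnorm(24), 6); p <- matrix(stats::rnorm(24), 6)
  s1 <- pairwise_similarity(tuning_table(g, p), ss4)
  g[2, ] <- 3 * g[2, ] + 7
  p[5, ] <- 0.5 * p[5, ] - 2
  s2 <- pairwise_similarity(tuning_table(g, p), ss4)
  expect_equal(s1$r_g, s2$r_g, tolerance = 1e-12)
  expect_equal(s1$r_p, s2$r_p, tolerance = 1e-12)
})

test_that("the 2-D K-S statistic behaves at its extremes", {
  set.seed(52)
  a <- matrix(stats::runif(60), 30)
  expect_equal(ks2d_two_sample(a, a)$D, 0)
  expect_equal(ks2d_two_sample(a, a)$p, 1)
  # total separation: every point of a below-left of every point of b;
  # with anchors counted in their own sample the attainable maximum is
  # 1 - 1/(2 nb)
  b <- matrix(stats::runif(60), 30) + 5
  res <- ks2d_two_sample(a, b)
  expect_equal(res$D, 1 - 1 / (2 * nrow(b)))
  expect_lt(res$p, 1e-6)
  # symmetry in the two samples
  set.seed(53)
  c1 <- matrix(stats::rnorm(80), 40); c2 <- matrix(stats::rnorm(100), 50)
  expect_equal(ks2d_two_sample(c1, c2)$D, ks2d_two_sample(c2, c1)$D)
  expect_warning(ks2d_two_sample(matrix(stats::runif(10), 5), c1),
                 "unreliable")
})

test_that("a single-rule population never rejects n = 1", {
  set.seed(54)
  g <- matrix(stats::rnorm(80), 20)
  tab <- tuning_table(g, g)  # plaid tuning identical -> r_p = r_g exactly
  sim <- pairwise_similarity(tab, ss4)
  expect_equal(sim$r_p, sim$r_g, tolerance = 1e-12)
  rb <- rules_bootstrap(sim, n_range = 1:3, resamples = 25, seed = 55)
  expect_false(rb$results$rejected[rb$results$n == 1])
  expect_equal(rb$min_sufficient_n, 1)
  # aligning within-group pairs of an already aligned table changes nothing
  expect_true(all(rb$p_values[["1"]] == 1))
})

test_that("a multi-rule population rejects n = 1", {
  set.seed(56)
  n_cells <- 30
  g <- matrix(stats::rnorm(4 * n_cells), n_cells)
  perms <- list(c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1),
                c(2, 3, 4, 1), c(3, 1, 4, 2))
  rule <- rep_len(1:5, n_cells)
  p <- t(vapply(seq_len(n_cells),
                function(i) g[i, perms[[rule[i]]]] + 0.1 * stats::rnorm(4),
                numeric(4)))
  sim <- pairwise_similarity(tuning_table(g, p), ss4)
  rb <- rules_bootstrap(sim, n_range = 1, resamples = 25, seed = 57)
  expect_true(rb$results$rejected[1])
})

test_that("rule counts too large for the population are skipped", {
  set.seed(58)
  g <- matrix(stats::rnorm(24), 6)
  sim <- pairwise_similarity(tuning_table(g, g), ss4)
  rb <- rules_bootstrap(sim, n_range = c(1, 4), resamples = 5, seed = 59)
  expect_false(rb$results$skipped[rb$results$n == 1])
  expect_true(rb$results$skipped[rb$results$n == 4])  # groups of < 2 cells
})
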