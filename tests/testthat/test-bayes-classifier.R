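test_that("identical predictions and observations are always accepted", {
  obs <- lapply(1:4, function(i) c(1, 2, 3, 4, 5) + i)
  names(obs) <- as.character(c(0, 45, 90, 135))
  res <- ks_accept(obs, obs)
  expect_true(res$accepted)
  expect_true(all(res$p_values == 1))
})

test_that("a fully shifted plaid is rejected after Holm correction", {
  # D = 1 at n = m = 5: exact two-sample K-S p = 2 / choose(10, 5)
  preds <- lapply(1:4, function(i) stats::rnorm(5, 10, 1))
  obs <- preds
  obs[[2]] <- obs[[2]] + 100
  names(preds) <- names(obs) <- as.character(c(0, 45, 90, 135))
  res <- ks_accept(preds, obs)
  expect_false(res$accepted)
  expect_equal(unname(res$p_values[2]), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(unname(res$p_adjusted[2]), 4 * 2 / choose(10, 5),
               tolerance = 1e-12)
})

test_that("alternative test variants and corrections agree on clear cases", {
  set.seed(10)
  preds <- lapply(1:4, function(i) stats::rnorm(20, 10, 1))
  names(preds) <- as.character(c(0, 45, 90, 135))
  shifted <- preds
  shifted[[3]] <- shifted[[3]] + 50
  for (tv in c("cramer_von_mises", "anderson_darling")) {
    expect_true(ks_accept(preds, preds, test = tv, seed = 1)$accepted)
    expect_false(ks_accept(preds, shifted, test = tv, seed = 1)$accepted)
  }
  expect_false(ks_accept(preds, shifted, mcc = "benjamini_hochberg")$accepted)
})

test_that("Holm rejections contain the Bonferroni rejections", {
  set.seed(11)
  for (i in 1:200) {
    p <- stats::runif(sample(2:8, 1))^sample(1:3, 1)
    holm <- stats::p.adjust(p, "holm") < 0.05
    bonf <- stats::p.adjust(p, "bonferroni") < 0.05
    expect_true(all(bonf <= holm))
  }
})

test_that("deciban ranking applies the Jeffreys threshold", {
  expect_true(is.na(rank_models(c(a = -30, b = -30))$winner))
  r <- rank_models(c(a = -30, b = -31))
  expect_equal(r$winner, "a")
  expect_equal(r$deciban_lead, 10)
  expect_true(is.na(rank_models(c(a = -30, b = -30.4))$winner))
  # antisymmetry of the pairwise matrix is exact
  m <- rank_models(c(a = -12.3, b = -45.6, c = -1.2))$deciban_matrix
  expect_identical(m, -t(m))
})

test_that("the KDE likelihood favours the model whose mode covers the data", {
  # observations at the component prediction mode, far from pattern's
  tab <- sample_cell_responses(
    make_cell(c(10, 10, 10, 10), rep(10, 4), sd = 1), ss4,
    n_trials = 5, seed = 2)
  tab$response_dff_pct[tab$stim_type == "plaid"] <-
    stats::rnorm(20, 10, 0.7)
  lc <- mc_likelihood(get_model("component"), tab, ss4, k = 1,
                      n_samples = 5000, seed = 3)$log10_lik
  lp <- mc_likelihood(get_model("pattern"), tab, ss4, k = 5,
                      n_samples = 5000, seed = 3)$log10_lik
  expect_gt(10 * (lc - lp), 5)
})

test_that("the likelihood estimate is deterministic under a fixed seed", {
  tab <- sample_cell_responses(make_cell(c(20, 6, 0.2, 6), c(10, 10, 3, 3)),
                               ss4, n_trials = 5, seed = 2)
  l1 <- mc_likelihood(get_model("component"), tab, ss4, 1, 2000, seed = 9)
  l2 <- mc_likelihood(get_model("component"), tab, ss4, 1, 2000, seed = 9)
  expect_identical(l1$log10_lik, l2$log10_lik)
})

test_that("the kernel density estimate is a normalized density", {
  set.seed(12)
  x <- stats::rnorm(5000, 3, 2)
  grid <- seq(-15, 21, length.out = 4000)
  dens <- plaidclass:::kde_density_at(grid, x)
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 0.01)
})

test_that("type-II error drops when the model is far from the data", {
  # flat gratings, alternating plaids: the optimal gain leaves a 5-SD
  # residual on every plaid, so the wrong model is nearly always rejected
  tab <- sample_cell_responses(make_cell(rep(10, 4), c(20, 0, 20, 0), sd = 2),
                               ss4, n_trials = 5, seed = 3)
  b <- estimate_type2_error(get_model("component"), tab, ss4,
                            n_resamples = 100, seed = 4)
  expect_gte(b$h0_h1_separation, 4)
  expect_lt(b$beta, 0.2)
})

test_that("type-II error decreases with the trial count", {
  tab5 <- sample_cell_responses(make_cell(rep(10, 4), c(12, 10, 10, 10),
                                          sd = 2), ss4, 5, seed = 3)
  b5 <- estimate_type2_error(get_model("component"), tab5, ss4,
                             n_resamples = 150, n_trials = 5, seed = 4)$beta
  b20 <- estimate_type2_error(get_model("component"), tab5, ss4,
                              n_resamples = 150, n_trials = 20, seed = 4)$beta
  expect_gte(b5, b20 - 0.05)  # monotone within Monte-Carlo error
})
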