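cfg_fast <- plaid_config(n_mc_samples = 2000, seed = 77)

test_that("an ideal component cell is component-classified", {
  pop <- make_population(n_cells = 1, class_mix = c(component = 1),
                         noise_sd = 1, seed = 30)
  tab <- sample_cell_responses(pop[[1]], ss4, n_trials = 10, seed = 31)
  res <- classify_cell(tab, ss4, cfg_fast, seed = 32)
  expect_equal(res$category, "component_classified")
})

test_that("an ideal pattern cell is pattern-classified", {
  pop <- make_population(n_cells = 1, class_mix = c(pattern = 1),
                         noise_sd = 1, seed = 33)
  tab <- sample_cell_responses(pop[[1]], ss4, n_trials = 10, seed = 34)
  res <- classify_cell(tab, ss4, cfg_fast, seed = 35)
  expect_equal(res$category, "pattern_classified")
})

test_that("single-class responders go straight to the MI dominance step", {
  # gratings ~ 0, strong plaids: MI = 1 -> pattern-dominant
  tab <- sample_cell_responses(make_cell(rep(0, 4), rep(20, 4), sd = 1),
                               ss4, n_trials = 8, seed = 36)
  res <- classify_cell(tab, ss4, cfg_fast)
  expect_equal(res$category, "pattern_dominant")
  expect_false(res$diagnostics$responds_grating)
  # and the mirror image
  tab2 <- sample_cell_responses(make_cell(rep(20, 4), rep(0, 4), sd = 1),
                                ss4, n_trials = 8, seed = 37)
  expect_equal(classify_cell(tab2, ss4, cfg_fast)$category,
               "component_dominant")
  # a weak single-class responder inside the MI band stays unclassified
  tab3 <- sample_cell_responses(make_cell(rep(0.3, 4), rep(0.45, 4), sd = 1),
                                ss4, n_trials = 8, seed = 38)
  res3 <- classify_cell(tab3, ss4, cfg_fast)
  expect_equal(res3$category, "unclassified")
  expect_equal(res3$reason, "weak_responder")
})

test_that("ambiguous cells fall through to unclassified(indistinguishable)", {
  # flat tuning: both models predict the same mean, MI ~ 0. Plaid trials are
  # placed at quantiles of a Normal whose SD sits midway (in expected
  # log-density) between the two models' predicted spreads, so neither model
  # scores a 5 dB lead and the KS stage accepts both.
  tab <- sample_cell_responses(make_cell(rep(10, 4), rep(10, 4), sd = 2),
                               ss4, n_trials = 8, seed = 6)
  for (th in c(0, 45, 90, 135))
    tab$response_dff_pct[tab$stim_type == "plaid" &
                           tab$orientation_deg == th] <-
      stats::qnorm(seq(0.1, 0.9, length.out = 8), 10, 2.4)
  res <- classify_cell(tab, ss4, cfg_fast, seed = 41)
  expect_equal(res$category, "unclassified")
  expect_equal(res$reason, "indistinguishable")
  expect_lt(abs(res$mi), 0.33)
})

test_that("cells without both stimulus classes raise a data error", {
  tab <- sample_cell_responses(make_cell(rep(10, 4), rep(10, 4)), ss4, 5,
                               seed = 42)
  expect_error(classify_cell(tab[tab$stim_type == "grating", ], ss4,
                             cfg_fast), "missing plaid")
})

test_that("every screened-in cell lands in exactly one category", {
  ds <- simulate_dataset(n_cells = 24, n_trials = 6, noise_sd = 3, seed = 44)
  res <- classify_cells(ds$responses, ds$stimuli, cfg_fast)
  expect_equal(nrow(res), 24)
  cats <- c("component_classified", "pattern_classified",
            "component_dominant", "pattern_dominant", "unclassified",
            "excluded")
  expect_true(all(res$category %in% cats))
  s <- summarize_population(res)
  expect_equal(s$n_selective, sum(res$category != "excluded"))
  expect_equal(sum(unlist(s$fractions)), 1, tolerance = 1e-12)
  # unselective ground-truth cells are excluded by the ANOVA screen
  truth <- truth_of(ds)
  expect_true(all(res$category[truth[res$cell_id] == "unselective"] ==
                    "excluded"))
})

test_that("summaries handle the empty and all-excluded cases", {
  ds <- simulate_dataset(n_cells = 4, class_mix = c(unselective = 1),
                         n_trials = 5, seed = 45)
  res <- classify_cells(ds$responses, ds$stimuli, cfg_fast)
  s <- summarize_population(res)
  expect_equal(s$n_selective, 0)
  expect_equal(sum(unlist(s$fractions)), 0)
})
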