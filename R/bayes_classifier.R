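# Model acceptance, Monte-Carlo likelihoods and deciban ranking.

# two-sample test statistic + p-value; exact two-sample K-S null when both
# samples are small (n, m <= 25), asymptotic otherwise. Alternative variants
# (Cramer-von Mises, Anderson-Darling) use Monte-Carlo permutation p-values.
two_sample_test <- function(x, y, variant = c("ks", "cramer_von_mises",
                                              "anderson_darling"),
                            n_perm = 999, seed = NULL) {
  variant <- match.arg(variant)
  if (variant == "ks") {
    exact <- length(x) <= 25 && length(y) <= 25
    res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    return(list(statistic = unname(res$statistic), p = res$p.value))
  }
  stat_fun <- if (variant == "cramer_von_mises") cvm2_stat else ad2_stat
  obs <- stat_fun(x, y)
  pooled <- c(x, y)
  n <- length(x)
  with_seed(seed, {
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pooled), n)
      stat_fun(pooled[idx], pooled[-idx])
    })
    list(statistic = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
  })
}

# two-sample Cramer-von Mises statistic (rank form)
cvm2_stat <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  u <- n * sum((r[seq_len(n)] - seq_len(n))^2) +
    m * sum((r[n + seq_len(m)] - seq_len(m))^2)
  u / (n * m * (n + m)) - (4 * n * m - 1) / (6 * (n + m))
}

# two-sample Anderson-Darling statistic (k-sample form, k = 2)
ad2_stat <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  z <- sort(c(x, y))
  zs <- z[-N]
  mi <- vapply(zs, function(v) sum(x <= v), numeric(1))
  j <- seq_len(N - 1)
  (1 / (n * m)) * sum((mi * N - n * j)^2 / (j * (N - j)))
}

#' Model acceptance by per-plaid two-sample tests with familywise correction
#'
#' Compares a model's single-trial prediction set to the observed single-trial
#' plaid responses with one two-sample test per plaid stimulus, then combines
#' the per-plaid p-values with a Holm-Bonferroni correction (or
#' Benjamini-Hochberg, by config). The model is accepted iff no test rejects
#' after correction at familywise level `alpha`.
#'
#' @param pred_by_plaid Named list: prediction values per plaid.
#' @param obs_by_plaid Named list: observed single-trial plaid responses,
#'   same names.
#' @param alpha Familywise significance level (default 0.05).
#' @param mcc Multiple-comparisons correction: `"holm"` (default) or
#'   `"benjamini_hochberg"`.
#' @param test Two-sample test variant: `"ks"` (default; exact small-sample
#'   null when both samples have <= 25 values), `"cramer_von_mises"` or
#'   `"anderson_darling"` (permutation p-values).
#' @param n_perm,seed Permutation count and seed for the non-KS variants.
#' @return List with `p_values`, `p_adjusted`, `statistics` (all named by
#'   plaid), and `accepted` (logical).
#' @export
ks_accept <- function(pred_by_plaid, obs_by_plaid, alpha = 0.05,
                      mcc = c("holm", "benjamini_hochberg"),
                      test = "ks", n_perm = 999, seed = NULL) {
  mcc <- match.arg(mcc)
  stopifnot(identical(names(pred_by_plaid), names(obs_by_plaid)))
  for (nm in names(obs_by_plaid)) {
    assert_that(length(pred_by_plaid[[nm]]) >= 1 &&
                  length(obs_by_plaid[[nm]]) >= 1,
                paste("empty sample for plaid", nm))
    if (length(obs_by_plaid[[nm]]) < 3)
      warning("fewer than 3 observed trials for plaid ", nm,
              "; the test has little power", call. = FALSE)
  }
  res <- mapply(function(pred, obs) two_sample_test(pred, obs, test, n_perm, seed),
                pred_by_plaid, obs_by_plaid, SIMPLIFY = FALSE)
  p <- vapply(res, `[[`, numeric(1), "p")
  stat <- vapply(res, `[[`, numeric(1), "statistic")
  p_adj <- stats::p.adjust(p, method = if (mcc == "holm") "holm" else "BH")
  list(p_values = p, p_adjusted = p_adj, statistics = stat,
       accepted = all(p_adj >= alpha))
}

# Gaussian KDE density of `samples` evaluated at `at`, Silverman bandwidth
kde_density_at <- function(at, samples, bw = NULL, floor = 1e-300) {
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(samples), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0)
      bw <- max(1e-6, 1e-6 * abs(mean(samples)))  # near point mass
  }
  dens <- vapply(at, function(v) mean(stats::dnorm(v, samples, bw)), numeric(1))
  pmax(dens, floor)
}

#' Monte-Carlo kernel-density pseudo-log-likelihood of a model
#'
#' For each plaid stimulus, the grating inputs the model consumes are
#' approximated by Normal distributions with the sample mean and SD (n - 1
#' denominator) of the observed single-trial grating responses. `n_samples`
#' model outputs are drawn by Monte-Carlo sampling of these Normals, a
#' Gaussian kernel density (Silverman bandwidth) is fitted over the samples,
#' and the observed single-trial plaid responses are scored against it. The
#' value returned is the sum over plaids and trials of log10 density, with a
#' density floor applied before the log; only differences between models
#' scored on the same responses are meaningful.
#'
#' @param model A `plaid_model`.
#' @param cell_table Trial response table rows for one cell.
#' @param stimuli Stimulus set.
#' @param k Gain (from [fit_gain()]).
#' @param n_samples Monte-Carlo samples per plaid (default 10000).
#' @param seed Optional seed; the estimate is deterministic under a fixed
#'   seed.
#' @param density_floor Floor applied to densities before log10.
#' @return List with `log10_lik`, `per_plaid` (named vector of per-plaid
#'   log10-likelihood contributions) and `degenerate_inputs` (orientations
#'   with zero trial SD, scored as near point masses).
#' @export
mc_likelihood <- function(model, cell_table, stimuli, k, n_samples = 10000,
                          seed = NULL, density_floor = 1e-300) {
  assert_that(n_samples >= 1, "`n_samples` must be >= 1")
  gt <- grating_trials(cell_table, stimuli$grating_orientations)
  mu <- vapply(gt, mean, numeric(1))
  sigma <- vapply(gt, stats::sd, numeric(1))
  assert_that(all(vapply(gt, length, integer(1)) >= 2),
              "need >= 2 trials per grating orientation")
  pt <- plaid_trials(cell_table, stimuli$plaid_orientations)
  degenerate <- names(sigma)[sigma == 0]
  with_seed(seed, {
    per_plaid <- vapply(as.character(stimuli$plaid_orientations), function(th) {
      ori <- as.character(model$input_orientations(as.numeric(th), stimuli))
      draws <- lapply(ori, function(o) stats::rnorm(n_samples, mu[o], sigma[o]))
      samples <- switch(model$name,
        component = k * (draws[[1]] + draws[[2]]) / 2,
        pattern   = k * draws[[1]],
        # generic models: apply predict to paired draws via trial lists of
        # length 1 per sample (kept simple and correct, if slower)
        apply_model_samples(model, draws, k))
      obs <- pt[[th]]
      sum(log10(kde_density_at(obs, samples, floor = density_floor)))
    }, numeric(1))
    list(log10_lik = sum(per_plaid), per_plaid = per_plaid,
         degenerate_inputs = degenerate)
  })
}

apply_model_samples <- function(model, draws, k) {
  n <- length(draws[[1]])
  vapply(seq_len(n), function(i) {
    model$predict(lapply(draws, `[`, i), k)[1]
  }, numeric(1))
}

#' Rank models in decibans
#'
#' Ranks models by their pseudo-log-likelihoods; the best model wins only if
#' its lead over the runner-up exceeds `threshold_db` decibans, where the
#' deciban difference between two models is `10 * (log10 L1 - log10 L2)`
#' (Jeffreys' scale: more than 5 dB is substantial evidence).
#'
#' @param log10_liks Named numeric vector of log10 likelihoods (>= 2 models).
#' @param threshold_db Winning margin in decibans (default 5).
#' @return List with `winner` (model name or NA), `deciban_lead` (lead of the
#'   best model over the runner-up) and `deciban_matrix` (antisymmetric
#'   pairwise matrix `10 * (Li - Lj)`).
#' @export
rank_models <- function(log10_liks, threshold_db = 5) {
  assert_that(length(log10_liks) >= 2 && all(is.finite(log10_liks)),
              "need >= 2 finite log10 likelihoods")
  mat <- 10 * outer(log10_liks, log10_liks, "-")
  ord <- order(log10_liks, decreasing = TRUE)
  lead <- 10 * (log10_liks[ord[1]] - log10_liks[ord[2]])
  list(winner = if (lead > threshold_db) names(log10_liks)[ord[1]] else
         NA_character_,
       deciban_lead = unname(lead), deciban_matrix = mat)
}

#' Type-II error of the acceptance stage, by Monte-Carlo resampling
#'
#' Estimates, for one cell and model, the probability that the K-S/Holm
#' acceptance stage fails to reject the model when the true response
#' distribution differs from the model's prediction. The observed plaid
#' responses define the "truth" (H0 of the resampling): per plaid, a Normal
#' fit to the observed trials. The model prediction defines H1: Normal
#' grating fits pushed through the model at the fitted gain. Each resample
#' draws fresh synthetic observations from the truth and a fresh
#' all-combination prediction set from H1, and runs the acceptance test; the
#' type-II error `beta` is the fraction of resamples in which the (wrong)
#' model is accepted. When the model prediction coincides with the observed
#' distribution there is no true effect and `beta` is not meaningful; the
#' returned `h0_h1_separation` (largest standardized per-plaid mean
#' difference) flags this case.
#'
#' @param model A `plaid_model`.
#' @param cell_table Trial response table rows for one cell.
#' @param stimuli Stimulus set.
#' @param n_resamples Number of Monte-Carlo resamples (default 200).
#' @param n_trials Synthetic trials per plaid per resample (default: the
#'   observed trial count).
#' @param alpha,mcc,test Passed to [ks_accept()].
#' @param seed Optional seed.
#' @return List with `beta`, `n_resamples`, `h0_h1_separation` and `k`.
#' @export
estimate_type2_error <- function(model, cell_table, stimuli,
                                 n_resamples = 200, n_trials = NULL,
                                 alpha = 0.05, mcc = "holm", test = "ks",
                                 seed = NULL) {
  fit <- fit_gain(model, cell_table, stimuli)
  assert_that(!fit$degenerate, "model is degenerate for this cell")
  gt <- grating_trials(cell_table, stimuli$grating_orientations)
  mu_g <- vapply(gt, mean, numeric(1))
  sd_g <- vapply(gt, stats::sd, numeric(1))
  pt <- plaid_trials(cell_table, stimuli$plaid_orientations)
  mu_p <- vapply(pt, mean, numeric(1))
  sd_p <- vapply(pt, stats::sd, numeric(1))
  if (is.null(n_trials)) n_trials <- max(vapply(pt, length, integer(1)))
  pang <- as.character(stimuli$plaid_orientations)

  # H1 per-plaid predicted moments, for the separation diagnostic
  sep <- vapply(pang, function(th) {
    ori <- as.character(model$input_orientations(as.numeric(th), stimuli))
    pred_mu <- switch(model$name,
                      component = fit$k * mean(mu_g[ori]),
                      pattern = fit$k * mu_g[ori],
                      fit$k * mean(mu_g[ori]))
    abs(pred_mu - mu_p[th]) / max(sd_p[th], .Machine$double.eps)
  }, numeric(1))

  with_seed(seed, {
    accepted <- vapply(seq_len(n_resamples), function(r) {
      preds <- lapply(pang, function(th) {
        ori <- as.character(model$input_orientations(as.numeric(th), stimuli))
        draws <- lapply(ori, function(o)
          stats::rnorm(n_trials, mu_g[o], sd_g[o]))
        model$predict(draws, fit$k)
      })
      names(preds) <- pang
      obs <- lapply(pang, function(th) stats::rnorm(n_trials, mu_p[th], sd_p[th]))
      names(obs) <- pang
      ks_accept(preds, obs, alpha = alpha, mcc = mcc, test = test)$accepted
    }, logical(1))
    list(beta = mean(accepted), n_resamples = n_resamples,
         h0_h1_separation = max(sep), k = fit$k)
  })
}
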