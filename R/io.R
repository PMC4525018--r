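# Configuration, response-table IO and the end-to-end pipeline.

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline with its default.
#' Every report written by [run_pipeline()] embeds the resolved config.
#'
#' @param alpha_screen ANOVA selectivity threshold (default 0.05).
#' @param alpha_ks Familywise level of the model-acceptance stage (0.05).
#' @param alpha_pc One-tailed level of the PC classifier (0.1).
#' @param mi_threshold Dominance band half-width on MI (0.33).
#' @param deciban_threshold Winning margin for model ranking (5 dB).
#' @param n_mc_samples Monte-Carlo samples per plaid for likelihoods (10000).
#' @param n_trials_min Minimum trials per stimulus expected of input data (5).
#' @param sd_mult,trial_frac Responsiveness rule: responses above
#'   `sd_mult` baseline SDs in more than `trial_frac` of trials.
#' @param test_variant `"ks"`, `"cramer_von_mises"` or `"anderson_darling"`.
#' @param mcc_variant `"holm"` or `"benjamini_hochberg"`.
#' @param directional_resolution `"direction_8"` or `"orientation_4"` (see
#'   [partial_correlation_classify()]).
#' @param models Model names to test (must be registered).
#' @param seed Optional integer seed; all pipeline randomness derives from
#'   it.
#' @return Named list of class `plaid_config`.
#' @export
plaid_config <- function(alpha_screen = 0.05, alpha_ks = 0.05,
                         alpha_pc = 0.1, mi_threshold = 0.33,
                         deciban_threshold = 5, n_mc_samples = 10000,
                         n_trials_min = 5, sd_mult = 2, trial_frac = 0.5,
                         test_variant = "ks", mcc_variant = "holm",
                         directional_resolution = "direction_8",
                         models = c("component", "pattern"), seed = NULL) {
  for (a in c(alpha_screen, alpha_ks, alpha_pc))
    assert_that(a > 0 && a < 1, "significance levels must lie in (0, 1)")
  assert_that(mi_threshold > 0 && deciban_threshold > 0 && n_mc_samples >= 1,
              "thresholds must be positive")
  structure(list(alpha_screen = alpha_screen, alpha_ks = alpha_ks,
                 alpha_pc = alpha_pc, mi_threshold = mi_threshold,
                 deciban_threshold = deciban_threshold,
                 n_mc_samples = n_mc_samples, n_trials_min = n_trials_min,
                 sd_mult = sd_mult, trial_frac = trial_frac,
                 test_variant = test_variant, mcc_variant = mcc_variant,
                 directional_resolution = directional_resolution,
                 models = models, seed = seed),
            class = "plaid_config")
}

RESPONSE_COLUMNS <- c("cell_id", "stim_id", "stim_type", "orientation_deg",
                      "trial_idx", "response_dff_pct")

#' Write / read a trial response table as CSV
#'
#' The on-disk dialect has columns `cell_id`, `stim_id`, `stim_type`
#' (`grating`/`plaid`), `orientation_deg`, `trial_idx`,
#' `response_dff_pct`. Reading validates the schema, rejects duplicate
#' (cell, stimulus, trial) keys, and (when a stimulus set is supplied)
#' checks that every orientation is actually presented.
#'
#' @param responses Trial response table.
#' @param path File path.
#' @param stimuli Optional [make_stimulus_set()] object to validate against.
#' @return `read_responses()` returns the validated data.frame;
#'   `write_responses()` its path, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses[, RESPONSE_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, stimuli = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(df))
  assert_that(length(missing_cols) == 0,
              paste("response table is missing column(s):",
                    paste(missing_cols, collapse = ", ")))
  assert_that(all(df$stim_type %in% c("grating", "plaid")),
              "stim_type must be 'grating' or 'plaid'")
  assert_that(is.numeric(df$response_dff_pct) && is.numeric(df$orientation_deg),
              "response and orientation columns must be numeric")
  key <- paste(df$cell_id, df$stim_id, df$trial_idx)
  if (anyDuplicated(key))
    stop("duplicate (cell, stimulus, trial) key: ", key[duplicated(key)][1],
         call. = FALSE)
  if (!is.null(stimuli)) {
    bad_g <- setdiff(unique(df$orientation_deg[df$stim_type == "grating"]),
                     stimuli$grating_orientations)
    bad_p <- setdiff(unique(df$orientation_deg[df$stim_type == "plaid"]),
                     stimuli$plaid_orientations)
    if (length(c(bad_g, bad_p)))
      stop("orientation(s) absent from the stimulus set: ",
           paste(c(bad_g, bad_p), collapse = ", "), call. = FALSE)
  }
  df
}

#' Run the full classification pipeline
#'
#' Screens, classifies (Bayesian two-step and PC), computes indices, and
#' optionally runs the similarity/rules analysis over the unclassified
#' cells. With `out_dir` set, writes `cells.csv` (per-cell report),
#' `summary.json` (population summary with the resolved config embedded)
#' and, if requested, `similarity.csv` and `rules.json`. Identical inputs,
#' config and seed give identical outputs.
#'
#' @param responses Trial response table (or a path to one).
#' @param stimuli Stimulus set.
#' @param config A [plaid_config()].
#' @param baseline_sd See [classify_cells()].
#' @param similarity Run [pairwise_similarity()] + [rules_bootstrap()] over
#'   the cells left unclassified by the two-step procedure (needs >= 4 such
#'   cells).
#' @param out_dir Optional output directory.
#' @return List with `cells`, `summary`, `config` and (optionally)
#'   `similarity`, `rules`.
#' @export
run_pipeline <- function(responses, stimuli = make_stimulus_set(4),
                         config = plaid_config(), baseline_sd = NULL,
                         similarity = FALSE, out_dir = NULL) {
  if (is.character(responses)) responses <- read_responses(responses, stimuli)
  if (nrow(responses) == 0) {
    out <- list(cells = data.frame(), summary = list(n_total = 0,
                n_selective = 0), config = unclass(config))
    if (!is.null(out_dir)) write_report(out, out_dir)
    return(out)
  }
  cells <- classify_cells(responses, stimuli, config, baseline_sd)
  out <- list(cells = cells, summary = summarize_population(cells),
              config = unclass(config))
  if (similarity) {
    uc <- cells$cell_id[cells$category == "unclassified"]
    if (length(uc) >= 4) {
      sim <- pairwise_similarity(responses, stimuli, cells = uc)
      out$similarity <- sim
      out$rules <- rules_bootstrap(sim, seed = config$seed)
    } else {
      message("similarity analysis skipped: fewer than 4 unclassified cells")
    }
  }
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

write_report <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(out$cells %||% data.frame()) > 0)
    utils::write.csv(out$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(summary = out$summary, config = out$config),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  if (!is.null(out$similarity))
    utils::write.csv(out$similarity, file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
  if (!is.null(out$rules))
    jsonlite::write_json(list(results = out$rules$results,
                              min_sufficient_n = out$rules$min_sufficient_n,
                              aggregate = out$rules$aggregate,
                              alpha = out$rules$alpha),
                         file.path(out_dir, "rules.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  invisible(out_dir)
}
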