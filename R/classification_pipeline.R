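# Two-step classification: model acceptance/ranking, then MI dominance.

# class-level responsiveness: the 2-SD rule restricted to one stimulus class
responds_to_class <- function(cell_table, stim_type, baseline_sd,
                              sd_mult = 2, trial_frac = 0.5) {
  sub <- cell_table[cell_table$stim_type == stim_type, , drop = FALSE]
  if (nrow(sub) == 0) return(FALSE)
  screen_responsive(split(sub$response_dff_pct, sub$stim_id), baseline_sd,
                    sd_mult, trial_frac)
}

mi_step <- function(mi, mi_threshold, reason_if_mid) {
  if (!is.na(mi) && mi > mi_threshold)
    list(category = "pattern_dominant", reason = "none")
  else if (!is.na(mi) && mi < -mi_threshold)
    list(category = "component_dominant", reason = "none")
  else list(category = "unclassified", reason = reason_if_mid)
}

#' Classify one cell
#'
#' Runs the full two-step decision procedure for a single screened-in cell:
#' \enumerate{
#'   \item Cells responding (2-SD criterion) to only one stimulus class skip
#'     model testing and go straight to the MI step.
#'   \item Both models are fitted ([fit_gain()]) and tested
#'     ([ks_accept()]); a degenerate gain counts as a rejection.
#'   \item Exactly one model accepted: the cell takes that model's category
#'     (`component_classified` / `pattern_classified`).
#'   \item Both accepted: Monte-Carlo likelihoods ([mc_likelihood()]) are
#'     ranked in decibans; a winner beyond the threshold takes its category,
#'     otherwise the cell falls through to the MI step
#'     (reason `indistinguishable` if MI stays inside the band).
#'   \item Both rejected: MI step (reason `both_rejected` inside the band).
#'   \item MI step: MI above `mi_threshold` gives `pattern_dominant`, below
#'     the negative threshold `component_dominant`.
#' }
#'
#' @param cell_table Trial response table rows for one cell (must contain
#'   grating and plaid rows).
#' @param stimuli Stimulus set.
#' @param config A [plaid_config()] list.
#' @param baseline_sd Baseline SD for the class-responsiveness rule (scalar);
#'   NULL uses the cell's pooled within-stimulus trial SD.
#' @param seed Optional seed for the Monte-Carlo likelihood stage.
#' @return List with `category`, `unclassified_reason`, `mi` and
#'   `diagnostics` (per-model fits, acceptance results, likelihoods,
#'   ranking).
#' @export
classify_cell <- function(cell_table, stimuli, config = plaid_config(),
                          baseline_sd = NULL, seed = NULL) {
  has_g <- any(cell_table$stim_type == "grating")
  has_p <- any(cell_table$stim_type == "plaid")
  if (!has_g || !has_p)
    stop("cell ", cell_table$cell_id[1], ": missing ",
         if (!has_g) "grating" else "plaid", " data", call. = FALSE)
  if (is.null(baseline_sd))
    baseline_sd <- pooled_trial_sd(split(cell_table$response_dff_pct,
                                         cell_table$stim_id))
  gbar <- vapply(grating_trials(cell_table, stimuli$grating_orientations),
                 mean, numeric(1))
  pbar <- vapply(plaid_trials(cell_table, stimuli$plaid_orientations),
                 mean, numeric(1))
  mi <- modulation_index(gbar, pbar)

  resp_g <- responds_to_class(cell_table, "grating", baseline_sd,
                              config$sd_mult, config$trial_frac)
  resp_p <- responds_to_class(cell_table, "plaid", baseline_sd,
                              config$sd_mult, config$trial_frac)
  diagnostics <- list(responds_grating = resp_g, responds_plaid = resp_p,
                      baseline_sd = baseline_sd)

  if (!resp_g || !resp_p) {
    # single-class responders bypass model testing entirely
    res <- mi_step(mi, config$mi_threshold, "weak_responder")
    return(c(res, list(mi = mi, diagnostics = diagnostics)))
  }

  obs <- plaid_trials(cell_table, stimuli$plaid_orientations)
  names(obs) <- as.character(stimuli$plaid_orientations)
  models <- lapply(config$models, get_model)
  names(models) <- config$models
  verdicts <- lapply(models, function(m) {
    fit <- fit_gain(m, cell_table, stimuli)
    if (fit$degenerate)
      return(list(fit = fit, accepted = FALSE, ks = NULL))
    preds <- lapply(stimuli$plaid_orientations, function(th)
      prediction_set(m, cell_table, th, stimuli, fit$k))
    names(preds) <- names(obs)
    ks <- ks_accept(preds, obs, alpha = config$alpha_ks,
                    mcc = config$mcc_variant, test = config$test_variant,
                    seed = seed)
    list(fit = fit, accepted = ks$accepted, ks = ks)
  })
  diagnostics$models <- verdicts
  accepted <- vapply(verdicts, `[[`, logical(1), "accepted")

  category <- NULL; reason <- "none"
  if (sum(accepted) == 1) {
    category <- paste0(names(which(accepted)), "_classified")
  } else if (sum(accepted) >= 2) {
    liks <- vapply(names(which(accepted)), function(nm) {
      mc_likelihood(models[[nm]], cell_table, stimuli,
                    k = verdicts[[nm]]$fit$k,
                    n_samples = config$n_mc_samples, seed = seed)$log10_lik
    }, numeric(1))
    rk <- rank_models(liks, config$deciban_threshold)
    diagnostics$log10_liks <- liks
    diagnostics$deciban_lead <- rk$deciban_lead
    if (!is.na(rk$winner)) {
      category <- paste0(rk$winner, "_classified")
    } else {
      res <- mi_step(mi, config$mi_threshold, "indistinguishable")
      category <- res$category; reason <- res$reason
    }
  } else {
    res <- mi_step(mi, config$mi_threshold, "both_rejected")
    category <- res$category; reason <- res$reason
  }
  list(category = category, reason = reason, mi = mi,
       diagnostics = diagnostics)
}

#' Classify every cell of a response table
#'
#' Applies the screening stage ([screen_cells()]) and the two-step
#' classification ([classify_cell()]) to every cell. Cells failing the
#' responsiveness or selectivity screen are `excluded`; every screened-in
#' cell lands in exactly one of `component_classified`,
#' `pattern_classified`, `component_dominant`, `pattern_dominant`,
#' `unclassified`.
#'
#' @param responses Trial response table.
#' @param stimuli Stimulus set.
#' @param config A [plaid_config()] list.
#' @param baseline_sd Scalar or per-cell named vector; NULL for the
#'   pooled-trial-SD fallback.
#' @return data.frame with one row per cell: `category`,
#'   `unclassified_reason`, screening results, MI/SI, PC classification and
#'   model diagnostics.
#' @export
classify_cells <- function(responses, stimuli = make_stimulus_set(4),
                           config = plaid_config(), baseline_sd = NULL) {
  screen <- screen_cells(responses, baseline_sd = baseline_sd,
                         alpha = config$alpha_screen,
                         sd_mult = config$sd_mult,
                         trial_frac = config$trial_frac)
  metrics <- classic_metrics(responses, stimuli,
                             alpha_pc = config$alpha_pc,
                             directional_resolution =
                               config$directional_resolution)
  rows <- lapply(seq_len(nrow(screen)), function(i) {
    cid <- screen$cell_id[i]
    sub <- responses[responses$cell_id == cid, , drop = FALSE]
    base <- data.frame(cell_id = cid, responsive = screen$responsive[i],
                       selective = screen$selective[i],
                       anova_p = screen$anova_p[i],
                       reliability = screen$reliability[i])
    if (!screen$responsive[i] || !screen$selective[i]) {
      cl <- data.frame(category = "excluded", unclassified_reason = "none",
                       mi = NA_real_, k_component = NA_real_,
                       k_pattern = NA_real_, component_accepted = NA,
                       pattern_accepted = NA, deciban_lead = NA_real_)
    } else {
      res <- classify_cell(sub, stimuli, config,
                           baseline_sd = screen$baseline_sd[i],
                           seed = if (is.null(config$seed)) NULL
                                  else config$seed + i)
      vd <- res$diagnostics$models
      getk <- function(nm) if (!is.null(vd[[nm]])) vd[[nm]]$fit$k else NA_real_
      geta <- function(nm) if (!is.null(vd[[nm]])) vd[[nm]]$accepted else NA
      cl <- data.frame(category = res$category,
                       unclassified_reason = res$reason, mi = res$mi,
                       k_component = getk("component"),
                       k_pattern = getk("pattern"),
                       component_accepted = geta("component"),
                       pattern_accepted = geta("pattern"),
                       deciban_lead = res$diagnostics$deciban_lead %||% NA_real_)
    }
    cbind(base, cl)
  })
  out <- do.call(rbind, rows)
  merge(out, metrics, by = "cell_id", sort = FALSE)
}

#' Population summary of classification results
#'
#' Counts and fractions per category over the selective (non-excluded)
#' population, plus the breakdown of unclassified reasons.
#'
#' @param classifications Output of [classify_cells()].
#' @return List with `n_total`, `n_selective`, `counts`, `fractions`
#'   (of the selective population) and `unclassified_reasons`.
#' @export
summarize_population <- function(classifications) {
  cats <- c("component_classified", "pattern_classified",
            "component_dominant", "pattern_dominant", "unclassified",
            "excluded")
  counts <- table(factor(classifications$category, levels = cats))
  sel <- classifications$category != "excluded"
  n_sel <- sum(sel)
  fractions <- if (n_sel > 0) counts[setdiff(cats, "excluded")] / n_sel
               else counts[setdiff(cats, "excluded")] * 0
  reasons <- table(factor(
    classifications$unclassified_reason[classifications$category ==
                                          "unclassified"],
    levels = c("both_rejected", "indistinguishable", "weak_responder")))
  list(n_total = nrow(classifications), n_selective = n_sel,
       counts = as.list(counts), fractions = as.list(fractions),
       unclassified_reasons = as.list(reasons))
}
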