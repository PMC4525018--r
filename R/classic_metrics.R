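#' Modulation index
#'
#' `MI = (max(pbar) - max(gbar)) / (max(pbar) + max(gbar))` over the
#' trial-averaged responses to the plaid and grating sets. Positive MI means
#' plaid-facilitated, negative plaid-suppressed. Non-positive maxima are
#' treated as zero, so a plaid-only responder has MI = +1; if both maxima are
#' non-positive the index is undefined (NA).
#'
#' @param g_means Trial-averaged grating responses.
#' @param p_means Trial-averaged plaid responses.
#' @return MI in `[-1, 1]`, or NA.
#' @export
modulation_index <- function(g_means, p_means) {
  mg <- max(c(g_means, 0))
  mp <- max(c(p_means, 0))
  if (mg == 0 && mp == 0) return(NA_real_)
  (mp - mg) / (mp + mg)
}

#' Selectivity index
#'
#' Over a vector of trial-averaged responses to one stimulus class (negative
#' responses clipped to zero):
#' `SI = 1 - (-1 + sum(s) / max(s)) / (N - 1)`.
#' SI is 1 for one-hot tuning, 0 for a flat response profile. Undefined (NA)
#' when every response is non-positive.
#'
#' @param s_means Trial-averaged responses over one stimulus class (N >= 2).
#' @return SI in `[0, 1]`, or NA.
#' @export
selectivity_index <- function(s_means) {
  n <- length(s_means)
  assert_that(n >= 2, "need >= 2 stimuli")
  s <- pmax(s_means, 0)
  if (max(s) == 0) return(NA_real_)
  1 - (-1 + sum(s) / max(s)) / (n - 1)
}

#' Classical fixed-form model predictions for partial-correlation analysis
#'
#' The partial-correlation classifier uses the fixed classical model forms:
#' the component prediction is the linear sum of the two component gratings'
#' trial-averaged responses (gain 2 in the shared-model notation) and the
#' pattern prediction is the trial-averaged response of the
#' matched-direction grating.
#'
#' @param cell_table Trial response table rows for one cell.
#' @param stimuli Stimulus set.
#' @return List with `p_means`, `pred_component`, `pred_pattern`, all indexed
#'   by plaid orientation.
#' @export
pc_predictions <- function(cell_table, stimuli) {
  gt <- grating_trials(cell_table, stimuli$grating_orientations)
  gbar <- vapply(gt, mean, numeric(1))
  pt <- plaid_trials(cell_table, stimuli$plaid_orientations)
  pbar <- vapply(pt, mean, numeric(1))
  pred_c <- vapply(as.character(stimuli$plaid_orientations), function(th) {
    sum(gbar[as.character(stimuli$component_map[[th]])])
  }, numeric(1))
  pred_p <- vapply(as.character(stimuli$plaid_orientations), function(th) {
    gbar[as.character(stimuli$pattern_map[[th]])]
  }, numeric(1))
  list(p_means = pbar, pred_component = pred_c, pred_pattern = pred_p)
}

fisher_z <- function(r, d, cap = 1 - 1e-12) {
  atanh(pmin(pmax(r, -cap), cap)) * sqrt(d)
}

#' Partial-correlation (PC) classification
#'
#' The classical component/pattern classifier. Correlates the observed
#' trial-averaged plaid responses with the fixed component and pattern model
#' predictions, partials each correlation on the other
#' (`Rc = (rho_c - rho_p * rho_pc) / sqrt((1 - rho_p^2) (1 - rho_pc^2))`,
#' symmetrically for `Rp`), Fisher-transforms them
#' (`Z = atanh(R) * sqrt(d)`), and classifies the cell as component if `Zc`
#' exceeds both the one-tailed critical value at level `alpha` and `Zp`
#' (pattern by symmetry), else leaves it unclassified.
#'
#' The degrees of freedom are `d = (number of plaid response values) - 3`.
#' Each stimulus here is orientation-collapsed (it drifts in both directions
#' within a trial), so with `directional_resolution = "direction_8"`
#' (default) every plaid value counts for its two drift directions, giving
#' `d = 5` with 4 plaids — the classical accounting; `"orientation_4"`
#' counts each orientation once (`d = 1`). The duplication leaves all
#' correlations unchanged; only `d` moves.
#'
#' @param p_means Observed trial-averaged plaid responses (>= 4 values).
#' @param pred_c,pred_p Component and pattern model predicted means.
#' @param alpha One-tailed significance level (default 0.1).
#' @param directional_resolution `"direction_8"` or `"orientation_4"`.
#' @return List of class `pc_result`: `rho_c`, `rho_p`, `rho_pc`, `R_c`,
#'   `R_p`, `Z_c`, `Z_p`, `d`, `pc_class` in
#'   `{"component", "pattern", "unclassified"}` and `reason`.
#' @export
partial_correlation_classify <- function(p_means, pred_c, pred_p, alpha = 0.1,
                                         directional_resolution =
                                           c("direction_8", "orientation_4")) {
  directional_resolution <- match.arg(directional_resolution)
  assert_that(length(p_means) >= 4, "need >= 4 plaid response values")
  n_vals <- length(p_means) * if (directional_resolution == "direction_8") 2 else 1
  d <- n_vals - 3
  assert_that(d >= 1, "degrees of freedom < 1")
  out <- list(rho_c = NA_real_, rho_p = NA_real_, rho_pc = NA_real_,
              R_c = NA_real_, R_p = NA_real_, Z_c = NA_real_, Z_p = NA_real_,
              d = d, pc_class = "unclassified", reason = NA_character_)
  if (stats::sd(p_means) == 0 || stats::sd(pred_c) == 0 ||
      stats::sd(pred_p) == 0) {
    out$reason <- "zero_variance_vector"
    return(structure(out, class = "pc_result"))
  }
  rho_c <- stats::cor(p_means, pred_c)
  rho_p <- stats::cor(p_means, pred_p)
  rho_pc <- stats::cor(pred_c, pred_p)
  # cap at +-(1 - 1e-12) so perfect correlations keep the partials defined
  # and Z stays finite (a capped large value stands in for Z = +-Inf)
  cap <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  rc <- cap(rho_c); rp <- cap(rho_p); rpc <- cap(rho_pc)
  R_c <- (rc - rp * rpc) / sqrt((1 - rp^2) * (1 - rpc^2))
  R_p <- (rp - rc * rpc) / sqrt((1 - rc^2) * (1 - rpc^2))
  Z_c <- fisher_z(R_c, d)
  Z_p <- fisher_z(R_p, d)
  crit <- stats::qnorm(1 - alpha)
  cls <- if (Z_c > crit && Z_c > Z_p) "component"
         else if (Z_p > crit && Z_p > Z_c) "pattern"
         else "unclassified"
  structure(list(rho_c = rho_c, rho_p = rho_p, rho_pc = rho_pc,
                 R_c = R_c, R_p = R_p, Z_c = Z_c, Z_p = Z_p, d = d,
                 pc_class = cls, reason = NA_character_),
            class = "pc_result")
}

#' Per-cell indices and PC classification over a response table
#'
#' @param responses Trial response table.
#' @param stimuli Stimulus set.
#' @param alpha_pc PC significance level.
#' @param directional_resolution See [partial_correlation_classify()].
#' @return data.frame with one row per cell: PC diagnostics, `pc_class`,
#'   `mi`, `si_grating`, `si_plaid`.
#' @export
classic_metrics <- function(responses, stimuli, alpha_pc = 0.1,
                            directional_resolution = "direction_8") {
  cells <- unique(responses$cell_id)
  rows <- lapply(cells, function(cid) {
    sub <- responses[responses$cell_id == cid, , drop = FALSE]
    preds <- pc_predictions(sub, stimuli)
    pc <- partial_correlation_classify(preds$p_means, preds$pred_component,
                                       preds$pred_pattern, alpha_pc,
                                       directional_resolution)
    gbar <- vapply(grating_trials(sub, stimuli$grating_orientations), mean,
                   numeric(1))
    data.frame(cell_id = cid, rho_c = pc$rho_c, rho_p = pc$rho_p,
               rho_pc = pc$rho_pc, R_c = pc$R_c, R_p = pc$R_p,
               Z_c = pc$Z_c, Z_p = pc$Z_p, d = pc$d, pc_class = pc$pc_class,
               mi = modulation_index(gbar, preds$p_means),
               si_grating = selectivity_index(gbar),
               si_plaid = selectivity_index(preds$p_means))
  })
  do.call(rbind, rows)
}
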