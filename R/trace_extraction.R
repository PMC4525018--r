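#' Extract the peak single-trial response from a dF/F trace epoch
#'
#' Returns the mean of the peak frame and its two neighbouring frames inside
#' the stimulus epoch (at 2 Hz this 3-frame average spans the 1.5 s window
#' around the peak fluorescence change), minus the mean pre-stimulus
#' fluorescence. When the peak frame sits on an epoch boundary the 3-frame
#' window is shifted inward so that all three frames lie inside the epoch and
#' include the peak; when several frames tie for the maximum (a plateau), the
#' tied frame whose window mean is largest defines the peak.
#'
#' @param trace Numeric dF/F vector.
#' @param onset_s,offset_s Epoch boundaries in seconds.
#' @param frame_rate Frames per second.
#' @param prestim_window_s Length of the pre-stimulus baseline window
#'   immediately preceding the epoch (seconds); defaults to 2 s. A window
#'   falling before the start of the trace is truncated; an empty window
#'   contributes a baseline of 0.
#' @return Peak response (dF/F %), baseline-subtracted.
#' @export
extract_peak_response <- function(trace, onset_s, offset_s, frame_rate,
                                  prestim_window_s = 2) {
  on <- floor(onset_s * frame_rate) + 1L
  off <- min(floor(offset_s * frame_rate), length(trace))
  assert_that(on >= 1 && off <= length(trace) && off >= on,
              "epoch lies outside the trace")
  n_ep <- off - on + 1L
  if (n_ep < 3L) stop("invalid epoch: fewer than 3 frames", call. = FALSE)
  ep <- trace[on:off]
  # among frames attaining the epoch maximum (ties: e.g. a plateau), take the
  # one whose clamped peak+-1 window has the largest mean
  pks <- which(ep == max(ep))
  peak_avg <- max(vapply(pks, function(pk) {
    lo <- min(max(pk - 1L, 1L), n_ep - 2L)
    mean(ep[lo:(lo + 2L)])
  }, numeric(1)))
  b_lo <- max(1L, on - round(prestim_window_s * frame_rate))
  baseline <- if (b_lo <= on - 1L) mean(trace[b_lo:(on - 1L)]) else 0
  peak_avg - baseline
}

#' Convert rendered traces into a trial response table
#'
#' Applies [extract_peak_response()] to every (cell, epoch) of a trace set in
#' the format produced by [render_traces()].
#'
#' @param traceset List with `traces`, `schedule`, `frame_rate` (see
#'   [render_traces()]).
#' @param prestim_window_s Baseline window, see [extract_peak_response()].
#' @return Trial response table (data.frame with `cell_id`, `stim_id`,
#'   `stim_type`, `orientation_deg`, `trial_idx`, `response_dff_pct`).
#' @export
extract_responses <- function(traceset, prestim_window_s = 2) {
  sched <- traceset$schedule
  fr <- traceset$frame_rate
  out <- lapply(names(traceset$traces), function(cid) {
    tr <- traceset$traces[[cid]]
    vals <- mapply(function(on, off) {
      extract_peak_response(tr, on, off, fr, prestim_window_s)
    }, sched$onset_s, sched$offset_s)
    data.frame(cell_id = cid, stim_id = sched$stim_id,
               stim_type = ifelse(startsWith(sched$stim_id, "g"),
                                  "grating", "plaid"),
               orientation_deg = as.numeric(sub("^[gp]", "", sched$stim_id)),
               trial_idx = sched$trial_idx,
               response_dff_pct = vals)
  })
  do.call(rbind, out)
}

#' Responsiveness screen (2-SD baseline criterion)
#'
#' A cell is responsive if, for at least one stimulus, strictly more than
#' `trial_frac` of its trials exceed `sd_mult` times the baseline SD.
#'
#' @param responses_by_stim Named list of numeric vectors: single-trial peak
#'   responses per stimulus.
#' @param baseline_sd Baseline standard deviation (dF/F %), > 0.
#' @param sd_mult Threshold multiplier (default 2).
#' @param trial_frac Fraction of trials that must exceed the threshold
#'   (strict inequality; default 0.5).
#' @return Logical.
#' @export
screen_responsive <- function(responses_by_stim, baseline_sd, sd_mult = 2,
                              trial_frac = 0.5) {
  assert_that(length(baseline_sd) == 1L && is.finite(baseline_sd) &&
                baseline_sd > 0, "`baseline_sd` must be a positive scalar")
  any(vapply(responses_by_stim, function(v) {
    length(v) > 0 && mean(v > sd_mult * baseline_sd) > trial_frac
  }, logical(1)))
}

#' Selectivity screen (one-way ANOVA over all stimuli)
#'
#' One-way ANOVA on single-trial peak responses grouped by stimulus, over
#' gratings and plaids together; the cell is selective if p < `alpha`.
#'
#' @param responses Numeric vector of single-trial responses.
#' @param stim Stimulus label per response (factor or character).
#' @param alpha Significance threshold (default 0.05).
#' @return List with `selective` (logical) and `p` (ANOVA p-value). Fully
#'   degenerate input (zero variance everywhere, equal means) gives p = 1.
#' @export
screen_selective <- function(responses, stim, alpha = 0.05) {
  stim <- factor(stim)
  assert_that(nlevels(stim) >= 2, "need >= 2 stimuli")
  assert_that(all(table(stim) >= 2), "need >= 2 trials per stimulus")
  mu <- tapply(responses, stim, mean)
  ss_between <- sum(tapply(responses, stim, length) * (mu - mean(responses))^2)
  ss_within <- sum((responses - mu[stim])^2)
  if (ss_within <= .Machine$double.eps * sum(responses^2)) {
    p <- if (ss_between <= .Machine$double.eps * max(1, sum(responses^2))) 1 else 0
  } else {
    df1 <- nlevels(stim) - 1
    df2 <- length(responses) - nlevels(stim)
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(selective = p < alpha, p = p)
}

#' Trial-to-trial response reliability
#'
#' Mean Pearson correlation between the per-stimulus response vectors of
#' every pair of complete trials. Pairs involving a zero-variance trial
#' vector are excluded (their count is returned as attribute `n_dropped`).
#'
#' @param cell_table Trial response table rows for one cell.
#' @return Mean pairwise correlation in `[-1, 1]` (NA if no valid pair),
#'   with attribute `n_dropped`.
#' @export
reliability <- function(cell_table) {
  m <- stats::xtabs(response_dff_pct ~ stim_id + trial_idx, data = cell_table)
  counts <- stats::xtabs(~ stim_id + trial_idx, data = cell_table)
  complete <- colSums(counts > 0) == nrow(counts)
  m <- m[, complete, drop = FALSE]
  if (ncol(m) < 2) {
    out <- NA_real_
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  pairs <- utils::combn(ncol(m), 2)
  r <- apply(pairs, 2, function(ij) {
    a <- m[, ij[1]]; b <- m[, ij[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  })
  out <- mean(r, na.rm = TRUE)
  if (is.nan(out)) out <- NA_real_
  attr(out, "n_dropped") <- sum(is.na(r))
  out
}

#' Screen every cell of a response table
#'
#' Computes responsiveness, selectivity (ANOVA) and reliability per cell.
#' The responsiveness criterion needs a baseline SD; when none is supplied it
#' falls back to the cell's pooled within-stimulus trial SD (the trial-noise
#' estimate), which matches the gray-screen baseline SD for the synthetic
#' generator's noise model.
#'
#' @param responses Trial response table.
#' @param baseline_sd Baseline SD: a scalar, a named vector (per cell), or
#'   NULL for the pooled-trial-SD fallback.
#' @param alpha ANOVA significance threshold.
#' @param sd_mult,trial_frac See [screen_responsive()].
#' @return data.frame: `cell_id`, `responsive`, `selective`, `anova_p`,
#'   `reliability`, `baseline_sd`.
#' @export
screen_cells <- function(responses, baseline_sd = NULL, alpha = 0.05,
                         sd_mult = 2, trial_frac = 0.5) {
  cells <- unique(responses$cell_id)
  rows <- lapply(cells, function(cid) {
    sub <- responses[responses$cell_id == cid, , drop = FALSE]
    by_stim <- split(sub$response_dff_pct, sub$stim_id)
    bsd <- if (is.null(baseline_sd)) pooled_trial_sd(by_stim)
           else if (length(baseline_sd) > 1) unname(baseline_sd[cid])
           else baseline_sd
    resp <- screen_responsive(by_stim, bsd, sd_mult, trial_frac)
    sel <- screen_selective(sub$response_dff_pct, sub$stim_id, alpha)
    rel <- reliability(sub)
    data.frame(cell_id = cid, responsive = resp, selective = sel$selective,
               anova_p = sel$p, reliability = as.numeric(rel),
               baseline_sd = bsd)
  })
  do.call(rbind, rows)
}

# pooled within-stimulus trial SD: the default baseline proxy for table-only
# input, where no gray-screen segment exists to measure the baseline from
pooled_trial_sd <- function(by_stim) {
  vars <- vapply(by_stim, function(v) {
    if (length(v) >= 2) stats::var(v) else NA_real_
  }, numeric(1))
  dfs <- vapply(by_stim, function(v) max(length(v) - 1, 0), numeric(1))
  sqrt(sum(vars * dfs, na.rm = TRUE) / sum(dfs[!is.na(vars)]))
}
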