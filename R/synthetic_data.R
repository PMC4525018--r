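#' Circular-Gaussian orientation tuning curve
#'
#' Mean response of a tuned cell at orientation(s) `theta`, with a Gaussian
#' profile in circular orientation distance (180-degree domain).
#'
#' @param theta Orientation(s) in degrees.
#' @param pref Preferred orientation in degrees.
#' @param peak Peak response (dF/F %).
#' @param bandwidth_deg Tuning width (SD of the Gaussian profile, degrees).
#' @return Numeric vector of mean responses.
#' @export
tuning_curve <- function(theta, pref, peak, bandwidth_deg) {
  d <- orientation_dist(theta, pref)
  peak * exp(-d^2 / (2 * bandwidth_deg^2))
}

new_ground_truth_cell <- function(cell_id, true_class, grating_tuning,
                                  plaid_tuning, gain_k, noise_sd, pref) {
  assert_that(all(noise_sd > 0), "noise_sd must be positive")
  structure(list(cell_id = cell_id, true_class = true_class,
                 grating_tuning = grating_tuning, plaid_tuning = plaid_tuning,
                 gain_k = gain_k, noise_sd = noise_sd, pref = pref),
            class = "ground_truth_cell")
}

#' Generate a synthetic population with known response classes
#'
#' Draws ground-truth cells of six response classes over a grating/plaid
#' stimulus set. Grating tuning follows a circular-Gaussian profile; plaid
#' tuning is derived from the class-defining rule:
#' \describe{
#'   \item{component}{plaid mean = `k * (g1 + g2) / 2` over the plaid's two
#'     component gratings; single-trial plaid noise follows the model's own
#'     process, so the plaid trial SD is `k * noise_sd / sqrt(2)`.}
#'   \item{pattern}{plaid mean = `k * g` at the plaid's pattern direction;
#'     plaid trial SD is `k * noise_sd`.}
#'   \item{component_dominant}{tuned grating responses, flat weak plaid
#'     responses (`dominant_ratio` of the peak), giving MI well below -0.33.}
#'   \item{pattern_dominant}{the mirror image.}
#'   \item{complex}{independently tuned grating and plaid responses (plaid
#'     tuning unpredictable from grating tuning).}
#'   \item{unselective}{flat weak responses to everything.}
#' }
#'
#' @param n_cells Number of cells.
#' @param class_mix Named non-negative weights over the six classes; converted
#'   to counts by largest remainder. Defaults to an even mix.
#' @param stimuli A [make_stimulus_set()] object.
#' @param peak_dff Peak mean response of tuned cells (dF/F %).
#' @param bandwidth_deg Grating tuning width (degrees).
#' @param gain_range Range from which each cell's gain `k` is drawn uniformly.
#' @param noise_sd Trial-to-trial SD of grating responses (dF/F %).
#' @param dominant_ratio Flat response level of the non-preferred stimulus
#'   class for *-dominant cells, as a fraction of `peak_dff`.
#' @param unselective_level Flat response level of unselective cells, as a
#'   fraction of `peak_dff`.
#' @param seed Optional integer seed; the population is a pure function of
#'   the arguments and the seed.
#' @return List of `ground_truth_cell` objects, with attribute `stimuli`.
#' @export
make_population <- function(n_cells = 60,
                            class_mix = c(component = 1, pattern = 1,
                                          component_dominant = 1,
                                          pattern_dominant = 1,
                                          complex = 1, unselective = 1),
                            stimuli = make_stimulus_set(4),
                            peak_dff = 20, bandwidth_deg = 30,
                            gain_range = c(0.8, 1.25), noise_sd = 2,
                            dominant_ratio = 0.1, unselective_level = 0.05,
                            seed = NULL) {
  classes <- c("component", "pattern", "component_dominant",
               "pattern_dominant", "complex", "unselective")
  assert_that(all(names(class_mix) %in% classes) && all(class_mix >= 0) &&
                sum(class_mix) > 0, "invalid `class_mix`")
  assert_that(noise_sd > 0, "`noise_sd` must be positive")
  mix <- stats::setNames(rep(0, length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  frac <- mix / sum(mix)
  counts <- floor(frac * n_cells)
  rem <- n_cells - sum(counts)
  if (rem > 0) {
    extra <- order(frac * n_cells - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  cell_classes <- rep(classes, counts)

  gang <- stimuli$grating_orientations
  pang <- stimuli$plaid_orientations
  gid <- grating_stim_id(gang)
  pid <- plaid_stim_id(pang)

  with_seed(seed, {
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cls <- cell_classes[i]
      pref <- stats::runif(1, 0, 180)
      k <- stats::runif(1, gain_range[1], gain_range[2])
      gcurve <- function(th) tuning_curve(th, pref, peak_dff, bandwidth_deg)
      g <- gcurve(gang)
      sd_g <- rep(noise_sd, length(gang))
      if (cls == "component") {
        p <- vapply(pang, function(th) {
          comp <- stimuli$component_map[[as.character(th)]]
          k * mean(gcurve(comp))
        }, numeric(1))
        sd_p <- rep(k * noise_sd / sqrt(2), length(pang))
      } else if (cls == "pattern") {
        p <- vapply(pang, function(th) k * gcurve(th), numeric(1))
        sd_p <- rep(k * noise_sd, length(pang))
      } else if (cls == "component_dominant") {
        p <- rep(dominant_ratio * peak_dff, length(pang))
        sd_p <- rep(noise_sd, length(pang))
      } else if (cls == "pattern_dominant") {
        g <- rep(dominant_ratio * peak_dff, length(gang))
        p <- tuning_curve(pang, pref, peak_dff, bandwidth_deg)
        sd_p <- rep(noise_sd, length(pang))
      } else if (cls == "complex") {
        pref2 <- stats::runif(1, 0, 180)
        amp2 <- stats::runif(1, 0.6, 1) * peak_dff
        p <- tuning_curve(pang, pref2, amp2, bandwidth_deg)
        sd_p <- rep(noise_sd, length(pang))
      } else { # unselective
        g <- rep(unselective_level * peak_dff, length(gang))
        p <- rep(unselective_level * peak_dff, length(pang))
        sd_p <- rep(noise_sd, length(pang))
      }
      cells[[i]] <- new_ground_truth_cell(
        cell_id = sprintf("cell%03d", i), true_class = cls,
        grating_tuning = stats::setNames(g, gid),
        plaid_tuning = stats::setNames(p, pid),
        gain_k = k,
        noise_sd = stats::setNames(c(sd_g, sd_p), c(gid, pid)),
        pref = pref)
    }
    attr(cells, "stimuli") <- stimuli
    cells
  })
}

#' Ground-truth table for a synthetic population
#'
#' @param cells List of `ground_truth_cell` objects from [make_population()].
#' @return data.frame with one row per cell: `cell_id`, `true_class`,
#'   `gain_k`, and one column of mean response per stimulus.
#' @export
ground_truth_table <- function(cells) {
  rows <- lapply(cells, function(cl) {
    data.frame(cell_id = cl$cell_id, true_class = cl$true_class,
               gain_k = cl$gain_k,
               as.list(c(cl$grating_tuning, cl$plaid_tuning)),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample single-trial responses for one ground-truth cell
#'
#' Each trial response is an independent Normal draw with mean equal to the
#' cell's tuning value for the stimulus and SD equal to the cell's
#' per-stimulus `noise_sd`. Negative draws are kept (dF/F amplitudes can be
#' negative after baseline subtraction).
#'
#' @param cell A `ground_truth_cell`.
#' @param stimuli The matching [make_stimulus_set()] object.
#' @param n_trials Trials per stimulus (>= 1).
#' @param seed Optional seed; identical seeds give identical tables.
#' @return data.frame with columns `cell_id`, `stim_id`, `stim_type`,
#'   `orientation_deg`, `trial_idx`, `response_dff_pct`.
#' @export
sample_cell_responses <- function(cell, stimuli, n_trials = 5, seed = NULL) {
  assert_that(n_trials >= 1, "`n_trials` must be >= 1")
  gang <- stimuli$grating_orientations
  pang <- stimuli$plaid_orientations
  ids <- c(grating_stim_id(gang), plaid_stim_id(pang))
  types <- rep(c("grating", "plaid"), c(length(gang), length(pang)))
  oris <- c(gang, pang)
  means <- c(cell$grating_tuning, cell$plaid_tuning)[ids]
  sds <- cell$noise_sd[ids]
  with_seed(seed, {
    vals <- stats::rnorm(length(ids) * n_trials,
                         mean = rep(means, each = n_trials),
                         sd = rep(sds, each = n_trials))
    data.frame(cell_id = cell$cell_id,
               stim_id = rep(ids, each = n_trials),
               stim_type = rep(types, each = n_trials),
               orientation_deg = rep(oris, each = n_trials),
               trial_idx = rep(seq_len(n_trials), length(ids)),
               response_dff_pct = vals)
  })
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: generates a population with [make_population()] and
#' samples a single-trial response table for every cell. All randomness flows
#' from `seed`; regenerating with the same arguments reproduces the responses
#' bit for bit.
#'
#' @param n_cells,class_mix,stimuli,noise_sd,seed See [make_population()].
#' @param n_trials Trials per stimulus (default 5, the minimum trial count of
#'   the imaging paradigm).
#' @param ... Further arguments passed to [make_population()].
#' @return List with `cells` (ground truth), `responses` (trial response
#'   table), `stimuli` and `seed`.
#' @export
simulate_dataset <- function(n_cells = 60,
                             class_mix = c(component = 1, pattern = 1,
                                           component_dominant = 1,
                                           pattern_dominant = 1,
                                           complex = 1, unselective = 1),
                             stimuli = make_stimulus_set(4), n_trials = 5,
                             noise_sd = 2, seed = NULL, ...) {
  with_seed(seed, {
    cells <- make_population(n_cells = n_cells, class_mix = class_mix,
                             stimuli = stimuli, noise_sd = noise_sd,
                             seed = NULL, ...)
    responses <- do.call(rbind, lapply(cells, sample_cell_responses,
                                       stimuli = stimuli,
                                       n_trials = n_trials, seed = NULL))
    list(cells = cells, responses = responses, stimuli = stimuli, seed = seed)
  })
}

#' Render dF/F traces from a trial response table
#'
#' Builds per-cell calcium-like dF/F time series realizing each tabulated
#' single-trial response as a stimulus-locked transient, separated by
#' gray-screen gaps carrying baseline noise only. The transient rises over
#' two frames, peaks for one frame and decays exponentially with time
#' constant `decay_tau`; its amplitude is scaled so that the 3-frame peak
#' average extracted by [extract_peak_response()] recovers the tabulated
#' response exactly when `baseline_sd = 0` (positive responses; negative
#' responses do not round-trip since the epoch peak then sits off the
#' transient).
#'
#' @param responses Trial response table (see [sample_cell_responses()]).
#' @param frame_rate Imaging frame rate in Hz (default 2).
#' @param epoch_s Stimulus epoch duration in seconds (default 4: two drift
#'   directions at 2 s each).
#' @param gap_s Gray-screen gap between epochs in seconds (default 5).
#' @param decay_tau Transient decay time constant in seconds (> 0).
#' @param baseline_sd SD of additive Gaussian baseline noise (dF/F %).
#' @param seed Optional seed for the baseline noise.
#' @return List with `traces` (named list of numeric dF/F vectors, one per
#'   cell), `schedule` (data.frame: `stim_id`, `trial_idx`, `onset_s`,
#'   `offset_s`) shared by all cells, and `frame_rate`.
#' @export
render_traces <- function(responses, frame_rate = 2, epoch_s = 4, gap_s = 5,
                          decay_tau = 1, baseline_sd = 0, seed = NULL) {
  assert_that(frame_rate > 0, "`frame_rate` must be > 0")
  assert_that(epoch_s > 0 && gap_s > 0, "`epoch_s` and `gap_s` must be > 0")
  assert_that(decay_tau > 0, "`decay_tau` must be > 0")
  ep_frames <- round(epoch_s * frame_rate)
  gap_frames <- round(gap_s * frame_rate)
  assert_that(ep_frames >= 4, "epoch too short: need >= 4 frames")

  # one shared presentation schedule: trials in order, stimuli within trial
  stim_ids <- unique(responses$stim_id)
  trials <- sort(unique(responses$trial_idx))
  sched <- expand.grid(stim_id = stim_ids, trial_idx = trials,
                       stringsAsFactors = FALSE)
  sched <- sched[order(sched$trial_idx), , drop = FALSE]
  n_ep <- nrow(sched)
  onset_fr <- gap_frames + (seq_len(n_ep) - 1) * (ep_frames + gap_frames) + 1
  sched$onset_s <- (onset_fr - 1) / frame_rate
  sched$offset_s <- sched$onset_s + ep_frames / frame_rate
  total_frames <- n_ep * (ep_frames + gap_frames) + gap_frames

  # transient shape: q^2, q, 1, q, q^2, ... peak at epoch frame 3
  q <- exp(-1 / (frame_rate * decay_tau))
  shape <- c(q^2, q, 1, q^seq_len(ep_frames - 3))

  key <- paste(responses$stim_id, responses$trial_idx)
  skey <- paste(sched$stim_id, sched$trial_idx)
  cells <- unique(responses$cell_id)
  traces <- with_seed(seed, {
    lapply(stats::setNames(cells, cells), function(cid) {
      sub <- responses[responses$cell_id == cid, , drop = FALSE]
      amp <- sub$response_dff_pct[match(skey, paste(sub$stim_id, sub$trial_idx))]
      tr <- numeric(total_frames)
      for (e in seq_len(n_ep)) {
        if (is.na(amp[e])) next
        a <- 3 * amp[e] / (1 + 2 * q)
        idx <- onset_fr[e] + seq_along(shape) - 1
        tr[idx] <- tr[idx] + a * shape
      }
      if (baseline_sd > 0) tr <- tr + stats::rnorm(total_frames, 0, baseline_sd)
      tr
    })
  })
  list(traces = traces,
       schedule = sched[, c("stim_id", "trial_idx", "onset_s", "offset_s")],
       frame_rate = frame_rate)
}
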