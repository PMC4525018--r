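# Shared fixture builders and independent oracles.

ss4 <- make_stimulus_set(4)
GID <- paste0("g", ss4$grating_orientations)
PID <- paste0("p", ss4$plaid_orientations)

# a ground-truth cell with explicit tuning vectors
make_cell <- function(g, p, sd = 2, k = 1, id = "c1", class = "complex") {
  if (length(sd) == 1) sd <- rep(sd, 8)
  structure(list(cell_id = id, true_class = class,
                 grating_tuning = stats::setNames(g, GID),
                 plaid_tuning = stats::setNames(p, PID),
                 gain_k = k, noise_sd = stats::setNames(sd, c(GID, PID)),
                 pref = 0),
            class = "ground_truth_cell")
}

# a response table whose trial means are exactly the given tuning values
# (one trial per stimulus)
mean_table <- function(g, p, id = "c1") {
  data.frame(cell_id = id,
             stim_id = c(GID, PID),
             stim_type = rep(c("grating", "plaid"), each = 4),
             orientation_deg = rep(ss4$grating_orientations, 2),
             trial_idx = 1L,
             response_dff_pct = c(g, p))
}

# independent 1-D SSE minimizer for the model gain: staged grid refinement,
# final resolution < 1e-7
grid_gain_oracle <- function(b, pbar, lo = -6, hi = 6) {
  sse <- function(k) sum((k * b - pbar)^2)
  for (pass in 1:4) {
    ks <- seq(lo, hi, length.out = 201)
    vals <- vapply(ks, sse, numeric(1))
    i <- which.min(vals)
    step <- ks[2] - ks[1]
    lo <- ks[i] - step
    hi <- ks[i] + step
  }
  (lo + hi) / 2
}

# independent partial correlation: correlation of residuals after regressing
# each variable on the control
residual_partial_cor <- function(x, y, z) {
  rx <- stats::resid(stats::lm(x ~ z))
  ry <- stats::resid(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# ground-truth class lookup for a simulated dataset
truth_of <- function(ds) {
  stats::setNames(vapply(ds$cells, `[[`, character(1), "true_class"),
                  vapply(ds$cells, `[[`, character(1), "cell_id"))
}

expected_category <- c(component = "component_classified",
                       pattern = "pattern_classified",
                       component_dominant = "component_dominant",
                       pattern_dominant = "pattern_dominant")
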