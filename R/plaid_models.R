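#' Predictive plaid-response models
#'
#' A plaid model predicts a neuron's single-trial response to a plaid from
#' single-trial responses to one or more of its grating inputs, with a single
#' per-cell gain `k`. Two models are built in:
#' \describe{
#'   \item{component}{`p = k * (g1 + g2) / 2` over the plaid's two component
#'     gratings; `k = 2` recovers the classical linear-sum component cell,
#'     `k = 1` the mean of the components.}
#'   \item{pattern}{`p = k * g` for the grating drifting in the plaid's
#'     pattern direction.}
#' }
#' Any alternative model can be registered with [register_model()]; it must
#' be commutative over its grating inputs.
#'
#' @param name Model name.
#' @param arity Number of grating inputs consumed per prediction.
#' @param input_orientations Function `(plaid_angle, stimuli)` returning the
#'   grating orientations the model consumes for that plaid.
#' @param predict Function `(trials, k)` where `trials` is a list of `arity`
#'   numeric vectors of single-trial grating responses; must return the full
#'   combination set of predictions.
#' @return An object of class `plaid_model`.
#' @export
plaid_model <- function(name, arity, input_orientations, predict) {
  assert_that(is.function(predict) && is.function(input_orientations),
              "`predict` and `input_orientations` must be functions")
  structure(list(name = name, arity = arity,
                 input_orientations = input_orientations, predict = predict),
            class = "plaid_model")
}

#' Component-model single-trial predictions
#'
#' All-combination prediction set `{k * (a + b) / 2}` over the two component
#' gratings' trials; commutative in its inputs and of size `T1 * T2`.
#'
#' @param g1_trials,g2_trials Single-trial responses to the two component
#'   gratings (non-empty numeric vectors).
#' @param k Gain.
#' @return Numeric vector of predictions.
#' @export
component_predict <- function(g1_trials, g2_trials, k) {
  if (length(g1_trials) == 0 || length(g2_trials) == 0)
    stop("missing grating trials for a component-model input", call. = FALSE)
  assert_that(is.finite(k), "`k` must be finite")
  as.vector(k * outer(g1_trials, g2_trials, "+") / 2)
}

#' Pattern-model single-trial predictions
#'
#' `{k * a}` over the trials of the grating drifting in the plaid's pattern
#' direction (size `T`).
#'
#' @param g3_trials Single-trial responses to the matched-direction grating.
#' @param k Gain.
#' @return Numeric vector of predictions.
#' @export
pattern_predict <- function(g3_trials, k) {
  if (length(g3_trials) == 0)
    stop("missing grating trials for the pattern-model input", call. = FALSE)
  assert_that(is.finite(k), "`k` must be finite")
  k * g3_trials
}

#' @rdname plaid_model
#' @export
component_model <- function() {
  plaid_model(
    name = "component", arity = 2,
    input_orientations = function(plaid_angle, stimuli) {
      ori <- stimuli$component_map[[as.character(plaid_angle)]]
      if (is.null(ori)) stop("plaid angle ", plaid_angle,
                             " not in stimulus set", call. = FALSE)
      ori
    },
    predict = function(trials, k) component_predict(trials[[1]], trials[[2]], k))
}

#' @rdname plaid_model
#' @export
pattern_model <- function() {
  plaid_model(
    name = "pattern", arity = 1,
    input_orientations = function(plaid_angle, stimuli) {
      ori <- stimuli$pattern_map[[as.character(plaid_angle)]]
      if (is.null(ori)) stop("pattern-direction grating for plaid ",
                             plaid_angle, " absent from stimulus set",
                             call. = FALSE)
      ori
    },
    predict = function(trials, k) pattern_predict(trials[[1]], k))
}

.model_registry <- new.env(parent = emptyenv())

#' Model registry
#'
#' The registry maps model names to [plaid_model()] objects so that
#' classification configs can address models by name. `component` and
#' `pattern` are pre-registered.
#'
#' @param model A `plaid_model`.
#' @param name Model name.
#' @return `register_model()` returns the model invisibly; `get_model()` the
#'   named model; `list_models()` the registered names.
#' @export
register_model <- function(model) {
  assert_that(inherits(model, "plaid_model"), "not a `plaid_model`")
  assign(model$name, model, envir = .model_registry)
  invisible(model)
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  if (!exists(name, envir = .model_registry))
    stop("unknown model: ", name, call. = FALSE)
  get(name, envir = .model_registry)
}

#' @rdname register_model
#' @export
list_models <- function() ls(.model_registry)

# grating trials per orientation for one cell, as a named list
grating_trials <- function(cell_table, orientations) {
  g <- cell_table[cell_table$stim_type == "grating", , drop = FALSE]
  lapply(stats::setNames(orientations, orientations), function(o) {
    g$response_dff_pct[g$orientation_deg == o]
  })
}

plaid_trials <- function(cell_table, orientations) {
  p <- cell_table[cell_table$stim_type == "plaid", , drop = FALSE]
  lapply(stats::setNames(orientations, orientations), function(o) {
    p$response_dff_pct[p$orientation_deg == o]
  })
}

# model base predictions at k = 1, from per-orientation trial means
model_base_means <- function(model, cell_table, stimuli) {
  gt <- grating_trials(cell_table, stimuli$grating_orientations)
  gbar <- vapply(gt, mean, numeric(1))
  vapply(stimuli$plaid_orientations, function(th) {
    ori <- model$input_orientations(th, stimuli)
    mean(gbar[as.character(ori)])
  }, numeric(1))
}

#' Fit the per-cell model gain
#'
#' Least-squares gain shared across all of a cell's plaid stimuli: with
#' `b` the model's trial-average predictions at `k = 1` and `pbar` the
#' observed trial-average plaid responses, `k = sum(b * pbar) / sum(b^2)`,
#' the closed-form minimizer of the summed squared error. A cell whose base
#' predictions are all zero has no defined gain and the model is flagged
#' degenerate; a negative fitted gain is also flagged (it has no
#' physiological reading and signals anti-correlated predictions).
#'
#' @param model A `plaid_model`.
#' @param cell_table Trial response table rows for one cell.
#' @param stimuli The stimulus set.
#' @return List with `k`, `degenerate` (logical) and `reason` (NA or a
#'   string).
#' @export
fit_gain <- function(model, cell_table, stimuli) {
  b <- model_base_means(model, cell_table, stimuli)
  pt <- plaid_trials(cell_table, stimuli$plaid_orientations)
  if (any(vapply(pt, length, integer(1)) == 0))
    stop("missing plaid trials for gain fit", call. = FALSE)
  pbar <- vapply(pt, mean, numeric(1))
  denom <- sum(b^2)
  if (denom == 0)
    return(list(k = NA_real_, degenerate = TRUE, reason = "zero_base_prediction"))
  k <- sum(b * pbar) / denom
  list(k = k, degenerate = k < 0,
       reason = if (k < 0) "negative_gain" else NA_character_)
}

#' Single-trial prediction set for one plaid stimulus
#'
#' Applies a model to all combinations of the cell's observed single-trial
#' grating responses at the model's input orientations.
#'
#' @param model A `plaid_model`.
#' @param cell_table Trial response table rows for one cell.
#' @param plaid_angle Plaid orientation (degrees).
#' @param stimuli The stimulus set.
#' @param k Gain.
#' @return Numeric vector of predicted single-trial plaid responses.
#' @export
prediction_set <- function(model, cell_table, plaid_angle, stimuli, k) {
  ori <- model$input_orientations(plaid_angle, stimuli)
  trials <- grating_trials(cell_table, ori)
  empty <- vapply(trials, length, integer(1)) == 0
  if (any(empty))
    stop("no trials for grating orientation(s) ",
         paste(ori[empty], collapse = ", "), call. = FALSE)
  model$predict(trials, k)
}
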