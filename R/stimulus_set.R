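#' Construct the grating/plaid stimulus set
#'
#' Builds the set of grating orientations and plaid pattern-motion
#' orientations used throughout the package, together with the maps relating
#' each plaid to its two orthogonal grating components and to the grating
#' drifting in the plaid's pattern direction. Orientations live on the
#' 180-degree domain (each stimulus drifts back and forward within a trial,
#' so responses are collapsed over drift direction).
#'
#' With the default `n_orientations = 4` the gratings are 0, 45, 90 and 135
#' degrees and each plaid at orientation `theta` superimposes the gratings at
#' `theta + 45` and `theta + 135` (mod 180), which are orthogonal to each
#' other; the grating at `theta` itself drifts in the plaid's pattern
#' direction.
#'
#' @param n_orientations Number of evenly spaced grating orientations on
#'   `[0, 180)`. Must divide 180, and the spacing must divide 45 so that every
#'   plaid's component gratings are themselves presented (4 works; 3 or 5 do
#'   not).
#' @return An object of class `stimulus_set`: a list with
#'   `grating_orientations`, `plaid_orientations`, `component_map` (named list
#'   mapping each plaid orientation to its ordered pair of component grating
#'   orientations) and `pattern_map` (plaid orientation to the matched-direction
#'   grating orientation).
#' @examples
#' ss <- make_stimulus_set(4)
#' ss$component_map[["45"]]  # c(0, 90)
#' @export
make_stimulus_set <- function(n_orientations = 4) {
  assert_that(is.numeric(n_orientations) && length(n_orientations) == 1L &&
                n_orientations == round(n_orientations) && n_orientations >= 2,
              "`n_orientations` must be a single integer >= 2")
  assert_that(180 %% n_orientations == 0,
              "`n_orientations` must divide 180 evenly")
  step <- 180 / n_orientations
  assert_that(45 %% step == 0,
              paste0("with spacing ", step,
                     " deg, the plaid component orientations (+45, +135) are ",
                     "not in the presented grating set"))
  ang <- seq(0, 180 - step, by = step)
  component_map <- stats::setNames(
    lapply(ang, function(th) c((th + 45) %% 180, (th + 135) %% 180)),
    as.character(ang))
  pattern_map <- stats::setNames(as.list(ang), as.character(ang))
  structure(list(grating_orientations = ang,
                 plaid_orientations   = ang,
                 component_map        = component_map,
                 pattern_map          = pattern_map),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", length(x$grating_orientations), "gratings /",
      length(x$plaid_orientations), "plaids\n")
  cat("  grating orientations:", paste(x$grating_orientations, collapse = ", "),
      "deg\n")
  for (th in names(x$component_map))
    cat(sprintf("  plaid %s: components (%s), pattern direction %s\n", th,
                paste(x$component_map[[th]], collapse = ", "),
                x$pattern_map[[th]]))
  invisible(x)
}

grating_stim_id <- function(orientation) paste0("g", orientation)
plaid_stim_id   <- function(orientation) paste0("p", orientation)

# stim ids for one stimulus set, gratings first
all_stim_ids <- function(stimuli) {
  c(grating_stim_id(stimuli$grating_orientations),
    plaid_stim_id(stimuli$plaid_orientations))
}
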