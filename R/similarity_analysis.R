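# Pairwise grating/plaid response similarity and the "number of rules"
# bootstrap over unclassified cells.

#' Pairwise grating and plaid response similarity
#'
#' Pearson correlations between the trial-averaged grating response vectors
#' (`r_g`) and, independently, the plaid response vectors (`r_p`) of every
#' unordered cell pair. Pairs involving a zero-variance tuning vector are
#' dropped (with a message).
#'
#' @param responses Trial response table.
#' @param stimuli Stimulus set.
#' @param cells Optional subset of cell ids (default: all).
#' @return data.frame with columns `cell_i`, `cell_j`, `r_g`, `r_p`; one row
#'   per unordered pair.
#' @export
pairwise_similarity <- function(responses, stimuli, cells = NULL) {
  if (is.null(cells)) cells <- unique(responses$cell_id)
  assert_that(length(cells) >= 2, "need >= 2 cells")
  tune <- lapply(stats::setNames(cells, cells), function(cid) {
    sub <- responses[responses$cell_id == cid, , drop = FALSE]
    list(g = vapply(grating_trials(sub, stimuli$grating_orientations), mean,
                    numeric(1)),
         p = vapply(plaid_trials(sub, stimuli$plaid_orientations), mean,
                    numeric(1)))
  })
  gm <- vapply(tune, `[[`, numeric(length(stimuli$grating_orientations)), "g")
  pm <- vapply(tune, `[[`, numeric(length(stimuli$plaid_orientations)), "p")
  ok <- apply(gm, 2, stats::sd) > 0 & apply(pm, 2, stats::sd) > 0
  if (any(!ok)) {
    message("dropping ", sum(!ok), " cell(s) with zero-variance tuning: ",
            paste(cells[!ok], collapse = ", "))
    gm <- gm[, ok, drop = FALSE]; pm <- pm[, ok, drop = FALSE]
    cells <- cells[ok]
  }
  assert_that(length(cells) >= 2, "fewer than 2 cells with usable tuning")
  rg <- stats::cor(gm)
  rp <- stats::cor(pm)
  idx <- utils::combn(length(cells), 2)
  data.frame(cell_i = cells[idx[1, ]], cell_j = cells[idx[2, ]],
             r_g = rg[t(idx)], r_p = rp[t(idx)])
}

#' Two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' Fasano-Franceschini variant of Peacock's 2-D K-S test: the statistic `D`
#' is the largest difference between the two samples' point fractions over
#' the four quadrants anchored at every data point of both samples. The
#' p-value uses the standard asymptotic formula with the correlation
#' correction, on the effective sample size `n1 * n2 / (n1 + n2)`.
#'
#' @param a,b Two-column matrices (or data.frames) of 2-D points.
#' @return List with `D`, `p` and `n_effective`. Identical samples give
#'   `D = 0`, `p = 1`. A warning is issued below 10 points per sample.
#' @export
ks2d_two_sample <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(ncol(a) == 2 && ncol(b) == 2, "inputs must be 2-column")
  n1 <- nrow(a); n2 <- nrow(b)
  assert_that(n1 >= 1 && n2 >= 1, "empty sample")
  if (n1 < 10 || n2 < 10)
    warning("fewer than 10 points per sample; the p-value is unreliable",
            call. = FALSE)
  # average of the max discrepancies anchored at each sample's own points
  D <- (quadrant_max_diff(a, a, b) + quadrant_max_diff(b, a, b)) / 2
  n_eff <- n1 * n2 / (n1 + n2)
  r1 <- if (n1 > 1) stats::cor(a[, 1], a[, 2]) else 0
  r2 <- if (n2 > 1) stats::cor(b[, 1], b[, 2]) else 0
  if (!is.finite(r1)) r1 <- 0
  if (!is.finite(r2)) r2 <- 0
  rr <- sqrt(1 - mean(c(r1^2, r2^2)))
  lambda <- sqrt(n_eff) * D / (1 + rr * (0.25 - 0.75 / sqrt(n_eff)))
  list(D = D, p = q_ks(lambda), n_effective = n_eff)
}

# max over eval points of the quadrant-fraction differences between samples
quadrant_max_diff <- function(eval_pts, a, b) {
  fr <- function(s) {
    xle <- outer(eval_pts[, 1], s[, 1], ">=")
    yle <- outer(eval_pts[, 2], s[, 2], ">=")
    cbind(rowMeans(xle & yle), rowMeans(xle & !yle),
          rowMeans(!xle & yle), rowMeans(!xle & !yle))
  }
  max(abs(fr(a) - fr(b)))
}

# Kolmogorov asymptotic survival function Q_KS(lambda)
q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Minimum-number-of-rules bootstrap
#'
#' Tests whether `n` concurrent grating-to-plaid response rules suffice to
#' explain the observed joint distribution of pairwise similarities
#' `(r_g, r_p)`. For each `n` and each of `resamples` resamples, the cells
#' are randomly partitioned into `n` equal-size groups (remainder cells
#' spread one per group); within-group pairs have `r_p` set equal to `r_g`
#' (two cells obeying the same rule must be similarly similar under gratings
#' and plaids), between-group pairs are left unchanged; the resampled
#' `(r_g, r_p)` cloud is compared with the observed cloud by the 2-D
#' two-sample K-S test. A rule count `n` is insufficient when the resampled
#' distributions differ significantly from the observed one at `alpha`,
#' aggregated over resamples by the configured rule (median resample p by
#' default).
#'
#' @param sim_table Output of [pairwise_similarity()].
#' @param n_range Rule counts to test (default 1:10).
#' @param resamples Resamples per rule count (default 100).
#' @param alpha Significance level (default 0.05).
#' @param aggregate How the resample p-values become one verdict per `n`:
#'   `"median"` (default; median p < alpha), `"any"` (any p < alpha) or
#'   `"majority"` (more than half of p < alpha).
#' @param seed Optional seed.
#' @return List of class `rules_test`: data.frame `results` (`n`,
#'   `p_median`, `reject_fraction`, `rejected`, `skipped`), the per-n p-value
#'   lists in `p_values`, `min_sufficient_n` (smallest non-rejected `n`, NA
#'   if all rejected), and the settings used.
#' @export
rules_bootstrap <- function(sim_table, n_range = 1:10, resamples = 100,
                            alpha = 0.05,
                            aggregate = c("median", "any", "majority"),
                            seed = NULL) {
  aggregate <- match.arg(aggregate)
  cells <- sort(unique(c(sim_table$cell_i, sim_table$cell_j)))
  n_cells <- length(cells)
  observed <- cbind(sim_table$r_g, sim_table$r_p)
  i_idx <- match(sim_table$cell_i, cells)
  j_idx <- match(sim_table$cell_j, cells)
  with_seed(seed, {
    p_values <- lapply(n_range, function(n) {
      if (n > floor(n_cells / 2)) return(NULL)  # groups would have < 2 cells
      vapply(seq_len(resamples), function(r) {
        grp <- sample(rep_len(seq_len(n), n_cells))
        same <- grp[i_idx] == grp[j_idx]
        resampled <- observed
        resampled[same, 2] <- resampled[same, 1]
        suppressWarnings(ks2d_two_sample(resampled, observed)$p)
      }, numeric(1))
    })
    names(p_values) <- as.character(n_range)
    results <- do.call(rbind, lapply(seq_along(n_range), function(i) {
      p <- p_values[[i]]
      if (is.null(p))
        return(data.frame(n = n_range[i], p_median = NA_real_,
                          reject_fraction = NA_real_, rejected = NA,
                          skipped = TRUE))
      rej <- switch(aggregate,
                    median = stats::median(p) < alpha,
                    any = any(p < alpha),
                    majority = mean(p < alpha) > 0.5)
      data.frame(n = n_range[i], p_median = stats::median(p),
                 reject_fraction = mean(p < alpha), rejected = rej,
                 skipped = FALSE)
    }))
    ok <- results$n[!results$skipped & !results$rejected]
    structure(list(results = results, p_values = p_values,
                   min_sufficient_n = if (length(ok)) min(ok) else NA_integer_,
                   alpha = alpha, aggregate = aggregate,
                   resamples = resamples, n_cells = n_cells),
              class = "rules_test")
  })
}

#' @export
print.rules_test <- function(x, ...) {
  cat("Number-of-rules bootstrap over", x$n_cells, "cells (",
      x$resamples, "resamples/n, aggregate =", x$aggregate, ")\n")
  print(x$results, row.names = FALSE)
  cat("minimum sufficient number of rules:", x$min_sufficient_n, "\n")
  invisible(x)
}
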