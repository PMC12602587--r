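# Factorial simulation harness comparing corrected with uncorrected
# estimation after sum-score selection.

#' Enumerate the simulation design
#'
#' The full factorial grid of post-selection sample sizes, cutoffs and
#' replicates, with the per-run bookkeeping: for `k > 0` each run estimates
#' six networks (three estimators, corrected and uncorrected); for `k = 0`
#' corrected and uncorrected coincide, so three networks are estimated.
#'
#' @param n post-selection sample sizes (default `c(500, 1000, 2500, 5000)`).
#' @param k sum-score cutoffs (default `c(0, 2, 5)`).
#' @param reps replicates per (n, k) condition (default 100).
#' @param estimators estimator labels (default all three).
#' @return a data frame with one row per (n, k, replicate) run, a
#'   `networks_per_run` column, and attribute `n_runs`.
#' @examples
#' nrow(study_grid()) # 1200 runs in the default design
#' @export
study_grid <- function(n = c(500L, 1000L, 2500L, 5000L),
                       k = c(0L, 2L, 5L),
                       reps = 100L,
                       estimators = c("elasso", "nodewise", "multivariate")) {
  grid <- expand.grid(replicate = seq_len(reps), k = as.integer(k),
                      n = as.integer(n), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("n", "k", "replicate")]
  grid$networks_per_run <- ifelse(grid$k == 0L, length(estimators),
                                  2L * length(estimators))
  attr(grid, "n_runs") <- nrow(grid)
  attr(grid, "estimators") <- estimators
  grid
}

# Deterministic per-replicate seed: a multiplicative mix of the base seed
# with the condition, kept inside 32-bit integer range so that replicates
# are schedule-invariant and independent of grid ordering.
#' @keywords internal
#' @noRd
replicate_seed <- function(base_seed, n, k, replicate) {
  mix <- function(s, x) (s * 69069 + x + 1) %% 2147483647
  s <- mix(base_seed %% 2147483647, 0)
  for (x in c(n, k, replicate)) s <- mix(s, x)
  as.integer(s)
}

#' @keywords internal
#' @noRd
fit_one <- function(data, k, estimator, corrected, alpha, gamma) {
  switch(estimator,
    multivariate = ising_fit(data, k = k, method = "multivariate",
                             corrected = corrected, alpha = alpha),
    nodewise = ising_fit(data, k = k, method = "nodewise",
                         corrected = corrected, alpha = alpha),
    elasso = ising_fit(data, k = k, method = "elasso",
                       corrected = corrected, gamma = gamma)
  )
}

#' Run the simulation study
#'
#' For every (n, k, replicate) cell: draw `n` cases from the
#' sum-score-conditioned distribution of `model` at cutoff `k`
#' ([ising_sample()], so `n` is the post-selection count), fit each
#' estimator with and without the correction (corrected only, once, when
#' `k = 0`), and score all four recovery metrics against `model`.
#' Estimator failures in a replicate are recorded as missing metrics with
#' the error message, never as a crash. The whole table is a deterministic
#' function of `base_seed`.
#'
#' @param model the data-generating [ising_model].
#' @param n vector of post-selection sample sizes.
#' @param k vector of sum-score cutoffs.
#' @param reps replicates per condition.
#' @param base_seed integer seed for the whole study.
#' @param estimators subset of `c("elasso", "nodewise", "multivariate")`.
#' @param alpha significance level for thresholding/pruning.
#' @param gamma EBIC hyperparameter for the lasso estimator.
#' @return an object of class `ising_study`: a data frame with one row per
#'   replicate x estimator x corrected flag, the four metrics, the seed
#'   used, and a `failure` column (`NA` when the fit succeeded).
#' @export
run_study <- function(model,
                      n = c(500L, 1000L, 2500L, 5000L),
                      k = c(0L, 2L, 5L),
                      reps = 100L,
                      base_seed = 1L,
                      estimators = c("elasso", "nodewise", "multivariate"),
                      alpha = 0.01,
                      gamma = 0.25) {
  grid <- study_grid(n = n, k = k, reps = reps, estimators = estimators)
  rows <- vector("list", nrow(grid) * 2L * length(estimators))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    ng <- grid$n[g]
    kg <- grid$k[g]
    rep_i <- grid$replicate[g]
    seed <- replicate_seed(base_seed, ng, kg, rep_i)
    data <- ising_sample(model, n = ng, k = kg, seed = seed)
    flags <- if (kg == 0L) TRUE else c(TRUE, FALSE)
    for (est in estimators) {
      for (corrected in flags) {
        res <- tryCatch(
          {
            fit <- suppressWarnings(
              fit_one(data, kg, est, corrected, alpha, gamma)
            )
            c(recovery_metrics(model, fit), list(failure = NA_character_))
          },
          error = function(e) {
            list(total_edge_weight_error = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, prop_spurious_negative = NA_real_,
                 failure = conditionMessage(e))
          }
        )
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          n = ng, k = kg, replicate = rep_i, estimator = est,
          corrected = corrected, seed = seed,
          total_edge_weight_error = res$total_edge_weight_error,
          sensitivity = res$sensitivity,
          specificity = res$specificity,
          prop_spurious_negative = res$prop_spurious_negative,
          failure = res$failure,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  class(out) <- c("ising_study", "data.frame")
  out
}

#' Condition-level means of a simulation study
#'
#' Mean of each recovery metric over replicates, per
#' (n, k, estimator, corrected) cell, with the replicate and failure
#' counts.
#'
#' @param results an `ising_study` table from [run_study()].
#' @return a data frame of condition means.
#' @export
summarise_study <- function(results) {
  key <- interaction(results$n, results$k, results$estimator,
                     results$corrected, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    data.frame(
      n = d$n[1L], k = d$k[1L], estimator = d$estimator[1L],
      corrected = d$corrected[1L],
      reps = nrow(d),
      failures = sum(!is.na(d$failure)),
      total_edge_weight_error = mean(d$total_edge_weight_error, na.rm = TRUE),
      sensitivity = mean(d$sensitivity, na.rm = TRUE),
      specificity = mean(d$specificity, na.rm = TRUE),
      prop_spurious_negative = mean(d$prop_spurious_negative, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$estimator, out$k, out$n, !out$corrected), ]
  rownames(out) <- NULL
  out
}

#' Panel plot of condition means against sample size
#'
#' One panel per metric x cutoff, sample size on the x axis; dashed lines
#' for corrected, solid for uncorrected fits, one colour per estimator.
#'
#' @param summary a condition-mean table from [summarise_study()].
#' @param metrics which metrics to draw.
#' @export
plot_study <- function(summary,
                       metrics = c("total_edge_weight_error", "sensitivity",
                                   "specificity", "prop_spurious_negative")) {
  ks <- sort(unique(summary$k))
  ests <- sort(unique(summary$estimator))
  cols <- stats::setNames(seq_along(ests) + 1L, ests)
  old <- graphics::par(mfrow = c(length(metrics), length(ks)),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (metric in metrics) {
    for (kk in ks) {
      d <- summary[summary$k == kk, ]
      ylim <- range(summary[[metric]], na.rm = TRUE)
      graphics::plot(NA, xlim = range(d$n), ylim = ylim, log = "x",
                     xlab = "n", ylab = metric,
                     main = sprintf("k = %d", kk))
      for (est in ests) {
        for (corr in unique(d$corrected)) {
          dd <- d[d$estimator == est & d$corrected == corr, ]
          dd <- dd[order(dd$n), ]
          graphics::lines(dd$n, dd[[metric]], col = cols[[est]],
                          lty = if (corr) 2 else 1)
          graphics::points(dd$n, dd[[metric]], col = cols[[est]], pch = 16)
        }
      }
    }
  }
  invisible(summary)
}
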