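#' @keywords internal
#' @noRd
new_ising_fit <- function(method, corrected, k, k_norm, tau, omega, edge_mask,
                          alpha, gamma, loglik, converged, n, m,
                          diagnostics = list(), se = NULL, se_tau = NULL,
                          call = NULL) {
  omega[!edge_mask] <- omega[!edge_mask] * 0 # masked edges are exactly zero
  diag(omega) <- 0
  structure(
    list(
      method = method, corrected = corrected, k = k, k_norm = k_norm,
      tau = tau, omega = omega, edge_mask = edge_mask,
      alpha = alpha, gamma = gamma, loglik = loglik, converged = converged,
      n = n, m = m, se = se, se_tau = se_tau,
      diagnostics = diagnostics, call = call
    ),
    class = "ising_fit"
  )
}

#' Fit an Ising model to sum-score-selected binary data
#'
#' The main fitting front-end. Given a 0/1 data matrix whose rows were
#' retained only if their sum score reached a cutoff `k`, estimates the
#' thresholds and pairwise weights of the Ising model of the *unselected*
#' population by correcting the selection (Berkson) bias:
#' \describe{
#'   \item{`"multivariate"`}{maximum likelihood with the partition function
#'     restricted to response patterns with sum score \eqn{\ge k}
#'     (\eqn{Z^{(k)}}), followed by one pass of Wald pruning at level
#'     `alpha` and constrained re-estimation (set `prune = FALSE` to skip).}
#'   \item{`"nodewise"`}{pseudo-likelihood via per-node logistic
#'     regressions with the logically determined cases (predictor sum
#'     `k - 1`) removed; edges kept only if significant at `alpha` in both
#'     directed regressions (AND rule), weights averaged across
#'     directions.}
#'   \item{`"elasso"`}{as `"nodewise"` but each regression is an L1
#'     (lasso) path and the model minimising the extended BIC
#'     \eqn{-2\ell + d\log n' + 2\gamma d \log(m-1)} is selected; edges
#'     kept if nonzero in both directions.}
#' }
#' With `corrected = FALSE` the same machinery runs without the correction
#' (full-support normaliser, no case removal) — "estimation as usual" on
#' the selected data, the biased baseline. With `k = 0` corrected and
#' uncorrected fits coincide.
#'
#' @param data 0/1 matrix (rows: cases, columns: nodes). If it carries a
#'   `cutoff` attribute (as matrices from [ising_sample()] do), that is the
#'   default `k`.
#' @param k sum-score cutoff under which the rows were selected.
#' @param method `"multivariate"`, `"nodewise"`, or `"elasso"`.
#' @param corrected apply the selection-bias correction (default `TRUE`).
#' @param alpha two-sided significance level for pruning / the AND rule
#'   (default 0.01).
#' @param gamma EBIC hyperparameter for `"elasso"` (default 0.25).
#' @param prune for `"multivariate"`: prune non-significant edges and
#'   re-estimate (default `TRUE`).
#' @param rule edge-inclusion rule across the two directed regressions,
#'   `"AND"` (default) or `"OR"`.
#' @param ridge optional ridge penalty on the weights in the multivariate
#'   likelihood for near-degenerate truncated data (default 0, off).
#' @param nlambda,lambda_min_ratio lasso path resolution for `"elasso"`.
#' @return an object of class `ising_fit`: estimated `tau`, `omega`
#'   (symmetric, zero diagonal, exact zeros off the `edge_mask`),
#'   `edge_mask`, `loglik`, `converged`, standard errors (multivariate),
#'   and per-node diagnostics (dropped-row counts, separation flags).
#' @examples
#' net <- make_toy_network("five-chain")
#' y <- ising_sample(net, n = 2000, k = 2, seed = 7)
#' fit <- ising_fit(y, k = 2, method = "nodewise", alpha = 0.05)
#' coef(fit)$omega
#' @export
ising_fit <- function(data, k = NULL,
                      method = c("multivariate", "nodewise", "elasso"),
                      corrected = TRUE, alpha = 0.01, gamma = 0.25,
                      prune = TRUE, rule = c("AND", "OR"), ridge = 0,
                      nlambda = 100L, lambda_min_ratio = 0.001) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (is.null(k)) {
    k <- attr(data, "cutoff") %||% 0L
  }
  k <- as.integer(k)
  fit <- switch(method,
    multivariate = fit_ising_ml(data, k, corrected = corrected, prune = prune,
                                alpha = alpha, ridge = ridge),
    nodewise = fit_ising_nodewise(data, k, corrected = corrected,
                                  alpha = alpha, rule = rule),
    elasso = fit_ising_elasso(data, k, corrected = corrected, gamma = gamma,
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              rule = rule)
  )
  fit$call <- match.call()
  fit
}

#' @export
print.ising_fit <- function(x, ...) {
  cat(sprintf(
    "Ising fit (%s, %s), n = %d, m = %d, cutoff k = %d\n",
    x$method, if (x$corrected) "selection-corrected" else "uncorrected",
    x$n, x$m, x$k
  ))
  cat(sprintf("  edges included: %d / %d\n",
              sum(upper_tri_values(x$edge_mask)),
              x$m * (x$m - 1L) / 2L))
  cat(sprintf("  log-likelihood: %.2f%s\n", x$loglik,
              if (isTRUE(x$converged)) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.ising_fit <- function(object, ...) {
  w <- upper_tri_values(object$omega)
  mask <- upper_tri_values(object$edge_mask)
  out <- list(
    method = object$method, corrected = object$corrected, k = object$k,
    n = object$n, m = object$m,
    n_edges = sum(mask), n_pairs = length(mask),
    n_negative = sum(w < 0),
    mean_abs_weight = if (any(mask)) mean(abs(w[mask])) else NA_real_,
    tau = object$tau, converged = object$converged,
    dropped_rows = object$diagnostics$dropped_rows,
    separation = object$diagnostics$separation
  )
  class(out) <- "summary.ising_fit"
  out
}

#' @export
print.summary.ising_fit <- function(x, ...) {
  cat(sprintf("Ising fit summary (%s, %s)\n", x$method,
              if (x$corrected) "selection-corrected" else "uncorrected"))
  cat(sprintf("  n = %d cases, m = %d nodes, cutoff k = %d\n", x$n, x$m, x$k))
  cat(sprintf("  edges: %d included of %d pairs (%d negative)\n",
              x$n_edges, x$n_pairs, x$n_negative))
  if (!is.na(x$mean_abs_weight)) {
    cat(sprintf("  mean |weight| of included edges: %.3f\n", x$mean_abs_weight))
  }
  if (!is.null(x$dropped_rows)) {
    cat(sprintf("  rows removed by the k-1 rule, per node: %s\n",
                paste(x$dropped_rows, collapse = " ")))
  }
  if (!isTRUE(x$converged)) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.ising_fit <- function(object, ...) {
  list(tau = object$tau, omega = object$omega)
}

#' @export
logLik.ising_fit <- function(object, ...) {
  npar <- object$m + sum(upper_tri_values(object$edge_mask))
  structure(object$loglik, df = npar, nobs = object$n, class = "logLik")
}

#' Convert a fit to an Ising model object
#'
#' @param x an `ising_fit`.
#' @param ... unused.
#' @return an [ising_model] built from the estimated parameters.
#' @export
as_ising_model <- function(x, ...) {
  UseMethod("as_ising_model")
}

#' @export
as_ising_model.ising_fit <- function(x, ...) {
  ising_model(x$tau, x$omega)
}

#' @export
as_ising_model.ising_model <- function(x, ...) x

#' Simulate from a fitted Ising model
#'
#' Draws from the estimated (population, i.e. unselected) model; pass `k`
#' to draw from its sum-score-conditioned version instead.
#'
#' @param object an `ising_fit`.
#' @param nsim number of rows.
#' @param seed integer seed.
#' @param k sum-score cutoff for the draw (default 0).
#' @param ... unused.
#' @export
simulate.ising_fit <- function(object, nsim = 1, seed = NULL, k = 0L, ...) {
  ising_sample(as_ising_model(object), n = nsim, k = k, seed = seed)
}

#' Nodewise conditional predictions from a fit
#'
#' For each case and each node, the fitted conditional probability that
#' the node is 1 given the observed values of the other nodes, honouring
#' the selection: under cutoff `k`, cases whose other variables sum to
#' `k - 1` get probability exactly 1.
#'
#' @param object an `ising_fit`.
#' @param newdata 0/1 matrix; defaults cannot be recovered from the fit,
#'   so it must be supplied.
#' @param k sum-score cutoff of the conditioning (default: the fit's `k`
#'   if the fit is corrected, else 0).
#' @param ... unused.
#' @return an n by m matrix of conditional probabilities.
#' @export
predict.ising_fit <- function(object, newdata, k = NULL, ...) {
  if (missing(newdata)) {
    stop_ising("ising_validation_error", "predict.ising_fit requires `newdata`")
  }
  newdata <- check_binary_matrix(newdata)
  if (ncol(newdata) != object$m) {
    stop_ising("ising_dim_error",
               sprintf("newdata has %d columns; the fit has %d nodes",
                       ncol(newdata), object$m))
  }
  if (is.null(k)) {
    k <- if (object$corrected) object$k else 0L
  }
  model <- as_ising_model(object)
  out <- matrix(NA_real_, nrow(newdata), object$m)
  for (node in seq_len(object$m)) {
    others <- newdata[, -node, drop = FALSE]
    s_others <- rowSums(others)
    eta <- model$tau[node] +
      drop(others %*% model$omega[node, -node])
    p <- stats::plogis(eta)
    p[s_others == k - 1] <- 1
    out[, node] <- p
  }
  colnames(out) <- paste0("v", seq_len(object$m))
  out
}

#' Response residuals of a fit
#'
#' Observed value minus fitted conditional probability, per case and node
#' (see [predict.ising_fit()]).
#'
#' @param object an `ising_fit`.
#' @param newdata 0/1 matrix of observations.
#' @param ... passed to [predict.ising_fit()].
#' @export
residuals.ising_fit <- function(object, newdata, ...) {
  newdata <- check_binary_matrix(newdata)
  newdata - predict(object, newdata, ...)
}

#' Plot an estimated or true network
#'
#' Draws the weighted graph with `igraph` when available (edge width
#' proportional to |weight|, red for negative, blue for positive edges);
#' falls back to an image of the weight matrix otherwise.
#'
#' @param x an `ising_fit` or [ising_model].
#' @param ... passed to the underlying plot call.
#' @export
plot.ising_fit <- function(x, ...) {
  plot_ising_network(x$omega, ...)
}

#' @export
plot.ising_model <- function(x, ...) {
  plot_ising_network(x$omega, ...)
}

#' @keywords internal
#' @noRd
plot_ising_network <- function(omega, ...) {
  m <- ncol(omega)
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(
      abs(omega), mode = "undirected", weighted = TRUE, diag = FALSE
    )
    el <- igraph::as_edgelist(g, names = FALSE)
    signs <- omega[el]
    ew <- igraph::E(g)$weight
    igraph::plot.igraph(
      g,
      edge.width = 1 + 4 * ew / max(ew, na.rm = TRUE),
      edge.color = ifelse(signs < 0, "firebrick", "steelblue"),
      vertex.color = "grey90", vertex.label.color = "black", ...
    )
  } else {
    stats::heatmap(omega, Rowv = NA, Colv = NA, symm = TRUE,
                   main = "edge weights", ...)
  }
  invisible(NULL)
}
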