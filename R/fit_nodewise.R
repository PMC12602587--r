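# Corrected pseudo-likelihood estimation.
#
# Each node is regressed logistically on all others. After selection on
# s >= k the conditional probability of a node given the others is still
# the ordinary logistic function — except when the other variables sum to
# exactly k - 1, in which case the response is logically forced to 1 and
# the case carries likelihood 1. Removing those cases from the regression
# is therefore exactly equivalent to the corrected pseudo-likelihood.

#' Build the (corrected) design for one nodewise regression
#'
#' Extracts node `node` as response and the remaining columns as
#' predictors. With `corrected = TRUE` and `k >= 1`, rows whose predictor
#' sum equals `k - 1` are removed: for those cases the response is
#' logically 1 under selection at \eqn{s \ge k} and contributes likelihood
#' 1. Predictor sums below `k - 1` cannot occur in data selected at
#' \eqn{s \ge k} and raise an error.
#'
#' @param data 0/1 matrix selected at cutoff `k` (every row sum `>= k`).
#' @param node index of the response column.
#' @param k sum-score cutoff under which the rows were selected.
#' @param corrected apply the k-1 case removal (default `TRUE`).
#' @return a list with `node`, `response`, `predictors`, `dropped_rows`
#'   (indices into the original rows), and `k`.
#' @export
prepare_node_regression <- function(data, node, k, corrected = TRUE) {
  data <- check_binary_matrix(data)
  m <- ncol(data)
  if (node < 1L || node > m) {
    stop_ising("ising_dim_error", sprintf("node %d outside 1..%d", node, m))
  }
  rs <- rowSums(data)
  if (any(rs < k)) {
    bad <- which(rs < k)[1L]
    stop_ising(
      "ising_row_error",
      sprintf("row %d has sum score %d below the declared cutoff k = %d",
              bad, rs[bad], k)
    )
  }
  response <- data[, node]
  predictors <- data[, -node, drop = FALSE]
  dropped <- integer(0)
  if (corrected && k >= 1L) {
    psum <- rowSums(predictors)
    dropped <- which(psum == k - 1L)
  }
  keep <- if (length(dropped)) -dropped else TRUE
  list(
    node = as.integer(node),
    response = response[keep],
    predictors = predictors[keep, , drop = FALSE],
    dropped_rows = dropped,
    k = as.integer(k)
  )
}

#' Conditional probability of one node under sum-score selection
#'
#' \eqn{\Pr(Y_\mathrm{node} = y \mid Y^{(-\mathrm{node})} = \mathrm{others},
#' s \ge k)}. When the other variables sum to at least `k` the selection is
#' uninformative and the value is the ordinary logistic
#' \eqn{\sigma(\tau + \sum_j \omega_j y_j)}. When they sum to exactly
#' `k - 1` the response must be 1 for the case to be in the sample, so the
#' probability of response 1 is exactly 1. Sums below `k - 1` are
#' impossible under the selection and raise an error.
#'
#' @param model an [ising_model].
#' @param node index of the predicted variable.
#' @param others 0/1 vector of the remaining `m - 1` variables, in node
#'   order with `node` removed.
#' @param k sum-score cutoff (default 0: no selection).
#' @param response predicted value, 0 or 1 (default 1).
#' @return a probability.
#' @export
corrected_conditional_probability <- function(model, node, others, k = 0L,
                                              response = 1) {
  m <- model$m
  others <- as.numeric(others)
  if (length(others) != m - 1L) {
    stop_ising("ising_dim_error",
               sprintf("`others` has length %d; expected %d", length(others), m - 1L))
  }
  if (!all(others %in% c(0, 1)) || !response %in% c(0, 1)) {
    stop_ising("ising_binary_error", "pattern entries must be 0 or 1")
  }
  s_others <- sum(others)
  if (s_others < k - 1L) {
    stop_ising(
      "ising_support_error",
      sprintf(paste0(
        "conditioning event is impossible: the other variables sum to %d ",
        "but selection at s >= %d requires at least %d"
      ), s_others, k, k - 1L)
    )
  }
  if (s_others == k - 1L) {
    return(if (response == 1) 1 else 0)
  }
  eta <- model$tau[node] + sum(model$omega[node, -node] * others)
  stats::plogis(if (response == 1) eta else -eta)
}

#' Fit one corrected nodewise logistic regression
#'
#' Unpenalised logistic maximum likelihood of node `node` on the remaining
#' variables, after [prepare_node_regression()] case removal. The intercept
#' estimates \eqn{\tau_\mathrm{node}} and the slopes estimate
#' \eqn{\omega_{\mathrm{node},j}}. Complete separation is flagged
#' (divergent coefficients, |slope| > 15, or glm non-convergence) rather
#' than "fixed": the affected fit is marked non-converged.
#'
#' @inheritParams prepare_node_regression
#' @return a list with `intercept`, `coef` (named slopes for the other
#'   nodes), `se`, `p_value`, `converged`, `separation`, `dropped_rows`,
#'   `loglik`, and `n_used`.
#' @export
fit_node_regression <- function(data, node, k, corrected = TRUE) {
  reg <- prepare_node_regression(data, node, k, corrected = corrected)
  y <- reg$response
  if (length(unique(y)) < 2L) {
    stop_ising(
      "ising_degenerate_node_error",
      sprintf("node %d takes a single value after correction; no logistic fit exists",
              node),
      nodes = as.integer(node)
    )
  }
  x <- reg$predictors
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(y = y, x)
  gfit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial())
  )
  cf <- stats::coef(gfit)
  sm <- suppressWarnings(summary(gfit)$coefficients)
  # aliased (collinear) predictors: coefficient NA, no summary row; treat
  # the directed edge as absent and non-significant
  slope_names <- names(cf)[-1L]
  se <- stats::setNames(rep(NA_real_, length(slope_names)), slope_names)
  pv <- stats::setNames(rep(1, length(slope_names)), slope_names)
  have <- intersect(rownames(sm), slope_names)
  se[have] <- sm[have, "Std. Error"]
  pv[have] <- sm[have, "Pr(>|z|)"]
  cf[is.na(cf)] <- 0
  separation <- !gfit$converged || any(abs(cf[-1L]) > 15)
  if (separation) {
    warning(sprintf("possible separation in the regression for node %d; its directed edges are treated as non-significant", node),
            call. = FALSE)
  }
  other_nodes <- setdiff(seq_len(ncol(data)), node)
  slopes <- cf[-1L]
  names(slopes) <- names(se) <- names(pv) <- other_nodes
  list(
    node = node,
    intercept = unname(cf[1L]),
    coef = slopes,
    se = se,
    p_value = pv,
    converged = gfit$converged && !separation,
    separation = separation,
    dropped_rows = reg$dropped_rows,
    loglik = as.numeric(stats::logLik(gfit)),
    n_used = length(y)
  )
}

# Combine m directed regressions into a symmetric network. Inclusion per
# the AND rule (both directions pass) or OR rule; weights are the mean of
# the two directed slopes for included edges, zero otherwise.
#' @keywords internal
#' @noRd
combine_directed <- function(m, slopes, include_directed, rule = "AND") {
  omega <- matrix(0, m, m)
  mask <- matrix(FALSE, m, m)
  pairs <- pair_index(m)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    j <- pairs[r, 2L]
    ok <- if (rule == "AND") {
      include_directed[i, j] && include_directed[j, i]
    } else {
      include_directed[i, j] || include_directed[j, i]
    }
    if (ok) {
      omega[i, j] <- omega[j, i] <- (slopes[i, j] + slopes[j, i]) / 2
      mask[i, j] <- mask[j, i] <- TRUE
    }
  }
  list(omega = omega, mask = mask)
}

#' @keywords internal
#' @noRd
fit_ising_nodewise <- function(data, k, corrected = TRUE, alpha = 0.01,
                               rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  data <- check_fit_data(data, k)
  m <- ncol(data)
  slopes <- matrix(0, m, m)
  include <- matrix(FALSE, m, m)
  tau <- numeric(m)
  loglik <- 0
  dropped <- integer(m)
  separation <- logical(m)
  for (node in seq_len(m)) {
    nf <- fit_node_regression(data, node, k, corrected = corrected)
    tau[node] <- nf$intercept
    others <- as.integer(names(nf$coef))
    slopes[node, others] <- nf$coef
    # Directed significance; a separated regression contributes no edges.
    include[node, others] <- if (nf$separation) FALSE else nf$p_value <= alpha
    loglik <- loglik + nf$loglik
    dropped[node] <- length(nf$dropped_rows)
    separation[node] <- nf$separation
  }
  comb <- combine_directed(m, slopes, include, rule = rule)
  new_ising_fit(
    method = "nodewise", corrected = corrected, k = as.integer(k),
    k_norm = if (corrected) as.integer(k) else 0L,
    tau = tau, omega = comb$omega, edge_mask = comb$mask,
    alpha = alpha, gamma = NULL, loglik = loglik,
    converged = !any(separation), n = nrow(data), m = m,
    diagnostics = list(dropped_rows = dropped, separation = separation,
                       rule = rule, directed_slopes = slopes)
  )
}

# EBIC for one candidate logistic model on a lasso path: d counts nonzero
# slopes, n' the post-correction rows, p the number of candidate
# predictors (m - 1).
#' @keywords internal
#' @noRd
ebic_score <- function(loglik, d, n, p, gamma) {
  -2 * loglik + d * log(n) + 2 * gamma * d * log(p)
}

#' @keywords internal
#' @noRd
fit_ising_elasso <- function(data, k, corrected = TRUE, gamma = 0.25,
                             nlambda = 100L, lambda_min_ratio = 0.001,
                             rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  data <- check_fit_data(data, k)
  m <- ncol(data)
  slopes <- matrix(0, m, m)
  include <- matrix(FALSE, m, m)
  tau <- numeric(m)
  loglik <- 0
  dropped <- integer(m)
  separation <- logical(m)
  ebic_sel <- numeric(m)
  for (node in seq_len(m)) {
    reg <- prepare_node_regression(data, node, k, corrected = corrected)
    y <- reg$response
    if (length(unique(y)) < 2L) {
      stop_ising(
        "ising_degenerate_node_error",
        sprintf("node %d takes a single value after correction; no logistic fit exists",
                node),
        nodes = as.integer(node)
      )
    }
    x <- reg$predictors
    np <- length(y)
    path <- glmnet::glmnet(
      x, y, family = "binomial", standardize = FALSE,
      nlambda = nlambda, lambda.min.ratio = lambda_min_ratio
    )
    # loglik along the path; binomial deviance has zero saturated term.
    dev <- (1 - path$dev.ratio) * path$nulldev
    ll <- -dev / 2
    d <- path$df
    scores <- ebic_score(ll, d, np, m - 1L, gamma)
    best <- which.min(scores)
    beta <- as.numeric(path$beta[, best])
    tau[node] <- path$a0[best]
    others <- setdiff(seq_len(m), node)
    slopes[node, others] <- beta
    sep <- any(abs(beta) > 15)
    include[node, others] <- if (sep) FALSE else beta != 0
    loglik <- loglik + ll[best]
    dropped[node] <- length(reg$dropped_rows)
    separation[node] <- sep
    ebic_sel[node] <- scores[best]
  }
  comb <- combine_directed(m, slopes, include, rule = rule)
  new_ising_fit(
    method = "elasso", corrected = corrected, k = as.integer(k),
    k_norm = if (corrected) as.integer(k) else 0L,
    tau = tau, omega = comb$omega, edge_mask = comb$mask,
    alpha = NULL, gamma = gamma, loglik = loglik,
    converged = !any(separation), n = nrow(data), m = m,
    diagnostics = list(dropped_rows = dropped, separation = separation,
                       rule = rule, directed_slopes = slopes,
                       ebic = ebic_sel)
  )
}
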