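# Corrected multivariate maximum likelihood.
#
# The sum-score-conditioned Ising model is a full exponential family in
# theta = (tau, upper-triangle omega) with sufficient statistics
# (y_i, y_i y_j) and normaliser Z^(k). Enumeration of the truncated support
# gives exact moments, so the likelihood is maximised by Newton iterations
# with the exact Hessian (the truncated-model covariance of the sufficient
# statistics); the gradient is observed minus expected sufficient
# statistics.

# Sufficient statistic design: node indicators then pairwise products,
# pairs in column-major upper-triangle order.
#' @keywords internal
#' @noRd
suff_stats <- function(Y) {
  m <- ncol(Y)
  pairs <- pair_index(m)
  cbind(Y, Y[, pairs[, 1L], drop = FALSE] * Y[, pairs[, 2L], drop = FALSE])
}

#' Negative log-likelihood of the sum-score-conditioned Ising model
#'
#' \eqn{-\sum_p [\log \mathrm{Pot}(y_p) - \log Z^{(k)}]}. For `k = 0` this
#' is the ordinary full-data Ising negative log-likelihood. Rows whose sum
#' score falls below `k` have probability zero under the conditional model
#' and raise an error.
#'
#' @param model an [ising_model].
#' @param data 0/1 matrix, one response pattern per row.
#' @param k sum-score cutoff used in the normaliser.
#' @param cap enumeration ceiling on `m`.
#' @return a scalar negative log-likelihood.
#' @export
ising_nll <- function(model, data, k = 0L, cap = ENUM_CAP) {
  data <- check_binary_matrix(data)
  if (ncol(data) != model$m) {
    stop_ising("ising_dim_error",
               sprintf("data has %d columns but the model has %d nodes",
                       ncol(data), model$m))
  }
  rs <- rowSums(data)
  if (any(rs < k)) {
    bad <- which(rs < k)[1L]
    stop_ising(
      "ising_row_error",
      sprintf(paste0(
        "row %d has sum score %d < k = %d: its probability is zero under ",
        "the sum-score-conditioned model"
      ), bad, rs[bad], k)
    )
  }
  lz <- log_partition_truncated(model, k, cap = cap)
  -(sum(log_potentials(model, data)) - nrow(data) * lz)
}

# Newton maximisation of the (possibly edge-constrained) truncated
# likelihood. `free_edges` masks upper-triangle omega entries held at zero.
# Objective and gradient are on the per-observation scale.
#' @keywords internal
#' @noRd
ml_engine <- function(data, k_norm, free_edges = NULL, ridge = 0,
                      grad_tol = 1e-5, max_iter = 200L, cap = ENUM_CAP) {
  m <- ncol(data)
  n <- nrow(data)
  n_pairs <- m * (m - 1L) / 2L
  if (is.null(free_edges)) {
    free_edges <- rep(TRUE, n_pairs)
  }
  free <- c(rep(TRUE, m), free_edges)
  d <- m + n_pairs

  sup <- enumerate_support(m, k_norm, cap = cap)
  S <- suff_stats(sup$patterns)
  obs <- colMeans(suff_stats(data))

  ridge_vec <- c(rep(0, m), rep(ridge, n_pairs))[free]
  Sf <- S[, free, drop = FALSE]
  obs_f <- obs[free]

  objective <- function(theta_f) {
    logsumexp(drop(Sf %*% theta_f)) - sum(obs_f * theta_f) +
      0.5 * sum(ridge_vec * theta_f^2)
  }
  moments <- function(theta_f) {
    lp <- drop(Sf %*% theta_f)
    p <- exp(lp - logsumexp(lp))
    mu <- drop(crossprod(Sf, p))
    H <- crossprod(Sf * sqrt(p)) - tcrossprod(mu)
    list(mu = mu, H = H)
  }

  # Marginal logits are a cheap start inside the concave basin.
  pbar <- pmin(pmax(colMeans(data), 1 / (2 * n)), 1 - 1 / (2 * n))
  theta_f <- c(stats::qlogis(pbar), rep(0, sum(free_edges)))

  f <- objective(theta_f)
  converged <- FALSE
  iter <- 0L
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    mo <- moments(theta_f)
    g <- mo$mu - obs_f + ridge_vec * theta_f
    grad_norm <- max(abs(g))
    if (grad_norm < grad_tol) {
      converged <- TRUE
      break
    }
    H <- mo$H
    diag(H) <- diag(H) + ridge_vec
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      diag(H) <- diag(H) + 1e-8
      step <- tryCatch(solve(H, g), error = function(e) g)
    }
    # Backtracking keeps Newton monotone far from the optimum.
    alpha_step <- 1
    repeat {
      theta_new <- theta_f - alpha_step * step
      f_new <- objective(theta_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) {
        break
      }
      alpha_step <- alpha_step / 2
      if (alpha_step < 1e-10) {
        theta_new <- theta_f
        f_new <- f
        break
      }
    }
    theta_f <- theta_new
    f <- f_new
  }
  if (!converged) {
    mo <- moments(theta_f)
    grad_norm <- max(abs(mo$mu - obs_f + ridge_vec * theta_f))
    converged <- grad_norm < grad_tol
    if (!converged) {
      warning(sprintf(
        "truncated-likelihood optimiser did not reach gradient tolerance (max |grad| = %.2e)",
        grad_norm
      ), call. = FALSE)
    }
  }

  theta <- numeric(d)
  theta[free] <- theta_f
  tau <- theta[seq_len(m)]
  omega <- matrix_from_upper(theta[m + seq_len(n_pairs)], m)
  list(
    tau = tau, omega = omega, free_edges = free_edges,
    loglik = -n * f, converged = converged, grad_norm = grad_norm,
    iterations = iter
  )
}

#' @keywords internal
#' @noRd
check_fit_data <- function(data, k) {
  data <- check_binary_matrix(data)
  rs <- rowSums(data)
  if (any(rs < k)) {
    bad <- which(rs < k)[1L]
    stop_ising(
      "ising_row_error",
      sprintf("row %d has sum score %d below the declared cutoff k = %d",
              bad, rs[bad], k)
    )
  }
  cm <- colMeans(data)
  degenerate <- which(cm == 0 | cm == 1)
  if (length(degenerate)) {
    stop_ising(
      "ising_degenerate_node_error",
      sprintf("node%s %s take%s a single value in the data; the threshold is not estimable",
              if (length(degenerate) > 1L) "s" else "",
              paste(degenerate, collapse = ", "),
              if (length(degenerate) > 1L) "" else "s"),
      nodes = degenerate
    )
  }
  data
}

#' @keywords internal
#' @noRd
fit_ising_ml <- function(data, k, corrected = TRUE, prune = TRUE,
                         alpha = 0.01, ridge = 0, cap = ENUM_CAP) {
  data <- check_fit_data(data, k)
  k_norm <- if (corrected) as.integer(k) else 0L
  eng <- ml_engine(data, k_norm, ridge = ridge, cap = cap)
  fit <- new_ising_fit(
    method = "multivariate", corrected = corrected, k = as.integer(k),
    k_norm = k_norm, tau = eng$tau, omega = eng$omega,
    edge_mask = eng$omega != 0 | matrix_from_upper(eng$free_edges, ncol(data)) > 0,
    alpha = alpha, gamma = NULL, loglik = eng$loglik,
    converged = eng$converged, n = nrow(data), m = ncol(data),
    diagnostics = list(grad_norm = eng$grad_norm, iterations = eng$iterations,
                       ridge = ridge)
  )
  se <- standard_errors(fit, data)
  fit$se <- se$omega
  fit$se_tau <- se$tau
  if (prune) {
    fit <- prune_edges(fit, data, alpha = alpha)
  }
  fit
}

#' Exact standard errors for a multivariate fit
#'
#' Standard errors from the inverse observed information of the
#' sum-score-conditioned likelihood at the fitted parameters. Because the
#' model is an exponential family and the truncated support is enumerated,
#' the information is the exact covariance of the sufficient statistics
#' under the fitted conditional model, scaled by `n`.
#'
#' @param fit an `ising_fit` from the multivariate method with
#'   `converged = TRUE`.
#' @param data the 0/1 data matrix the fit was computed on (used for its
#'   row count).
#' @return a list with `tau` (length-m SE vector) and `omega` (symmetric
#'   matrix of edge SEs, `NA` for edges constrained to zero).
#' @export
standard_errors <- function(fit, data) {
  if (!inherits(fit, "ising_fit") || fit$method != "multivariate") {
    stop_ising("ising_validation_error",
               "standard_errors() requires a multivariate ising_fit")
  }
  if (!isTRUE(fit$converged)) {
    stop_ising("ising_validation_error",
               "standard errors require a converged fit")
  }
  m <- fit$m
  n <- if (missing(data) || is.null(data)) fit$n else nrow(data)
  n_pairs <- m * (m - 1L) / 2L
  free_edges <- upper_tri_values(fit$edge_mask)
  free <- c(rep(TRUE, m), free_edges)
  sup <- enumerate_support(m, fit$k_norm)
  S <- suff_stats(sup$patterns)[, free, drop = FALSE]
  theta_f <- c(fit$tau, upper_tri_values(fit$omega))[free]
  lp <- drop(S %*% theta_f)
  p <- exp(lp - logsumexp(lp))
  mu <- drop(crossprod(S, p))
  info <- n * (crossprod(S * sqrt(p)) - tcrossprod(mu))
  cov <- tryCatch(solve(info), error = function(e) {
    stop_ising(
      "ising_singular_error",
      paste0("the observed information is singular; some parameters are ",
             "not identified on the truncated support")
    )
  })
  se_all <- rep(NA_real_, m + n_pairs)
  se_all[free] <- sqrt(pmax(diag(cov), 0))
  se_omega <- matrix(NA_real_, m, m)
  se_omega[upper.tri(se_omega)] <- se_all[m + seq_len(n_pairs)]
  se_omega[lower.tri(se_omega)] <- t(se_omega)[lower.tri(se_omega)]
  list(tau = se_all[seq_len(m)], omega = se_omega)
}

#' Significance pruning of a multivariate fit
#'
#' One pass of Wald pruning: for each currently free edge,
#' \eqn{z = \hat\omega_{ij} / \mathrm{SE}_{ij}}; edges whose two-sided p
#' value exceeds `alpha` are constrained to exactly zero and the network is
#' re-estimated once under the constraints, with the same cutoff in the
#' normaliser. Standard errors are recomputed for the retained edges.
#'
#' @param fit a converged multivariate `ising_fit` with standard errors.
#' @param data the 0/1 data matrix the fit was computed on.
#' @param alpha two-sided significance level (default 0.01).
#' @return an `ising_fit` with updated `edge_mask`, estimates and SEs.
#' @export
prune_edges <- function(fit, data, alpha = 0.01) {
  if (is.null(fit$se)) {
    se <- standard_errors(fit, data)
    fit$se <- se$omega
    fit$se_tau <- se$tau
  }
  w <- upper_tri_values(fit$omega)
  s <- upper_tri_values(fit$se)
  free <- upper_tri_values(fit$edge_mask)
  z <- ifelse(free & !is.na(s) & s > 0, w / s, 0)
  p <- 2 * stats::pnorm(-abs(z))
  keep <- free & (p <= alpha)
  if (all(keep == free)) {
    fit$alpha <- alpha
    return(fit)
  }
  eng <- ml_engine(check_binary_matrix(data), fit$k_norm, free_edges = keep,
                   ridge = fit$diagnostics$ridge %||% 0)
  out <- fit
  out$tau <- eng$tau
  out$omega <- eng$omega
  out$edge_mask <- matrix_from_upper(as.numeric(keep), fit$m) > 0
  out$loglik <- eng$loglik
  out$converged <- eng$converged
  out$alpha <- alpha
  out$diagnostics$grad_norm <- eng$grad_norm
  out$diagnostics$pruned_edges <- sum(free) - sum(keep)
  se <- standard_errors(out, data)
  out$se <- se$omega
  out$se_tau <- se$tau
  out
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
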