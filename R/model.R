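#' Construct an Ising model
#'
#' An Ising model over \eqn{m} binary (0/1) variables is parameterised by a
#' threshold \eqn{\tau_i} per node and a symmetric pairwise weight matrix
#' \eqn{\omega} with zero diagonal. The joint distribution over response
#' patterns \eqn{y \in \{0,1\}^m} is
#' \deqn{\Pr(Y = y) = \frac{1}{Z}\exp\Big(\sum_i \tau_i y_i +
#'   \sum_{i<j} \omega_{ij} y_i y_j\Big),}
#' where each unordered pair contributes a single term and \eqn{Z} sums the
#' exponential (the "potential") over all \eqn{2^m} patterns. Variables are
#' coded 0 = absent, 1 = present; a positive \eqn{\omega_{ij}} makes equal
#' states of \eqn{i} and \eqn{j} more likely.
#'
#' @param tau numeric vector of node thresholds (log scale).
#' @param omega symmetric numeric matrix of pairwise weights with zero
#'   diagonal; dimensions must match `length(tau)`.
#' @return an object of class `ising_model` with elements `m`, `tau`,
#'   `omega`.
#' @examples
#' mod <- ising_model(tau = c(0, 0), omega = matrix(c(0, log(2), log(2), 0), 2))
#' potential(mod, c(1, 1)) # exp(log 2) = 2
#' @export
ising_model <- function(tau, omega) {
  tau <- as.numeric(tau)
  m <- length(tau)
  if (m < 1L) {
    stop_ising("ising_validation_error", "model must have at least one node")
  }
  omega <- as.matrix(omega)
  if (!all(dim(omega) == c(m, m))) {
    stop_ising(
      "ising_dim_error",
      sprintf(
        "omega must be %d x %d to match tau; got %d x %d",
        m, m, nrow(omega), ncol(omega)
      )
    )
  }
  storage.mode(omega) <- "double"
  if (!all(is.finite(tau)) || !all(is.finite(omega))) {
    stop_ising("ising_validation_error", "tau and omega must be finite")
  }
  if (!isTRUE(all.equal(omega, t(omega), tolerance = 0, check.attributes = FALSE))) {
    bad <- which(omega != t(omega), arr.ind = TRUE)[1L, ]
    stop_ising(
      "ising_validation_error",
      sprintf("omega must be symmetric; omega[%d,%d] != omega[%d,%d]",
              bad[1L], bad[2L], bad[2L], bad[1L])
    )
  }
  if (any(diag(omega) != 0)) {
    stop_ising(
      "ising_validation_error",
      sprintf("omega must have a zero diagonal; omega[%1$d,%1$d] is nonzero",
              which(diag(omega) != 0)[1L])
    )
  }
  dimnames(omega) <- NULL
  structure(list(m = m, tau = unname(tau), omega = omega),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  nz <- sum(upper_tri_values(x$omega) != 0)
  cat(sprintf("Ising model: %d nodes, %d of %d edges nonzero\n",
              x$m, nz, x$m * (x$m - 1L) / 2L))
  cat("thresholds (tau):\n")
  print(round(x$tau, 3))
  invisible(x)
}

#' @export
summary.ising_model <- function(object, ...) {
  w <- upper_tri_values(object$omega)
  structure(
    list(
      m = object$m,
      n_edges = sum(w != 0),
      n_pairs = length(w),
      density = mean(w != 0),
      mean_present_weight = if (any(w != 0)) mean(w[w != 0]) else NA_real_,
      tau_range = range(object$tau)
    ),
    class = "summary.ising_model"
  )
}

#' @export
print.summary.ising_model <- function(x, ...) {
  cat(sprintf("Ising model with %d nodes\n", x$m))
  cat(sprintf("  edges present: %d / %d (density %.2f)\n",
              x$n_edges, x$n_pairs, x$density))
  if (!is.na(x$mean_present_weight)) {
    cat(sprintf("  mean present-edge weight: %.3f\n", x$mean_present_weight))
  }
  cat(sprintf("  threshold range: [%.3f, %.3f]\n", x$tau_range[1], x$tau_range[2]))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_pattern <- function(model, y) {
  y <- as.numeric(y)
  if (length(y) != model$m) {
    stop_ising(
      "ising_dim_error",
      sprintf("pattern has length %d but the model has %d nodes",
              length(y), model$m)
    )
  }
  if (!all(y %in% c(0, 1))) {
    stop_ising(
      "ising_binary_error",
      sprintf("pattern entries must be 0 or 1; entry %d is %s",
              which(!(y %in% c(0, 1)))[1L], format(y[which(!(y %in% c(0, 1)))[1L]]))
    )
  }
  y
}

# Log potentials for a matrix of patterns (rows). The pair sum counts each
# unordered pair once: y' omega y / 2 with omega symmetric, zero diagonal.
#' @keywords internal
#' @noRd
log_potentials <- function(model, patterns) {
  drop(patterns %*% model$tau + 0.5 * rowSums((patterns %*% model$omega) * patterns))
}

#' Potential of a response pattern
#'
#' The unnormalised probability
#' \eqn{\exp(\sum_i \tau_i y_i + \sum_{i<j} \omega_{ij} y_i y_j)}
#' of pattern `y` under `model`.
#'
#' @param model an [ising_model].
#' @param y a 0/1 vector of length `model$m`.
#' @return a strictly positive scalar.
#' @export
potential <- function(model, y) {
  y <- check_pattern(model, y)
  exp(log_potentials(model, matrix(y, nrow = 1L)))
}

# Default ceiling on exhaustive state enumeration (2^20 ~ 1e6 patterns).
# Beyond it the exact operations refuse rather than silently approximate.
#' @keywords internal
#' @noRd
ENUM_CAP <- 20L

#' @keywords internal
#' @noRd
check_enum_cap <- function(m, cap) {
  if (m > cap) {
    stop_ising(
      "ising_cap_error",
      sprintf(paste0(
        "exact enumeration of 2^%d states exceeds the cap of m = %d nodes; ",
        "raise `cap` explicitly if you accept the cost"
      ), m, cap)
    )
  }
}

# All 2^m patterns in lexicographic order, node 1 as the most significant
# bit: row r encodes r - 1 in binary.
#' @keywords internal
#' @noRd
enumerate_patterns <- function(m) {
  idx <- 0:(2^m - 1)
  vapply(seq_len(m), function(j) (idx %/% 2^(m - j)) %% 2, numeric(length(idx)))
}

#' Enumerate the truncated support
#'
#' Materialises the set of response patterns whose sum score
#' \eqn{s = \sum_i y_i} is at least `k` — the domain over which the
#' truncated partition function \eqn{Z^{(k)}} sums. Patterns are ordered
#' lexicographically with node 1 as the most significant bit.
#'
#' @param m number of nodes.
#' @param k sum-score cutoff, `0 <= k <= m`.
#' @param cap enumeration ceiling on `m` (default 20).
#' @return an object of class `ising_support`: a list with `m`, `k`, and
#'   `patterns`, a `choose`-sum-by-`m` 0/1 matrix.
#' @examples
#' enumerate_support(3, 2)$patterns # the four patterns with sum >= 2
#' @export
enumerate_support <- function(m, k, cap = ENUM_CAP) {
  m <- as.integer(m)
  k <- as.integer(k)
  if (k < 0L) {
    stop_ising("ising_support_error", "cutoff k must be non-negative")
  }
  if (k > m) {
    stop_ising(
      "ising_support_error",
      sprintf("cutoff k = %d exceeds m = %d: the truncated support is empty", k, m)
    )
  }
  check_enum_cap(m, cap)
  patterns <- enumerate_patterns(m)
  keep <- rowSums(patterns) >= k
  structure(
    list(m = m, k = k, patterns = patterns[keep, , drop = FALSE]),
    class = "ising_support"
  )
}

#' @export
print.ising_support <- function(x, ...) {
  cat(sprintf("Truncated support: %d patterns on %d nodes with sum score >= %d\n",
              nrow(x$patterns), x$m, x$k))
  invisible(x)
}

#' Log partition function
#'
#' Log of \eqn{Z}, the sum of potentials over all \eqn{2^m} patterns,
#' accumulated in log space (log-sum-exp) for numerical stability.
#'
#' @inheritParams potential
#' @param cap enumeration ceiling on `m` (default 20).
#' @return a scalar, \eqn{\log Z}.
#' @export
log_partition <- function(model, cap = ENUM_CAP) {
  log_partition_truncated(model, k = 0L, cap = cap)
}

#' Log truncated partition function
#'
#' Log of \eqn{Z^{(k)}}, the sum of potentials restricted to patterns whose
#' sum score is at least `k`. This is the normalising constant of the
#' distribution of the data after selection on \eqn{s \ge k}; for `k = 0`
#' it equals the full [log_partition].
#'
#' @inheritParams log_partition
#' @param k sum-score cutoff.
#' @return a scalar, \eqn{\log Z^{(k)}}.
#' @export
log_partition_truncated <- function(model, k, cap = ENUM_CAP) {
  sup <- enumerate_support(model$m, k, cap = cap)
  logsumexp(log_potentials(model, sup$patterns))
}

#' Conditional probability of a pattern given sum-score selection
#'
#' \eqn{\Pr(Y = y \mid s \ge k)}: the potential of `y` divided by
#' \eqn{Z^{(k)}} when the sum score of `y` reaches `k`, and exactly 0
#' otherwise. For `k = 0` this is the unconditional Ising probability.
#'
#' @inheritParams potential
#' @param k sum-score cutoff.
#' @param cap enumeration ceiling on `m` (default 20).
#' @return a probability.
#' @export
conditional_pmf <- function(model, y, k, cap = ENUM_CAP) {
  y <- check_pattern(model, y)
  if (k > model$m || k < 0) {
    stop_ising("ising_support_error",
               sprintf("cutoff k = %d outside 0..%d", k, model$m))
  }
  if (sum(y) < k) {
    return(0)
  }
  lz <- log_partition_truncated(model, k, cap = cap)
  exp(log_potentials(model, matrix(y, nrow = 1L)) - lz)
}

# Full table of conditional pattern probabilities on the truncated support;
# the workhorse behind exact sampling and exact model moments.
#' @keywords internal
#' @noRd
pattern_distribution <- function(model, k = 0L, cap = ENUM_CAP) {
  sup <- enumerate_support(model$m, k, cap = cap)
  lp <- log_potentials(model, sup$patterns)
  lz <- logsumexp(lp)
  list(support = sup, prob = exp(lp - lz), log_z = lz)
}
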