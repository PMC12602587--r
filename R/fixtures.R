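#' Generate the 9-node data-generating network
#'
#' Builds a deterministic "true" network with the summary structure of a
#' dense, all-positive depression-symptom network: 9 nodes, 29 strictly
#' positive edges and 7 absent ones (density 29/36, about .81), with the
#' mean present-edge weight rescaled to exactly `mean_weight`. The absent
#' pairs and the weight magnitudes are drawn from the seeded RNG (weights
#' from a Gamma(2, .) shape, then rescaled), so the topology is a seeded
#' stand-in rather than a hand-picked graph. Thresholds are drawn uniformly
#' from `tau_range`; if the model puts less than `min_tail_prob` mass on sum
#' scores \eqn{\ge 5}, thresholds are re-drawn (deterministically, from the
#' continuing RNG stream) so that selection at high cutoffs remains
#' meaningful.
#'
#' @param seed integer seed; the model is a pure function of the arguments.
#' @param m number of nodes (default 9).
#' @param n_present number of strictly positive edges (default 29).
#' @param mean_weight exact mean of the present-edge weights (default 0.61).
#' @param tau_range interval for the uniform threshold draw (default
#'   `c(-3, -1)`).
#' @param min_tail_prob minimum \eqn{\Pr(s \ge 5)} the model must attain
#'   (default 0.01).
#' @param max_tries bound on threshold re-draws before giving up.
#' @return an [ising_model].
#' @examples
#' net <- make_true_network(seed = 1)
#' summary(net)
#' @export
make_true_network <- function(seed,
                              m = 9L,
                              n_present = 29L,
                              mean_weight = 0.61,
                              tau_range = c(-3, -1),
                              min_tail_prob = 0.01,
                              max_tries = 100L) {
  if (missing(seed) || is.null(seed)) {
    stop_ising("ising_seed_error",
               "make_true_network() requires an explicit seed")
  }
  n_pairs <- m * (m - 1L) / 2L
  if (n_present < 1L || n_present > n_pairs) {
    stop_ising("ising_validation_error",
               sprintf("n_present must be in 1..%d", n_pairs))
  }
  with_seed(seed, {
    present <- sort(sample.int(n_pairs, n_present))
    raw <- stats::rgamma(n_present, shape = 2, rate = 2)
    weights <- raw * (mean_weight / mean(raw))
    upper <- numeric(n_pairs)
    upper[present] <- weights
    omega <- matrix_from_upper(upper, m)
    for (try in seq_len(max_tries)) {
      tau <- stats::runif(m, tau_range[1L], tau_range[2L])
      model <- ising_model(tau, omega)
      tail_prob <- exp(log_partition_truncated(model, 5L) - log_partition(model))
      if (tail_prob >= min_tail_prob) {
        return(model)
      }
    }
    stop_ising(
      "ising_calibration_error",
      sprintf(
        "could not calibrate thresholds to Pr(s >= 5) >= %g in %d tries",
        min_tail_prob, max_tries
      )
    )
  })
}

#' Small worked-example networks
#'
#' Three fixed toy models used throughout the documentation and tests:
#' \describe{
#'   \item{`"pair-ln2"`}{2 nodes, zero thresholds, a single edge of weight
#'     \eqn{\log 2}; the (1,1) pattern has probability 2/5.}
#'   \item{`"triple-uniform"`}{3 nodes, all parameters zero; every pattern
#'     equiprobable, so the sum-score-conditioned distribution is uniform
#'     on the retained patterns.}
#'   \item{`"five-chain"`}{5 nodes in a chain with edge weights 0.5 and
#'     thresholds \eqn{-1}.}
#' }
#'
#' @param name one of `"pair-ln2"`, `"triple-uniform"`, `"five-chain"`.
#' @return an [ising_model].
#' @export
make_toy_network <- function(name = c("pair-ln2", "triple-uniform", "five-chain")) {
  name <- match.arg(name)
  switch(name,
    "pair-ln2" = {
      omega <- matrix(0, 2, 2)
      omega[1, 2] <- omega[2, 1] <- log(2)
      ising_model(tau = c(0, 0), omega = omega)
    },
    "triple-uniform" = ising_model(tau = rep(0, 3), omega = matrix(0, 3, 3)),
    "five-chain" = {
      omega <- matrix(0, 5, 5)
      for (i in 1:4) omega[i, i + 1] <- omega[i + 1, i] <- 0.5
      ising_model(tau = rep(-1, 5), omega = omega)
    }
  )
}
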