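# Independent brute-force oracles. These deliberately avoid the package's
# vectorised potential/partition code paths: potentials are accumulated
# with explicit double loops over nodes and pairs, and partition sums are
# plain sums over an explicitly generated pattern list.

brute_patterns <- function(m) {
  pats <- as.matrix(do.call(expand.grid, rep(list(0:1), m)))
  dimnames(pats) <- NULL
  pats
}

brute_log_potential <- function(tau, omega, y) {
  y <- unname(y)
  acc <- 0
  for (i in seq_along(tau)) {
    acc <- acc + tau[i] * y[i]
  }
  for (i in seq_along(tau)) {
    for (j in seq_along(tau)) {
      if (i < j) acc <- acc + omega[i, j] * y[i] * y[j]
    }
  }
  acc
}

brute_z <- function(tau, omega, k = 0) {
  pats <- brute_patterns(length(tau))
  total <- 0
  for (r in seq_len(nrow(pats))) {
    y <- pats[r, ]
    if (sum(y) >= k) {
      total <- total + exp(brute_log_potential(tau, omega, y))
    }
  }
  total
}

brute_pmf <- function(tau, omega, y, k = 0) {
  if (sum(y) < k) {
    return(0)
  }
  exp(brute_log_potential(tau, omega, y)) / brute_z(tau, omega, k)
}

brute_nll <- function(tau, omega, data, k = 0) {
  total <- 0
  for (r in seq_len(nrow(data))) {
    total <- total - log(brute_pmf(tau, omega, data[r, ], k))
  }
  total
}

ut <- function(mat) mat[upper.tri(mat)]

sym_from_upper <- function(values, m) {
  out <- matrix(0, m, m)
  out[upper.tri(out)] <- values
  out + t(out)
}

random_ising <- function(m, seed, weight_sd = 0.8, tau_sd = 1) {
  set.seed(seed)
  tau <- rnorm(m, 0, tau_sd)
  w <- rnorm(m * (m - 1) / 2, 0, weight_sd)
  omega <- matrix(0, m, m)
  omega[upper.tri(omega)] <- w
  omega <- omega + t(omega)
  ising_model(tau, omega)
}
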