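test_that("negative log-likelihood matches enumeration", {
  null3 <- make_toy_network("triple-uniform")
  # one retained row under a uniform conditional distribution on 4 patterns
  expect_equal(ising_nll(null3, matrix(c(1, 1, 0), 1), k = 2), log(4))

  mod <- random_ising(5, 3)
  data <- ising_sample(mod, n = 50, seed = 9)
  expect_equal(ising_nll(mod, data, k = 0),
               brute_nll(mod$tau, mod$omega, data, 0), tolerance = 1e-8)
  data2 <- ising_sample(mod, n = 50, k = 2, seed = 10)
  expect_equal(ising_nll(mod, data2, k = 2),
               brute_nll(mod$tau, mod$omega, data2, 2), tolerance = 1e-8)

  expect_error(ising_nll(null3, matrix(c(1, 0, 0), 1), k = 2),
               class = "ising_row_error")
})

test_that("the corrected MLE matches truncated-model moments", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 4000, k = 2, seed = 21)
  fit <- ising_fit(data, k = 2, method = "multivariate", prune = FALSE)
  expect_true(fit$converged)

  sup <- enumerate_support(5, 2)
  probs <- apply(sup$patterns, 1, conditional_pmf,
                 model = as_ising_model(fit), k = 2)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      observed <- mean(data[, i] * data[, j])
      expected <- sum(probs * sup$patterns[, i] * sup$patterns[, j])
      expect_lt(abs(observed - expected), 1e-4)
    }
  }
})

test_that("corrected and uncorrected fits coincide at k = 0", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 1500, seed = 33)
  f1 <- ising_fit(data, k = 0, method = "multivariate", corrected = TRUE,
                  prune = FALSE)
  f2 <- ising_fit(data, k = 0, method = "multivariate", corrected = FALSE,
                  prune = FALSE)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-6)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-6)
})

test_that("fitting refuses zero-variance nodes and sub-cutoff rows", {
  data <- cbind(rep(1, 50), rep(0:1, 25), rep(c(0, 0, 1, 1), length.out = 50))
  expect_error(ising_fit(data, k = 0, method = "multivariate"),
               class = "ising_degenerate_node_error")
  data2 <- rbind(c(1, 1, 0), c(1, 0, 0))
  expect_error(ising_fit(data2, k = 2, method = "multivariate"),
               class = "ising_row_error")
})

test_that("information-matrix standard errors match finite differences", {
  mod <- random_ising(4, 61, weight_sd = 0.5)
  data <- ising_sample(mod, n = 800, k = 1, seed = 62)
  fit <- ising_fit(data, k = 1, method = "multivariate", prune = FALSE)
  expect_true(all(ut(fit$se) > 0))
  expect_true(all(fit$se_tau > 0))

  # central finite differences of the truncated nll around the optimum
  m <- 4
  theta_hat <- c(fit$tau, ut(fit$omega))
  d <- length(theta_hat)
  make_model <- function(theta) {
    ising_model(theta[1:m], sym_from_upper(theta[-(1:m)], m))
  }
  nll_theta <- function(theta) ising_nll(make_model(theta), data, k = 1)
  h <- 1e-4
  H <- matrix(0, d, d)
  for (a in seq_len(d)) {
    for (b in a:d) {
      ea <- eb <- numeric(d)
      ea[a] <- h
      eb[b] <- h
      H[a, b] <- H[b, a] <-
        (nll_theta(theta_hat + ea + eb) - nll_theta(theta_hat + ea - eb) -
           nll_theta(theta_hat - ea + eb) + nll_theta(theta_hat - ea - eb)) /
        (4 * h^2)
    }
  }
  se_num <- sqrt(diag(solve(H)))
  expect_equal(unname(c(fit$se_tau, ut(fit$se))), se_num,
               tolerance = 1e-3)
})

test_that("standard errors shrink like one over root n", {
  mod <- random_ising(4, 71, weight_sd = 0.5)
  ratios <- sapply(1:3, function(s) {
    small <- ising_sample(mod, n = 1000, k = 1, seed = 80 + s)
    big <- ising_sample(mod, n = 4000, k = 1, seed = 90 + s)
    f1 <- ising_fit(small, k = 1, method = "multivariate", prune = FALSE)
    f2 <- ising_fit(big, k = 1, method = "multivariate", prune = FALSE)
    mean(ut(f1$se) / ut(f2$se))
  })
  expect_lt(abs(mean(ratios) - 2), 0.3)
})

test_that("pruning zeroes non-significant edges and re-estimates once", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 3000, k = 0, seed = 101)
  fit <- ising_fit(data, k = 0, method = "multivariate", prune = TRUE,
                   alpha = 0.01)
  expect_true(all(fit$omega[!fit$edge_mask] == 0))
  expect_true(all(diag(fit$edge_mask) == FALSE))
  # pruning an already-pruned fit at the same level changes nothing
  again <- prune_edges(fit, data, alpha = 0.01)
  expect_equal(again$omega, fit$omega)
  expect_equal(again$edge_mask, fit$edge_mask)
})
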