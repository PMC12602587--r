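test_that("model constructor enforces symmetry, zero diagonal, finiteness", {
  omega <- matrix(c(0, 1, 1, 0), 2)
  expect_s3_class(ising_model(c(0, 0), omega), "ising_model")

  bad <- omega
  bad[1, 2] <- 2
  expect_error(ising_model(c(0, 0), bad), class = "ising_validation_error")
  bad <- omega
  diag(bad) <- 1
  expect_error(ising_model(c(0, 0), bad), class = "ising_validation_error")
  expect_error(ising_model(c(0, Inf), omega), class = "ising_validation_error")
  expect_error(ising_model(c(0, 0), matrix(0, 3, 3)),
               class = "ising_dim_error")
})

test_that("potential matches hand evaluation on the worked pair model", {
  pair <- make_toy_network("pair-ln2")
  expect_equal(potential(pair, c(1, 1)), 2)
  expect_equal(potential(pair, c(1, 0)), 1)
  null3 <- make_toy_network("triple-uniform")
  expect_equal(potential(null3, c(1, 0, 1)), 1)

  expect_error(potential(pair, c(1, 0, 0)), class = "ising_dim_error")
  expect_error(potential(pair, c(1, 2)), class = "ising_binary_error")
})

test_that("log partition agrees with direct enumeration", {
  expect_equal(log_partition(make_toy_network("triple-uniform")), log(8))
  expect_equal(log_partition(make_toy_network("pair-ln2")), log(5))
  for (seed in 1:20) {
    m <- 2 + (seed %% 7)
    mod <- random_ising(m, seed)
    expect_equal(log_partition(mod), log(brute_z(mod$tau, mod$omega)),
                 tolerance = 1e-10)
  }
})

test_that("truncated partition sums only the retained patterns", {
  null3 <- make_toy_network("triple-uniform")
  expect_equal(log_partition_truncated(null3, 2), log(4))
  pair <- make_toy_network("pair-ln2")
  expect_equal(log_partition_truncated(pair, 1), log(4))
  mod <- random_ising(6, 99)
  expect_equal(log_partition_truncated(mod, 0), log_partition(mod))
  expect_error(log_partition_truncated(mod, 7), class = "ising_support_error")
})

test_that("truncated partition is non-increasing in the cutoff", {
  for (seed in 1:5) {
    mod <- random_ising(5, seed + 100)
    z <- vapply(0:5, function(k) log_partition_truncated(mod, k), numeric(1))
    expect_true(all(diff(z) <= 1e-12))
  }
})

test_that("partition functions are invariant under node relabeling", {
  mod <- random_ising(6, 7)
  set.seed(8)
  perm <- sample(6)
  permuted <- ising_model(mod$tau[perm], mod$omega[perm, perm])
  expect_equal(log_partition(permuted), log_partition(mod))
  for (k in c(1, 3, 5)) {
    expect_equal(log_partition_truncated(permuted, k),
                 log_partition_truncated(mod, k))
  }
  y <- c(1, 0, 1, 1, 0, 0)
  expect_equal(conditional_pmf(permuted, y[perm], 2),
               conditional_pmf(mod, y, 2))
})

test_that("conditional pmf restricts, renormalises, and reduces at k = 0", {
  null3 <- make_toy_network("triple-uniform")
  expect_equal(conditional_pmf(null3, c(1, 1, 0), 2), 0.25)
  expect_equal(conditional_pmf(null3, c(1, 0, 0), 2), 0)

  mod <- random_ising(5, 11)
  y <- c(1, 0, 1, 0, 0)
  expect_equal(conditional_pmf(mod, y, 0),
               brute_pmf(mod$tau, mod$omega, y, 0), tolerance = 1e-12)

  for (k in 0:5) {
    sup <- enumerate_support(5, k)
    total <- sum(apply(sup$patterns, 1, conditional_pmf, model = mod, k = k))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("support enumeration is lexicographic, unique, and of binomial size", {
  sup <- enumerate_support(3, 2)
  expect_equal(nrow(sup$patterns), 4)
  expect_setequal(
    apply(sup$patterns, 1, paste, collapse = ""),
    c("110", "101", "011", "111")
  )
  expect_equal(nrow(enumerate_support(3, 0)$patterns), 8)
  expect_equal(enumerate_support(5, 5)$patterns,
               matrix(1, 1, 5))

  for (m in c(4, 6)) {
    for (k in 0:m) {
      pats <- enumerate_support(m, k)$patterns
      expect_equal(nrow(pats), sum(choose(m, k:m)))
      expect_false(any(duplicated(pats)))
      expect_true(all(rowSums(pats) >= k))
      # lexicographic: node 1 is the most significant bit
      codes <- pats %*% 2^((m - 1):0)
      expect_true(all(diff(codes) > 0))
    }
  }

  expect_error(enumerate_support(4, 5), class = "ising_support_error")
  expect_error(log_partition(random_ising(5, 1), cap = 4),
               class = "ising_cap_error")
})
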