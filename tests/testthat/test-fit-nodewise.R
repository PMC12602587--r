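test_that("the k-1 case removal drops exactly the logically determined rows", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 400, k = 3, seed = 13)
  none <- prepare_node_regression(data, node = 1, k = 0)
  expect_length(none$dropped_rows, 0)

  reg <- prepare_node_regression(data, node = 1, k = 3)
  psum <- rowSums(data[, -1])
  expect_identical(reg$dropped_rows, which(psum == 2))
  # for every removed row the response is logically forced to 1
  expect_true(all(data[reg$dropped_rows, 1] == 1))
  expect_equal(nrow(reg$predictors) + length(reg$dropped_rows), nrow(data))

  # a single constructed row: predictors of node 1 sum to k - 1 = 2
  row <- matrix(c(1, 1, 1, 0, 0), 1)
  one <- prepare_node_regression(row, node = 1, k = 3)
  expect_identical(one$dropped_rows, 1L)

  # constructed table with a known number of forced rows for node 1
  tab <- rbind(
    matrix(rep(c(1, 1, 1, 0, 0), 7), ncol = 5, byrow = TRUE),  # psum = 2
    matrix(rep(c(1, 1, 1, 1, 0), 4), ncol = 5, byrow = TRUE),  # psum = 3
    matrix(rep(c(0, 1, 1, 1, 0), 2), ncol = 5, byrow = TRUE)   # psum = 3
  )
  reg7 <- prepare_node_regression(tab, node = 1, k = 3)
  expect_identical(reg7$dropped_rows, 1:7)

  expect_error(prepare_node_regression(rbind(c(1, 0, 0, 0, 0)), 1, k = 3),
               class = "ising_row_error")
})

test_that("corrected conditional probability is 1 at predictor sum k-1 and logistic above", {
  chain <- make_toy_network("five-chain")
  for (k in 1:3) {
    others <- c(rep(1, k - 1), rep(0, 4 - (k - 1)))
    expect_identical(
      corrected_conditional_probability(chain, 1, others, k = k, response = 1),
      1
    )
    expect_identical(
      corrected_conditional_probability(chain, 1, others, k = k, response = 0),
      0
    )
  }
  expect_error(
    corrected_conditional_probability(chain, 1, c(0, 0, 0, 0), k = 3),
    class = "ising_support_error"
  )

  null3 <- make_toy_network("triple-uniform")
  expect_equal(corrected_conditional_probability(null3, 2, c(1, 0), k = 1), 0.5)

  # k = 0: ordinary logistic, cross-checked against a joint-pmf ratio
  mod <- random_ising(4, 17)
  others <- c(1, 0, 1)
  for (node in 1:4) {
    y1 <- append(others, 1, after = node - 1)
    y0 <- append(others, 0, after = node - 1)
    ratio <- brute_pmf(mod$tau, mod$omega, y1) /
      (brute_pmf(mod$tau, mod$omega, y1) + brute_pmf(mod$tau, mod$omega, y0))
    expect_equal(
      corrected_conditional_probability(mod, node, others, k = 0),
      ratio,
      tolerance = 1e-12
    )
  }
})

test_that("dropping forced cases equals assigning them likelihood 1", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 1500, k = 2, seed = 29)
  node <- 2
  nf <- fit_node_regression(data, node, k = 2, corrected = TRUE)
  o <- matrix(0, 5, 5)
  o[node, -node] <- nf$coef
  est <- ising_model(replace(rep(0, 5), node, nf$intercept), o + t(o))
  # corrected pseudo-log-likelihood over ALL rows, forced cases contributing
  # log(1) = 0, equals the logistic log-likelihood on the retained rows
  ll_all <- sum(log(vapply(seq_len(nrow(data)), function(r) {
    corrected_conditional_probability(
      est, node, data[r, -node], k = 2, response = data[r, node]
    )
  }, numeric(1))))
  expect_equal(ll_all, nf$loglik, tolerance = 1e-10)
})

test_that("nodewise regression recovers generating parameters", {
  net <- make_true_network(seed = 3)
  data <- ising_sample(net, n = 50000, k = 2, seed = 31)
  nf <- fit_node_regression(data, node = 1, k = 2, corrected = TRUE)
  expect_true(all(abs(nf$coef - net$omega[1, -1]) < 0.1))

  # independence null at k = 0: slopes within 3 SEs of zero
  null5 <- ising_model(rep(0, 5), matrix(0, 5, 5))
  y <- ising_sample(null5, n = 5000, seed = 37)
  nf0 <- fit_node_regression(y, node = 3, k = 0)
  expect_true(all(abs(nf0$coef / nf0$se) < 3))
})

test_that("degenerate nodes are refused by name", {
  data <- cbind(rep(1, 40), rep(0:1, 20), rep(c(0, 1, 1, 0), 10))
  err <- tryCatch(fit_node_regression(data, 1, k = 0),
                  error = function(e) e)
  expect_s3_class(err, "ising_degenerate_node_error")
  expect_identical(err$nodes, 1L)
})

test_that("the AND rule includes only edges significant in both directions", {
  include <- matrix(FALSE, 3, 3)
  include[1, 2] <- TRUE # significant 1 -> 2 but not 2 -> 1
  include[1, 3] <- include[3, 1] <- TRUE
  slopes <- matrix(0, 3, 3)
  slopes[1, 2] <- 0.8
  slopes[2, 1] <- 0.7
  slopes[1, 3] <- 0.4
  slopes[3, 1] <- 0.6
  comb <- isingselect:::combine_directed(3, slopes, include, rule = "AND")
  expect_false(comb$mask[1, 2])
  expect_equal(comb$omega[1, 2], 0)
  expect_true(comb$mask[1, 3])
  expect_equal(comb$omega[1, 3], 0.5)
  comb_or <- isingselect:::combine_directed(3, slopes, include, rule = "OR")
  expect_true(comb_or$mask[1, 2])
  expect_equal(comb_or$omega[2, 1], 0.75)
})

test_that("the nodewise fit is symmetric with zero diagonal", {
  chain <- make_toy_network("five-chain")
  data <- ising_sample(chain, n = 2500, k = 2, seed = 41)
  fit <- ising_fit(data, k = 2, method = "nodewise", alpha = 0.05)
  expect_equal(fit$omega, t(fit$omega))
  expect_true(all(diag(fit$omega) == 0))
  expect_equal(fit$edge_mask, t(fit$edge_mask))
  expect_true(all(fit$omega[!fit$edge_mask] == 0))
})

test_that("separation is flagged and treated conservatively", {
  # node 1 identical to node 2: the 1 ~ 2 regression separates perfectly
  set.seed(43)
  base <- ising_sample(make_toy_network("triple-uniform"), n = 120, seed = 43)
  data <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])
  ws <- capture_warnings(
    fit <- ising_fit(data, k = 0, method = "nodewise", alpha = 0.05)
  )
  expect_true(any(grepl("separation", ws)))
  expect_false(fit$converged)
  expect_true(any(fit$diagnostics$separation))
  expect_false(fit$edge_mask[1, 2])
})

test_that("EBIC selection shrinks with gamma and empties at full penalty", {
  net <- make_true_network(seed = 5)
  data <- ising_sample(net, n = 800, k = 0, seed = 47)
  f0 <- ising_fit(data, k = 0, method = "elasso", gamma = 0)
  f1 <- ising_fit(data, k = 0, method = "elasso", gamma = 1)
  s0 <- f0$diagnostics$directed_slopes
  s1 <- f1$diagnostics$directed_slopes
  # per node, the gamma = 1 selection is no larger than the gamma = 0 one,
  # and on this nested path it is a subset
  for (node in 1:9) {
    sel0 <- which(s0[node, ] != 0)
    sel1 <- which(s1[node, ] != 0)
    expect_lte(length(sel1), length(sel0))
    expect_true(all(sel1 %in% sel0))
  }

  # a huge gamma forces the empty (maximal-penalty) end of the path
  fmax <- ising_fit(data, k = 0, method = "elasso", gamma = 1e6)
  expect_true(all(fmax$diagnostics$directed_slopes == 0))
  expect_equal(sum(fmax$edge_mask), 0)
})

test_that("eLasso selects the empty network for most null-model draws", {
  null5 <- ising_model(rep(0, 5), matrix(0, 5, 5))
  empty <- vapply(1:40, function(s) {
    y <- ising_sample(null5, n = 1000, seed = 400 + s)
    fit <- ising_fit(y, k = 0, method = "elasso", gamma = 0.25)
    sum(fit$edge_mask) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.7)
})
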