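test_that("fit metrics match their closed forms", {
  expect_equal(euclidean_error(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_error(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  x <- runif(15); y <- runif(15)
  expect_equal(euclidean_error(x, y), sqrt(sum((x - y)^2)),
               tolerance = 1e-12)
  expect_error(euclidean_error(1:3, 1:4), "equal length")

  expect_equal(spearman_correlation(1:5, 1:5), 1)
  expect_equal(spearman_correlation(1:5, 5:1), -1)
  expect_equal(spearman_correlation(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 1:2), ">= 3")

  t0 <- c(0.1, 0.3, 0.2, 0.5)
  expect_equal(explained_variance(t0, t0), 1)
  expect_equal(explained_variance(rep(mean(t0), 4), t0), 0)
  f0 <- runif(4)
  expect_equal(explained_variance(f0, t0),
               1 - sum((t0 - f0)^2) / sum((t0 - mean(t0))^2),
               tolerance = 1e-12)
  expect_error(explained_variance(1:3, rep(2, 3)), "zero variance")
})

test_that("greedy selection is exact for k = 1 and respects the exhaustive bound", {
  prof <- random_profile(6, 4, seed = 2)
  tgt <- prof$M[4, ]
  fit <- greedy_subset(prof, tgt, k = 1)
  expect_equal(fit$selected_indices, 4L)
  expect_equal(fit$train_error, 0)
  expect_equal(fit$weights, 1)

  # first step always equals the minimum single-row distance
  set.seed(3)
  for (i in 1:20) {
    p <- random_profile(8, 5, seed = 100 + i)
    t1 <- runif(5, -0.5, 0.5)
    g1 <- greedy_subset(p, t1, k = 1)
    expect_equal(g1$train_error,
                 min(sqrt(colSums((t(p$M) - t1)^2))))
    # greedy is never better than exhaustive search
    g3 <- greedy_subset(p, t1, k = 3)
    expect_gte(g3$train_error + 1e-12,
               exhaustive_subset_error(p$M, t1, 3))
  }
  expect_error(greedy_subset(prof, tgt, k = 7), "exceeds")
})

test_that("greedy tie-breaks toward the lowest neuron index", {
  M <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0, 0))
  fit <- greedy_subset(modulation_profile(M), c(0.5, 0.5), k = 1)
  expect_equal(fit$selected_indices, 1L)
})

test_that("full population weights solve the simplex least-squares problem", {
  one <- modulation_profile(matrix(c(0.2, 0.4), 1, 2))
  f1 <- full_population_weights(one, c(0, 0))
  expect_equal(unname(f1$weights), 1)
  expect_equal(f1$train_error, sqrt(0.2^2 + 0.4^2))

  # midpoint of two distinct rows
  two <- modulation_profile(rbind(c(0, 1, 0), c(1, 0, 0)))
  f2 <- full_population_weights(two, c(0.5, 0.5, 0))
  expect_equal(unname(f2$weights), c(0.5, 0.5), tolerance = 1e-9)
  expect_lt(f2$train_error, 1e-9)

  # enumeration oracle on random 3-neuron instances
  for (i in 1:10) {
    p <- random_profile(3, 15, seed = 200 + i)
    tgt <- runif(15, -0.5, 0.5)
    fit <- full_population_weights(p, tgt)
    oracle <- simplex_grid_objective(p$M, tgt, lambda = 0)
    expect_lte(objective_value(p$M, tgt, unname(fit$weights)),
               oracle$objective + 1e-6)
  }
})

test_that("the regularized fit interpolates between the exact fit and uniformity", {
  prof <- random_profile(12, 6, seed = 5)
  set.seed(5)
  tgt <- runif(6, -0.4, 0.4)

  r0 <- regularized_subset(prof, tgt, lam = 0, k = 5)
  f0 <- full_population_weights(prof, tgt)
  expect_equal(unname(r0$weights), unname(f0$weights), tolerance = 1e-7)

  rb <- regularized_subset(prof, tgt, lam = 1e6, k = 5)
  expect_lt(max(abs(rb$weights - 1 / 12)), 1e-3)

  # enumeration oracle on random 4-neuron instances at the default lambda
  for (i in 1:10) {
    p <- random_profile(4, 15, seed = 300 + i)
    t4 <- runif(15, -0.5, 0.5)
    fit <- regularized_subset(p, t4, lam = 0.8, k = 2)
    oracle <- simplex_grid_objective(p$M, t4, lambda = 0.8)
    expect_lte(objective_value(p$M, t4, unname(fit$weights), 0.8),
               oracle$objective + 1e-6)
  }
})

test_that("regularized selection reports thresholded weights and rescores equally", {
  prof <- random_profile(40, 5, seed = 7)
  set.seed(7)
  tgt <- runif(5, -0.3, 0.3)
  fit <- regularized_subset(prof, tgt, lam = 0.8, k = 10,
                            report_threshold = 2e-3)
  expect_length(fit$selected_indices, 10)
  expect_false(anyDuplicated(fit$selected_indices) > 0)
  expect_equal(fit$weight_fraction,
               mean(fit$weights >= 2e-3))
  # train error refers to the equally weighted selected subset
  expect_equal(fit$train_error,
               euclidean_error(colMeans(prof$M[fit$selected_indices, ]),
                               tgt))
  # the selected neurons carry the k largest weights
  expect_equal(sort(fit$selected_indices),
               sort(order(-fit$weights, seq_along(fit$weights))[1:10]))
})

test_that("the simplex solver agrees with an independent QP implementation", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    M <- matrix(runif(n * 15, -0.9, 0.9), n, 15)
    tgt <- runif(15, -0.5, 0.5)
    for (lam in c(0.1, 0.8)) {
      fit <- v2texture:::simplex_lsq(M, tgt, lambda = lam)
      qp <- pracma::lsqlincon(
        C = rbind(t(M), sqrt(lam) * diag(n)),
        d = c(tgt, rep(0, n)),
        Aeq = matrix(1, 1, n), beq = 1,
        lb = rep(0, n), ub = rep(1, n))
      f_mine <- objective_value(M, tgt, fit$w, lam)
      f_qp <- objective_value(M, tgt, qp, lam)
      expect_lte(f_mine, f_qp + 1e-7)
    }
  }
})

test_that("the dominance chain between fitting methods holds", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    p <- random_profile(n, 5, seed = 400 + i)
    tgt <- runif(5, -0.5, 0.5)
    k <- sample(2:4, 1)
    e_full <- full_population_weights(p, tgt)$train_error
    e_greedy <- greedy_subset(p, tgt, k)$train_error
    e_exh <- exhaustive_subset_error(p$M, tgt, k)
    expect_lte(e_full, e_greedy + 1e-9)
    expect_lte(e_full, e_exh + 1e-9)
    expect_lte(e_exh, e_greedy + 1e-12)
  }
})

test_that("train errors are invariant to neuron order", {
  p <- random_profile(15, 6, seed = 17)
  set.seed(17)
  tgt <- runif(6, -0.4, 0.4)
  perm <- sample(15)
  pp <- modulation_profile(p$M[perm, ])
  expect_equal(greedy_subset(p, tgt, 5)$train_error,
               greedy_subset(pp, tgt, 5)$train_error, tolerance = 1e-10)
  expect_equal(full_population_weights(p, tgt)$train_error,
               full_population_weights(pp, tgt)$train_error,
               tolerance = 1e-8)
  expect_equal(regularized_subset(p, tgt, 0.8, 5)$train_error,
               regularized_subset(pp, tgt, 0.8, 5)$train_error,
               tolerance = 1e-8)
})

test_that("a planted-subset target is recovered to numerical precision", {
  set.seed(19)
  M <- matrix(runif(200 * 15, -0.8, 0.8), 200, 15)
  prof <- modulation_profile(M)
  tgt <- generate_planted_target(prof, sample(200, 50))
  expect_lte(full_population_weights(prof, tgt)$train_error, 1e-8)
})

test_that("invalid neurons are excluded from fitting but keep their indices", {
  M <- rbind(c(0.1, 0.2), c(NA, 0.3), c(0.5, 0.6))
  prof <- modulation_profile(M)
  fit <- greedy_subset(prof, c(0.5, 0.6), k = 1)
  expect_equal(fit$selected_indices, 3L)
  w <- full_population_weights(prof, c(0.3, 0.4))$weights
  expect_equal(names(w), c("1", "3"))
})
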