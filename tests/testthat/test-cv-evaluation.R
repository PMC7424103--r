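test_that("CV plans partition every family into groups", {
  plan <- make_cv_plan(15, 225, group_size = 15, seed = 1)
  expect_equal(length(plan$points), 225)
  fams <- vapply(plan$points, `[[`, integer(1), "family")
  expect_equal(as.vector(table(fams)), rep(15, 15))
  for (f in 1:15) {
    got <- sort(unlist(lapply(plan$points[fams == f], `[[`, "samples")))
    expect_equal(got, 1:225)   # exact cover, pairwise disjoint
  }

  small <- make_cv_plan(2, 30, 15, seed = 2)
  expect_equal(length(small$points), 4)

  expect_identical(make_cv_plan(3, 12, 4, seed = 5),
                   make_cv_plan(3, 12, 4, seed = 5))
  expect_error(make_cv_plan(3, 10, 4), "divisible")
})

test_that("cross-validation is exact on noiseless planted tensors", {
  set.seed(21)
  planted <- matrix(runif(30 * 4, -0.6, 0.6), 30, 4)
  tens <- generate_response_tensor(
    planted_response_params(planted, n_samples = 6, noise_sd = 0))
  tgt <- generate_planted_target(modulation_profile(planted), sample(30, 10))
  plan <- make_cv_plan(4, 6, group_size = 2, seed = 3)
  cv <- cross_validate(tens, tgt, plan, "full_population")
  expect_lte(cv$mean_train_error, 1e-8)
  expect_lte(cv$mean_test_error, 1e-8)
  expect_equal(cv$n_skipped, 0)

  # fold order does not change the aggregates
  plan2 <- plan
  plan2$points <- rev(plan2$points)
  cv2 <- cross_validate(tens, tgt, plan2, "full_population")
  expect_equal(cv2$mean_test_error, cv$mean_test_error)
  expect_equal(cv2$euclidean, cv$euclidean)
})

test_that("cross-validation separates structured from label-shuffled tensors", {
  # responses with planted structure should predict a high-modulation
  # target better than exchangeable (no-structure) responses
  wins <- 0
  for (rep in 1:20) {
    set.seed(600 + rep)
    planted <- matrix(runif(20 * 3, 0.2, 0.6), 20, 3)
    tens_s <- generate_response_tensor(
      planted_response_params(planted, n_samples = 6, noise_sd = 0.1,
                              seed = rep))
    flat <- generate_response_tensor(
      planted_response_params(matrix(0, 20, 3) + 1e-9, n_samples = 6,
                              noise_sd = 0.1, seed = rep))
    tgt <- colMeans(planted)
    plan <- make_cv_plan(3, 6, 3, seed = rep)
    e_s <- cross_validate(tens_s, tgt, plan, "greedy", k = 5)$mean_test_error
    e_f <- cross_validate(flat, tgt, plan, "greedy", k = 5)$mean_test_error
    if (e_s < e_f) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("on average CV train error does not exceed test error", {
  set.seed(23)
  diffs <- vapply(1:50, function(rep) {
    planted <- matrix(runif(15 * 3, -0.5, 0.5), 15, 3)
    tens <- generate_response_tensor(
      planted_response_params(planted, n_samples = 4, noise_sd = 0.15,
                              seed = rep))
    tgt <- generate_planted_target(modulation_profile(planted), 1:5)
    plan <- make_cv_plan(3, 4, 2, seed = rep)
    cv <- cross_validate(tens, tgt, plan, "greedy", k = 5)
    # per-fold train error is a 15-dim distance, test a 1-dim deviation;
    # compare on the per-family scale
    cv$mean_train_error / sqrt(3) - cv$mean_test_error
  }, numeric(1))
  expect_lte(mean(diffs), 0)
})

test_that("leave-family-out predicts from the held-out family's profile", {
  # constant profile: every neuron has index 0.25 for every family
  arr <- array(0, c(6, 4, 2, 2))
  arr[, , , 1] <- 1.25
  arr[, , , 2] <- 0.75
  tens <- response_tensor(arr)
  prof <- modulation_matrix(tens)
  expect_equal(prof$M, matrix(0.25, 6, 4), tolerance = 1e-10)
  lfo <- leave_family_out(tens, target = c(0.25, 0.25, 0.25, 0.25),
                          method = "greedy", k = 3)
  expect_equal(lfo$family_prediction, rep(0.25, 4), tolerance = 1e-10)
  expect_lte(lfo$euclidean, 1e-9)

  set.seed(25)
  one_fam <- generate_response_tensor(
    planted_response_params(matrix(0.2, 4, 1), n_samples = 3))
  expect_error(leave_family_out(one_fam, 0.2), ">= 2")
})

test_that("leave-family-out error exceeds leave-one-group-out error on average", {
  set.seed(27)
  d <- vapply(1:30, function(rep) {
    planted <- matrix(runif(20 * 4, -0.5, 0.5), 20, 4)
    tens <- generate_response_tensor(
      planted_response_params(planted, n_samples = 4, noise_sd = 0.1,
                              seed = rep))
    tgt <- generate_planted_target(modulation_profile(planted), 1:6)
    plan <- make_cv_plan(4, 4, 2, seed = rep)
    e_cv <- cross_validate(tens, tgt, plan, "greedy", k = 5)$mean_test_error
    lfo <- leave_family_out(tens, tgt, "greedy", k = 5)
    mean(lfo$abs_error) - e_cv
  }, numeric(1))
  expect_gte(mean(d), 0)
})

test_that("the pipeline is reproducible and covers all taps and methods", {
  spec <- architecture_spec(list(
    layer_conv(4, 5, stride = 2), layer_relu(), layer_maxpool(2, 2),
    layer_conv(6, 3, stride = 1, pad = 1), layer_relu(),
    layer_maxpool(2, 2), layer_lrn()))
  cfg <- pipeline_config(
    texture_params = synthetic_texture_params(n_families = 3, n_samples = 3,
                                              image_side = 32, seed = 2),
    spec = spec, weight_modes = "structured",
    tap_points = c("conv2", "relu2", "pool2", "norm2"),
    factor = 1, methods = c("greedy", "full_population"), k = 6,
    out_dir = file.path(tempdir(), "pipe_a"), seed = 5)
  out1 <- run_pipeline(cfg)
  expect_equal(nrow(out1$fit_table), 8)   # 4 taps x 2 methods
  expect_true(all(c("conv2", "relu2", "pool2", "norm2") %in%
                    out1$fit_table$tap_point))

  cfg$out_dir <- file.path(tempdir(), "pipe_b")
  out2 <- run_pipeline(cfg)
  for (f in c("fit_results.csv", "mean_modulation.csv")) {
    expect_identical(readLines(file.path(tempdir(), "pipe_a", f)),
                     readLines(file.path(tempdir(), "pipe_b", f)))
  }
  expect_true(file.exists(file.path(tempdir(), "pipe_a", "summary.json")))
})

test_that("structure-bearing second-stage weights beat random ones in one replicate", {
  res <- compare_structured_random(seed = 101)
  expect_gt(res[["mod_structured"]], res[["mod_random"]])
  expect_lt(res[["err_structured"]], res[["err_random"]])
  expect_identical(res, compare_structured_random(seed = 101))
})
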