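test_that("local response normalization matches the scalar formula and bounds", {
  z <- array(0, c(3, 3, 4))
  expect_equal(local_response_norm(z), z)

  one <- array(1, c(1, 1, 1))
  expect_equal(local_response_norm(one)[1, 1, 1], 1 / (2 + 1e-4)^0.75,
               tolerance = 1e-10)

  a <- array(abs(rnorm(5 * 5 * 8)), c(5, 5, 8))
  expect_equal(local_response_norm(a, k = 1, alpha = 0), a)

  b <- local_response_norm(a, k = 2, alpha = 0.1, beta = 0.75, m = 5)
  expect_true(all(b >= 0))
  expect_true(all(b <= a / 2^0.75 + 1e-12))

  # channel-edge clamping: independent recomputation for one position
  kk <- 2; al <- 0.1; be <- 0.75; m <- 5
  i <- 1   # at the low edge the window spans channels 1..3
  manual <- a[2, 3, 1] / (kk + al * sum(a[2, 3, 1:3]^2))^be
  expect_equal(b[2, 3, 1], manual)

  expect_error(local_response_norm(array(-1, c(2, 2, 2))), "nonnegative")
  expect_error(local_response_norm(a, m = 4), "odd")
})

test_that("receptive field arithmetic reproduces the printed sizes", {
  s2 <- alexnet_spec(conv1_stride = 2)
  expect_identical(receptive_field_size(s2, "pool1")$rf_side, 15)
  expect_identical(receptive_field_size(s2, "pool2")$rf_side, 39)
  s4 <- alexnet_spec(conv1_stride = 4)
  expect_identical(receptive_field_size(s4, "pool2")$rf_side, 67)
  expect_identical(receptive_field_size(vgg_spec(2), "pool2")$rf_side, 16)
  expect_identical(receptive_field_size(vgg_spec(3), "pool3")$rf_side, 44)
  expect_error(receptive_field_size(s2, "pool9"), "unknown tap")
})

test_that("receptive field arithmetic agrees with an influence-support oracle", {
  # small random specs, positive weights so max pooling is monotone in the
  # input: a unit's response changes iff the perturbed pixel lies in its RF
  set.seed(11)
  specs <- list(
    architecture_spec(list(layer_conv(2, 3, stride = 1),
                           layer_relu(), layer_maxpool(2, 2))),
    architecture_spec(list(layer_conv(1, 5, stride = 2), layer_relu(),
                           layer_maxpool(3, 1), layer_conv(2, 3, stride = 1),
                           layer_relu())),
    architecture_spec(list(layer_conv(2, 3, stride = 2), layer_lrn(m = 1),
                           layer_maxpool(2, 2)))
  )
  for (spec in specs) {
    tap <- utils::tail(names(spec$layers), 1)
    rf <- receptive_field_size(spec, tap)$rf_side
    side <- rf + 6
    w <- init_weights(spec, "random", seed = 2)
    for (nm in names(w)) w[[nm]] <- abs(w[[nm]]) + 0.1
    base <- matrix(runif(side^2), side, side)
    ref <- forward_image(base, spec, w, tap)[1, 1, 1]
    affected <- matrix(FALSE, side, side)
    for (i in seq_len(side)) for (j in seq_len(side)) {
      pert <- base
      pert[i, j] <- pert[i, j] + 50
      affected[i, j] <- forward_image(pert, spec, w, tap)[1, 1, 1] != ref
    }
    support <- which(affected, arr.ind = TRUE)
    expect_equal(max(support[, 1]) - min(support[, 1]) + 1, rf)
    expect_equal(max(support[, 2]) - min(support[, 2]) + 1, rf)
  }
})

test_that("weight initialization modes honour their contracts", {
  spec <- alexnet_spec(conv1_stride = 2, n_filters_l1 = 4, n_filters_l2 = 6)
  w <- init_weights(spec, "random", seed = 3)
  expect_identical(w, init_weights(spec, "random", seed = 3))
  expect_true(all(vapply(w, function(a) all(a >= -1 & a <= 1), logical(1))))
  expect_equal(dim(w$conv1), c(4, 1, 11, 11))
  expect_equal(dim(w$conv2), c(6, 4, 5, 5))

  sh <- init_weights(spec, "shuffled", seed = 4, base = w)
  for (f in 1:4) {
    expect_equal(sort(as.vector(sh$conv1[f, 1, , ])),
                 sort(as.vector(w$conv1[f, 1, , ])))
  }
  expect_false(identical(sh$conv1, w$conv1))

  # 1x1 kernels have a single spatial position: shuffling is the identity
  spec1 <- architecture_spec(list(layer_conv(3, 1), layer_relu()))
  w1 <- init_weights(spec1, "random", seed = 5)
  expect_identical(init_weights(spec1, "shuffled", seed = 9, base = w1)[[1]],
                   w1[[1]])

  expect_error(init_weights(spec, "shuffled"), "requires")
  bad <- w; bad$conv2 <- w$conv2[, , 1:3, 1:3, drop = FALSE]
  expect_error(init_weights(spec, "provided", base = bad), "mismatch")
})

test_that("the forward pass matches direct convolution and layer contracts", {
  set.seed(6)
  img <- matrix(runif(64), 8, 8)

  # single 1x1 identity filter passes the input through
  spec_id <- architecture_spec(list(layer_conv(1, 1)))
  w_id <- structure(list(conv1 = array(1, c(1, 1, 1, 1))),
                    class = "weight_set")
  expect_equal(forward_image(img, spec_id, w_id, "conv1")[, , 1], img)

  # 3x3 averaging against the direct-loop oracle (interior = valid region)
  spec_avg <- architecture_spec(list(layer_conv(1, 3, stride = 1, pad = 1)))
  w_avg <- structure(list(conv1 = array(1 / 9, c(1, 1, 3, 3))),
                     class = "weight_set")
  out <- forward_image(img, spec_avg, w_avg, "conv1")[, , 1]
  expect_equal(out[2:7, 2:7], direct_xcorr(img, matrix(1 / 9, 3, 3)))
  const <- matrix(2, 8, 8)
  expect_equal(forward_image(const, spec_avg, w_avg, "conv1")[2:7, 2:7, 1],
               matrix(2, 6, 6))

  # rectified taps are nonnegative
  spec2 <- alexnet_spec(conv1_stride = 2, n_filters_l1 = 3, n_filters_l2 = 4)
  w2 <- init_weights(spec2, "random", seed = 8)
  big <- matrix(runif(64 * 64), 64, 64)
  expect_true(all(forward_image(big, spec2, w2, "relu1") >= 0))

  # stride and pad bookkeeping: strided conv output size
  spec_s <- architecture_spec(list(layer_conv(1, 3, stride = 2, pad = 1)))
  w_s <- init_weights(spec_s, "random", seed = 1)
  expect_equal(dim(forward_image(img, spec_s, w_s, "conv1"))[1:2], c(4, 4))

  # a map that shrinks below 1x1 names the offending layer
  spec_bad <- architecture_spec(list(layer_conv(1, 3), layer_maxpool(9, 2)))
  w_bad <- init_weights(spec_bad, "random", seed = 1)
  expect_error(forward_image(matrix(1, 6, 6) + img[1:6, 1:6] * 0,
                             spec_bad, w_bad, "pool1"), "pool1")
})

test_that("grayscale stimuli are replicated over declared input channels", {
  spec3 <- architecture_spec(list(layer_conv(2, 3)), input_channels = 3)
  w3 <- init_weights(spec3, "random", seed = 2)
  img <- matrix(runif(36), 6, 6)
  out <- forward_image(img, spec3, w3, "conv1")
  # equivalent single-channel filter: sum over the channel dimension
  wsum <- structure(list(conv1 = array(apply(w3$conv1, c(1, 3, 4), sum),
                                       c(2, 1, 3, 3))), class = "weight_set")
  spec1 <- architecture_spec(list(layer_conv(2, 3)), input_channels = 1)
  expect_equal(out, forward_image(img, spec1, wsum, "conv1"))
})

test_that("translation covariance holds away from the borders", {
  spec <- architecture_spec(list(layer_conv(2, 3, stride = 2),
                                 layer_relu(), layer_maxpool(2, 2)))
  w <- init_weights(spec, "random", seed = 13)
  jump <- receptive_field_size(spec, "pool1")$jump
  set.seed(14)
  img <- matrix(runif(40 * 40), 40, 40)
  shifted <- rbind(img[-seq_len(jump), ], matrix(0, jump, 40))
  m1 <- forward_image(img, spec, w, "pool1")
  m2 <- forward_image(shifted, spec, w, "pool1")
  S <- dim(m1)[1]
  expect_equal(m1[3:(S - 1), 2:(S - 1), ], m2[2:(S - 2), 2:(S - 1), ])
})

test_that("population extraction uses the centered neighborhood in stable order", {
  maps <- array(seq_len(6 * 6 * 128) / 100, c(6, 6, 128))
  pop <- extract_population(maps, population_selector(NULL, 2, "tap"))
  expect_equal(nrow(pop$responses), 512)   # 128 filters x 2x2
  expect_equal(pop$meta$filter[1:8], rep(1:2, each = 4))
  expect_equal(pop$meta$row[1:4], c(3, 3, 4, 4))
  expect_equal(pop$meta$col[1:4], c(3, 4, 3, 4))
  expect_equal(pop$responses[1, 1], maps[3, 3, 1])
  expect_equal(pop$responses[4, 1], maps[4, 4, 1])

  odd <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  p1 <- extract_population(odd, population_selector(NULL, 1, "tap"))
  expect_equal(p1$responses[, 1], c(odd[3, 3, 1], odd[3, 3, 2]))

  full <- extract_population(odd, population_selector(NULL, 5, "tap"))
  expect_equal(nrow(full$responses), 2 * 25)

  expect_error(extract_population(odd, population_selector(NULL, 6, "t")),
               "larger")
  expect_error(extract_population(odd, population_selector(5, 1, "t")),
               "out of range")
})

test_that("compute_response_tensor assembles a consistent tensor", {
  p <- synthetic_texture_params(n_families = 2, n_samples = 2,
                                image_side = 32, seed = 1)
  ens <- build_ensemble(generate_texture_set(p), factor = 1, seed = 2)
  spec <- architecture_spec(list(layer_conv(3, 5, stride = 2), layer_relu(),
                                 layer_maxpool(2, 2)))
  w <- init_weights(spec, "random", seed = 3)
  sel <- population_selector(NULL, 2, "pool1")
  tens <- compute_response_tensor(ens, spec, w, sel)
  expect_s3_class(tens, "response_tensor")
  expect_equal(dim(tens), c(12, 2, 2, 2))
  expect_true(all(tens >= 0))
  # spot check one entry against a direct forward pass
  maps <- forward_image(ens$families[[2]]$samples[[1]]$noise, spec, w, "pool1")
  direct <- extract_population(maps, sel)$responses[, 1]
  expect_equal(tens[, 2, 1, 2], direct)
})
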