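# dual-pathway network: shape arithmetic vs a brute-force forward pass,
# the softmax-with-loss identities, and training/prediction contracts

test_that("the 51 px trace matches the published feature-map geometry", {
  tr <- trace_shapes(network_spec())
  expect_equal(tr$size, c(51, 47, 23, 19, 9, 5, 5, 1))
  concat <- tr[tr$layer == "concat", ]
  expect_equal(concat$channels, 128)
  expect_equal(concat$size, 5)
  cascade <- tr[tr$layer == "cascade", ]
  expect_equal(cascade$channels, 512)
  expect_equal(cascade$size, 1)
})

test_that("inputs smaller than the first kernel are rejected", {
  spec <- network_spec()
  expect_error(trace_shapes(spec, input_size = 4L), "too small")
})

test_that("trace arithmetic agrees with a brute-force layer-by-layer pass", {
  # chain the actual conv/pool primitives (small channel counts) over every
  # input size 31..91 and compare spatial dims; inadmissible sizes must fail
  # in both routes at the same depth
  spec <- network_spec(channels = c(2L, 3L, 4L), cascade = 6L, fc_tap = 4L,
                       fc_join = 4L)
  brute_sizes <- function(p) {
    x <- array(runif(p * p), c(p, p, 1))
    sizes <- c(p)
    conv <- function(x, cout) {
      cin <- dim(x)[3]
      W <- matrix(runif(cout * cin * 25), cout)
      dualpathseg:::cpp_conv2d_forward(x, W, numeric(cout), 5L)
    }
    for (l in 1:2) {
      x <- conv(x, spec$channels[l]); sizes <- c(sizes, dim(x)[1])
      x <- dualpathseg:::cpp_maxpool2d(x, 3L, 2L); sizes <- c(sizes, dim(x)[1])
    }
    x <- conv(x, spec$channels[3]); sizes <- c(sizes, dim(x)[1])
    cc <- array(c(x, x), c(dim(x)[1:2], 2 * dim(x)[3]))
    sizes <- c(sizes, dim(cc)[1])
    out <- conv(cc, spec$cascade)
    c(sizes, dim(out)[1])
  }
  for (p in 31:91) {
    traced <- tryCatch(trace_shapes(spec, input_size = p), error = identity)
    brute <- tryCatch(brute_sizes(p), error = identity)
    if (inherits(traced, "error")) {
      expect_true(inherits(brute, "error"), label = sprintf("p = %d", p))
    } else {
      expect_equal(traced$size, brute, label = sprintf("p = %d", p))
    }
  }
})

test_that("softmax probabilities and loss follow the defining identities", {
  r <- softmax_loss(c(0, 0), 1)
  expect_equal(r$sigma, c(0.5, 0.5))
  expect_equal(r$loss, log(2))
  r2 <- softmax_loss(c(2, 0), 1)
  expect_equal(r2$loss, log(1 + exp(-2)))
  set.seed(4)
  for (i in 1:20) {
    z <- rnorm(5, sd = 10)
    y <- sample(5, 1)
    r <- softmax_loss(z, y)
    expect_gte(min(r$sigma), 0)
    expect_equal(sum(r$sigma), 1, tolerance = 1e-12)
    # loss = -log(sigma_y) to machine precision (absolute: sigma_y can
    # round to 1 when one score dominates)
    expect_lt(abs(r$loss - (-log(r$sigma[y]))), 1e-10)
    # shift invariance
    expect_equal(softmax_loss(z + 17.3, y)$sigma, r$sigma, tolerance = 1e-12)
  }
  # stability for large scores
  expect_equal(softmax_loss(c(1000, 998), 1)$loss, log(1 + exp(-2)),
               tolerance = 1e-9)
})

test_that("a training step with zero learning rate leaves parameters unchanged", {
  spec <- network_spec(channels = c(2L, 3L, 4L), cascade = 6L, fc_tap = 4L,
                       fc_join = 4L)
  init <- dualpathseg:::init_weights(spec, seed = 8L)
  ptr <- dualpathseg:::cpp_net_create(init$weights, init$biases, c(spec, list()))
  set.seed(2)
  xs <- array(runif(51 * 51 * 2), c(51, 51, 2))
  drop <- matrix(1, 2, spec$fc_join)
  dualpathseg:::cpp_net_train_batch(ptr, xs, xs, c(0L, 1L), drop,
                                    lr = 0, momentum = 0.9, weight_decay = 0)
  after <- dualpathseg:::cpp_net_weights(ptr)
  for (i in seq_along(init$weights))
    expect_equal(after$weights[[i]], init$weights[[i]], tolerance = 1e-7)
})

test_that("training is deterministic for a fixed seed", {
  sp <- fix_samples()
  sub <- dualpathseg:::sample_subset(sp$train, 1:64)
  cfg <- train_config(batch_size = 32L, epochs = 1L, seed = 77L)
  m1 <- train_network(sub, NULL, network_spec(channels = c(2L, 3L, 4L),
                                              cascade = 6L, fc_tap = 4L,
                                              fc_join = 4L), cfg)
  m2 <- train_network(sub, NULL, network_spec(channels = c(2L, 3L, 4L),
                                              cascade = 6L, fc_tap = 4L,
                                              fc_join = 4L), cfg)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$weights, m2$weights)
})

test_that("a bias-only classifier outputs the softmax of its biases", {
  spec <- network_spec(channels = c(2L, 3L, 4L), cascade = 6L, fc_tap = 4L,
                       fc_join = 4L)
  init <- dualpathseg:::init_weights(spec, seed = 1L)
  zeroed <- lapply(init$weights, function(w) w * 0)
  biases <- init$biases
  biases[[11]] <- c(0.3, -0.7)
  model <- dualpathseg:::new_model(spec, zeroed, biases, input_scale = 255)
  set.seed(6)
  xs <- array(runif(51 * 51 * 4, 0, 255), c(51, 51, 4))
  p <- predict_batch(model, xs, xs)
  expect_equal(p, rep(softmax_loss(c(0.3, -0.7), 1)$sigma[2], 4),
               tolerance = 1e-6)
})

test_that("duplicated inputs get identical probabilities and shapes are enforced", {
  model <- fix_model()
  sp <- fix_samples()
  one_s <- sp$val$small[, , 1, drop = FALSE]
  one_l <- sp$val$large[, , 1, drop = FALSE]
  dup_s <- array(one_s[, , c(1, 1, 1)], c(51, 51, 3))
  dup_l <- array(one_l[, , c(1, 1, 1)], c(51, 51, 3))
  p <- predict_batch(model, dup_s, dup_l)
  expect_true(all(p == p[1]))
  expect_true(all(p >= 0 & p <= 1))
  bad <- array(0, c(31, 31, 2))
  expect_error(predict_batch(model, bad, bad), "patches must be")
})

test_that("the network separates phantom textures", {
  model <- fix_model()
  sp <- fix_samples()
  expect_gte(model$val_accuracy, 0.95)
  p <- predict_batch(model, sp$val)
  y <- sp$val$label
  auroc <- mean(outer(p[y == 1], p[y == 0], `>`) +
                  0.5 * outer(p[y == 1], p[y == 0], `==`))
  expect_gte(auroc, 0.99)
  # learning happened: late-epoch loss well below the -ln(0.5) baseline
  tail_loss <- mean(tail(model$history$loss, 5))
  expect_lt(tail_loss, log(2))
})
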