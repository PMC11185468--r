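test_that("enumeration matches the hand-counted census of the fixture CNN", {
  m <- make_tiny_cnn(seed = 3L)
  lay <- enumerate_target_layers(m)
  # 3 x (conv, norm, relu, pool) + gap + fc, counted from the architecture
  expect_equal(nrow(lay), 14L)
  expect_equal(lay$index, 0:13)
  expect_equal(lay$name[1:4], c("conv1", "norm1", "relu1", "pool1"))
  expect_equal(sum(lay$shape_class == "spatial2d"), 12L)
  expect_equal(lay$shape_class[13:14], c("vector1d", "vector1d"))
  # forward-definition order is enumeration order
  expect_equal(lay$kind[c(1, 5, 9)], rep("conv2d", 3))
  # determinism
  expect_identical(lay, enumerate_target_layers(m))
})

test_that("a single-layer model enumerates to one LayerRef with index 0", {
  conv <- camroad:::cr_conv2d(1L, 1L, name = "only")
  m <- camroad:::cr_sequential(list(conv), c(4L, 4L, 1L), "single")
  lay <- enumerate_target_layers(m)
  expect_equal(nrow(lay), 1L)
  expect_equal(lay$index, 0L)
  expect_error(enumerate_target_layers(m, include_filter = function(l) FALSE),
               "no qualifying")
})

test_that("output-shape classification follows the 1-D filtering rule", {
  expect_equal(classify_output_shape(c(1, 256, 14, 14)), "spatial2d")
  expect_equal(classify_output_shape(c(1, 1000)), "vector1d")
  expect_equal(classify_output_shape(c(1, 49, 768)), "token_sequence")
  expect_equal(classify_output_shape(c(1, 32, 1, 1)), "vector1d")
  expect_equal(classify_output_shape(c(1, 8, 1, 7)), "vector1d")
  expect_error(classify_output_shape(integer(0)), "positive")
  expect_error(classify_output_shape(c(1, 0, 3)), "positive")
})

test_that("capture returns exact activations for an identity convolution", {
  conv <- camroad:::cr_conv2d(1L, 1L, kernel = 1L, pad = 0L, name = "id")
  conv$params$weight[1, 1] <- 1
  fc <- camroad:::cr_linear(16L, 2L, name = "fc")
  fc$params$weight[] <- matrix(rnorm(32), 2, 16)
  m <- camroad:::cr_sequential(list(conv, fc), c(4L, 4L, 1L), "idmodel")
  img <- matrix(runif(16), 4, 4)
  cap <- capture(m, img, layers = "id")
  expect_equal(array(cap$activations$id, c(4, 4)), img)
})

test_that("captured gradient of y = w * GAP(A) is constant w / (H*W)", {
  h <- 6L; w_val <- 1.7
  m <- gap_linear_model(h = h, w_out = w_val)
  img <- matrix(runif(h * h), h, h)
  cap <- capture(m, img, layers = "conv", target = 1L, need_gradients = TRUE)
  g <- array(cap$gradients$conv, c(h, h))
  expect_equal(g, matrix(w_val / (h * h), h, h), tolerance = 1e-12)
})

test_that("capture is deterministic and never mutates the model", {
  m <- make_tiny_cnn(seed = 5L)
  img <- default_split()$test[[1]]$image
  before <- camroad:::cr_param_checksum(m)
  cap1 <- capture(m, img, need_gradients = TRUE)
  cap2 <- capture(m, img, need_gradients = TRUE)
  expect_identical(cap1$activations, cap2$activations)
  expect_identical(cap1$gradients, cap2$gradients)
  expect_identical(camroad:::cr_param_checksum(m), before)
})

test_that("capture rejects an out-of-range target naming the class count", {
  m <- make_tiny_cnn(seed = 5L)
  img <- default_split()$test[[1]]$image
  expect_error(capture(m, img, target = 7L), "2 classes")
  expect_error(capture(m, matrix(0, 8, 8)), "does not match")
})

test_that("profile totals are exact and invariant to weights", {
  m1 <- make_tiny_cnn(seed = 1L)
  m2 <- make_tiny_cnn(seed = 99L)
  p1 <- profile(m1)
  # hand-computed from the stated architecture:
  # conv 80 + bn 16 + conv 1168 + bn 32 + conv 4640 + bn 64 + fc 66
  expect_equal(p1$total_params, 6066)
  expect_equal(p1$n_target_layers, 14L)
  expect_equal(profile(m2)$total_params, p1$total_params)
  pool_only <- camroad:::cr_sequential(
    list(camroad:::cr_maxpool2d("p")), c(4L, 4L, 1L), "pool")
  expect_equal(profile(pool_only)$total_params, 0)
  js <- jsonlite::fromJSON(profile_json(p1))
  expect_equal(js$total_params, 6066)
  expect_equal(nrow(js$layers), 14L)
})
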