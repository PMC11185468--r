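test_that("gradcam reproduces the closed-form map of the one-layer GAP model", {
  h <- 6L
  m <- gap_linear_model(h = h, w_out = 1)
  img <- matrix(runif(h * h, 0.1, 1), h, h)
  fr <- compute_cam(m, img, "conv", target = 1L, scheme = "gradcam")
  # alpha = mean gradient = 1/(H*W), so the pre-ReLU map is A / (H*W)
  expect_equal(fr$pre_relu_map, img / (h * h), tolerance = 1e-12)
  expect_equal(fr$raw_map, img / (h * h), tolerance = 1e-12)
})

test_that("everywhere-negative pre-ReLU maps rectify to identically zero", {
  h <- 6L
  m <- gap_linear_model(h = h, w_out = 1)
  img <- matrix(-runif(h * h, 0.1, 1), h, h)   # negative activations
  for (sc in c("gradcam", "hirescam", "layercam")) {
    fr <- compute_cam(m, img, "conv", target = 1L, scheme = sc)
    expect_true(all(fr$raw_map == 0), info = sc)
  }
})

test_that("linear schemes are scale covariant on the one-layer fixture", {
  h <- 6L
  m <- gap_linear_model(h = h, w_out = 1)
  img <- matrix(runif(h * h, -0.5, 1), h, h)
  for (sc in c("gradcam", "hirescam", "xgradcam")) {
    f1 <- compute_cam(m, img, "conv", target = 1L, scheme = sc)
    f3 <- compute_cam(m, 3 * img, "conv", target = 1L, scheme = sc)
    expect_equal(f3$pre_relu_map, 3 * f1$pre_relu_map, tolerance = 1e-6,
                 info = sc)
  }
})

test_that("gradcam maps are class discriminative on disjoint evidence", {
  m <- two_half_model(h = 8L)
  img <- two_half_image(h = 8L)
  f1 <- compute_cam(m, img, "conv", target = 1L, scheme = "gradcam")
  f2 <- compute_cam(m, img, "conv", target = 2L, scheme = "gradcam")
  am1 <- which(f1$raw_map == max(f1$raw_map), arr.ind = TRUE)[1, ]
  am2 <- which(f2$raw_map == max(f2$raw_map), arr.ind = TRUE)[1, ]
  expect_lte(am1["col"], 4L)   # class-1 evidence in the left half
  expect_gte(am2["col"], 5L)   # class-2 evidence in the right half
})

test_that("randomcam is seed-reproducible with weights in [-1, 1]", {
  w1 <- channel_weights("randomcam", array(1, c(4, 4, 64)), seed = 11L)
  w2 <- channel_weights("randomcam", array(1, c(4, 4, 64)), seed = 11L)
  w3 <- channel_weights("randomcam", array(1, c(4, 4, 64)), seed = 12L)
  expect_identical(w1$value, w2$value)
  expect_false(identical(w1$value, w3$value))
  expect_true(all(w1$value >= -1 & w1$value <= 1))
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  fa <- compute_cam(m, img, "conv3", 2L, "randomcam", seed = 7L)
  fb <- compute_cam(m, img, "conv3", 2L, "randomcam", seed = 7L)
  expect_identical(fa$raw_map, fb$raw_map)
})

test_that("eigencam recovers the map of a rank-1 activation and ignores the class", {
  h <- 5L; k <- 6L
  V <- matrix(runif(h * h), h, h)
  u <- runif(k, 0.5, 2)
  A <- array(0, c(h, h, k))
  for (j in seq_len(k)) A[, , j] <- u[j] * V
  w <- channel_weights("eigencam", A)
  expect_equal(w$type, "direct")
  ratio <- w$value / V
  expect_lt(diff(range(ratio)), 1e-8)       # proportional to V
  expect_gte(sum(w$value), 0)               # sign convention
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  e1 <- compute_cam(m, img, "conv3", 1L, "eigencam")
  e2 <- compute_cam(m, img, "conv3", 2L, "eigencam")
  expect_identical(e1$raw_map, e2$raw_map)
})

test_that("per-scheme weight rules hold on hand-built inputs", {
  # gradcam on a constant gradient: alpha_k equals the constant
  A <- array(runif(32), c(4, 4, 2))
  G <- array(rep(c(0.3, -1.2), each = 16), c(4, 4, 2))
  w <- channel_weights("gradcam", A, G)
  expect_equal(w$value, c(0.3, -1.2), tolerance = 1e-12)
  # ablationcam: a channel whose removal leaves the score unchanged gets 0
  oracle <- function(kind, ...) {
    args <- list(...)
    switch(kind, base_score = 5,
           ablated_score = if (args$channel == 1L) 3 else 5)
  }
  wa <- channel_weights("ablationcam", A, oracle = oracle)
  expect_equal(wa$value[2], 0)
  expect_gt(wa$value[1], 0)
  # scorecam: all-constant activations yield zero weights, no blow-up
  wz <- channel_weights("scorecam", array(0, c(4, 4, 3)),
                        oracle = function(kind, ...) stop("not called"))
  expect_equal(wz$value, c(0, 0, 0))
})

test_that("scorecam and ablationcam run end to end on the trained fixture", {
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  fs <- compute_cam(m, img, "conv3", 2L, "scorecam")
  fa <- compute_cam(m, img, "conv3", 2L, "ablationcam")
  expect_true(all(is.finite(fs$raw_map)))
  expect_true(all(is.finite(fa$raw_map)))
  expect_gt(max(fs$raw_map), 0)
})

test_that("bilinear upsampling matches its closed form and edge cases", {
  # 1x1 constant extension
  expect_equal(upsample_bilinear(matrix(3.5, 1, 1), 5, 7),
               matrix(3.5, 5, 7))
  # 2x2 -> 4x4 against independently computed bilinear weights
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  s <- (0:3) / 3
  w0 <- 1 - s; w1 <- s
  expected <- outer(w0, w0) * m[1, 1] + outer(w0, w1) * m[1, 2] +
    outer(w1, w0) * m[2, 1] + outer(w1, w1) * m[2, 2]
  got <- upsample_bilinear(m, 4, 4)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got[c(1, 4), c(1, 4)], m)    # corners preserved
  # idempotence at identical shape
  r <- matrix(runif(12), 3, 4)
  expect_equal(upsample_bilinear(r, 3, 4), r)
  expect_error(upsample_bilinear(r, 0, 4), "positive")
})

test_that("scheme and layer validation errors are informative", {
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  expect_error(compute_cam(m, img, "conv3", 2L, "notascheme"))
  expect_error(compute_cam(m, img, "gap", 2L, "gradcam"), "filtered out")
  expect_error(compute_cam(m, img, "fc", 2L, "gradcam"), "vector1d")
})
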