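test_that("dataset splits follow the 80-10-10 proportions and are seeded", {
  ds <- make_dataset(n = 100L, seed = 2L)
  expect_equal(length(ds$train), 80L)
  expect_equal(length(ds$val), 10L)
  expect_equal(length(ds$test), 10L)
  ds2 <- make_dataset(n = 100L, seed = 2L)
  expect_identical(ds, ds2)
  ds3 <- make_dataset(n = 100L, seed = 3L)
  expect_false(identical(ds$train[[1]]$image, ds3$train[[1]]$image))
  expect_error(make_dataset(n = 10L), "at least 20")
  expect_error(make_dataset(n = 100L, contrast = 0), "positive")
})

test_that("labels, masks and contrast behave as specified", {
  ds <- make_dataset(n = 40L, contrast = 0.4, noise_level = 0, seed = 4L)
  all_samples <- c(ds$train, ds$val, ds$test)
  labels <- vapply(all_samples, `[[`, 1L, "label")
  expect_equal(sort(unique(labels)), c(0L, 1L))
  expect_equal(sum(labels), 20L)            # class balanced
  for (s in all_samples) {
    expect_equal(s$label == 1L, any(s$truth_mask))  # label 1 iff lesion
    if (s$label == 1L) {
      # noiseless limit: lesion pixels exactly at background + contrast
      expect_equal(unique(s$image[s$truth_mask]), 0.3 + 0.4)
      expect_equal(unique(s$image[!s$truth_mask]), 0.3)
    }
  }
  # with speckle, mean lesion intensity still exceeds background by ~contrast
  dsn <- make_dataset(n = 40L, contrast = 0.4, noise_level = 0.15, seed = 4L)
  les <- Filter(function(s) s$label == 1L, dsn$train)
  gaps <- vapply(les, function(s)
    mean(s$image[s$truth_mask]) - mean(s$image[!s$truth_mask]), 1.0)
  expect_true(all(gaps > 0.25))
})

test_that("the tiny CNN census matches the stated architecture", {
  m <- make_tiny_cnn(seed = 6L)
  # conv1 3*3*1*8+8 = 80, bn1 16, conv2 3*3*8*16+16 = 1168, bn2 32,
  # conv3 3*3*16*32+32 = 4640, bn3 64, fc 32*2+2 = 66  => 6066
  expect_equal(camroad:::cr_param_count(m), 80 + 16 + 1168 + 32 + 4640 + 64 + 66)
  expect_equal(nrow(enumerate_target_layers(m)), 14L)
  expect_identical(camroad:::cr_param_vector(make_tiny_cnn(seed = 6L)),
                   camroad:::cr_param_vector(m))
  expect_false(identical(camroad:::cr_param_vector(make_tiny_cnn(seed = 7L)),
                         camroad:::cr_param_vector(m)))
})

test_that("zero-epoch training leaves the model bit-unchanged", {
  ds <- make_dataset(n = 40L, seed = 5L)
  m <- make_tiny_cnn(seed = 5L)
  before <- camroad:::cr_param_checksum(m)
  fit <- train_fixture(m, ds, epochs = 0L)
  expect_identical(camroad:::cr_param_checksum(fit$model), before)
  expect_false(fit$diverged)
})

test_that("one epoch of training reduces the loss from its initial value", {
  ds <- make_dataset(n = 120L, seed = 8L)
  m <- make_tiny_cnn(seed = 8L)
  fit <- train_fixture(m, ds, epochs = 2L, seed = 8L)
  expect_lt(fit$history$loss[2], fit$history$loss[1])
})

test_that("training improves test accuracy over random weights (10 seeds)", {
  wins <- 0L
  for (seed in 1:10) {
    ds <- make_dataset(n = 120L, seed = seed)
    m0 <- make_tiny_cnn(seed = seed)
    acc0 <- camroad:::cr_eval_accuracy(m0, ds$test)
    fit <- train_fixture(m0, ds, epochs = 4L, seed = seed)
    acc1 <- fit$test_accuracy
    wins <- wins + (acc1 > acc0)
  }
  expect_gte(wins, 9L)
})

test_that("localization IoU handles exact, disjoint and invalid inputs", {
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  expect_equal(localization_iou(mask * 1.0, mask, 0.5), 1)
  other <- matrix(0, 8, 8); other[7:8, 7:8] <- 1
  expect_equal(localization_iou(other, mask, 0.5), 0)
  expect_error(localization_iou(other, matrix(FALSE, 8, 8)), "empty truth")
})

test_that("gradcam entropy decreases from the first to the last conv block", {
  # diffuse early activations vs focused late ones, measured at the
  # rectified block outputs (the signed pre-norm conv response is sparse
  # and not representative of what the block passes forward)
  fit <- trained_fixture()
  smp <- lesion_test_samples(10)
  drops <- vapply(smp, function(s) {
    f_first <- compute_cam(fit$model, s$image, "relu1", 2L, "gradcam")
    f_last <- compute_cam(fit$model, s$image, "relu3", 2L, "gradcam")
    map_entropy(f_first$raw_map) - map_entropy(f_last$raw_map)
  }, 1.0)
  expect_gt(mean(drops), 0)
})

test_that("the pipeline also accepts 224x224 inputs", {
  m <- make_tiny_cnn(seed = 2L, input_size = 224L)
  img <- matrix(runif(224 * 224), 224, 224)
  fr <- compute_cam(m, img, "conv3", 1L, "gradcam")
  expect_equal(dim(fr$raw_map), c(224L, 224L))
})

test_that("fixture export writes PNGs and a labels CSV", {
  out <- withr::local_tempdir()
  ds <- make_dataset(n = 20L, seed = 9L)
  csv <- export_fixture_png(ds, out)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 20L)
  expect_true(all(file.exists(file.path(out, df$file))))
  back <- png::readPNG(file.path(out, df$file[1]))
  orig_first <- ds$train[[1]]$image
  expect_equal(dim(back), dim(orig_first))
})
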