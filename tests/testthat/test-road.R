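test_that("pixel selection counts, ranks and tie-breaks are exact", {
  m10 <- matrix(runif(100), 10, 10)
  expect_equal(sum(select_pixels(m10, 0.2, "most_relevant")), 20L)
  for (p in c(0.2, 0.4, 0.6, 0.8)) {
    expect_equal(sum(select_pixels(m10, p, "most_relevant")),
                 round(p * 100), info = p)
  }
  # strictly increasing map: most_relevant 0.5 is exactly the upper half
  inc <- matrix(seq(0, 1, length.out = 64), 8, 8)
  mk <- select_pixels(inc, 0.5, "most_relevant")
  expect_true(all(inc[mk] > inc[!mk]))
  # constant map: ties broken by ascending flat index (stable-sort oracle)
  cst <- matrix(0.5, 10, 10)
  mk2 <- select_pixels(cst, 0.3, "most_relevant")
  oracle <- logical(100); oracle[order(rep(0.5, 100), seq_len(100))[1:30]] <- TRUE
  expect_equal(as.vector(mk2), oracle)
  expect_equal(which(mk2), 1:30)
  # monotone mask growth in p
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(p) sum(select_pixels(m10, p, "least_relevant")), 1L)
  expect_true(all(diff(sizes) > 0))
})

test_that("noisy linear imputation solves the neighbor-mean system exactly", {
  # single interior pixel with equal neighbors
  img <- matrix(0.7, 5, 5)
  mk <- matrix(FALSE, 5, 5); mk[3, 3] <- TRUE
  expect_equal(noisy_linear_impute(img, mk, noise_sd = 0)[3, 3], 0.7)
  # corner pixel with two neighbors a, b -> (a+b)/2
  img2 <- matrix(runif(25), 5, 5)
  mk2 <- matrix(FALSE, 5, 5); mk2[1, 1] <- TRUE
  got <- noisy_linear_impute(img2, mk2, noise_sd = 0)[1, 1]
  expect_equal(got, (img2[2, 1] + img2[1, 2]) / 2)
  # unmasked pixels bit-unchanged; empty mask returns the image bit-identical
  out2 <- noisy_linear_impute(img2, mk2, noise_sd = 0.05, seed = 3L)
  expect_identical(out2[!mk2], img2[!mk2])
  expect_identical(noisy_linear_impute(img2, matrix(FALSE, 5, 5)), img2)
})

test_that("sparse imputation equals the dense solve on random 8x8 instances", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      img <- matrix(runif(64), 8, 8)
      mk <- matrix(FALSE, 8, 8)
      mk[sample(64, round(0.2 * 64))] <- TRUE
    })
    sparse <- noisy_linear_impute(img, mk, noise_sd = 0)
    dense <- dense_impute_oracle(img, mk)
    expect_lt(max(abs(sparse - dense)), 1e-8)
  }
})

test_that("a fully masked image falls back to channel-mean fill with warning", {
  img <- matrix(runif(16), 4, 4)
  expect_warning(out <- noisy_linear_impute(img, matrix(TRUE, 4, 4),
                                            noise_sd = 0), "ill-posed")
  expect_equal(out, matrix(mean(img), 4, 4))
})

test_that("the combined score is exactly antisymmetric under label swap", {
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  fr <- compute_cam(m, img, "conv3", 2L, "gradcam")
  cfg <- road_config(seed = 17L)
  fwdward <- road_score(m, img, fr, 2L, cfg)
  swapped <- road_score(m, img, fr, 2L, cfg,
                        orders = c("most_relevant", "least_relevant"))
  expect_identical(swapped$combined, -fwdward$combined)
  expect_identical(swapped$per_fraction$C_LRP, fwdward$per_fraction$C_MRP)
})

test_that("a symmetric map on a symmetric image scores exactly zero", {
  # map whose LRP and MRP selections produce identical imputed images:
  # constant saliency on a constant image
  m <- trained_fixture()$model
  img <- matrix(0.4, 64, 64)
  sal <- matrix(0.5, 64, 64)
  rs <- road_score(m, img, sal, 2L, road_config(noise_sd = 0, seed = 2L))
  expect_equal(rs$combined, 0)
})

test_that("truth-oracle saliency outscores inverted-truth saliency", {
  m <- trained_fixture()$model
  smp <- lesion_test_samples(3)
  wins <- 0L
  for (s in smp) {
    truth_map <- s$truth_mask * 1.0
    rs_truth <- road_score(m, s$image, truth_map, 2L, road_config(seed = 5L))
    rs_inv <- road_score(m, s$image, 1 - truth_map, 2L, road_config(seed = 5L))
    wins <- wins + (rs_truth$combined > rs_inv$combined)
  }
  expect_gte(wins, 2L)
})

test_that("the ybROAD series summaries and length are consistent", {
  m <- trained_fixture()$model
  img <- lesion_test_samples(1)[[1]]$image
  yb <- ybroad(m, img, "gradcam", 2L, road_config(seed = 9L))
  lay <- enumerate_target_layers(m)
  expect_equal(nrow(yb$series), sum(lay$shape_class == "spatial2d"))
  expect_equal(yb$mean_score, mean(yb$series$combined))
  expect_equal(yb$max_score, max(yb$series$combined))
  amax <- yb$series$layer_index[which.max(yb$series$combined)]
  expect_equal(yb$argmax_layer_index, amax)
  expect_equal(nrow(yb$skipped), sum(lay$shape_class != "spatial2d"))
  g <- glance(yb)
  expect_equal(g$mean_score, yb$mean_score)
  expect_equal(nrow(tidy(yb)), nrow(yb$series))
})
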