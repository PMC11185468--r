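make_frame <- function(map, index = 0L, name = "conv") {
  structure(list(layer_index = index, layer_name = name, method = "gradcam",
                 target_class = 1L, shape_class = "spatial2d",
                 pre_relu_map = map, raw_map = map),
            class = "cam_frame")
}

make_stack <- function(maps) {
  frames <- lapply(seq_along(maps), function(i)
    make_frame(maps[[i]], index = i - 1L, name = paste0("l", i - 1L)))
  rngs <- vapply(frames, function(f) range(f$raw_map), numeric(2))
  structure(list(frames = frames,
                 index = tibble::tibble(index = seq_along(maps) - 1L,
                                        name = paste0("l", seq_along(maps) - 1L),
                                        shape_class = "spatial2d",
                                        local_min = rngs[1, ],
                                        local_max = rngs[2, ]),
                 skipped = tibble::tibble(),
                 global_min = min(rngs[1, ]), global_max = max(rngs[2, ]),
                 method = "gradcam", target_class = 1L),
            class = "cam_stack")
}

test_that("local normalization rescales affinely and flags degenerate maps", {
  expect_equal(normalize_local(matrix(c(0, 5, 10, 5), 2, 2)),
               matrix(c(0, 0.5, 1, 0.5), 2, 2))
  expect_warning(z <- normalize_local(matrix(2, 3, 3)), "degenerate")
  expect_equal(z, matrix(0, 3, 3))
  m01 <- matrix(c(0, 0.25, 1, 0.5), 2, 2)
  expect_equal(normalize_local(m01), m01)   # idempotent on a [0,1] map
})

test_that("global normalization attenuates weaker layers as expected", {
  m1 <- matrix(seq(0, 1, length.out = 16), 4, 4)
  m2 <- matrix(seq(0, 10, length.out = 16), 4, 4)
  st <- make_stack(list(m1, m2))
  g <- normalize_global(st)
  expect_equal(max(g[[1]]), 0.1)            # attenuated to a tenth
  expect_equal(max(g[[2]]), 1)
  # single-frame stack equals local normalization
  st1 <- make_stack(list(m2))
  expect_equal(normalize_global(st1)[[1]], normalize_local(m2))
  # scale invariance: scaling all frames by 3 changes nothing
  st3 <- make_stack(list(3 * m1, 3 * m2))
  expect_equal(normalize_global(st3), g)
  # the globally maximal frame agrees between the two normalizations
  expect_equal(g[[2]], normalize_local(m2))
})

test_that("global normalization of an all-constant stack warns and zeroes", {
  st <- make_stack(list(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_warning(g <- normalize_global(st), "constant")
  expect_true(all(vapply(g, function(m) all(m == 0), TRUE)))
})

test_that("overlay rendering blends exactly and is deterministic", {
  img <- matrix(runif(64), 8, 8)
  um <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  r0 <- render_overlay(img, um, alpha = 0)
  expect_equal(r0$rgb[, , 1], img)
  expect_equal(r0$rgb[, , 2], img)
  r1 <- render_overlay(img, matrix(0, 8, 8), alpha = 1)
  low <- colormap_jet(0)
  expect_equal(unique(as.vector(r1$rgb[, , 3])), unname(low[1, "b"]))
  expect_error(render_overlay(img, matrix(0.5, 4, 4)), "differ")
  expect_error(render_overlay(img, um * 2), "0, 1")
  # byte-identical PNG re-render
  ra <- render_overlay(img, um, alpha = 0.5, caption = "L000 CONV")
  rb <- render_overlay(img, um, alpha = 0.5, caption = "L000 CONV")
  fa <- tempfile(fileext = ".png"); fb <- tempfile(fileext = ".png")
  png::writePNG(ra$rgb, fa); png::writePNG(rb$rgb, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("animation encoding round-trips frame count and order", {
  # three frames with distinct uniform heat levels
  img <- matrix(0.5, 16, 16)
  maps <- list(matrix(0, 16, 16), matrix(0.5, 16, 16), matrix(1, 16, 16))
  frames <- lapply(seq_along(maps), function(i)
    render_overlay(img, maps[[i]], alpha = 1))
  out <- withr::local_tempdir()
  res <- suppressWarnings(encode_animation(frames, fps = 2, out_dir = out))
  expect_equal(res$n_frames, 3L)
  expect_equal(length(res$frame_paths), 3L)
  expect_true(all(file.exists(res$frame_paths)))
  expect_equal(gif_frame_count(res$video), 3L)
  # PNG frames decode back in stack order: under the jet colormap the
  # red-minus-blue difference is strictly monotone in heat level
  warmth <- vapply(res$frame_paths, function(p) {
    px <- png::readPNG(p)
    mean(px[, , 1]) - mean(px[, , 3])
  }, 1.0)
  expect_true(all(diff(warmth) > 0))
  # re-encoding identical frames yields an identical frame count
  res2 <- suppressWarnings(encode_animation(frames, fps = 2,
                                            out_dir = withr::local_tempdir()))
  expect_equal(gif_frame_count(res2$video), 3L)
  expect_error(encode_animation(list(), fps = 2, out_dir = out), "no frames")
})

test_that("10 frames at 2 fps give a 5 second animation", {
  img <- matrix(0.2, 8, 8)
  frames <- lapply(seq(0, 1, length.out = 10), function(v)
    render_overlay(img, matrix(v, 8, 8), alpha = 0.6))
  out <- withr::local_tempdir()
  res <- suppressWarnings(encode_animation(frames, fps = 2, out_dir = out))
  expect_equal(res$n_frames, 10L)
  expect_equal(gif_frame_count(res$video), 10L)
  # per-frame delay stored as centiseconds: 100 / fps = 50 -> 5 s total
  bytes <- readBin(res$video, "raw", file.size(res$video))
  gce <- which(bytes == as.raw(0x21) & c(bytes[-1], as.raw(0)) == as.raw(0xF9))[1]
  delay <- as.integer(bytes[gce + 4L]) + 256L * as.integer(bytes[gce + 5L])
  expect_equal(delay * res$n_frames, 500L)
})

test_that("rendering does not alter CAM frame data", {
  m <- matrix(runif(64), 8, 8)
  fr <- make_frame(m)
  snapshot <- unserialize(serialize(fr, NULL))
  invisible(render_overlay(matrix(0.5, 8, 8), normalize_local(fr)))
  expect_identical(fr, snapshot)
})
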