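# Frame normalization and stack assembly.
#
# Local normalization rescales one layer's map by that layer's own min/max
# ("what matters at this layer?"); global normalization rescales every
# layer's map by the min/max over all layers ("which layer matters most
# overall?"), so strongly attenuated layers stay visibly attenuated.

#' Compute the ordered CAM stack over all spatial layers
#'
#' Runs [compute_cam()] for every `spatial2d` layer of the model in forward
#' order and assembles the frames, the global extrema over all raw maps, and
#' an index tibble. Layers with `vector1d` outputs are skipped (1-D
#' representations are filtered out) and reported once via a message and in
#' the `skipped` tibble.
#'
#' @inheritParams compute_cam
#' @param quiet suppress the skipped-layer message.
#' @return an object of class `cam_stack`: `frames` (list of `cam_frame`),
#'   `index` tibble, `skipped` tibble, `global_min`, `global_max`, and
#'   provenance fields `method` / `target_class`.
#' @export
cam_stack <- function(model, image, scheme = "gradcam", target = "argmax",
                      seed = NULL, quiet = FALSE) {
  layers <- enumerate_target_layers(model)
  spat <- layers[layers$shape_class == "spatial2d", ]
  skip <- layers[layers$shape_class != "spatial2d", ]
  if (nrow(spat) == 0L) stop("model has no spatial2d layers to map",
                             call. = FALSE)
  if (nrow(skip) > 0L && !quiet) {
    message("skipping ", nrow(skip), " non-spatial layer(s): ",
            paste(skip$name, collapse = ", "))
  }
  frames <- lapply(seq_len(nrow(spat)), function(i) {
    compute_cam(model, image, spat$name[i], target = target, scheme = scheme,
                seed = if (is.null(seed)) NULL else seed + i)
  })
  tc <- frames[[1]]$target_class
  rngs <- vapply(frames, function(f) range(f$raw_map), numeric(2))
  idx <- tibble::tibble(
    index = vapply(frames, `[[`, 1L, "layer_index"),
    name = vapply(frames, `[[`, "", "layer_name"),
    shape_class = "spatial2d",
    local_min = rngs[1, ],
    local_max = rngs[2, ]
  )
  structure(list(frames = frames, index = idx,
                 skipped = skip[c("index", "name", "shape_class")],
                 global_min = min(rngs[1, ]), global_max = max(rngs[2, ]),
                 method = scheme, target_class = tc),
            class = "cam_stack")
}

#' @export
print.cam_stack <- function(x, ...) {
  cat("<cam_stack> ", length(x$frames), " frames (", x$method, ", class ",
      x$target_class, "), global range [",
      signif(x$global_min, 4), ", ", signif(x$global_max, 4), "]\n", sep = "")
  invisible(x)
}

#' Locally normalize a CAM frame to \[0, 1\]
#'
#' Rescales by the frame's own min and max. A constant (degenerate) frame
#' becomes all zeros with a warning.
#'
#' @param frame a `cam_frame` or a plain numeric matrix.
#' @return a unit-scaled matrix.
#' @export
normalize_local <- function(frame) {
  m <- if (inherits(frame, "cam_frame")) frame$raw_map else as.matrix(frame)
  if (!all(is.finite(m))) stop("map contains non-finite values", call. = FALSE)
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate frame (constant map); returning zeros", call. = FALSE)
    return(array(0, dim(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Globally normalize all frames of a CAM stack
#'
#' Rescales every frame by the single (global_min, global_max) pair of the
#' stack, preserving relative pixel ordering across layers: the layer
#' holding the global maximum attains 1 somewhere, all other layers appear
#' attenuated.
#'
#' @param stack a `cam_stack`.
#' @return a list of unit-scaled matrices, one per frame.
#' @export
normalize_global <- function(stack) {
  stopifnot(inherits(stack, "cam_stack"))
  span <- stack$global_max - stack$global_min
  if (span <= 0) {
    warning("all frames constant and equal; returning zeros", call. = FALSE)
    return(lapply(stack$frames, function(f) array(0, dim(f$raw_map))))
  }
  lapply(stack$frames, function(f) (f$raw_map - stack$global_min) / span)
}

## ---- rendering -------------------------------------------------------------

#' Jet-like colormap
#' @param v numeric vector in \[0, 1\].
#' @return matrix with columns r, g, b in \[0, 1\].
#' @export
colormap_jet <- function(v) {
  cl <- function(x) pmin(pmax(x, 0), 1)
  cbind(r = cl(pmin(4 * v - 1.5, -4 * v + 4.5)),
        g = cl(pmin(4 * v - 0.5, -4 * v + 3.5)),
        b = cl(pmin(4 * v + 0.5, -4 * v + 2.5)))
}

#' Render a heatmap overlay frame
#'
#' Alpha-blends a colormapped unit map over the input image:
#' `overlay = (1 - alpha) * image + alpha * colormap(map)`. The caption is
#' stamped into the top-left corner with a built-in 3x5 pixel font.
#'
#' @param image grayscale matrix `(H, W)` or RGB array `(H, W, 3)` in
#'   \[0, 1\].
#' @param unit_map matrix in \[0, 1\] of the same spatial shape.
#' @param colormap `"jet"` (default) or a function mapping \[0,1\] to an
#'   `n x 3` RGB matrix.
#' @param alpha blend weight of the heatmap in \[0, 1\].
#' @param caption text stamped on the frame (`NULL` for none).
#' @param normalization tag recorded on the frame (`"local"`/`"global"`).
#' @return a `rendered_frame`: list with `rgb` array `(H, W, 3)`, `caption`
#'   and `normalization`.
#' @export
render_overlay <- function(image, unit_map, colormap = "jet", alpha = 0.5,
                           caption = NULL, normalization = "local") {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  d <- dim(image)
  if (!identical(d[1:2], dim(unit_map))) {
    stop("image and map spatial shapes differ", call. = FALSE)
  }
  if (min(unit_map) < 0 || max(unit_map) > 1) {
    stop("unit_map must lie in [0, 1]", call. = FALSE)
  }
  cmap_fun <- if (is.function(colormap)) colormap else colormap_jet
  cols <- cmap_fun(as.vector(unit_map))
  heat <- array(cols, c(d[1], d[2], 3L))
  out <- (1 - alpha) * image + alpha * heat
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(caption)) out <- cr_stamp_text(out, toupper(caption))
  structure(list(rgb = out, caption = caption, normalization = normalization),
            class = "rendered_frame")
}

#' @export
print.rendered_frame <- function(x, ...) {
  d <- dim(x$rgb)
  cat("<rendered_frame> ", d[1], "x", d[2], " [", x$normalization, "] ",
      if (is.null(x$caption)) "" else x$caption, "\n", sep = "")
  invisible(x)
}

#' Render all frames of a stack under one normalization mode
#'
#' @param stack a `cam_stack`.
#' @param image the input image the stack was computed from.
#' @param mode `"local"` or `"global"` normalization.
#' @inheritParams render_overlay
#' @return list of `rendered_frame`s in layer order.
#' @export
render_stack <- function(stack, image, mode = c("local", "global"),
                         colormap = "jet", alpha = 0.5) {
  mode <- match.arg(mode)
  maps <- if (mode == "global") normalize_global(stack)
          else lapply(stack$frames, function(f)
            suppressWarnings(normalize_local(f)))
  base <- if (length(dim(image)) == 3L && dim(image)[3] == 1L)
    array(image, dim(image)[1:2]) else image
  lapply(seq_along(maps), function(i) {
    f <- stack$frames[[i]]
    render_overlay(base, maps[[i]], colormap = colormap, alpha = alpha,
                   caption = sprintf("L%03d %s", f$layer_index, f$layer_name),
                   normalization = mode)
  })
}

#' Encode rendered frames into an animation
#'
#' Writes every frame as a zero-padded-index PNG and encodes the sequence
#' into a video container in frame order: MP4 via an external `ffmpeg`
#' binary when one is on the PATH, otherwise an animated GIF via the
#' package's native GIF89a writer (with a warning).
#'
#' @param frames list of `rendered_frame`s of identical dimensions.
#' @param fps frames per second.
#' @param out_dir output directory (created if needed).
#' @param gif also/force write `animation.gif`.
#' @param basename stem for the container file.
#' @return invisibly, a list with `frame_paths`, `video` (path), `format`
#'   and `n_frames`.
#' @export
encode_animation <- function(frames, fps = 10, out_dir, gif = TRUE,
                             basename = "animation") {
  if (length(frames) == 0L) stop("no frames to encode", call. = FALSE)
  dims <- lapply(frames, function(f) dim(f$rgb))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all frames must share dimensions", call. = FALSE)
  }
  dir.create(file.path(out_dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  frame_paths <- character(length(frames))
  for (i in seq_along(frames)) {
    cap <- frames[[i]]$caption
    slug <- if (is.null(cap)) sprintf("%04d", i - 1L)
            else sprintf("%04d_%s", i - 1L,
                         gsub("[^A-Za-z0-9_.-]+", "_", cap))
    frame_paths[i] <- file.path(out_dir, "frames", paste0(slug, ".png"))
    png::writePNG(frames[[i]]$rgb, frame_paths[i])
  }
  ffmpeg <- Sys.which("ffmpeg")
  video <- NULL; fmt <- NULL
  if (nzchar(ffmpeg)) {
    video <- file.path(out_dir, paste0(basename, ".mp4"))
    listfile <- tempfile(fileext = ".txt")
    writeLines(sprintf("file '%s'\nduration %f", normalizePath(frame_paths),
                       1 / fps), listfile)
    status <- system2(ffmpeg, c("-y", "-loglevel", "error", "-f", "concat",
                                "-safe", "0", "-i", listfile, "-pix_fmt",
                                "yuv420p", video))
    fmt <- "mp4"
    if (!identical(status, 0L)) { video <- NULL; fmt <- NULL }
  }
  if (is.null(video) || isTRUE(gif)) {
    if (is.null(video) && !nzchar(ffmpeg)) {
      warning("no MP4 encoder available; falling back to GIF", call. = FALSE)
    }
    gif_path <- file.path(out_dir, paste0(basename, ".gif"))
    write_gif(lapply(frames, `[[`, "rgb"), gif_path,
              delay_cs = max(1L, round(100 / fps)))
    if (is.null(video)) { video <- gif_path; fmt <- "gif" }
  }
  invisible(list(frame_paths = frame_paths, video = video, format = fmt,
                 n_frames = length(frames)))
}
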