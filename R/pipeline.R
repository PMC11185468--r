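# End-to-end orchestration: validated run configurations, the animation
# pipeline (enumerate -> capture -> CAM per layer -> normalize -> render ->
# encode) and the per-layer faithfulness pipeline, with self-describing
# output directories (config copy, run log, CSV/JSON artifacts).

#' Build and validate a run configuration
#'
#' @param model model spec: `"tiny_cnn"` (seeded untrained fixture),
#'   `"tiny_cnn_trained"` (fixture trained on a seeded synthetic dataset at
#'   the stock settings), a zoo architecture name (profiling only), or a
#'   `cr_model` object.
#' @param image image spec: a numeric matrix/array, a PNG file path, or
#'   `"fixture:<part>:<i>"` drawing sample `i` from the seeded synthetic
#'   dataset (e.g. `"fixture:test:1"`; lesion samples are class 1).
#' @param scheme CAM weighting scheme, see [cam_schemes()].
#' @param target `"argmax"` or 1-based class index.
#' @param normalization `"local"`, `"global"` or `"both"`.
#' @param road a [road_config()].
#' @param out_dir output directory.
#' @param fps animation frames per second.
#' @param colormap heatmap colormap name.
#' @param alpha overlay blend weight.
#' @param seed master seed for every random element of the run.
#' @return a validated `run_config`.
#' @export
run_config <- function(model = "tiny_cnn_trained", image = "fixture:test:1",
                       scheme = "gradcam", target = "argmax",
                       normalization = c("local", "global", "both"),
                       road = road_config(), out_dir = tempfile("camrun"),
                       fps = 10, colormap = "jet", alpha = 0.5, seed = 1L) {
  normalization <- match.arg(normalization)
  scheme <- match.arg(scheme, cam_schemes())
  stopifnot(alpha >= 0, alpha <= 1, fps > 0)
  if (!identical(target, "argmax")) target <- as.integer(target)
  structure(list(model = model, image = image, scheme = scheme,
                 target = target, normalization = normalization,
                 road = road, out_dir = out_dir, fps = fps,
                 colormap = colormap, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

cr_config_yaml <- function(config) {
  lst <- unclass(config)
  lst$model <- if (inherits(lst$model, "cr_model")) lst$model$name else lst$model
  lst$image <- if (is.character(lst$image)) lst$image else "<array>"
  lst$road <- unclass(lst$road)
  yaml::as.yaml(lst)
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; keys mirror the arguments of [run_config()]
#'   (`road` is a nested map of [road_config()] arguments).
#' @param overrides named list applied over the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides)
  if (!is.null(vals$road)) vals$road <- do.call(road_config, vals$road)
  do.call(run_config, vals)
}

# resolve the model spec; fixture training parameters are the stock study
# conditions (n = 400, contrast = 0.4, 10 epochs)
cr_resolve_model <- function(spec, seed) {
  if (inherits(spec, "cr_model")) return(spec)
  if (identical(spec, "tiny_cnn")) return(make_tiny_cnn(seed = seed))
  if (identical(spec, "tiny_cnn_trained")) {
    split <- make_dataset(n = 400L, contrast = 0.4, seed = seed)
    fit <- train_fixture(make_tiny_cnn(seed = seed), split, epochs = 10L,
                         seed = seed)
    return(fit$model)
  }
  if (is.character(spec) && spec %in% list_zoo_models()) {
    stop("zoo architecture '", spec, "' is a parameter census only; ",
         "it cannot run CAMs. Use run_profile().", call. = FALSE)
  }
  stop("unknown model spec", call. = FALSE)
}

cr_resolve_image <- function(spec, seed) {
  if (is.numeric(spec)) return(spec)
  if (is.character(spec) && grepl("^fixture:", spec)) {
    parts <- strsplit(spec, ":")[[1]]
    split <- make_dataset(n = 400L, contrast = 0.4, seed = seed)
    part <- parts[2]; i <- as.integer(parts[3])
    stopifnot(part %in% c("train", "val", "test"))
    return(split[[part]][[i]]$image)
  }
  if (is.character(spec) && file.exists(spec)) {
    img <- png::readPNG(spec)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3], c(1, 2), mean)
    return(img)
  }
  stop("cannot resolve image spec", call. = FALSE)
}

cr_run_log <- function(out_dir) {
  logfile <- file.path(out_dir, "run.log")
  function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
    message(line)
  }
}

cr_check_downsizing <- function(image, log) {
  d <- dim(image)
  if (max(d[1:2]) > 2 * 64) {
    log("note: input is ", d[1], "x", d[2],
        "; downsizing medical images by more than 2x can discard ",
        "clinically relevant resolution")
  }
}

#' Run the end-to-end layer-wise animation pipeline
#'
#' Enumerates the model's spatial layers, computes one CAM per layer,
#' normalizes locally and/or globally, renders overlays and encodes the
#' animation. Writes `frames/`, the container file(s), `frames_index.csv`,
#' `run.log` and a copy of the configuration into the output directory.
#'
#' @param config a [run_config()].
#' @return invisibly, the output directory path.
#' @export
run_animate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- cr_run_log(config$out_dir)
  writeLines(cr_config_yaml(config), file.path(config$out_dir, "config.yaml"))
  log("stage resolve: model=", if (is.character(config$model)) config$model
      else config$model$name)
  model <- cr_resolve_model(config$model, config$seed)
  image <- cr_resolve_image(config$image, config$seed)
  cr_check_downsizing(image, log)
  log("stage stack: scheme=", config$scheme)
  stack <- suppressMessages(
    cam_stack(model, image, config$scheme, config$target,
              seed = config$seed, quiet = TRUE))
  if (nrow(stack$skipped) > 0L) {
    log("filtered ", nrow(stack$skipped), " non-spatial layer(s): ",
        paste(stack$skipped$name, collapse = ", "))
  }
  modes <- if (config$normalization == "both") c("local", "global")
           else config$normalization
  for (mode in modes) {
    log("stage render: ", mode)
    frames <- render_stack(stack, image, mode, colormap = config$colormap,
                           alpha = config$alpha)
    suffix <- if (length(modes) > 1L) paste0("animation_", mode)
              else "animation"
    res <- suppressWarnings(
      encode_animation(frames, fps = config$fps,
                       out_dir = file.path(config$out_dir, mode),
                       basename = suffix))
    log("encoded ", res$n_frames, " frames -> ", res$video)
  }
  idx <- stack$index
  idx$global_min <- stack$global_min
  idx$global_max <- stack$global_max
  skipped <- stack$skipped
  if (nrow(skipped) > 0L) {
    skipped$local_min <- NA_real_; skipped$local_max <- NA_real_
    skipped$global_min <- NA_real_; skipped$global_max <- NA_real_
    idx <- dplyr::bind_rows(idx, skipped)
    idx <- idx[order(match(idx$name, c(stack$index$name, skipped$name))), ]
  }
  utils::write.csv(idx, file.path(config$out_dir, "frames_index.csv"),
                   row.names = FALSE)
  log("done")
  invisible(config$out_dir)
}

#' Run the per-layer ROAD faithfulness pipeline
#'
#' Computes the ybROAD series for the configured model/image/scheme, writes
#' `ybroad.csv`, `ybroad_summary.json` and `best_layer.png` (the overlay of
#' the argmax layer — the most faithful explanatory layer).
#'
#' A |mean| below 0.05 is annotated as a failure case in the summary: the
#' map family was essentially uninformative about the class on this image,
#' the signature of a model (or scheme) unable to identify the class.
#'
#' @param config a [run_config()].
#' @return invisibly, the `ybroad_series`.
#' @export
run_ybroad <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- cr_run_log(config$out_dir)
  writeLines(cr_config_yaml(config), file.path(config$out_dir, "config.yaml"))
  model <- cr_resolve_model(config$model, config$seed)
  image <- cr_resolve_image(config$image, config$seed)
  road <- config$road
  road$seed <- config$seed
  log("stage ybroad: scheme=", config$scheme)
  yb <- ybroad(model, image, config$scheme, config$target, config = road,
               seed = config$seed)
  if (nrow(yb$skipped) > 0L) {
    log("filtered ", nrow(yb$skipped), " non-spatial layer(s): ",
        paste(yb$skipped$name, collapse = ", "))
  }
  utils::write.csv(yb$series, file.path(config$out_dir, "ybroad.csv"),
                   row.names = FALSE)
  failure_case <- abs(yb$mean_score) < 0.05
  summary <- list(mean = yb$mean_score, max = yb$max_score,
                  argmax_layer_index = yb$argmax_layer_index,
                  argmax_layer_name = yb$argmax_layer_name,
                  n_layers = nrow(yb$series), scheme = yb$scheme,
                  target_class = yb$target_class,
                  failure_case = failure_case,
                  config = list(fractions = road$fractions,
                                noise_sd = road$noise_sd,
                                aggregate = road$aggregate,
                                seed = road$seed))
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "ybroad_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (failure_case) {
    log("failure-case flag: |mean ybROAD| < 0.05 - the maps do not ",
        "distinguish the target class on this image")
  }
  best <- compute_cam(model, image, yb$argmax_layer_name,
                      target = yb$target_class, scheme = config$scheme,
                      seed = config$seed)
  base <- if (length(dim(image)) == 3L && dim(image)[3] == 1L)
    array(image, dim(image)[1:2]) else image
  rf <- render_overlay(base, suppressWarnings(normalize_local(best)),
                       colormap = config$colormap, alpha = config$alpha,
                       caption = sprintf("L%03d %s", best$layer_index,
                                         best$layer_name))
  png::writePNG(rf$rgb, file.path(config$out_dir, "best_layer.png"))
  log("best layer: ", yb$argmax_layer_index, " (", yb$argmax_layer_name,
      "), combined ", signif(yb$max_score, 4))
  invisible(yb)
}

#' Profile a model spec and return its census JSON
#'
#' @param model_spec a zoo architecture name, `"tiny_cnn"`, or a
#'   `cr_model`.
#' @param seed seed for fixture construction.
#' @return the JSON string (also the CLI stdout payload).
#' @export
run_profile <- function(model_spec, seed = 1L) {
  p <- if (inherits(model_spec, "cr_model")) {
    profile(model_spec)
  } else if (identical(model_spec, "tiny_cnn")) {
    profile(make_tiny_cnn(seed = seed))
  } else {
    profile(zoo_model(model_spec))
  }
  profile_json(p)
}
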