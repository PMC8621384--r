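#' Full pipeline configuration
#'
#' Bundles the stage parameters of the segmentation method: green-channel
#' extraction, aperture-rim suppression, multiscale Jerman vesselness,
#' curvelet-domain enhancement, mean-C thresholding and morphological
#' cleanup.
#'
#' @param jerman A [jerman_params()] object.
#' @param curvelet A [curvelet_params()] object.
#' @param threshold A [threshold_params()] object.
#' @param wiring What the curvelet stage enhances:
#'   `"vesselness-times-green"` (default; the vesselness map multiplied
#'   into the inverted green channel, so the curvelet stage sees graded
#'   vessel profiles gated by tubularity) or `"vesselness-only"` (the raw
#'   vesselness map, whose plateau saturation leaves the curvelet stage
#'   almost no intensity structure to sharpen).
#' @param evaluate_in_fov Compute metrics inside the field of view only.
#'   Default `TRUE`.
#' @param cleanup_enabled Apply [cleanup()] after thresholding. Default
#'   `TRUE`.
#' @param erosion_radius Aperture-rim erosion radius in pixels. Default 5.
#' @param fov_threshold Luminance threshold for field-of-view estimation.
#'   Default 0.1.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(jerman = jerman_params(),
                            curvelet = curvelet_params(),
                            threshold = threshold_params(),
                            wiring = c("vesselness-times-green",
                                       "vesselness-only"),
                            evaluate_in_fov = TRUE,
                            cleanup_enabled = TRUE,
                            erosion_radius = 5,
                            fov_threshold = 0.1) {
  wiring <- match.arg(wiring)
  stopifnot(inherits(jerman, "jerman_params"),
            inherits(curvelet, "curvelet_params"),
            inherits(threshold, "threshold_params"),
            erosion_radius >= 0, fov_threshold > 0, fov_threshold < 1)
  structure(list(jerman = jerman, curvelet = curvelet,
                 threshold = threshold, wiring = wiring,
                 evaluate_in_fov = isTRUE(evaluate_in_fov),
                 cleanup_enabled = isTRUE(cleanup_enabled),
                 erosion_radius = erosion_radius,
                 fov_threshold = fov_threshold),
            class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration (YAML)
#'
#' The round trip `config_from_yaml(config_to_yaml(cfg))` is the identity.
#'
#' @param cfg A `pipeline_config`.
#' @param path Optional file path; when given, the YAML is written there.
#' @return `config_to_yaml`: YAML string (invisibly when written to file);
#'   `config_from_yaml`: a `pipeline_config`.
#' @export
config_to_yaml <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  plain <- list(
    jerman = unclass(cfg$jerman),
    curvelet = unclass(cfg$curvelet),
    threshold = unclass(cfg$threshold),
    wiring = cfg$wiring,
    evaluate_in_fov = cfg$evaluate_in_fov,
    cleanup_enabled = cfg$cleanup_enabled,
    erosion_radius = cfg$erosion_radius,
    fov_threshold = cfg$fov_threshold)
  txt <- yaml::as.yaml(plain)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @param yaml_text YAML string (or `NULL` to read from `path`).
#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(yaml_text = NULL, path = NULL) {
  plain <- if (!is.null(path)) yaml::read_yaml(path)
           else yaml::yaml.load(yaml_text)
  thr <- plain$threshold
  pipeline_config(
    jerman = do.call(jerman_params, plain$jerman),
    curvelet = do.call(curvelet_params, plain$curvelet),
    threshold = threshold_params(window = thr$window, c = thr$c,
                                 opening_radius = thr$opening_radius,
                                 min_object_px = thr$min_object_px),
    wiring = plain$wiring,
    evaluate_in_fov = plain$evaluate_in_fov,
    cleanup_enabled = plain$cleanup_enabled,
    erosion_radius = plain$erosion_radius,
    fov_threshold = plain$fov_threshold)
}

#' Run the full vessel segmentation pipeline on one image
#'
#' Green-channel extraction, field-of-view handling and rim suppression,
#' multiscale Jerman vesselness, curvelet-domain enhancement, mean-C
#' thresholding, and (optionally) morphological cleanup and evaluation
#' against ground truth. Fully deterministic for fixed inputs and
#' configuration.
#'
#' @param img A `fundus_image`, a 2D matrix, or a 3-channel array.
#' @param cfg A [pipeline_config()].
#' @param truth Optional 0/1 ground-truth matrix; adds a metrics row.
#' @param fov Optional 0/1 field-of-view matrix. When absent it is
#'   estimated from the image; if estimation fails the whole frame is used.
#' @return An object of class `vesselx_result`: list with `mask` (0/1
#'   matrix), `vesselness` (a `vesselness_map`), `enhanced` (matrix in
#'   \[0, 1\]), `fov`, and `metrics` (one-row tibble or `NULL`).
#' @examples
#' ph <- make_vessel_tree(phantom_spec(height = 128, width = 128))
#' cfg <- pipeline_config(jerman = jerman_params(s_min = 2, s_max = 6,
#'                                               s_step = 1))
#' res <- run_pipeline(ph$image, cfg, truth = ph$truth, fov = ph$fov)
#' res$metrics
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), truth = NULL,
                         fov = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("vesselx [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  green <- stage("extract_green", extract_green(img))
  if (is.null(fov)) fov <- green$fov
  g <- green$pixels
  if (is.null(fov)) {
    fov <- tryCatch(compute_fov_mask(g, cfg$fov_threshold),
                    error = function(e) matrix(1L, nrow(g), ncol(g)))
  }
  g <- stage("suppress_border", suppress_border(g, fov, cfg$erosion_radius))
  v <- stage("vesselness", vesselness(g, cfg$jerman))
  base <- switch(cfg$wiring,
    "vesselness-only" = v$response,
    "vesselness-times-green" = v$response * (1 - g))
  enh <- stage("curvelet_enhance",
               curvelet_enhance(base, cfg$curvelet, fov = fov))
  mask <- stage("mean_c_threshold",
                mean_c_threshold(enh, cfg$threshold, fov))
  if (cfg$cleanup_enabled) mask <- stage("cleanup", cleanup(mask,
                                                            cfg$threshold))
  mrow <- NULL
  if (!is.null(truth)) {
    mrow <- stage("evaluate", metrics(confusion_counts(
      mask, truth, if (cfg$evaluate_in_fov) fov else NULL)))
  }
  structure(list(mask = mask, vesselness = v, enhanced = enh, fov = fov,
                 metrics = mrow),
            class = "vesselx_result")
}

#' Evaluate the pipeline over a directory of images
#'
#' Pairs images with ground-truth (and optional field-of-view) files by
#' shared filename stem, falling back to the leading numeric token of the
#' stem (the convention of the DRIVE `test/images` / `test/1st_manual` /
#' `test/mask` and CHASE_DB1 layouts; the first observer's annotation is
#' the ground truth). Images that fail to load are reported in the result
#' and excluded from the means, never silently dropped.
#'
#' @param image_dir,truth_dir Directories of images and ground-truth masks.
#' @param fov_dir Optional directory of field-of-view masks.
#' @param cfg A [pipeline_config()].
#' @return A `vesselx_report` (see [aggregate_metrics()]) with an extra
#'   `failed` character vector of unprocessable image files.
#' @export
evaluate_dataset <- function(image_dir, truth_dir, fov_dir = NULL,
                             cfg = pipeline_config()) {
  imgs <- sort(list.files(image_dir, full.names = TRUE))
  truths <- sort(list.files(truth_dir, full.names = TRUE))
  fovs <- if (!is.null(fov_dir)) sort(list.files(fov_dir, full.names = TRUE))
  key <- function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    num <- regmatches(stem, regexpr("^[0-9]+", stem))
    if (length(num)) num else stem
  }
  tk <- vapply(truths, key, character(1))
  fk <- if (!is.null(fovs)) vapply(fovs, key, character(1))
  rows <- list(); failed <- character(0)
  for (f in imgs) {
    k <- key(f)
    ti <- match(k, tk)
    if (is.na(ti)) next
    row <- tryCatch({
      fov <- NULL
      if (!is.null(fovs)) {
        fi <- match(k, fk)
        if (!is.na(fi)) fov <- load_mask(fovs[fi])
      }
      res <- run_pipeline(load_image(f), cfg,
                          truth = load_mask(truths[ti]), fov = fov)
      r <- res$metrics
      r$image_id <- tools::file_path_sans_ext(basename(f))
      r
    }, error = function(e) {
      failed <<- c(failed, paste0(basename(f), ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    stop("vesselx: no image/ground-truth pairs could be processed under ",
         image_dir, call. = FALSE)
  }
  report <- aggregate_metrics(do.call(rbind, rows))
  report$failed <- failed
  report
}

#' Metrics across a sweep of the Jerman cut-off threshold
#'
#' Runs the pipeline at each `tau` and reports one metrics row per value;
#' makes explicit how much per-image tuning of the cut-off threshold can
#' move the scores.
#'
#' @param img Image input as in [run_pipeline()].
#' @param truth 0/1 ground-truth matrix.
#' @param cfg A [pipeline_config()]; its `jerman$tau` is overridden.
#' @param taus Numeric vector of cut-off values. Default
#'   `seq(0.5, 1, 0.1)`.
#' @param fov Optional 0/1 field-of-view matrix.
#' @return Tibble with a `tau` column and the four metric columns; the
#'   attribute `"best"` holds the row index with highest accuracy.
#' @export
tau_sweep <- function(img, truth, cfg = pipeline_config(),
                      taus = seq(0.5, 1, by = 0.1), fov = NULL) {
  rows <- lapply(taus, function(tv) {
    cfg$jerman$tau <- tv
    r <- run_pipeline(img, cfg, truth = truth, fov = fov)$metrics
    r$image_id <- NULL
    tibble::tibble(tau = tv, r)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$accuracy)
  out
}
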