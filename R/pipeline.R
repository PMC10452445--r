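# End-to-end reproducible runs: convert -> truncate -> equalize -> segment
# -> quantify (-> evaluate when truth is given), with every output written
# under one directory together with a JSON report of parameters and seed.

#' Pipeline run configuration
#'
#' @param input path to the input stack (multi-page TIFF or frame
#'   directory), or an `IntensityStack` already in memory.
#' @param method detector: `"mip"`, `"rf"` or `"external"`.
#' @param output_dir directory for all outputs (created if needed).
#' @param truth optional ground-truth mask (path or `BinaryStack`);
#'   enables the evaluation stage.
#' @param axis_order geometry of the input (`"XZ_YSTACK"` inputs are
#'   converted first).
#' @param pixel_pitch_um,frame_spacing_um calibration (defaults 10/10).
#' @param max_depth_um depth truncation bound (default 350).
#' @param equalize apply per-frame histogram equalization (default `TRUE`).
#' @param mip [mip_params()] for `method = "mip"`.
#' @param rf list for `method = "rf"`: `labels` (a [sparse_labels()] set or
#'   a CSV path with columns frame,x,y,class), and optionally
#'   `feature_spec`, `n_trees`, `closing_radius_px`.
#' @param external producer for `method = "external"` (see
#'   [external_segment()]).
#' @param connectivity 3D connectivity for quantification (default 26).
#' @param anchor_frames bottom frames counting as the open-structure anchor
#'   (default 1).
#' @param seed integer seed recorded in the report and used for every
#'   stochastic stage (default 1).
#' @return a `RunConfig` list.
#' @export
run_config <- function(input, method = c("mip", "rf", "external"),
                       output_dir, truth = NULL,
                       axis_order = "XY_ZSTACK",
                       pixel_pitch_um = 10, frame_spacing_um = 10,
                       max_depth_um = 350, equalize = TRUE,
                       mip = mip_params(), rf = list(), external = NULL,
                       connectivity = 26, anchor_frames = 1L, seed = 1L) {
  if (missing(method)) stop("config field 'method' is required", call. = FALSE)
  method <- match.arg(method)
  if (missing(input)) stop("config field 'input' is required", call. = FALSE)
  if (missing(output_dir)) {
    stop("config field 'output_dir' is required", call. = FALSE)
  }
  if (method == "external" && is.null(external)) {
    stop("method 'external' requires the 'external' producer field",
         call. = FALSE)
  }
  if (method == "rf" && is.null(rf$labels)) {
    stop("method 'rf' requires rf$labels", call. = FALSE)
  }
  structure(list(input = input, method = method, output_dir = output_dir,
                 truth = truth, axis_order = axis_order,
                 pixel_pitch_um = pixel_pitch_um,
                 frame_spacing_um = frame_spacing_um,
                 max_depth_um = max_depth_um, equalize = equalize,
                 mip = mip, rf = rf, external = external,
                 connectivity = connectivity,
                 anchor_frames = as.integer(anchor_frames),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes convert (if acquired geometry) -> truncate -> equalize ->
#' segment -> quantify, and evaluate when ground truth is supplied. All
#' intermediate stacks, the vessel table CSV, the kappa profile CSV and a
#' JSON report (package version, parameters, seed, summary numbers) are
#' written under `config$output_dir`. Identical config + seed reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (list: files written, vessel totals,
#'   kappa summary when evaluated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  stack <- stage("read", {
    if (inherits(config$input, "IntensityStack")) config$input
    else read_stack(config$input, axis_order = config$axis_order,
                    pixel_pitch_um = config$pixel_pitch_um,
                    frame_spacing_um = config$frame_spacing_um)
  })
  if (stack$axis_order == "XZ_YSTACK") {
    stack <- stage("convert", convert_axes(stack))
  }
  stack <- stage("truncate", truncate_depth(stack, config$max_depth_um))
  pre <- if (config$equalize) {
    stage("equalize", equalize_histogram(stack))
  } else stack
  write_stack(pre, file.path(config$output_dir, "preprocessed.tif"))

  seg <- stage("segment", switch(config$method,
    mip = segment_mip(pre, config$mip),
    rf = run_rf_stage(pre, config),
    external = external_segment(pre, config$external)))
  write_stack(seg, file.path(config$output_dir, "segmentation.tif"))

  table <- stage("quantify", {
    vol <- label_components(seg, config$connectivity)
    summarize_vessels(vol, open_only = FALSE,
                      anchor_frames = config$anchor_frames)
  })
  utils::write.csv(table$records,
                   file.path(config$output_dir, "vessels.csv"),
                   row.names = FALSE)

  report <- list(package_version = as.character(utils::packageVersion("octlumen")),
                 method = config$method, seed = config$seed,
                 max_depth_um = config$max_depth_um,
                 equalize = config$equalize,
                 connectivity = config$connectivity,
                 n_frames = n_frames(pre),
                 totals = table$totals,
                 files = c("preprocessed.tif", "segmentation.tif",
                           "vessels.csv"))

  if (!is.null(config$truth)) {
    truth <- stage("truth", {
      if (inherits(config$truth, "BinaryStack")) config$truth
      else read_stack(config$truth, axis_order = "XY_ZSTACK",
                      pixel_pitch_um = config$pixel_pitch_um,
                      frame_spacing_um = config$frame_spacing_um,
                      binary = TRUE)
    })
    truth <- stage("truth", truncate_depth(truth, config$max_depth_um))
    prof <- stage("evaluate", kappa_profile(seg, truth))
    utils::write.csv(as.data.frame(prof),
                     file.path(config$output_dir, "kappa.csv"),
                     row.names = FALSE)
    report$kappa <- summarize_kappa(prof)[c("mean", "min", "max")]
    report$files <- c(report$files, "kappa.csv")
  }

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

run_rf_stage <- function(pre, config) {
  rf <- config$rf
  labels <- rf$labels
  if (is.character(labels)) {
    df <- utils::read.csv(labels)
    labels <- sparse_labels(df$frame, df$x, df$y, df$class)
  }
  spec <- if (is.null(rf$feature_spec)) feature_spec() else rf$feature_spec
  feats <- extract_features(pre, spec, frames = sort(unique(labels$frame)))
  cls <- train_rf(feats, labels,
                  n_trees = if (is.null(rf$n_trees)) 100 else rf$n_trees,
                  seed = config$seed)
  rf_segment(pre, cls,
             closing_radius_px =
               if (is.null(rf$closing_radius_px)) 2 else rf$closing_radius_px)
}
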