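# Trainable random-forest pixel classifier: a multi-scale filter-bank
# feature stack, sparse two-class labels, iterative label refinement, and
# morphological-closing post-processing -- the programmatic equivalent of an
# interactive trainable-segmentation session.

#' Feature bank specification
#'
#' @param sigmas Gaussian scales in px (default `c(1, 2, 4, 8)`).
#' @param features subset of `"gaussian"`, `"gradient_magnitude"`,
#'   `"laplacian"`, `"difference_of_gaussians"`, `"local_variance"`
#'   (default all five). Each selected filter is evaluated at every scale;
#'   the raw intensity is always appended, so a pixel carries
#'   `length(sigmas) * length(features) + 1` features.
#' @return a `FeatureSpec` list.
#' @export
feature_spec <- function(sigmas = c(1, 2, 4, 8),
                         features = c("gaussian", "gradient_magnitude",
                                      "laplacian", "difference_of_gaussians",
                                      "local_variance")) {
  features <- match.arg(features, several.ok = TRUE)
  if (length(sigmas) == 0 || length(features) == 0) {
    stop("need at least one sigma and one feature", call. = FALSE)
  }
  stopifnot(all(sigmas > 0))
  structure(list(sigmas = sigmas, features = features),
            class = "FeatureSpec")
}

#' Sparse pixel labels
#'
#' @param frame,x,y integer vectors: frame index and pixel coordinates
#'   (1-based, x = column, y = row).
#' @param class character/factor vector of `"lumen"` / `"background"`.
#' @return a `SparseLabels` data.frame.
#' @export
sparse_labels <- function(frame, x, y, class) {
  class <- as.character(class)
  if (!all(class %in% c("lumen", "background"))) {
    stop("class must be 'lumen' or 'background'", call. = FALSE)
  }
  structure(data.frame(frame = as.integer(frame), x = as.integer(x),
                       y = as.integer(y), class = class),
            class = c("SparseLabels", "data.frame"))
}

#' Extract the per-pixel feature stack
#'
#' Deterministic multi-scale filter bank per frame: Gaussian smoothing,
#' gradient magnitude, Laplacian and difference-of-Gaussians of the
#' smoothed frame, and local variance in a window matched to the scale --
#' plus the raw intensity.
#'
#' @param stack a converted `IntensityStack`.
#' @param spec a [feature_spec()].
#' @param frames frame indices to compute (default all).
#' @return a `FeatureStack`: list with `frames` (named list of
#'   height x width x n_features arrays), `spec`, `feature_names` and the
#'   source dimensions.
#' @export
extract_features <- function(stack, spec = feature_spec(), frames = NULL) {
  stopifnot(inherits(stack, "IntensityStack"), inherits(spec, "FeatureSpec"))
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  names <- c("raw",
             as.vector(outer(spec$features, spec$sigmas,
                             function(f, s) paste0(f, "_s", s))))
  out <- lapply(frames, function(i) {
    frame_features(stack$data[, , i], spec, names)
  })
  names(out) <- as.character(frames)
  structure(list(frames = out, spec = spec, feature_names = names,
                 dim = dim(stack$data)),
            class = "FeatureStack")
}

frame_features <- function(frame, spec, names) {
  d <- dim(frame)
  arr <- array(0, c(d[1], d[2], length(names)),
               dimnames = list(NULL, NULL, names))
  arr[, , "raw"] <- frame
  for (s in spec$sigmas) {
    g <- gblur_safe(frame, s)
    for (f in spec$features) {
      val <- switch(f,
        gaussian = g,
        gradient_magnitude = gradient_magnitude(g),
        laplacian = laplacian_filter(g),
        difference_of_gaussians =
          g - gblur_safe(frame, 1.6 * s),
        local_variance = local_variance(frame, s))
      arr[, , paste0(f, "_s", s)] <- val
    }
  }
  arr
}

gradient_magnitude <- function(g) {
  d <- dim(g)
  gx <- g[, c(2:d[2], d[2])] - g[, c(1, 1:(d[2] - 1))]
  gy <- g[c(2:d[1], d[1]), ] - g[c(1, 1:(d[1] - 1)), ]
  sqrt((gx / 2)^2 + (gy / 2)^2)
}

laplacian_filter <- function(g) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  ebi_matrix(EBImage::filter2(g, k))
}

local_variance <- function(frame, sigma) {
  w <- 2L * ceiling(sigma) + 1L
  k <- matrix(1 / w^2, w, w)
  m1 <- ebi_matrix(EBImage::filter2(frame, k))
  m2 <- ebi_matrix(EBImage::filter2(frame^2, k))
  pmax(m2 - m1^2, 0)
}

features_at <- function(features, labels) {
  stopifnot(inherits(features, "FeatureStack"))
  d <- features$dim
  bad <- labels$x < 1 | labels$x > d[2] | labels$y < 1 | labels$y > d[1] |
    labels$frame < 1 | labels$frame > d[3]
  if (any(bad)) {
    stop("labels reference out-of-range pixels (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(labels)), function(i) {
    fr <- features$frames[[as.character(labels$frame[i])]]
    if (is.null(fr)) {
      stop("feature stack has no frame ", labels$frame[i], call. = FALSE)
    }
    fr[labels$y[i], labels$x[i], ]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- features$feature_names
  m
}

#' Train the random-forest pixel classifier
#'
#' Fits a probability random forest on the feature vectors of the labeled
#' pixels. Training is deterministic under a fixed seed (single-threaded).
#'
#' @param features a `FeatureStack` from [extract_features()] covering every
#'   labeled frame.
#' @param labels a [sparse_labels()] set containing both classes.
#' @param n_trees trees in the forest (default 100).
#' @param seed integer seed (default 1).
#' @return a `PixelClassifier` carrying the fitted forest, the feature
#'   spec and the training labels (kept for [refine_labels()]).
#' @export
train_rf <- function(features, labels, n_trees = 100, seed = 1L) {
  stopifnot(inherits(labels, "SparseLabels"), n_trees >= 1)
  if (length(unique(labels$class)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  # canonical label order: training depends only on the label set, not on
  # the order labels were collected in
  ord <- order(labels$frame, labels$y, labels$x, labels$class)
  labels <- sparse_labels(labels$frame[ord], labels$x[ord], labels$y[ord],
                          labels$class[ord])
  x <- features_at(features, labels)
  df <- data.frame(x, check.names = FALSE)
  df$.class <- factor(labels$class, levels = c("background", "lumen"))
  model <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L
  )
  structure(list(model = model, spec = features$spec,
                 feature_names = features$feature_names,
                 labels = labels, n_trees = n_trees,
                 seed = as.integer(seed)),
            class = "PixelClassifier")
}

#' @export
print.PixelClassifier <- function(x, ...) {
  cat(sprintf("<PixelClassifier> %d trees, %d features, %d training pixels\n",
              x$n_trees, length(x$feature_names), nrow(x$labels)))
  invisible(x)
}

predict_lumen_prob <- function(classifier, feature_array) {
  d <- dim(feature_array)
  m <- matrix(feature_array, d[1] * d[2], d[3])
  colnames(m) <- classifier$feature_names
  p <- stats::predict(classifier$model, data.frame(m, check.names = FALSE),
                      num.threads = 1L)$predictions[, "lumen"]
  matrix(p, d[1], d[2])
}

#' Segment a stack with a trained pixel classifier
#'
#' Per-pixel lumen probability thresholded at 0.5 (ties are foreground),
#' followed by binary morphological closing with a disc, the post-processing
#' that fills small gaps and drops speck-scale misclassifications.
#'
#' @param stack an `IntensityStack` compatible with the classifier's
#'   feature spec.
#' @param classifier a `PixelClassifier` from [train_rf()].
#' @param closing_radius_px disc radius of the closing step (0 = none).
#' @return a `BinaryStack`, 1 = lumen.
#' @export
rf_segment <- function(stack, classifier, closing_radius_px = 2) {
  stopifnot(inherits(stack, "IntensityStack"),
            inherits(classifier, "PixelClassifier"),
            closing_radius_px >= 0)
  d <- dim(stack$data)
  ker <- if (closing_radius_px > 0)
    EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    feats <- frame_features(stack$data[, , i], classifier$spec,
                            classifier$feature_names)
    fg <- predict_lumen_prob(classifier, feats) >= 0.5
    if (!is.null(ker)) {
      fg <- ebi_matrix(EBImage::closing(fg * 1, ker)) > 0.5
    }
    out[, , i] <- fg * 1
  }
  binary_stack(out, stack$axis_order, stack$pixel_pitch_um,
               stack$frame_spacing_um)
}

#' Retrain the classifier with corrected labels
#'
#' The iterative refinement loop: inspect the current segmentation, label
#' misclassified pixels, and retrain on the union of the previous training
#' set and the corrections (corrections override earlier labels at the same
#' pixel). Seed and tree count are inherited from the classifier.
#'
#' @param features a `FeatureStack` covering the corrected frames.
#' @param classifier the current `PixelClassifier`.
#' @param corrections a non-empty [sparse_labels()] set.
#' @return the retrained `PixelClassifier`.
#' @export
refine_labels <- function(features, classifier, corrections) {
  stopifnot(inherits(classifier, "PixelClassifier"))
  if (!inherits(corrections, "SparseLabels") || nrow(corrections) == 0) {
    stop("corrections must be a non-empty SparseLabels set", call. = FALSE)
  }
  old <- classifier$labels
  key <- function(l) paste(l$frame, l$x, l$y)
  keep <- !key(old) %in% key(corrections)
  merged <- rbind(old[keep, ], corrections)
  merged <- sparse_labels(merged$frame, merged$x, merged$y, merged$class)
  train_rf(features, merged, n_trees = classifier$n_trees,
           seed = classifier$seed)
}
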