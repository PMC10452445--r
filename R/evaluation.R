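# Scoring detector output against ground truth: per-frame confusion counts,
# Cohen's kappa, depth-resolved profiles, cross-dataset aggregation, and the
# paired equivalence test for summary measurements.

#' Pixel-wise confusion counts of one frame pair
#'
#' Counts, over the ROI (the whole frame when no mask is given): TP =
#' predicted lumen overlapping true lumen, FP = predicted lumen on true
#' background, FN = missed true lumen, TN = agreed background.
#'
#' @param pred,truth binary matrices (0/1 or logical) of identical size.
#' @param roi optional binary matrix; only pixels with `roi == 1` are
#'   evaluated.
#' @return a `ConfusionCounts` list with fields `TP`, `FP`, `TN`, `FN`;
#'   the four always sum to the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, truth, roi = NULL) {
  pred <- as_binary_frame(pred); truth <- as_binary_frame(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth dimensions differ", call. = FALSE)
  }
  if (!is.null(roi)) {
    roi <- as_binary_frame(roi)
    if (!identical(dim(roi), dim(pred))) {
      stop("roi dimensions differ from frames", call. = FALSE)
    }
    keep <- roi
    pred <- pred[keep]; truth <- truth[keep]
  }
  structure(list(
    TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth)
  ), class = "ConfusionCounts")
}

as_binary_frame <- function(x) {
  if (inherits(x, "oct_stack")) x <- x$data
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L) {
    x <- x[, , 1]
  }
  stopifnot(is.matrix(x) || is.logical(x))
  x > 0.5
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement between a segmentation and the ground truth:
#' \deqn{\kappa = \frac{2(TP \cdot TN - FN \cdot FP)}
#'   {(TP+FP)(FP+TN) + (TP+FN)(FN+TN)}}
#' which equals the classic \eqn{(p_o - p_e) / (1 - p_e)} with \eqn{p_o}
#' the observed and \eqn{p_e} the chance agreement. When the denominator is
#' zero (both labelings constant) the degenerate frame scores 0 by
#' convention. `variant = "printed"` selects the same ratio without the
#' factor 2, a variant that appears in some reports of the formula and
#' reaches only 0.5 at perfect agreement; it is provided for auditing and is
#' never the default.
#'
#' @param counts a `ConfusionCounts` object (or list with TP/FP/TN/FN).
#' @param variant `"standard"` (default) or `"printed"`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(counts, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("all-zero confusion counts", call. = FALSE)
  den <- (TP + FP) * (FP + TN) + (TP + FN) * (FN + TN)
  if (den == 0) return(0)
  num <- TP * TN - FN * FP
  if (variant == "standard") 2 * num / den else num / den
}

#' Depth-resolved kappa profile
#'
#' Per-frame Cohen's kappa of a predicted mask stack against ground truth,
#' indexed by depth (frame i sits at `(i - 1) * frame_spacing_um`).
#' Degenerate frames (both masks constant) score 0 and are flagged.
#'
#' @param pred,truth `BinaryStack`s of identical geometry.
#' @param roi optional `MaskStack`/`BinaryStack` restricting evaluation.
#' @param dataset optional dataset identifier stored with the profile.
#' @return a `KappaProfile`: data.frame with columns `frame`, `depth_um`,
#'   `kappa`, `degenerate`.
#' @export
kappa_profile <- function(pred, truth, roi = NULL, dataset = NA_character_) {
  stopifnot(inherits(pred, "oct_stack"), inherits(truth, "oct_stack"))
  if (!same_geometry(pred, truth)) {
    stop("pred and truth geometry mismatch", call. = FALSE)
  }
  if (!is.null(roi) && !identical(dim(roi$data), dim(pred$data))) {
    stop("roi geometry mismatch", call. = FALSE)
  }
  nf <- n_frames(pred)
  kappa <- numeric(nf); degen <- logical(nf)
  for (i in seq_len(nf)) {
    cc <- confusion_counts(pred$data[, , i], truth$data[, , i],
                           roi = if (is.null(roi)) NULL else roi$data[, , i])
    den <- (cc$TP + cc$FP) * (cc$FP + cc$TN) + (cc$TP + cc$FN) * (cc$FN + cc$TN)
    degen[i] <- den == 0
    kappa[i] <- cohen_kappa(cc)
  }
  structure(data.frame(frame = seq_len(nf),
                       depth_um = (seq_len(nf) - 1) * pred$frame_spacing_um,
                       kappa = kappa, degenerate = degen),
            dataset = dataset,
            class = c("KappaProfile", "data.frame"))
}

#' Aggregate kappa profiles across datasets
#'
#' Grand mean over all frames of all profiles, with the spread reported as
#' the minimum and maximum of the per-dataset means (the error-bar
#' convention of multi-sample detector comparisons).
#'
#' @param profiles a `KappaProfile` or a list of them.
#' @return list with `mean`, `min`, `max` and the per-dataset means.
#' @export
summarize_kappa <- function(profiles) {
  if (inherits(profiles, "KappaProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0)
  per_dataset <- vapply(profiles, function(p) mean(p$kappa), numeric(1))
  all_kappa <- unlist(lapply(profiles, function(p) p$kappa))
  list(mean = mean(all_kappa),
       min = min(per_dataset), max = max(per_dataset),
       per_dataset = per_dataset)
}

#' Plot a depth-resolved kappa profile
#'
#' @param x a `KappaProfile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.KappaProfile <- function(x, ...) {
  graphics::plot(x$depth_um, x$kappa, type = "b", pch = 16,
                 xlab = "depth (um)", ylab = "Cohen's kappa",
                 ylim = c(min(0, x$kappa), 1), ...)
  graphics::abline(h = c(0.4, 0.6, 0.8), lty = 3, col = "grey")
  invisible(x)
}

#' Paired equivalence test of detector vs ground-truth summaries
#'
#' Two-sided paired t-test on matched per-dataset summary values (counts,
#' surface areas, diameters, ...). Zero-variance differences make the t
#' statistic undefined; by convention the test then returns p = 1 with a
#' warning (identical vectors are "as equivalent as measurable").
#'
#' @param values_a,values_b numeric vectors of equal length >= 2.
#' @return list with `p_value`, `t`, `df`, `mean_difference`.
#' @export
paired_equivalence_test <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(values_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  if (stats::var(d) == 0) {
    warning("zero-variance differences; returning p = 1 by convention")
    return(list(p_value = 1, t = NA_real_, df = length(d) - 1,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), mean_difference = mean(d))
}
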