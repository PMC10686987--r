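#' Confusion counts with female as the positive class
#'
#' @param truth,predicted equal-length vectors of labels; either the strings
#'   `"female"`/`"male"` or 0/1 codes with female = 1.
#' @return A list of class `confusion_counts` with integer fields `tp`, `tn`,
#'   `fp`, `fn` and `n`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  }
  t1 <- as_positive(truth); p1 <- as_positive(predicted)
  counts <- list(tp = sum(t1 == 1 & p1 == 1), tn = sum(t1 == 0 & p1 == 0),
                 fp = sum(t1 == 0 & p1 == 1), fn = sum(t1 == 1 & p1 == 0))
  confusion_counts(counts$tp, counts$tn, counts$fp, counts$fn)
}

#' @rdname confusion_matrix
#' @param tp,tn,fp,fn non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp, tn, fp, fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp),
                 fn = as.integer(fn), n = as.integer(sum(v))),
            class = "confusion_counts")
}

as_positive <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% c("female", "male"))) {
      stop("labels must be 'female'/'male' or 0/1", call. = FALSE)
    }
    as.integer(x == "female")
  } else {
    if (!all(x %in% c(0, 1))) stop("labels must be 'female'/'male' or 0/1",
                                   call. = FALSE)
    as.integer(x)
  }
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("            predicted F  predicted M\n"))
  cat(sprintf("  true F    %11d  %11d\n", x$tp, x$fn))
  cat(sprintf("  true M    %11d  %11d\n", x$fp, x$tn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`, `sensitivity = TP / (TP + FN)`
#' and `specificity = TN / (TN + FP)`, with female as the positive class.
#' Values are kept at full precision; the print method displays two decimals
#' (half up). A metric with a zero denominator is reported as `NA`, not 0.
#'
#' @param counts a `confusion_counts` (see [confusion_matrix]).
#' @return A list of class `metric_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `n`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = safe_div(counts$tp + counts$tn, counts$n),
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
    specificity = safe_div(counts$tn, counts$tn + counts$fp),
    n = counts$n), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d  accuracy %.2f  sensitivity %.2f  specificity %.2f\n",
              x$n, round_half_up(x$accuracy), round_half_up(x$sensitivity),
              round_half_up(x$specificity)))
  invisible(x)
}

#' Confidence interval for a difference of proportions
#'
#' Unpaired two-proportion normal-approximation (Wald) interval, without
#' continuity correction, for the difference in a metric (accuracy by
#' default) between two raters evaluated on test sets of the same size. The
#' interval is degenerate (width 0) when both proportions are 0 or both 1.
#'
#' @param counts_a,counts_b `confusion_counts` for the two raters.
#' @param level confidence level (default 0.95).
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @return A list: `estimate` (p_a - p_b), `lower`, `upper`, `level`,
#'   `method`.
#' @export
diff_proportion_ci <- function(counts_a, counts_b, level = 0.95,
                               metric = c("accuracy", "sensitivity", "specificity")) {
  metric <- match.arg(metric)
  stopifnot(inherits(counts_a, "confusion_counts"),
            inherits(counts_b, "confusion_counts"))
  num_den <- function(cc) switch(metric,
    accuracy = c(cc$tp + cc$tn, cc$n),
    sensitivity = c(cc$tp, cc$tp + cc$fn),
    specificity = c(cc$tn, cc$tn + cc$fp))
  ab <- num_den(counts_a); bb <- num_den(counts_b)
  if (ab[2] == 0 || bb[2] == 0) stop("zero denominator", call. = FALSE)
  pa <- ab[1] / ab[2]; pb <- bb[1] / bb[2]
  se <- sqrt(pa * (1 - pa) / ab[2] + pb * (1 - pb) / bb[2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = pa - pb, lower = pa - pb - z * se, upper = pa - pb + z * se,
       level = level, method = "unpaired two-proportion Wald, no continuity correction")
}

#' Attention-weighted volume for interpretation
#'
#' Multiplies each patch of a bag by its attention weight and scatters it
#' back to its grid origin, yielding a volume whose intensity encodes how
#' much the model attended to each region ("the warmer, the more weight").
#'
#' @param bag a `patch_bag`.
#' @param prediction either a length-K weight vector or a one-row prediction
#'   from [predict.mil_model] carrying the `"attention"` attribute.
#' @return A 3D array with values in `[0, max(weights)]` for binary bags.
#' @export
weighted_attention_volume <- function(bag, prediction) {
  stopifnot(inherits(bag, "patch_bag"))
  w <- if (is.numeric(prediction)) prediction else {
    att <- attr(prediction, "attention")
    if (is.null(att)) stop("'prediction' carries no attention weights", call. = FALSE)
    att[, 1]
  }
  if (length(w) != bag$k) {
    stop("attention weights do not align with the bag's patches", call. = FALSE)
  }
  assemble_patches(bag, weights = w)
}

#' Export an attention heatmap
#'
#' Writes the weighted volume as NIfTI (attention weights as intensities)
#' and, optionally, three orthogonal mid-plane PNG views.
#'
#' @param weighted_volume array from [weighted_attention_volume].
#' @param path output NIfTI path.
#' @param png_prefix if non-`NULL`, writes `<prefix>_axial.png` etc.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(weighted_volume, path, png_prefix = NULL) {
  v <- volume_image(weighted_volume + 0, dtype_role = "HU")
  write_nifti(v, path)
  if (!is.null(png_prefix)) {
    d <- dim(weighted_volume)
    views <- list(axial = weighted_volume[, , ceiling(d[3] / 2)],
                  coronal = weighted_volume[, ceiling(d[2] / 2), ],
                  sagittal = weighted_volume[ceiling(d[1] / 2), , ])
    for (nm in names(views)) {
      grDevices::png(sprintf("%s_%s.png", png_prefix, nm), width = 480, height = 480)
      graphics::image(views[[nm]], col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      axes = FALSE, main = nm)
      grDevices::dev.off()
    }
  }
  invisible(path)
}

#' Export a training loss curve
#'
#' Writes the per-epoch loss history as CSV and, optionally, a PNG plot of
#' the training and validation curves.
#'
#' @param history data.frame with `epoch`, `train_loss`, `val_loss` (as in a
#'   fitted model's `history`).
#' @param csv_path output CSV path.
#' @param plot_path optional PNG path.
#' @return `csv_path`, invisibly.
#' @export
export_loss_curve <- function(history, csv_path, plot_path = NULL) {
  utils::write.csv(history, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 640, height = 480)
    graphics::matplot(history$epoch, cbind(history$train_loss, history$val_loss),
                      type = "l", lty = 1, col = c("steelblue", "darkorange"),
                      xlab = "epoch", ylab = "loss")
    graphics::legend("topright", c("training", "validation"), lty = 1,
                     col = c("steelblue", "darkorange"), bty = "n")
    grDevices::dev.off()
  }
  invisible(csv_path)
}
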