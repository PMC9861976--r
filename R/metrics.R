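#' Pixel-wise confusion counts between a prediction and the truth
#'
#' @param pred,truth Binary maps/masks of identical shape (matrix,
#'   [enface_map()], or logical vector).
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
pixel_confusion <- function(pred, truth) {
  p <- as.logical(unclass(pred) > 0)
  t <- as.logical(unclass(truth) > 0)
  if (length(p) != length(t) ||
      !identical(dim(unclass(pred)), dim(unclass(truth)))) {
    stop("pred and truth shapes differ", call. = FALSE)
  }
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   fn = sum(!p & t), tn = sum(!p & !t))
}

#' @rdname pixel_confusion
#' @param tp,fp,fn,tn Non-negative counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Summary metrics from confusion counts
#'
#' Computes accuracy `(tp+tn)/N`, sensitivity (recall) `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, and the F-score (the
#' harmonic mean of precision and recall). Metrics with a zero denominator
#' are reported as `NA` with an explanatory note rather than silently
#' dropped; the F-score is defined as 0 when precision and recall are both
#' zero or undefined with positives present.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metrics_report`: one-row tibble with columns `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f_score`, and a
#'   `"notes"` attribute naming any undefined metric.
#' @examples
#' summary_metrics(confusion_counts(tp = 8, fp = 2, fn = 2, tn = 88))
#' @export
summary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) stop("all counts are zero", call. = FALSE)
  notes <- character()
  rate <- function(num, den, what) {
    if (den == 0) {
      notes <<- c(notes, paste0(what, " undefined: denominator is zero"))
      return(NA_real_)
    }
    num / den
  }
  acc <- (counts$tp + counts$tn) / n
  sens <- rate(counts$tp, counts$tp + counts$fn, "sensitivity")
  spec <- rate(counts$tn, counts$tn + counts$fp, "specificity")
  prec <- rate(counts$tp, counts$tp + counts$fp, "precision")
  f <- if (2 * counts$tp + counts$fp + counts$fn == 0) {
    notes <- c(notes, "f_score undefined: no positives in pred or truth")
    NA_real_
  } else {
    2 * counts$tp / (2 * counts$tp + counts$fp + counts$fn)
  }
  out <- tibble::tibble(accuracy = acc, sensitivity = sens,
                        specificity = spec, precision = prec, f_score = f)
  class(out) <- c("metrics_report", class(out))
  attr(out, "notes") <- notes
  out
}

#' Detection-level evaluation of presence/absence calls
#'
#' Confusion counts and summary metrics over paired boolean presence calls
#' -- per B-scan for the cross-sectional model or per volume for the
#' en face model.
#'
#' @param pred,truth Logical vectors of equal, positive length.
#' @return List with `counts` (`confusion_counts`) and `metrics`
#'   (`metrics_report`).
#' @export
detection_eval <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    stop("pred and truth must be non-empty and of equal length",
         call. = FALSE)
  }
  counts <- confusion_counts(tp = sum(pred & truth),
                             fp = sum(pred & !truth),
                             fn = sum(!pred & truth),
                             tn = sum(!pred & !truth))
  list(counts = counts, metrics = summary_metrics(counts))
}

#' Pearson correlation between predicted and ground-truth areas
#'
#' Product-moment correlation with the two-sided p-value from the
#' t-transform on `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param areas_pred,areas_truth Numeric vectors (n >= 3, non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_agreement <- function(areas_pred, areas_truth) {
  if (length(areas_pred) < 3 || length(areas_pred) != length(areas_truth)) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(areas_pred) == 0 || stats::sd(areas_truth) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(areas_pred, areas_truth, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(areas_pred))
}

#' Intraclass correlation for method-vs-truth agreement
#'
#' Two-way, absolute-agreement, single-measure ICC -- ICC(A,1) in the
#' McGraw & Wong taxonomy -- the standard choice when one "rater" is an
#' automated method and the other the ground truth and systematic offsets
#' should count against agreement. The estimate comes from the two-way
#' ANOVA mean squares (rows = subjects, columns = raters) and the
#' confidence interval from the F-distribution method with
#' Satterthwaite degrees of freedom. A `"consistency"` variant (ICC(C,1),
#' which ignores rater mean offsets) is available.
#'
#' @param areas_pred,areas_truth Paired measurements (n >= 5).
#' @param confidence Confidence level for the interval (default 0.95).
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @return List with `icc`, `ci_low`, `ci_high`, `confidence`, `variant`,
#'   and the mean squares `ms` (rows, columns, error).
#' @export
icc_agreement <- function(areas_pred, areas_truth, confidence = 0.95,
                          variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  n <- length(areas_pred)
  if (n < 5 || n != length(areas_truth)) {
    stop("need at least 5 paired observations", call. = FALSE)
  }
  x <- cbind(areas_pred, areas_truth)
  k <- 2
  if (stats::var(as.vector(x)) == 0) {
    stop("degenerate input: zero total variance", call. = FALSE)
  }
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - confidence
  if (variant == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], confidence = confidence,
       variant = variant, ms = c(rows = msr, cols = msc, error = mse))
}

#' Pooled pixel-wise ROC curve
#'
#' Sweeps a confidence threshold over all pixels pooled across scans and
#' reports the false/true positive rates at every distinct confidence
#' value, anchored at (0,0) and (1,1); the area under the curve uses the
#' trapezoid rule. Pixel pooling (rather than per-scan averaging) weights
#' every pixel equally regardless of scan.
#'
#' @param confidences Numeric vector, matrix, or list of maps with values
#'   in `[0, 1]`.
#' @param truths Binary labels of matching total length.
#' @return An object of class `roc_curve`: list with `points` (tibble:
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(confidences, truths) {
  conf <- unlist(lapply(if (is.list(confidences)) confidences
                        else list(confidences), function(m) as.numeric(unclass(m))))
  tr <- unlist(lapply(if (is.list(truths)) truths
                      else list(truths), function(m) as.numeric(unclass(m) > 0)))
  if (length(conf) != length(tr)) stop("shape mismatch", call. = FALSE)
  if (min(conf) < 0 || max(conf) > 1) {
    stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  np <- sum(tr == 1)
  nn <- sum(tr == 0)
  if (np == 0 || nn == 0) {
    stop("truth contains a single class; ROC undefined", call. = FALSE)
  }
  ord <- order(conf, decreasing = TRUE)
  conf_s <- conf[ord]
  tr_s <- tr[ord]
  cum_tp <- cumsum(tr_s)
  cum_fp <- cumsum(1 - tr_s)
  last <- cumsum(rle(conf_s)$lengths)  # last index of each distinct value
  pts <- tibble::tibble(
    threshold = c(Inf, conf_s[last], -Inf),
    tpr = c(0, cum_tp[last] / np, 1),
    fpr = c(0, cum_fp[last] / nn, 1)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = np, n_neg = nn),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f over %d positive / %d negative pixels\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
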