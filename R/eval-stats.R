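#' Confusion matrix
#'
#' Counts of agreement between the system's eligibility call and the expert
#' gold standard: TP (both eligible), FN (system negative, expert positive),
#' FP (system positive, expert negative), TN (both negative).
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return An `ltx_confusion`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers")
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "ltx_confusion")
}

#' @export
print.ltx_confusion <- function(x, ...) {
  cat("<confusion matrix> TP=", x$tp, " FN=", x$fn, " FP=", x$fp,
      " TN=", x$tn, " (n=", x$tp + x$fn + x$fp + x$tn, ")\n", sep = "")
  invisible(x)
}

#' Build a confusion matrix from labelled predictions
#'
#' @param predicted,actual Equal-length logical vectors (`TRUE` = eligible
#'   candidate). `predicted` is the system's call, `actual` the expert
#'   judgment.
#' @return An `ltx_confusion`.
#' @export
confusion_from_labels <- function(predicted, actual) {
  if (!is.logical(predicted) || !is.logical(actual)) {
    stop("predicted and actual must be logical vectors")
  }
  if (length(predicted) != length(actual)) {
    stop("length mismatch: ", length(predicted), " predictions vs ",
         length(actual), " labels")
  }
  if (length(predicted) == 0L) stop("empty label vectors")
  if (anyNA(predicted) || anyNA(actual)) stop("labels must not contain NA")
  confusion_matrix(
    tp = sum(predicted & actual),
    fn = sum(!predicted & actual),
    fp = sum(predicted & !actual),
    tn = sum(!predicted & !actual)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#' At `x = n` the lower bound has the closed form `(alpha/2)^(1/n)`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' clopper_pearson(50, 59)   # c(0.7301, 0.9278) to 4 d.p.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (length(successes) != 1L || length(n) != 1L || is.na(successes) || is.na(n) ||
      n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("need integers 0 <= successes <= n with n >= 1; got successes=",
         successes, ", n=", n)
  }
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(ci_low = lo, ci_high = hi)
}

.metric_estimate <- function(x, n, level, metric) {
  ci <- clopper_pearson(x, n, level)
  structure(
    list(metric = metric, point = x / n,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         level = level, successes = x, n = n, method = "clopper-pearson"),
    class = "ltx_metric"
  )
}

#' @export
print.ltx_metric <- function(x, ...) {
  cat(sprintf("%s: %.2f%% (%.2f-%.2f%%; %g%% CI, %s)\n",
              x$metric, 100 * x$point, 100 * x$ci_low, 100 * x$ci_high,
              100 * x$level, x$method))
  invisible(x)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' `accuracy` = (TP + TN) / (TP + TN + FP + FN);
#' `sensitivity` = TP / (TP + FN); `specificity` = TN / (TN + FP).
#' Each returns a point estimate with an exact Clopper-Pearson interval. A
#' zero denominator (e.g. sensitivity with no actual positives) is an
#' explicit error, never `NaN`.
#'
#' @param cm An [confusion_matrix()].
#' @param level Confidence level.
#' @return An `ltx_metric` (point, ci_low, ci_high, level, method).
#' @examples
#' cm <- confusion_matrix(tp = 28, fn = 9, fp = 0, tn = 22)
#' accuracy(cm)      # 84.75% (73.01-92.78%)
#' sensitivity(cm)   # 75.68% (58.80-88.23%)
#' specificity(cm)   # 100%
#' @export
accuracy <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "ltx_confusion"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0L) stop("undefined metric: accuracy of an empty matrix")
  .metric_estimate(cm$tp + cm$tn, n, level, "accuracy")
}

#' @rdname accuracy
#' @export
sensitivity <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "ltx_confusion"))
  pos <- cm$tp + cm$fn
  if (pos == 0L) stop("undefined metric: sensitivity with no actual positives")
  .metric_estimate(cm$tp, pos, level, "sensitivity")
}

#' @rdname accuracy
#' @export
specificity <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "ltx_confusion"))
  neg <- cm$tn + cm$fp
  if (neg == 0L) stop("undefined metric: specificity with no actual negatives")
  .metric_estimate(cm$tn, neg, level, "specificity")
}

#' All three metrics as a table
#'
#' @param cm An [confusion_matrix()].
#' @param level Confidence level.
#' @return Data frame with one row per metric: `metric`, `point`, `ci_low`,
#'   `ci_high` (proportions), plus `successes` and `n`.
#' @export
evaluation_table <- function(cm, level = 0.95) {
  ms <- list(accuracy(cm, level), sensitivity(cm, level), specificity(cm, level))
  do.call(rbind, lapply(ms, function(m) {
    data.frame(metric = m$metric, point = m$point, ci_low = m$ci_low,
               ci_high = m$ci_high, successes = m$successes, n = m$n,
               stringsAsFactors = FALSE)
  }))
}
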