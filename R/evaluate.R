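#' Balanced accuracy of carrier predictions
#'
#' Mean of sensitivity and specificity,
#' `(TP/(TP+FN) + TN/(FP+TN)) / 2`, which unlike raw accuracy is not
#' dominated by the majority class when carriers and non-carriers are
#' imbalanced (few carriers early in a sweep, few non-carriers late). If
#' the truth contains a single class, the available rate (sensitivity or
#' specificity) is returned alone with a warning.
#'
#' @param labels Predicted labels: logical, or `"carrier"`/`"non-carrier"`.
#' @param truth True labels, same encoding and length.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`,
#'   `balanced_accuracy` and `single_class` (TRUE when only one truth class
#'   was present).
#' @examples
#' balanced_accuracy(rep(c(TRUE, FALSE), c(110, 90)),
#'                   rep(c(TRUE, FALSE), c(100, 100)))
#' @export
balanced_accuracy <- function(labels, truth) {
  labels <- to_logical_label(labels)
  truth <- to_logical_label(truth)
  if (length(labels) != length(truth)) {
    stop("labels and truth must have equal length", call. = FALSE)
  }
  tp <- sum(labels & truth)
  fn <- sum(!labels & truth)
  tn <- sum(!labels & !truth)
  fp <- sum(labels & !truth)
  single <- (tp + fn) == 0 || (tn + fp) == 0
  ba <- if (single) {
    warning("truth contains a single class; reporting the one defined rate",
            call. = FALSE)
    if ((tp + fn) > 0) tp / (tp + fn) else tn / (fp + tn)
  } else {
    (tp / (tp + fn) + tn / (fp + tn)) / 2
  }
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 balanced_accuracy = ba, single_class = single)
}

to_logical_label <- function(x) {
  if (is.character(x) || is.factor(x)) as.character(x) == "carrier" else
    as.logical(x)
}

#' Wilcoxon rank-sum separation of carrier and non-carrier scores
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of identically
#' distributed scores in carriers versus non-carriers, through
#' [stats::wilcox.test()]: exact enumeration for small tie-free groups,
#' normal approximation with tie correction otherwise.
#'
#' @param scores Numeric vector of scores.
#' @param truth Carrier truth (logical or `"carrier"`/`"non-carrier"`).
#' @return A one-row tibble with `n_carrier`, `n_noncarrier`, `statistic`
#'   (the Mann-Whitney U of the carrier group) and `p_value`.
#' @examples
#' carrier_separation_test(c(1, 2, 3, 10, 11, 12),
#'                         rep(c(FALSE, TRUE), each = 3))  # p = 0.1
#' @export
carrier_separation_test <- function(scores, truth) {
  truth <- to_logical_label(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length", call. = FALSE)
  }
  if (!any(truth) || all(truth)) {
    stop("both carrier and non-carrier classes must be non-empty",
         call. = FALSE)
  }
  car <- scores[truth]
  non <- scores[!truth]
  exact <- length(car) <= 20 && length(non) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(car, non, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(n_carrier = length(car), n_noncarrier = length(non),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Evaluate a carrier prediction against simulation truth
#'
#' Convenience wrapper combining [balanced_accuracy()] and
#' [carrier_separation_test()] for a [predict_carriers()] result whose
#' input carried `carrier_truth`.
#'
#' @param prediction A `precioss` tibble with a `carrier_truth` column.
#' @return A one-row tibble with the confusion counts, balanced accuracy
#'   and Wilcoxon p-value (NA when truth is single-class).
#' @export
evaluate_prediction <- function(prediction) {
  if (is.null(prediction[["carrier_truth"]])) {
    stop("prediction has no carrier_truth to evaluate against",
         call. = FALSE)
  }
  ba <- balanced_accuracy(prediction$label, prediction[["carrier_truth"]])
  p <- if (ba$single_class) NA_real_ else {
    carrier_separation_test(prediction$score,
                            prediction[["carrier_truth"]])$p_value
  }
  ba$wilcoxon_p <- p
  ba
}
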