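#' Binary confusion matrix
#'
#' Cross-tabulates observed against predicted class codes for a two-class
#' task. All downstream metrics (accuracy, sensitivity, specificity,
#' precision, recall, F-measure, kappa) read their TP/FP/FN/TN counts from
#' this object.
#'
#' @param truth,predicted Equal-length vectors of class codes. Together they
#'   may contain at most two distinct codes.
#' @param positive The code treated as the positive class (default: the
#'   larger observed code, e.g. malignant = 2 against benign = 1).
#' @return An object of class `fz_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn` and `positive`.
#' @export
confusion_matrix <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) {
    rlang::abort("`truth` and `predicted` must have the same length")
  }
  if (length(truth) == 0) rlang::abort("no scored instances")
  codes <- sort(unique(c(truth, predicted)))
  if (length(codes) > 2) {
    rlang::abort("more than two distinct class codes; the metric suite is binary")
  }
  if (is.null(positive)) positive <- max(codes)
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, positive = positive),
            class = "fz_confusion")
}

#' @export
print.fz_confusion <- function(x, ...) {
  cat(sprintf("<fz_confusion> positive class = %s\n", format(x$positive)))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(t(m))
  invisible(x)
}

#' @method tidy fz_confusion
#' @export
tidy.fz_confusion <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}

# 0/0 ratios become 0 with a structured warning, never NaN
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    rlang::warn(sprintf("%s is 0/0; returning 0 by convention", what),
                class = "fuzzydx_degenerate_metric")
    return(0)
  }
  num / den
}

#' Threshold classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity `TP/(TP+FN)` (the
#' true-positive rate, identical to recall), specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` and the F-measure, the harmonic mean of precision
#' and recall. Any 0/0 denominator yields 0 with a warning.
#'
#' @param cm An [confusion_matrix()].
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `recall`, `f_measure`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "fz_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) rlang::abort("empty confusion matrix")
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  f <- safe_ratio(2 * prec * sens, prec + sens, "f_measure")
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / total,
    sensitivity = sens, specificity = spec,
    precision = prec, recall = sens, f_measure = f
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed accuracy and `p_e` the agreement expected from the row/column
#' marginals. When `p_e = 1` the statistic is 1 for perfect agreement and 0
#' (flagged) otherwise.
#'
#' @param cm An [confusion_matrix()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "fz_confusion"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) rlang::abort("empty confusion matrix")
  po <- (cm$tp + cm$tn) / total
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
         (cm$tn + cm$fp) * (cm$tn + cm$fn)) / total^2
  if (pe == 1) {
    if (po == 1) return(1)
    rlang::warn("kappa is 0/0 (degenerate marginals); returning 0",
                class = "fuzzydx_degenerate_metric")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive instance is scored above a
#' randomly chosen negative one: over all positive x negative pairs, a win
#' counts 1 and a tie 1/2. For the induced fuzzy classifiers the score is the
#' crisp defuzzified output, oriented so larger means more positive.
#'
#' @param truth Class codes.
#' @param scores Numeric scores, larger = more positive.
#' @param positive Code of the positive class (default: larger code).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(truth, scores, positive = NULL) {
  if (length(truth) != length(scores)) {
    rlang::abort("`truth` and `scores` must have the same length")
  }
  if (is.null(positive)) positive <- max(truth)
  pos <- truth == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Verbal category of an AUC value
#'
#' The conventional discrimination bands: 0.9-1.0 excellent, 0.8-0.9 good,
#' 0.7-0.8 fair, 0.6-0.7 poor, 0.5-0.6 failure (each band closed at its lower
#' edge), and below 0.5 "worse than chance".
#'
#' @param auc A value in `[0, 1]`.
#' @return A category label.
#' @export
auc_category <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1 || is.na(auc) || auc < 0 || auc > 1) {
    rlang::abort("`auc` must be a single value in [0, 1]")
  }
  if (auc >= 0.9) "excellent classification"
  else if (auc >= 0.8) "good classification"
  else if (auc >= 0.7) "fair classification"
  else if (auc >= 0.6) "poor classification"
  else if (auc >= 0.5) "failure"
  else "worse than chance"
}

#' Full metric set for one batch of predictions
#'
#' Bundles the whole evaluation suite into one row: confusion-matrix metrics,
#' Cohen's kappa, rank AUC and its verbal category.
#'
#' @param truth Observed class codes.
#' @param predicted Predicted class codes.
#' @param scores Optional numeric scores for AUC (larger = more positive);
#'   when omitted, AUC is computed from the predicted codes themselves.
#' @param positive Positive class code (default: larger observed code).
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f_measure`, `kappa`, `auc`, `auc_category`.
#' @export
fz_metric_set <- function(truth, predicted, scores = NULL, positive = NULL) {
  cm <- confusion_matrix(truth, predicted, positive = positive)
  if (is.null(scores)) {
    scores <- as.numeric(predicted == cm$positive)
  }
  auc <- if (length(unique(truth)) == 2) {
    rank_auc(truth, scores, positive = cm$positive)
  } else {
    NA_real_
  }
  dplyr::mutate(
    classification_metrics(cm),
    kappa = cohen_kappa(cm),
    auc = auc,
    auc_category = if (is.na(auc)) NA_character_ else auc_category(auc)
  )
}
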