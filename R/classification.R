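# Independent-set validation of a marker panel: train a classifier on the
# discovery dataset restricted to the marker genes, predict the validation
# dataset, and summarize with confusion counts, ACC/SEN/SPE/MCC and ROC/AUC.
# The metric formulas are implemented here directly; the classifier itself is
# pluggable (linear SVM by default).

#' Linear SVM classifier factory
#'
#' Returns a fit/predict closure satisfying the classifier contract used by
#' [train_and_predict()]: `fit(x, y)` takes a samples x features matrix and a
#' `case`/`control` factor and returns an object whose `predict(newx)` yields
#' hard labels and signed decision scores oriented so that larger means more
#' case-like.
#'
#' @param cost Regularization parameter C (default 1).
#' @param kernel SVM kernel (default `"linear"`).
#' @return A function `fit(x, y)`.
#' @export
svm_classifier <- function(cost = 1, kernel = "linear") {
  function(x, y) {
    model <- e1071::svm(x, y, kernel = kernel, cost = cost, scale = FALSE)
    list(predict = function(newx) {
      pr <- stats::predict(model, newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      scores <- drop(dv)
      # e1071 orients decision values towards the class named first in the
      # "A/B" column label; flip if that is not "case"
      positive <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (positive != "case") scores <- -scores
      list(labels = as.character(pr), scores = unname(scores))
    })
  }
}

#' Train on a discovery dataset and predict an independent validation set
#'
#' Restricts both datasets to the marker genes (features missing from the
#' validation dataset are dropped with a warning), fits the classifier on the
#' discovery samples, and scores the validation samples. Both datasets are
#' expected on the per-array standardized scale (see [integrate_studies()]).
#'
#' @param train,validation `integrated_dataset` objects.
#' @param features Character vector of marker gene ids (non-empty after
#'   intersection with both datasets).
#' @param classifier A classifier factory as returned by [svm_classifier()]
#'   (the default).
#' @return A list with `labels` (predicted `"case"`/`"control"` for the
#'   validation samples), `scores` (signed decision values, larger = more
#'   case-like), and `features_used`.
#' @export
train_and_predict <- function(train, validation, features,
                              classifier = svm_classifier()) {
  stopifnot(inherits(train, "integrated_dataset"),
            inherits(validation, "integrated_dataset"))
  features <- unique(as.character(features))
  if (!length(features)) stop("empty feature set", call. = FALSE)
  kept <- intersect(intersect(features, rownames(train$values)),
                    rownames(validation$values))
  lost <- setdiff(features, kept)
  if (!length(kept))
    stop("no features survive the intersection with the datasets; missing: ",
         paste(lost, collapse = ", "), call. = FALSE)
  if (length(lost))
    warning(sprintf("dropped %d feature(s) missing from a dataset: %s",
                    length(lost), paste(lost, collapse = ", ")), call. = FALSE)
  y <- factor(train$samples$group, levels = c("case", "control"))
  if (length(unique(y)) < 2)
    stop("training set contains a single class", call. = FALSE)
  fit <- classifier(t(train$values[kept, , drop = FALSE]), y)
  out <- fit$predict(t(validation$values[kept, , drop = FALSE]))
  out$features_used <- kept
  out
}

#' Confusion matrix with case as the positive class
#'
#' @param truth,predicted Character vectors of equal length with values
#'   `"case"`/`"control"`.
#' @return A list of class `confusion_matrix` with counts `TP`, `FN`, `TN`,
#'   `FP`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop(sprintf("length mismatch: %d truth vs %d predicted labels",
                 length(truth), length(predicted)), call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), c("case", "control"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(TP = sum(truth == "case" & predicted == "case"),
                 FN = sum(truth == "case" & predicted == "control"),
                 TN = sum(truth == "control" & predicted == "control"),
                 FP = sum(truth == "control" & predicted == "case")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FN=%d TN=%d FP=%d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' `ACC = (TP+TN)/total`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any ratio
#' with a zero denominator (including any zero factor under the MCC root) is
#' defined as 0 and flagged in the `undefined` element.
#'
#' @param cm A [confusion()] result, or a list/vector with elements `TP`,
#'   `FN`, `TN`, `FP`.
#' @return A list with `ACC`, `SEN`, `SPE`, `MCC` (full precision), `rounded`
#'   (the same, rounded half-up to 2 decimals, the table convention) and
#'   `undefined` (character vector naming zero-denominator metrics).
#' @examples
#' metrics(list(TP = 7, FN = 1, TN = 4, FP = 0))
#' @export
metrics <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); fn <- as.numeric(cm[["FN"]])
  tn <- as.numeric(cm[["TN"]]); fp <- as.numeric(cm[["FP"]])
  if (anyNA(c(tp, fn, tn, fp)) || any(c(tp, fn, tn, fp) < 0))
    stop("confusion counts must be non-negative numbers", call. = FALSE)
  total <- tp + fn + tn + fp
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  acc <- (tp + tn) / total
  sen <- ratio(tp, tp + fn, "SEN")
  spe <- ratio(tn, tn + fp, "SPE")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) { undefined <- c(undefined, "MCC"); 0 } else
    (tp * tn - fp * fn) / sqrt(denom)
  list(ACC = acc, SEN = sen, SPE = spe, MCC = mcc,
       rounded = c(ACC = round_half_up(acc, 2), SEN = round_half_up(sen, 2),
                   SPE = round_half_up(spe, 2), MCC = round_half_up(mcc, 2)),
       undefined = undefined)
}

# round() rounds half to even; published tables round half up.
round_half_up <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the Mann-Whitney statistic: the fraction of (case, control)
#' pairs in which the case score exceeds the control score, ties counted 1/2.
#' The ROC curve is a threshold sweep over the unique scores (predict case
#' when `score >= threshold`), starting at (0, 0) and ending at (1, 1); its
#' trapezoidal area equals the Mann-Whitney AUC.
#'
#' @param scores Numeric decision scores, larger = more case-like.
#' @param labels Character vector of true labels (`"case"`/`"control"`), both
#'   classes present.
#' @return A list with `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c("control", "control", "case", "case"))
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pos <- labels == "case"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0)
    stop("both classes must be present to compute ROC/AUC", call. = FALSE)
  # Mann-Whitney via mid-ranks: ties contribute 1/2 automatically
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n2, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

#' Full classification report against known validation labels
#'
#' @param truth True labels of the validation samples.
#' @param predicted Predicted labels.
#' @param scores Decision scores (larger = more case-like).
#' @return A list of class `classification_report` with `confusion`,
#'   `metrics`, `roc` and `auc`.
#' @export
classification_report <- function(truth, predicted, scores) {
  cm <- confusion(truth, predicted)
  ra <- roc_auc(scores, truth)
  structure(list(confusion = cm, metrics = metrics(cm),
                 roc = ra$roc, auc = ra$auc),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$metrics$rounded
  cat(sprintf("<classification_report> TP=%d FN=%d TN=%d FP=%d | ACC %.2f SEN %.2f SPE %.2f MCC %.2f AUC %.2f\n",
              x$confusion$TP, x$confusion$FN, x$confusion$TN, x$confusion$FP,
              m["ACC"], m["SEN"], m["SPE"], m["MCC"], x$auc))
  invisible(x)
}
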