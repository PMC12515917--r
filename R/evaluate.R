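#' Confusion-matrix metric suite
#'
#' Computes the full binary evaluation report with the normal class as the
#' positive category: TP = correctly predicted normal, TN = correctly
#' predicted abnormal, FP = abnormal predicted normal, FN = normal
#' predicted abnormal. Per-class precision and recall (precision_abnormal
#' = TN / (TN + FN), recall_abnormal = TN / (TN + FP)), per-class F1
#' (harmonic mean), accuracy = (TP + TN) / n, and — when scores are given
#' — the ROC curve and its trapezoidal AUC.
#'
#' @param labels True labels: `"normal"`/`"abnormal"` (character or
#'   factor).
#' @param predictions Predicted labels, same coding.
#' @param scores Optional numeric scores for the *normal* class (higher =
#'   more normal); enables ROC/AUC.
#' @return An `eval_report` list: `confusion` (2x2 matrix, rows = truth),
#'   `precision_normal`, `precision_abnormal`, `recall_normal`,
#'   `recall_abnormal`, `f1_normal`, `f1_abnormal`, `accuracy`, `roc`
#'   (tibble of FPR/TPR or `NULL`), `auc`, `n`.
#' @examples
#' compute_metrics(c("normal", "normal", "abnormal"),
#'                 c("normal", "abnormal", "abnormal"))$accuracy
#' @export
compute_metrics <- function(labels, predictions, scores = NULL) {
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(labels) == length(predictions))
  lv <- c("normal", "abnormal")
  labels <- factor(as.character(labels), levels = lv)
  predictions <- factor(as.character(predictions), levels = lv)
  tp <- sum(labels == "normal" & predictions == "normal")
  fn <- sum(labels == "normal" & predictions == "abnormal")
  fp <- sum(labels == "abnormal" & predictions == "normal")
  tn <- sum(labels == "abnormal" & predictions == "abnormal")
  n <- length(labels)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                 dimnames = list(truth = lv, prediction = lv))
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec_n <- safe_div(tp, tp + fp)
  prec_a <- safe_div(tn, tn + fn)
  rec_n <- safe_div(tp, tp + fn)
  rec_a <- safe_div(tn, tn + fp)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  roc <- NULL
  auc <- NA_real_
  if (!is.null(scores)) {
    ra <- roc_auc(labels, scores)
    roc <- ra$roc
    auc <- ra$auc
  }
  structure(
    list(confusion = conf,
         precision_normal = prec_n, precision_abnormal = prec_a,
         recall_normal = rec_n, recall_abnormal = rec_a,
         f1_normal = f1(prec_n, rec_n), f1_abnormal = f1(prec_a, rec_a),
         accuracy = (tp + tn) / n, roc = roc, auc = auc, n = n),
    class = "eval_report"
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (ties cross simultaneously),
#' tracing the ROC from (0, 0) to (1, 1) with the normal class positive,
#' and integrates the area by the trapezoidal rule.
#'
#' @param labels True labels (`"normal"`/`"abnormal"`, character or
#'   factor); both classes must be present.
#' @param scores Numeric scores for the normal class.
#' @param positive Which level counts as positive (default `"normal"`).
#' @return A list: `roc` (tibble with `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores, positive = "normal") {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores))
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp <- cumsum(!duplicated(s))          # tie groups, descending score
  tp_cum <- cumsum(p)
  fp_cum <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp_cum[last] / n_pos)
  fpr <- c(0, fp_cum[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr,
                            tpr = tpr),
       auc = auc)
}

#' Generalization decay rate
#'
#' Relative drop in AUC from the training site to an external site,
#' `GDR = (AUC_train - AUC_external) / AUC_train * 100` (percent). Decay
#' beyond 15% flags the need for domain adaptation.
#'
#' @param auc_train Training-site AUC (> 0).
#' @param auc_external External-site AUC.
#' @return A list: `gdr_percent` and `adaptation_needed` (GDR > 15).
#' @examples
#' gdr(0.9, 0.72)  # 20%, adaptation flagged
#' @export
gdr <- function(auc_train, auc_external) {
  if (auc_train <= 0) stop("auc_train must be positive", call. = FALSE)
  g <- (auc_train - auc_external) / auc_train * 100
  list(gdr_percent = g, adaptation_needed = g > 15)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d acc=%.3f | P/R/F1 normal %.2f/%.2f/%.2f abnormal %.2f/%.2f/%.2f | AUC %s\n",
    x$n, x$accuracy, x$precision_normal, x$recall_normal, x$f1_normal,
    x$precision_abnormal, x$recall_abnormal, x$f1_abnormal,
    if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("precision_normal", "precision_abnormal", "recall_normal",
               "recall_abnormal", "f1_normal", "f1_abnormal", "accuracy",
               "auc"),
    value = c(x$precision_normal, x$precision_abnormal, x$recall_normal,
              x$recall_abnormal, x$f1_normal, x$f1_abnormal, x$accuracy,
              x$auc)
  )
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, auc = x$auc,
                 tp = x$confusion[1, 1], fn = x$confusion[1, 2],
                 fp = x$confusion[2, 1], tn = x$confusion[2, 2])
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report has no ROC (no scores supplied)",
                                call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted model on a chart dataset
#'
#' Renders the dataset to tensors, predicts, and assembles an
#' [compute_metrics()] report (prediction = argmax; ROC score = normal
#' class probability).
#'
#' @param model A fitted `ctg_model`.
#' @param dataset A dataset tibble with `chart` and `binary_label`.
#' @param input_hw Optional resize target passed to [charts_to_tensor()].
#' @param mask_uc Blank the UC band (unimodal ablation).
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, dataset, input_hw = NULL,
                           mask_uc = FALSE) {
  x <- charts_to_tensor(dataset$chart, input_hw, mask_uc)
  probs <- predict_model(model, x)
  preds <- c("normal", "abnormal")[max.col(probs)]
  compute_metrics(dataset$binary_label, preds, scores = probs[, 1])
}
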