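## metrics: the evaluation suite for both heads.
## Conventions (documented, since several are underdetermined in common
## usage): score == threshold predicts positive; AUC and CI credit ties
## 0.5; MCC with a zero denominator factor is 0; precision with no
## predicted positives is 0 with a warning; Spearman uses average ranks.

#' Confusion counts at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold; `score >= threshold` predicts
#'   positive (default 0.5).
#' @return An object of class `pg_confusion`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores have different lengths (",
         length(labels), " vs ", length(scores), ")")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1)),
            class = "pg_confusion")
}

#' Construct confusion counts directly
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A `pg_confusion`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "pg_confusion")
}

#' @exportS3Method base::print
print.pg_confusion <- function(x, ...) {
  cat("<pg_confusion> TP=", x$TP, " FP=", x$FP, " TN=", x$TN,
      " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor
#' of the denominator is zero the result is 0 by convention.
#'
#' @param c A `pg_confusion`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "pg_confusion"))
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)  # doubles: no overflow
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic via average
#' ranks, so ties between a positive and a negative score are credited
#' 0.5.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric bundle
#'
#' AUC, TPR (= TP/(TP+FN)), precision (= TP/(TP+FP), 0 with a warning
#' when nothing is predicted positive), accuracy and MCC at a decision
#' threshold.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `pg_metrics` (named list).
#' @export
classification_report <- function(labels, scores, threshold = 0.5) {
  cc <- confusion(labels, scores, threshold)
  n <- cc$TP + cc$FP + cc$TN + cc$FN
  tpr <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0
  prec <- if (cc$TP + cc$FP > 0) {
    cc$TP / (cc$TP + cc$FP)
  } else {
    warning("no predicted positives; precision set to 0")
    0
  }
  structure(list(auc = roc_auc(labels, scores), tpr = tpr,
                 precision = prec, accuracy = (cc$TP + cc$TN) / n,
                 mcc = mcc(cc), counts = cc, threshold = threshold),
            class = "pg_metrics")
}

#' Regression metric bundle
#'
#' RMSE, MSE, Pearson and Spearman correlations, and the concordance
#' index.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return An object of class `pg_metrics` (named list).
#' @export
regression_report <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values")
  if (sd(y) == 0 || sd(yhat) == 0)
    stop("correlation undefined: zero variance input")
  mse <- mean((y - yhat)^2)
  structure(list(rmse = sqrt(mse), mse = mse,
                 pearson = cor(y, yhat),
                 spearman = cor(y, yhat, method = "spearman"),
                 ci = concordance_index(y, yhat)),
            class = "pg_metrics")
}

#' @exportS3Method base::print
print.pg_metrics <- function(x, ...) {
  nums <- x[vapply(x, is.numeric, TRUE)]
  nums <- nums[!vapply(nums, function(v) length(v) != 1, TRUE)]
  cat("<pg_metrics> ",
      paste(names(nums), sprintf("%.4f", unlist(nums)), sep = "=",
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Concordance index
#'
#' Over all pairs with `y_i > y_j`: credit 1 if `yhat_i > yhat_j`, 0.5
#' if equal, 0 otherwise; divided by the number of such pairs. For
#' binary `y` this equals [roc_auc()] exactly.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  gt <- outer(y, y, ">")
  if (!any(gt)) stop("CI undefined: all observed values equal")
  dp <- outer(yhat, yhat, "-")
  credit <- (dp > 0) + 0.5 * (dp == 0)
  sum(credit[gt]) / sum(gt)
}

#' Write a metric bundle as TSV and JSON
#'
#' @param x A `pg_metrics`.
#' @param path Output path without extension; writes `<path>.tsv` and
#'   `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "pg_metrics"))
  nums <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  df <- data.frame(metric = names(nums), value = unlist(nums))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(nums, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a DUD.E-style actives/inactives file pair
#'
#' Each file holds one molecule per line: SMILES first token, optional
#' id second token (.ism convention). Returns a data.frame with
#' `smiles`, `id` and `label` (1 for actives, 0 for inactives).
#'
#' @param actives_path,inactives_path File paths.
#' @return data.frame with columns `smiles`, `id`, `label`.
#' @export
read_actives_inactives <- function(actives_path, inactives_path) {
  rd <- function(p, lab) {
    ln <- readLines(p, warn = FALSE)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(trimws(ln), "[ \t]+")
    data.frame(smiles = vapply(parts, `[`, "", 1),
               id = vapply(parts, function(x)
                 if (length(x) > 1) x[[2]] else NA_character_, ""),
               label = lab, stringsAsFactors = FALSE)
  }
  rbind(rd(actives_path, 1), rd(inactives_path, 0))
}
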