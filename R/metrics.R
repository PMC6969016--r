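# Multiclass performance metrics: per-class one-vs-rest confusion counts,
# precision / recall / F1 computed literally from TP, FP, TN, FN, one-vs-rest
# AUC from the rank statistic, and prevalence-weighted aggregates.

#' Evaluate predictions against known classes
#'
#' Accuracy is the proportion of samples correctly classified. For each class
#' the predictions are reduced to one-vs-rest confusion counts, from which
#' precision = TP/(TP+FP), recall = TP/(TP+FN) and the F1 score (harmonic
#' mean of the two) follow. A zero denominator yields 0 with a warning and
#' the class still enters the weighted averages by prevalence. Per-class AUC
#' is computed from scores (the fraction of the k votes for the class) via
#' the Mann-Whitney rank statistic; aggregates are averages weighted by the
#' prevalence of each class in `y_true`.
#'
#' @param y_true,y_pred equal-length character vectors of classes.
#' @param scores optional numeric matrix (rows = samples, named columns =
#'   classes) of per-class scores for AUC.
#' @return A `metrics_report`: list with `per_class` (data.frame of counts
#'   and rates), `accuracy`, `precision`, `recall`, `f1`, `auc` (weighted
#'   aggregates), and `n_samples`.
#' @export
evaluate <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  n <- length(y_true)
  if (n == 0) stop("empty label vectors")
  classes <- sort(union(unique(y_true), unique(y_pred)))
  per <- data.frame(class = classes, tp = NA_integer_, fp = NA_integer_,
                    tn = NA_integer_, fn = NA_integer_,
                    prevalence = NA_real_, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                    stringsAsFactors = FALSE)
  zero_warned <- character(0)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    pos <- y_true == cl
    hat <- y_pred == cl
    tp <- sum(pos & hat); fp <- sum(!pos & hat)
    fn <- sum(pos & !hat); tn <- sum(!pos & !hat)
    prec <- if (tp + fp == 0) {
      zero_warned <- c(zero_warned, paste0(cl, " (precision)")); 0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0) {
      zero_warned <- c(zero_warned, paste0(cl, " (recall)")); 0
    } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    auc <- NA_real_
    if (!is.null(scores) && cl %in% colnames(scores)) {
      auc <- rank_auc(scores[, cl], pos)
    }
    per[i, c("tp", "fp", "tn", "fn")] <- c(tp, fp, tn, fn)
    per$prevalence[i] <- sum(pos) / n
    per$precision[i] <- prec; per$recall[i] <- rec; per$f1[i] <- f1
    per$auc[i] <- auc
  }
  if (length(zero_warned)) {
    warning("zero-denominator rate(s) reported as 0 for: ",
            paste(zero_warned, collapse = ", "))
  }
  w <- per$prevalence
  wmean <- function(v) {
    use <- w > 0 & !is.na(v)
    if (!any(use)) return(NA_real_)
    sum(v[use] * w[use]) / sum(w[use])
  }
  rep <- list(per_class = per,
              accuracy = mean(y_true == y_pred),
              precision = wmean(per$precision),
              recall = wmean(per$recall),
              f1 = wmean(per$f1),
              auc = if (is.null(scores)) NA_real_ else wmean(per$auc),
              n_samples = n)
  class(rep) <- "metrics_report"
  rep
}

# One-vs-rest AUC via the Mann-Whitney U statistic; midranks handle ties.
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, accuracy = %.4f\n", x$n_samples,
              x$accuracy))
  cat(sprintf("  weighted: precision %.4f  recall %.4f  F1 %.4f  AUC %s\n",
              x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  df <- x$per_class
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-16s P %.3f  R %.3f  F1 %.3f  (TP %d FP %d FN %d)\n",
                df$class[i], df$precision[i], df$recall[i], df$f1[i],
                df$tp[i], df$fp[i], df$fn[i]))
  }
  invisible(x)
}

#' Serialise a metrics report
#'
#' @param report a `metrics_report`.
#' @param path output path (`.json` or `.csv`).
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(report$per_class, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Scent-marking rate
#'
#' Marks per hour to two decimal places, the summary reported per deployment.
#'
#' @param n_marks number of scent-mark events.
#' @param hours deployment duration in hours.
#' @return `round(n_marks / hours, 2)`.
#' @export
scent_mark_rate <- function(n_marks, hours) {
  stopifnot(hours > 0)
  round(n_marks / hours, 2)
}
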