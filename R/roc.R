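#' ROC curve over score values
#'
#' One point per distinct score threshold plus the trivial endpoint
#' (threshold `Inf`), under the classification rule `score >= threshold =>
#' predicted positive` (higher score means recurrence).  Rows are ordered by
#' decreasing threshold, so sensitivity and 1-specificity increase down the
#' staircase from (0, 0) to (1, 1).
#'
#' @param scores numeric marker values.
#' @param labels logical outcome (`TRUE` = positive/recurrent).
#' @return a `roc_curve`: data frame `threshold, sensitivity, fpr` with
#'   attributes `n_pos`, `n_neg`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(is.finite(scores)))
    stop_pd("scores must be finite", class = "pd_validation_error")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop_pd("roc_curve needs both classes present (", n_pos, " positives, ",
            n_neg, " negatives)", class = "pd_degenerate_error")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  structure(data.frame(threshold = thr, sensitivity = sens, fpr = fpr),
            n_pos = n_pos, n_neg = n_neg, scores = scores, labels = labels,
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve with Hanley-McNeil confidence interval
#'
#' Trapezoidal area over the staircase; with ties this equals the
#' Mann-Whitney concordance probability (concordant pairs plus half of tied
#' pairs, over `n_pos * n_neg`).  The standard error follows Hanley & McNeil
#' (1982); the normal-approximation CI is clipped to `[0, 1]` and the
#' p-value tests AUC = 0.5.  `method = "delong"` substitutes the DeLong
#' structural-component variance.
#'
#' @param x a `roc_curve`, or a numeric score vector (then give `labels`).
#' @param labels logical outcome when `x` is a score vector.
#' @param conf_level confidence level (default 0.95).
#' @param method `"hanley-mcneil"` (default) or `"delong"`.
#' @return list `auc, se, ci_low, ci_high, p_value, method`.
#' @export
auc <- function(x, labels = NULL, conf_level = 0.95,
                method = c("hanley-mcneil", "delong")) {
  method <- match.arg(method)
  curve <- if (inherits(x, "roc_curve")) x else roc_curve(x, labels)
  A <- sum(diff(curve$fpr) * (utils::head(curve$sensitivity, -1) +
                              utils::tail(curve$sensitivity, -1)) / 2)
  n_pos <- attr(curve, "n_pos"); n_neg <- attr(curve, "n_neg")
  if (method == "hanley-mcneil") {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    se <- sqrt((A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
                (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg))
  } else {
    s <- attr(curve, "scores"); l <- attr(curve, "labels")
    pos <- s[l]; neg <- s[!l]
    # placement values: V10[i] = P(neg < pos_i) + P(neg == pos_i)/2
    v10 <- vapply(pos, function(p) (sum(neg < p) + sum(neg == p) / 2) / n_neg,
                  numeric(1))
    v01 <- vapply(neg, function(q) (sum(pos > q) + sum(pos == q) / 2) / n_pos,
                  numeric(1))
    se <- sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(A - 0.5) / se) else
    as.numeric(A == 0.5)
  list(auc = A, se = se, ci_low = max(0, A - z * se),
       ci_high = min(1, A + z * se), p_value = min(1, p), method = method)
}

#' Youden-optimal cutoff
#'
#' Threshold maximizing `J = sensitivity + specificity - 1` over the
#' staircase.  Ties are broken toward higher specificity, then toward the
#' higher threshold; the non-informative `Inf` endpoint is never returned.
#' `criterion = "closest"` instead minimizes the Euclidean distance to the
#' (0, 1) corner.
#'
#' @param curve a `roc_curve`.
#' @param criterion `"youden"` (default) or `"closest"` (closest to top-left).
#' @return list `cutoff, sensitivity, specificity, j`.
#' @export
youden_cutoff <- function(curve, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "roc_curve"))
  cand <- curve[is.finite(curve$threshold), , drop = FALSE]
  score <- switch(criterion,
    youden = cand$sensitivity - cand$fpr,
    closest = -sqrt((1 - cand$sensitivity)^2 + cand$fpr^2))
  best <- abs(score - max(score)) < 1e-12
  cand <- cand[best, , drop = FALSE]
  cand <- cand[cand$fpr == min(cand$fpr), , drop = FALSE]        # higher spec
  row <- cand[which.max(cand$threshold), , drop = FALSE]         # then higher t
  j <- row$sensitivity - row$fpr
  if (j <= 0)
    warning("degenerate ROC curve: maximal Youden J is ", signif(j, 3),
            call. = FALSE)
  list(cutoff = row$threshold, sensitivity = row$sensitivity,
       specificity = 1 - row$fpr, j = j)
}

#' Confusion matrix at a cutoff
#'
#' Rule: `score >= cutoff` predicts positive.
#'
#' @param scores numeric marker values.
#' @param labels logical outcome.
#' @param cutoff classification threshold.
#' @return a `confusion_matrix`: list `tp, fp, fn, tn, cutoff`.
#' @export
confusion_at <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pred <- scores >= cutoff
  structure(list(tp = sum(pred & labels), fp = sum(pred & !labels),
                 fn = sum(!pred & labels), tn = sum(!pred & !labels),
                 cutoff = cutoff), class = "confusion_matrix")
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, PPV `tp/(tp+fp)` and
#' NPV `tn/(tn+fn)`, as exact percentages.  PPV (resp. NPV) is `NA` when no
#' positive (negative) call was made — undefined, not zero.  Values are kept
#' at full precision; rounding half-up to the printed precision (2 decimals
#' for sensitivity/specificity, 1 for PPV/NPV) happens only in the print
#' method and in [roc_report()].
#'
#' @param cm a `confusion_matrix` (or list with `tp, fp, fn, tn`).
#' @return list `sensitivity, specificity, ppv, npv` (percent scale).
#' @examples
#' diagnostic_metrics(list(tp = 12, fp = 2, fn = 7, tn = 135))
#' @export
diagnostic_metrics <- function(cm) {
  with(cm, {
    if (tp + fn == 0 || fp + tn == 0)
      stop_pd("diagnostic_metrics needs both classes present",
              class = "pd_degenerate_error")
    list(sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (fp + tn),
         ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_)
  })
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("cutoff >= %g: TP %d  FP %d  FN %d  TN %d\n",
              x$cutoff, x$tp, x$fp, x$fn, x$tn))
  m <- try(diagnostic_metrics(x), silent = TRUE)
  if (!inherits(m, "try-error"))
    cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  PPV %s  NPV %s\n",
                round_half_up(m$sensitivity, 2), round_half_up(m$specificity, 2),
                if (is.na(m$ppv)) "undefined" else
                  sprintf("%.1f%%", round_half_up(m$ppv, 1)),
                if (is.na(m$npv)) "undefined" else
                  sprintf("%.1f%%", round_half_up(m$npv, 1))))
  invisible(x)
}

#' Full ROC report at a cutoff
#'
#' Bundles AUC (with CI and p against 0.5), the Youden-optimal threshold and
#' the diagnostic metrics at the configured cutoff into one list, rounded to
#' the printed precision.  Apparent (resubstitution) performance only: no
#' cross-validation is performed.
#'
#' @param scores,labels as [roc_curve()].
#' @param cutoff reporting cutoff (default 21).
#' @param conf_level CI level for the AUC.
#' @param method AUC CI method, see [auc()].
#' @return list mirroring the published performance-table fields.
#' @export
roc_report <- function(scores, labels, cutoff = 21, conf_level = 0.95,
                       method = "hanley-mcneil") {
  curve <- roc_curve(scores, labels)
  a <- auc(curve, conf_level = conf_level, method = method)
  y <- youden_cutoff(curve)
  m <- diagnostic_metrics(confusion_at(scores, labels, cutoff))
  cm <- confusion_at(scores, labels, cutoff)
  list(auc = a$auc, auc_ci_low = a$ci_low, auc_ci_high = a$ci_high,
       auc_p = a$p_value, auc_method = method,
       youden_cutoff = y$cutoff, cutoff = cutoff,
       tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
       sensitivity = round_half_up(m$sensitivity, 2),
       specificity = round_half_up(m$specificity, 2),
       ppv = round_half_up(m$ppv, 1), npv = round_half_up(m$npv, 1),
       note = "apparent (resubstitution) performance; no cross-validation")
}

#' Export ROC points as TSV
#'
#' @param curve a `roc_curve`.
#' @param path output file.
#' @export
write_roc_tsv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$specificity <- 1 - df$fpr
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a ROC staircase
#'
#' Base-graphics staircase with the chance diagonal and (optionally) the
#' annotated Youden threshold.
#'
#' @param curve a `roc_curve`.
#' @param annotate_youden mark the Youden-optimal point.
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(curve, annotate_youden = TRUE, ...) {
  graphics::plot(curve$fpr, curve$sensitivity, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  if (annotate_youden) {
    y <- youden_cutoff(curve)
    graphics::points(1 - y$specificity, y$sensitivity, pch = 19)
    graphics::text(1 - y$specificity, y$sensitivity,
                   labels = sprintf(">= %g", y$cutoff), pos = 4)
  }
  invisible(curve)
}
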