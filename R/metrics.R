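# Patch- and slide-level evaluation battery.

#' Top-k accuracy
#'
#' Fraction of rows whose true label is among the k largest scores; score
#' ties are broken by lower class index, so the result is deterministic.
#'
#' @param scores N x C score matrix with class columns (named or indexed).
#' @param labels true labels: column names or 1-based column indices.
#' @param k number of top classes considered.
#' @return fraction in [0, 1].
#' @export
topk_accuracy <- function(scores, labels, k = 1L) {
  stopifnot(is.matrix(scores), k >= 1L, k <= ncol(scores))
  if (length(labels) != nrow(scores)) stop("labels length must match score rows")
  yi <- if (is.character(labels)) match(labels, colnames(scores)) else as.integer(labels)
  if (anyNA(yi)) stop("label not among score columns")
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    topk <- order(-scores[i, ], seq_len(ncol(scores)))[seq_len(k)]
    yi[[i]] %in% topk
  }, logical(1L))
  mean(hits)
}

#' Support-weighted F1 score
#'
#' Mean of per-class F1 scores weighted by each class's share of the true
#' labels. Predicted classes absent from the truth contribute zero weight.
#'
#' @param preds predicted label vector.
#' @param labels true label vector (same length).
#' @return scalar in [0, 1].
#' @export
weighted_f1 <- function(preds, labels) {
  stopifnot(length(preds) == length(labels), length(labels) > 0L)
  classes <- unique(c(labels, preds))
  n <- length(labels)
  f1w <- 0
  for (cls in classes) {
    tp <- sum(preds == cls & labels == cls)
    fp <- sum(preds == cls & labels != cls)
    fn <- sum(preds != cls & labels == cls)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    f1w <- f1w + f1 * sum(labels == cls) / n
  }
  f1w
}

#' Hierarchical accuracy
#'
#' Mean partial credit over samples: 1.0 for exact leaf matches, 0.5 for a
#' shared level-2 parent, 0.25 for a shared level-1 root only, 0 otherwise.
#' Always at least the top-1 accuracy of the same predictions.
#'
#' @param preds,labels leaf id vectors.
#' @param tax a [dx_taxonomy()].
#' @return mean credit in [0, 1].
#' @export
hierarchical_accuracy <- function(preds, labels, tax) {
  mean(hierarchical_credit(preds, labels, tax))
}

#' Nonparametric percentile bootstrap confidence interval
#'
#' Resamples the per-sample inputs with replacement and returns the metric's
#' point estimate with percentile bounds. Seeded and reproducible.
#'
#' @param x per-sample inputs: a vector, or a matrix/data.frame resampled by
#'   rows.
#' @param metric_fn function of the (re)sampled inputs returning a scalar.
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `point`, `lo`, `hi`.
#' @export
bootstrap_ci <- function(x, metric_fn, reps = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(reps >= 1L)
  take <- function(obj, idx) {
    if (is.matrix(obj) || is.data.frame(obj)) obj[idx, , drop = FALSE] else obj[idx]
  }
  n <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
  point <- metric_fn(x)
  stat <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, replace = TRUE)
      val <- tryCatch(metric_fn(take(x, idx)), error = function(e) {
        stop("metric failed on bootstrap replicate ", r, ": ",
             conditionMessage(e))
      })
      as.numeric(val)
    }, numeric(1L))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(point = point, lo = qs[[1L]], hi = qs[[2L]])
}

#' Paired two-sided t-test on per-sample scores
#'
#' Classic paired Student's t-test on the per-sample differences.
#' Zero-variance differences are flagged as degenerate rather than returning
#' an infinite statistic.
#'
#' @param scores_a,scores_b equal-length (>= 2) per-sample score vectors.
#' @return list with `t` and two-sided `p`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    stop("degenerate paired t-test: zero-variance differences")
  }
  res <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value)
}

#' Majority-class baseline
#'
#' Constant predictor at the most frequent training class (ties broken by
#' first occurrence order), evaluated on the test labels with accuracy,
#' support-weighted F1 and, when a taxonomy is supplied, hierarchical
#' accuracy.
#'
#' @param labels_train training label vector (defines the majority class).
#' @param labels_test test label vector to evaluate on.
#' @param tax optional [dx_taxonomy()] for hierarchical accuracy.
#' @return list with `majority_class`, `accuracy`, `weighted_f1`, and
#'   optionally `hierarchical_accuracy`.
#' @export
majority_baseline <- function(labels_train, labels_test, tax = NULL) {
  stopifnot(length(labels_train) > 0L, length(labels_test) > 0L)
  tab <- table(factor(labels_train, levels = unique(labels_train)))
  maj <- names(tab)[[which.max(tab)]]
  preds <- rep(maj, length(labels_test))
  out <- list(majority_class = maj,
              accuracy = mean(preds == labels_test),
              weighted_f1 = weighted_f1(preds, labels_test))
  if (!is.null(tax)) {
    out$hierarchical_accuracy <- hierarchical_accuracy(preds, labels_test, tax)
  }
  out
}

#' ROC AUC from scores
#'
#' Rank-based area under the ROC curve (trapezoidal, via pROC).
#'
#' @param scores numeric score for the positive class.
#' @param labels label vector.
#' @param positive label value counted as positive (default "melanoma").
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "melanoma") {
  resp <- factor(labels == positive, levels = c(FALSE, TRUE))
  as.numeric(pROC::auc(pROC::roc(resp, scores, quiet = TRUE,
                                 levels = c("FALSE", "TRUE"),
                                 direction = "<")))
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: precision is evaluated at every positive in
#' descending score order and weighted by the recall increment.
#'
#' @inheritParams roc_auc
#' @return AUPRC in [0, 1].
#' @export
pr_auc <- function(scores, labels, positive = "melanoma") {
  y <- labels == positive
  stopifnot(any(y))
  ord <- order(-scores, seq_along(scores))  # ties broken by sample index
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y]) / sum(y)
}

#' Binary evaluation report with bootstrap confidence intervals
#'
#' The four-metric battery used at slide level: ROC AUC, accuracy, AUPRC and
#' weighted F1, each with a percentile bootstrap CI over samples (slides).
#'
#' @param scores positive-class scores.
#' @param labels true labels.
#' @param positive positive label value.
#' @param threshold score threshold for the hard prediction (default 0.5).
#' @param reps bootstrap replicates.
#' @param seed bootstrap seed.
#' @return data.frame with columns `metric`, `point`, `lo`, `hi`, and
#'   attribute `n` (number of samples).
#' @export
binary_eval_report <- function(scores, labels, positive = "melanoma",
                               threshold = 0.5, reps = 1000L, seed = 1L) {
  df <- data.frame(score = scores, label = labels, stringsAsFactors = FALSE)
  other <- setdiff(unique(labels), positive)[1] %||% paste0("not_", positive)
  preds_of <- function(dd) ifelse(dd$score >= threshold, positive, other)
  metrics <- list(
    roc_auc = function(dd) roc_auc(dd$score, dd$label, positive),
    accuracy = function(dd) mean(preds_of(dd) == dd$label),
    auprc = function(dd) pr_auc(dd$score, dd$label, positive),
    f1 = function(dd) weighted_f1(preds_of(dd), dd$label)
  )
  rows <- lapply(names(metrics), function(nm) {
    ci <- bootstrap_ci(df, metrics[[nm]], reps = reps, seed = seed)
    data.frame(metric = nm, point = ci[["point"]], lo = ci[["lo"]],
               hi = ci[["hi"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- nrow(df)
  out
}
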