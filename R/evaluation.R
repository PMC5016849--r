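#' Stratified subject-level fold assignment
#'
#' Randomly partitions subjects into k folds for cross-validation. By
#' default the split is stratified by class: within each class, fold sizes
#' differ by at most one, and classes' remainders are placed on the folds
#' with the fewest subjects so overall fold sizes are as even as possible.
#' A class with fewer than k members triggers a fall-back to unstratified
#' assignment with a warning.
#'
#' @param subject_labels Character vector of class labels named by subject
#'   id (names optional; positions are used otherwise).
#' @param k Number of folds (default 5; must be >= 2 so every fold has
#'   held-out data).
#' @param seed Integer seed; assignment is deterministic given the seed.
#' @param stratified Stratify by class (default TRUE).
#' @return Object of class `fold_assignment`: list with `k`, `fold`
#'   (integer vector in 1..k, named by subject), `seed`, `stratified`.
#' @export
make_folds <- function(subject_labels, k = 5L, seed = 1L,
                       stratified = TRUE) {
  n <- length(subject_labels)
  ids <- names(subject_labels) %||% as.character(seq_len(n))
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2: k = 1 leaves no held-out data")
  if (k > n) stop("more folds than subjects")
  if (stratified && any(table(subject_labels) < k)) {
    warning("a class has fewer than k members; falling back to unstratified folds")
    stratified <- FALSE
  }
  fold <- integer(n)
  with_seed(seed, {
    if (!stratified) {
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
    } else {
      totals <- integer(k)
      for (cls in names(sort(table(subject_labels), decreasing = TRUE))) {
        idx <- sample(which(subject_labels == cls))
        m <- length(idx)
        sizes <- rep(m %/% k, k)
        extras <- order(totals, seq_len(k))[seq_len(m %% k)]
        sizes[extras] <- sizes[extras] + 1L
        fold[idx] <- rep(seq_len(k), times = sizes)
        totals <- totals + sizes
      }
    }
  })
  names(fold) <- ids
  structure(list(k = k, fold = fold, seed = as.integer(seed),
                 stratified = stratified),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d subjects in %d folds (%sstratified), sizes: %s\n",
              length(x$fold), x$k, if (x$stratified) "" else "un",
              paste(tabulate(x$fold, x$k), collapse = " ")))
  invisible(x)
}

#' Confusion counts with PH as the positive class
#'
#' @param predicted,truth Character vectors of "PH" / "non-PH".
#' @return List of class `confusion_counts` with tp, tn, fp, fn.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  structure(list(tp = sum(predicted == "PH" & truth == "PH"),
                 tn = sum(predicted == "non-PH" & truth == "non-PH"),
                 fp = sum(predicted == "PH" & truth == "non-PH"),
                 fn = sum(predicted == "non-PH" & truth == "PH")),
            class = "confusion_counts")
}

#' Correct rate, false-negative rate and false-positive rate
#'
#' CR = (TP+TN)/(TP+TN+FP+FN), FNR = FN/(FN+TP), FPR = FP/(FP+TN). A rate
#' whose denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts A `confusion_counts` (or list with tp, tn, fp, fn).
#' @return Named list: correct_rate, fnr, fpr.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    total <- tp + tn + fp + fn
    if (total == 0) stop("empty confusion table")
    list(correct_rate = (tp + tn) / total,
         fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  })
}

#' ROC curve over the NLL-ratio test statistic
#'
#' Sweeps the decision threshold over the observed scores (plus -Inf and
#' +Inf endpoints): a subject is called PH when its score is below the
#' threshold, matching the orientation of the NLL ratio (PH-like subjects
#' score below 1). Equal scores are treated atomically, and the area under
#' the curve is computed by the trapezoidal rule.
#'
#' @param scores Numeric per-subject test statistic (e.g. `nll_ratio`);
#'   lower means more PH-like.
#' @param labels Character "PH" / "non-PH" truth labels.
#' @return Object of class `ph_roc`: list with `thresholds`, `tpr`, `fpr`
#'   (all aligned, from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- normalize_labels(labels)
  n_pos <- sum(labels == "PH"); n_neg <- sum(labels == "non-PH")
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both classes present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  # predicted PH when score < threshold: cumulative counts below each cutoff
  tpr <- vapply(thr, function(t) sum(scores < t & labels == "PH"), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores < t & labels == "non-PH"), 0) / n_neg
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "ph_roc")
}

#' @export
print.ph_roc <- function(x, ...) {
  cat(sprintf("<ph_roc> %d thresholds, AUC = %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.ph_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Subject-level k-fold cross-validation of the heart-sound classifier
#'
#' For each fold, both class mixtures are fit on the pooled frames of the
#' training-fold subjects only, and every held-out subject is scored by
#' its frame-averaged negative log-likelihood under each model. A
#' structural guard asserts that no test subject's frames enter the
#' training matrices. When mPAp values are supplied, a per-fold
#' train-versus-test balance check (Welch two-sample t-test on mPAp) is
#' recorded.
#'
#' Pooled (micro-averaged) confusion counts are the primary summary;
#' per-fold rates and their macro-average are also reported.
#'
#' @param features Named list of per-subject `mfcc_matrix` objects.
#' @param labels Character class labels, same order as `features`.
#' @param mpap Optional numeric mPAp (mmHg) per subject, for the balance
#'   check.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and model fits.
#' @param stratified Stratify folds by class (default TRUE).
#' @param ... Passed to [ph_classifier()] (n_components, covariance_mode,
#'   n_restarts, tol, ...).
#' @return Object of class `ph_cv`: list with `scores` (per-subject data
#'   frame), `counts` (pooled `confusion_counts`), `pooled` metrics,
#'   `per_fold` data frame (with balance p-values), `macro` metrics
#'   averaged over folds, `roc` (a [roc_curve()] on the NLL ratios), `auc`,
#'   `folds`.
#' @export
cross_validate <- function(features, labels, mpap = NULL, k = 5L,
                           seed = 1L, stratified = TRUE, ...) {
  stopifnot(length(features) == length(labels))
  labels <- normalize_labels(labels)
  ids <- names(features) %||%
    vapply(features, function(f) as.character(f$info$subject_id[1]), "")
  names(features) <- ids
  if (sum(labels == "PH") < 1 || sum(labels == "non-PH") < 1)
    stop("need both classes for cross-validation")
  names(labels) <- ids
  folds <- make_folds(labels, k = k, seed = seed, stratified = stratified)
  scores <- list(); per_fold <- list()
  for (f in seq_len(folds$k)) {
    test_ids <- ids[folds$fold == f]
    train_ids <- ids[folds$fold != f]
    if (!all(c("PH", "non-PH") %in% labels[train_ids]))
      stop(sprintf("training data for fold %d is missing a class", f))
    clf <- ph_classifier(features[train_ids], labels[train_ids],
                         seed = seed + 17L * f, ...)
    # leakage guard: no held-out subject's frames in the training pools
    train_subjects <- clf$training_subjects
    stopifnot(!any(test_ids %in% train_subjects))
    sc <- predict(clf, features[test_ids])
    sc$fold <- f
    sc$label <- unname(labels[test_ids])
    scores[[f]] <- sc
    m <- confusion_metrics(confusion_counts(sc$predicted, sc$label))
    balance_p <- NA_real_
    if (!is.null(mpap)) {
      mp <- stats::setNames(mpap, ids)
      balance_p <- stats::t.test(mp[train_ids], mp[test_ids])$p.value
    }
    per_fold[[f]] <- data.frame(fold = f, n = length(test_ids),
                                correct_rate = m$correct_rate,
                                fnr = m$fnr, fpr = m$fpr,
                                balance_p = balance_p)
  }
  scores <- do.call(rbind, scores)
  per_fold <- do.call(rbind, per_fold)
  counts <- confusion_counts(scores$predicted, scores$label)
  roc <- roc_curve(scores$nll_ratio, scores$label)
  structure(list(scores = scores, counts = counts,
                 pooled = confusion_metrics(counts),
                 per_fold = per_fold,
                 macro = list(correct_rate = mean(per_fold$correct_rate),
                              fnr = mean(per_fold$fnr, na.rm = TRUE),
                              fpr = mean(per_fold$fpr, na.rm = TRUE)),
                 roc = roc, auc = roc$auc, folds = folds, seed = seed),
            class = "ph_cv")
}

#' @export
print.ph_cv <- function(x, ...) {
  cat(sprintf("<ph_cv> %d-fold cross-validation, %d subjects\n",
              x$folds$k, nrow(x$scores)))
  cat(sprintf("  pooled: correct rate %.3f, FNR %.3f, FPR %.3f, AUC %.3f\n",
              x$pooled$correct_rate, x$pooled$fnr, x$pooled$fpr, x$auc))
  invisible(x)
}

#' @export
summary.ph_cv <- function(object, ...) {
  print(object)
  cat("  per fold:\n")
  print(object$per_fold, row.names = FALSE)
  by_cls <- tapply(object$scores$nll_ratio, object$scores$label, mean)
  cat(sprintf("  mean NLL ratio: PH %.3f, non-PH %.3f\n",
              by_cls["PH"], by_cls["non-PH"]))
  invisible(object)
}

#' @export
plot.ph_cv <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$roc)
  r <- x$scores$nll_ratio
  brk <- seq(min(r) - 1e-9, max(r) + 1e-9, length.out = 20)
  h1 <- graphics::hist(r[x$scores$label == "PH"], breaks = brk, plot = FALSE)
  h2 <- graphics::hist(r[x$scores$label == "non-PH"], breaks = brk,
                       plot = FALSE)
  graphics::plot(h1, col = grDevices::rgb(0, 0, 1, 0.4),
                 xlim = range(brk), ylim = c(0, max(h1$counts, h2$counts)),
                 main = "NLL ratio by class", xlab = "nll_ph / nll_nonph")
  graphics::plot(h2, col = grDevices::rgb(1, 0, 0, 0.4), add = TRUE)
  graphics::legend("topright", fill = grDevices::rgb(c(0, 1), 0, c(1, 0),
                                                     0.4),
                   legend = c("PH", "non-PH"), bty = "n")
  invisible(x)
}

#' Compare the algorithm's confusion metrics with human readers
#'
#' Computes correct rate, FNR and FPR for both confusion tables, their
#' differences (algorithm minus readers), and a chi-squared two-proportion
#' p-value per rate (this package's choice of test for comparing two
#' observed rates). A rate with a zero denominator on either side is
#' omitted with a warning.
#'
#' @param algorithm_counts,reader_counts `confusion_counts` objects.
#' @return Data frame: metric, algorithm, readers, difference, p_value.
#' @export
compare_readers <- function(algorithm_counts, reader_counts) {
  part <- function(cnt, metric) {
    with(cnt, switch(metric,
                     correct_rate = c(tp + tn, tp + tn + fp + fn),
                     fnr = c(fn, fn + tp),
                     fpr = c(fp, fp + tn)))
  }
  rows <- list()
  for (metric in c("correct_rate", "fnr", "fpr")) {
    a <- part(algorithm_counts, metric)
    r <- part(reader_counts, metric)
    if (a[2] == 0 || r[2] == 0) {
      warning("zero denominator for ", metric, "; comparison omitted")
      next
    }
    p <- if (a[1] / a[2] == r[1] / r[2]) 1 else
      suppressWarnings(stats::prop.test(c(a[1], r[1]), c(a[2], r[2]),
                                        correct = FALSE)$p.value)
    rows[[metric]] <- data.frame(metric = metric,
                                 algorithm = a[1] / a[2],
                                 readers = r[1] / r[2],
                                 difference = a[1] / a[2] - r[1] / r[2],
                                 p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
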