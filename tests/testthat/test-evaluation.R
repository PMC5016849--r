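test_that("stratified folds partition 86 + 78 subjects into sizes 33,33,33,33,32", {
  labels <- c(rep("PH", 86), rep("non-PH", 78))
  names(labels) <- sprintf("s%03d", seq_along(labels))
  fa <- make_folds(labels, k = 5, seed = 3)
  sizes <- tabulate(fa$fold, 5)
  expect_setequal(sizes, c(33, 33, 33, 33, 32))
  expect_equal(sum(sizes == 32), 1)
  # per-class sizes differ by at most one
  for (cls in c("PH", "non-PH")) {
    cs <- tabulate(fa$fold[labels == cls], 5)
    expect_lte(diff(range(cs)), 1)
  }
})

test_that("fold assignment is a disjoint cover for any seed, and k = 1 is refused", {
  labels <- rep(c("PH", "non-PH"), each = 10)
  for (s in 1:8) {
    fa <- make_folds(labels, k = 4, seed = s)
    expect_length(fa$fold, 20)
    expect_true(all(fa$fold %in% 1:4))
    expect_true(all(tabulate(fa$fold, 4) == 5))
  }
  expect_error(make_folds(labels, k = 1), "k = 1")
  expect_warning(make_folds(c(rep("PH", 2), rep("non-PH", 10)), k = 5,
                            seed = 1),
                 "unstratified")
})

test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(list(tp = 3, tn = 4, fp = 2, fn = 1))
  expect_equal(m$correct_rate, 0.70)
  expect_equal(m$fnr, 0.25)
  expect_equal(m$fpr, 1 / 3)

  perfect <- confusion_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(correct_rate = 1, fnr = 0, fpr = 0))

  nopos <- confusion_metrics(list(tp = 0, tn = 8, fp = 2, fn = 0))
  expect_true(is.na(nopos$fnr))
  expect_false(is.na(nopos$fpr))

  # CR identity
  cnt <- list(tp = 7, tn = 9, fp = 3, fn = 2)
  m2 <- confusion_metrics(cnt)
  expect_equal(m2$correct_rate, 1 - (cnt$fp + cnt$fn) / 21)
})

test_that("ROC endpoints, monotonicity and separability", {
  scores <- c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3)
  labels <- c(rep("PH", 3), rep("non-PH", 3))
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$tpr[1], 0); expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[length(roc$tpr)], 1)
  expect_equal(roc$fpr[length(roc$fpr)], 1)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_error(roc_curve(scores, rep("PH", 6)), "both classes")
})

test_that("AUC equals brute-force Mann-Whitney pair counting, and is monotone-invariant", {
  set.seed(51)
  scores <- round(rnorm(50), 1)          # rounding forces ties
  labels <- sample(c("PH", "non-PH"), 50, replace = TRUE,
                   prob = c(0.4, 0.6))
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, oracle_auc_pairs(scores, labels), tolerance = 1e-12)

  for (f in list(function(s) 3 * s - 2, exp, function(s) s^3)) {
    expect_equal(roc_curve(f(scores), labels)$auc, roc$auc,
                 tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(52)
  aucs <- replicate(10, {
    scores <- rnorm(200)
    labels <- rep(c("PH", "non-PH"), each = 100)
    roc_curve(scores, labels)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.1))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  scores <- rnorm(60)
  labels <- sample(rep(c("PH", "non-PH"), each = 30))
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("PH", "non-PH"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-10)
})

test_that("cross-validation scores every subject once, without leakage", {
  sc <- small_cohort()
  cv <- cross_validate(sc$features, sc$labels, mpap = sc$mpap, k = 3,
                       seed = 5, n_components = 2, n_restarts = 1)
  expect_equal(nrow(cv$scores), 12)
  expect_equal(sort(cv$scores$subject_id),
               sort(names(sc$features)))
  expect_equal(anyDuplicated(cv$scores$subject_id), 0)
  # scored subjects are exactly the held-out fold members
  for (f in 1:3) {
    held <- names(cv$folds$fold)[cv$folds$fold == f]
    expect_setequal(cv$scores$subject_id[cv$scores$fold == f], held)
  }
  # balance check recorded per fold
  expect_true(all(is.finite(cv$per_fold$balance_p)))
  expect_true(all(cv$per_fold$balance_p >= 0 & cv$per_fold$balance_p <= 1))
  # pooled counts match the per-subject table
  expect_equal(cv$counts$tp + cv$counts$tn + cv$counts$fp + cv$counts$fn,
               12)
})

test_that("a training fold missing one class is reported", {
  sc <- small_cohort()
  # 2 PH + 6 non-PH with k = 2 unstratified can orphan a class; force it
  feats <- sc$features[c(1, 7:12)]
  labels <- sc$labels[c(1, 7:12)]
  expect_error(
    suppressWarnings(cross_validate(feats, labels, k = 2, seed = 1,
                                    stratified = FALSE, n_components = 1,
                                    n_restarts = 1)),
    "missing a class|fewer components|missing")
})

test_that("reader comparison reproduces printed-rate arithmetic and an exact oracle", {
  a <- confusion_counts(rep(c("PH", "non-PH"), c(10, 10)),
                        rep(c("PH", "non-PH"), c(10, 10)))
  same <- compare_readers(a, a)
  expect_true(all(same$difference == 0))
  expect_true(all(same$p_value == 1))

  alg <- list(tp = 37, tn = 37, fp = 13, fn = 13)   # 74/100 correct
  rdr <- list(tp = 28, tn = 28, fp = 22, fn = 22)   # 56/100 correct
  cmp <- compare_readers(alg, rdr)
  cr <- cmp[cmp$metric == "correct_rate", ]
  expect_equal(cr$difference, 0.18, tolerance = 1e-12)
  expect_equal(cr$algorithm, 0.74)

  # exact enumeration oracle on small counts
  # cases keep expected counts in the chi-squared approximation's comfort
  # zone so the asymptotic and exact-enumeration p-values agree closely
  for (case in list(c(18, 25, 10, 25), c(12, 14, 6, 13), c(8, 12, 8, 12),
                    c(9, 14, 14, 14))) {
    small_a <- list(tp = case[1], tn = 0, fp = 0, fn = case[2] - case[1])
    small_r <- list(tp = case[3], tn = 0, fp = 0, fn = case[4] - case[3])
    got <- suppressWarnings(compare_readers(small_a, small_r))
    fnr_p <- got$p_value[got$metric == "fnr"]
    want <- oracle_two_prop_p(case[2] - case[1], case[2],
                              case[4] - case[3], case[4])
    expect_lt(abs(fnr_p - want), 0.02)
  }
})
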