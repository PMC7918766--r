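# AdaBoost / SVM classifiers, balancing, metrics, and cross-validation.

test_that("adaboost separates well-separated blobs perfectly", {
  toy <- make_blobs(n = 200, sep = 6, seed = 1)
  model <- train_adaboost(toy$x, toy$y, classifier_spec(n_learners = 20))
  expect_equal(mean(predict(model, toy$x) == toy$y), 1.0)
})

test_that("a one-learner ensemble reduces to a single tree", {
  toy <- make_blobs(n = 120, sep = 3, seed = 2)
  one <- train_adaboost(toy$x, toy$y, classifier_spec(n_learners = 1))
  expect_length(one$trees, 1)
  tree_pred <- predict(one$trees[[1]],
                       data.frame(as.matrix(toy$x), check.names = TRUE),
                       type = "class")
  expect_equal(as.character(predict(one, toy$x)), as.character(tree_pred))
})

test_that("adaboost handles three classes and rejects one", {
  xy <- withr::with_seed(3, {
    x <- rbind(matrix(rnorm(100), ncol = 2),
               matrix(rnorm(100, 5), ncol = 2),
               matrix(rnorm(100, c(0, 5)), ncol = 2))
    list(x = x, y = factor(rep(c("a", "b", "c"), each = 50)))
  })
  model <- train_adaboost(xy$x, xy$y, classifier_spec(n_learners = 30))
  expect_gt(mean(predict(model, xy$x) == xy$y), 0.95)
  expect_error(train_adaboost(xy$x, rep("a", 150)), "single class")
})

test_that("the RBF SVM solves XOR and enforces the binary contract", {
  xor <- withr::with_seed(4, {
    x <- matrix(runif(400, -1, 1), ncol = 2)
    # keep a clear margin around the axes so the pattern is learnable
    x <- x[abs(x[, 1]) > 0.15 & abs(x[, 2]) > 0.15, ]
    y <- factor(ifelse(x[, 1] * x[, 2] > 0, "p", "n"))
    list(x = x, y = y)
  })
  model <- train_svm(xor$x, xor$y, classifier_spec("svm"))
  expect_gt(mean(predict(model, xor$x) == xor$y), 0.95)

  # duplicating every observation leaves the decision function unchanged
  dup <- train_svm(rbind(xor$x, xor$x), factor(c(as.character(xor$y),
                                                 as.character(xor$y))),
                   classifier_spec("svm", kernel_scale = model$kernel_scale))
  grid <- as.matrix(expand.grid(seq(-0.9, 0.9, 0.2), seq(-0.9, 0.9, 0.2)))
  colnames(grid) <- NULL
  expect_gt(mean(predict(dup, grid) == predict(model, grid)), 0.95)

  y3 <- factor(rep(c("a", "b", "c"), length.out = nrow(xor$x)))
  expect_error(train_svm(xor$x, y3), "2 classes")
})

test_that("balancing undersamples to the minority count deterministically", {
  labels <- factor(rep(c("no_pain", "moderate_pain", "severe_pain"),
                       times = c(100, 40, 60)))
  idx <- balance_classes(labels, seed = 7)
  expect_true(all(table(labels[idx]) == 40))
  expect_length(idx, 120)
  expect_identical(idx, balance_classes(labels, seed = 7))
  expect_false(identical(idx, balance_classes(labels, seed = 8)))

  balanced <- factor(rep(c("a", "b"), each = 30))
  expect_length(balance_classes(balanced), 60)

  expect_error(balance_classes(labels, classes = c("no_pain", "absent")),
               "absent")
})

test_that("metrics match hand-computed confusion arithmetic", {
  # TP=8, FN=2, FP=1, TN=9
  y_true <- c(rep("p", 10), rep("n", 10))
  y_pred <- c(rep("p", 8), rep("n", 2), "p", rep("n", 9))
  m <- compute_metrics(y_true, y_pred, "p")
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 8 / 9, tolerance = 1e-9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-9)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)
  expect_length(m$undefined, 0)

  perfect <- compute_metrics(y_true, y_true, "p")
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "precision",
                                   "specificity", "f1")]) == 1))

  allneg <- compute_metrics(y_true, rep("n", 20), "p")
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true("precision" %in% allneg$undefined)

  expect_error(compute_metrics(y_true, y_pred[1:5], "p"), "equal length")
})

# Small synthetic frame-level dataset for CV bookkeeping tests: features
# carry the class signal so results are far from chance.
make_cv_data <- function(n_subj = 5, per_class = 30, seed = 10) {
  withr::with_seed(seed, {
    classes <- c("no_pain", "moderate_pain", "severe_pain")
    rows <- lapply(seq_len(n_subj), function(s) {
      lab <- rep(classes, each = per_class)
      x <- cbind(rnorm(length(lab), 3 * match(lab, classes)),
                 rnorm(length(lab), -3 * match(lab, classes)))
      list(x = x, lab = lab, subj = rep(sprintf("S%02d", s), length(lab)))
    })
    list(
      x = do.call(rbind, lapply(rows, `[[`, "x")),
      labels = factor(unlist(lapply(rows, `[[`, "lab")), levels = classes),
      subjects = unlist(lapply(rows, `[[`, "subj"))
    )
  })
}

test_that("10-fold CV aggregates runs x folds with balanced training sets", {
  d <- make_cv_data()
  res <- run_cv(d$x, d$labels, d$subjects, task = "multiclass",
                scheme = "kfold10", runs = 2, seed = 3,
                classifier = classifier_spec(n_learners = 10))
  expect_s3_class(res, "cv_result")
  expect_equal(unique(res$n_evals), 20)      # 2 runs x 10 folds
  expect_setequal(unique(res$class),
                  c("no_pain", "moderate_pain", "severe_pain"))
  expect_setequal(unique(res$metric),
                  c("accuracy", "sensitivity", "precision", "specificity",
                    "f1"))
  expect_true(all(res$mean >= 0 & res$mean <= 1))
  expect_true(all(res$sd >= 0))
  # separable data: every class recovered well
  expect_gt(macro_f1(res), 0.9)

  # identical seed reproduces identical results
  res2 <- run_cv(d$x, d$labels, d$subjects, task = "multiclass",
                 scheme = "kfold10", runs = 2, seed = 3,
                 classifier = classifier_spec(n_learners = 10))
  expect_equal(res$mean, res2$mean)
})

test_that("binary tasks restrict classes and use the first as positive", {
  d <- make_cv_data()
  res <- run_cv(d$x, d$labels, d$subjects, task = "sev_vs_no",
                scheme = "kfold10", runs = 1, seed = 4,
                classifier = classifier_spec(n_learners = 10))
  expect_equal(unique(res$class), "severe_pain")
  expect_gt(res$mean[res$metric == "f1"], 0.9)
})

test_that("one-patient-out never leaks the test subject into training", {
  d <- make_cv_data(n_subj = 4, per_class = 20)
  res <- run_cv(d$x, d$labels, d$subjects, task = "multiclass",
                scheme = "one_patient_out", runs = 1, seed = 5,
                classifier = classifier_spec(n_learners = 10))
  expect_equal(unique(res$n_evals), 4)       # one evaluation per subject
  expect_gt(macro_f1(res), 0.85)
  # the leakage guard is a hard assertion inside run_cv; additionally,
  # a subject lacking a class is skipped with a warning
  d2 <- d
  drop <- d2$subjects == "S01" & d2$labels == "severe_pain"
  d2$x <- d2$x[!drop, , drop = FALSE]
  d2$labels <- d2$labels[!drop]
  d2$subjects <- d2$subjects[!drop]
  expect_warning(
    res2 <- run_cv(d2$x, d2$labels, d2$subjects, task = "multiclass",
                   scheme = "one_patient_out", runs = 1, seed = 5,
                   classifier = classifier_spec(n_learners = 10)),
    "S01"
  )
  expect_equal(unique(res2$n_evals), 3)
})
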