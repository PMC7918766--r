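# Classifiers and evaluation: AdaBoost over depth-limited decision trees
# (SAMME multiclass extension), Gaussian-kernel SVM, random undersampling
# for class balance, confusion-matrix metrics, and the two cross-validation
# protocols (balanced 10-fold and one-patient-out) repeated over runs.

#' Classifier specification
#'
#' @param kind `"adaboost"` or `"svm"`.
#' @param n_learners Number of boosted trees (default 100).
#' @param max_branch_nodes Maximum number of split (branch) nodes per tree
#'   (default 20).
#' @param learning_rate Shrinkage of the boosting weight updates
#'   (default 1).
#' @param box_constraint SVM soft-margin cost C (default 1).
#' @param kernel_scale Gaussian kernel length scale; `NULL` (default) uses
#'   the median pairwise distance heuristic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("adaboost", "svm"),
                            n_learners = 100, max_branch_nodes = 20,
                            learning_rate = 1,
                            box_constraint = 1, kernel_scale = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_count(n_learners), is_count(max_branch_nodes),
            learning_rate > 0, box_constraint > 0)
  structure(
    list(kind = kind, n_learners = n_learners,
         max_branch_nodes = max_branch_nodes,
         learning_rate = learning_rate,
         box_constraint = box_constraint, kernel_scale = kernel_scale),
    class = "classifier_spec"
  )
}

# Fit one weight-limited tree: grow with cp = 0 then prune back to at most
# max_branch_nodes splits using the complexity table.
fit_weak_tree <- function(data, weights, max_branch_nodes) {
  fit <- rpart::rpart(
    y ~ ., data = data, weights = weights, method = "class",
    control = rpart::rpart.control(cp = 0, minsplit = 4, minbucket = 2,
                                   maxdepth = 10, xval = 0,
                                   maxcompete = 0, maxsurrogate = 0)
  )
  cpt <- fit$cptable
  if (!is.null(cpt) && max(cpt[, "nsplit"]) > max_branch_nodes) {
    ok <- cpt[cpt[, "nsplit"] <= max_branch_nodes, , drop = FALSE]
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"] * 0.9999)
  }
  fit
}

#' Train an AdaBoost ensemble of decision trees
#'
#' Binary problems use the classical AdaBoost.M1 weight update; problems
#' with more than two classes use the SAMME multiclass extension of the
#' exponential loss (learner weight `log((1 - err) / err) + log(K - 1)`).
#' Weak learners are classification trees pruned to at most
#' `max_branch_nodes` split nodes. Prediction is the weighted vote.
#'
#' @param features Numeric matrix (observations x features).
#' @param labels Factor (or coercible) of class labels; at least two
#'   classes must be present.
#' @param spec A [classifier_spec()] with `kind = "adaboost"`.
#' @param seed Integer seed (tree fitting is deterministic; the seed fixes
#'   any tie-breaking randomness).
#' @return An object of class `adaboost_model`.
#' @export
train_adaboost <- function(features, labels, spec = classifier_spec(),
                           seed = 1) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  K <- nlevels(labels)
  if (K < 2) stop("training data contains a single class")
  stopifnot(nrow(features) == length(labels))
  n <- nrow(features)
  df <- data.frame(y = labels, features, check.names = TRUE)

  with_seed(seed, {
    w <- rep(1 / n, n)
    trees <- list()
    alphas <- numeric(0)
    for (m in seq_len(spec$n_learners)) {
      tree <- fit_weak_tree(df, w * n, spec$max_branch_nodes)
      pred <- predict(tree, df, type = "class")
      miss <- pred != labels
      err <- sum(w * miss)
      if (err <= 1e-12) {           # perfect learner: keep it, stop boosting
        trees[[length(trees) + 1]] <- tree
        alphas <- c(alphas, spec$learning_rate * 20)
        break
      }
      if (err >= 1 - 1 / K) break   # no better than chance: stop
      alpha <- spec$learning_rate * (log((1 - err) / err) + log(K - 1))
      trees[[length(trees) + 1]] <- tree
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
    if (!length(trees)) {           # fall back to a single unweighted tree
      trees <- list(fit_weak_tree(df, rep(1, n), spec$max_branch_nodes))
      alphas <- 1
    }
    structure(
      list(trees = trees, alphas = alphas, levels = levels(labels),
           feature_names = colnames(df)[-1], spec = spec),
      class = "adaboost_model"
    )
  })
}

#' @export
predict.adaboost_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  df <- data.frame(newdata, check.names = TRUE)
  colnames(df) <- object$feature_names
  votes <- matrix(0, nrow(df), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$trees)) {
    p <- as.character(predict(object$trees[[m]], df, type = "class"))
    for (k in object$levels) {
      votes[, k] <- votes[, k] + object$alphas[m] * (p == k)
    }
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.adaboost_model <- function(x, ...) {
  cat(sprintf("<adaboost_model: %d trees, classes %s>\n",
              length(x$trees), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Train a Gaussian-kernel support vector machine
#'
#' Soft-margin binary SVM with an RBF kernel
#' `exp(-||u - v||^2 / (2 * scale^2))`; the kernel scale defaults to the
#' median pairwise Euclidean distance of the training set. Problems with
#' more than two classes are rejected.
#'
#' @inheritParams train_adaboost
#' @param spec A [classifier_spec()] with `kind = "svm"`.
#' @return An object of class `svm_model`.
#' @export
train_svm <- function(features, labels, spec = classifier_spec("svm")) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("the SVM supports exactly 2 classes; got ", nlevels(labels))
  stopifnot(nrow(features) == length(labels))
  scale <- spec$kernel_scale %||% median_pairwise_distance(features)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  fit <- e1071::svm(features, labels, type = "C-classification",
                    kernel = "radial", cost = spec$box_constraint,
                    gamma = 1 / (2 * scale^2), scale = FALSE)
  structure(list(fit = fit, kernel_scale = scale, levels = levels(labels)),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  predict(object$fit, as.matrix(newdata))
}

# Median pairwise distance over at most 500 deterministically thinned rows.
median_pairwise_distance <- function(x) {
  n <- nrow(x)
  if (n > 500) x <- x[round(seq(1, n, length.out = 500)), , drop = FALSE]
  median(stats::dist(x))
}

#' Balance classes by random undersampling
#'
#' Draws, without replacement, `min(class counts)` observations from every
#' class; deterministic for a fixed seed.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param classes Classes the task requires; an absent class is an error.
#'   Defaults to the observed classes.
#' @param seed Integer seed.
#' @return Integer vector of retained row indices (sorted).
#' @export
balance_classes <- function(labels, classes = NULL, seed = 1) {
  labels <- as.factor(labels)
  classes <- classes %||% levels(droplevels(labels))
  counts <- vapply(classes, function(k) sum(labels == k), numeric(1))
  if (any(counts == 0))
    stop("class absent from data: ",
         paste(classes[counts == 0], collapse = ", "))
  m <- min(counts)
  with_seed(seed, {
    idx <- unlist(lapply(classes, function(k) {
      i <- which(labels == k)
      if (length(i) == m) i else sort(sample(i, m))
    }))
    sort(idx)
  })
}

#' Confusion-matrix metrics for one positive class
#'
#' `accuracy = (TP + TN) / N`, `sensitivity = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`, `specificity = TN / (TN + FP)`,
#' `F1 = 2 * precision * sensitivity / (precision + sensitivity)`.
#' A ratio with zero denominator is reported as 0 and flagged.
#'
#' @param y_true,y_pred Equal-length vectors of class labels.
#' @param positive_class The class treated as positive (one-vs-rest).
#' @return An object of class `prr_metrics`: list of the five metrics plus
#'   `undefined`, the names of zero-denominator metrics.
#' @export
compute_metrics <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  prec <- safe(tp, tp + fp, "precision")
  spec <- safe(tn, tn + fp, "specificity")
  acc <- (tp + tn) / length(y_true)
  f1 <- if (prec + sens == 0) {
    undefined <- c(undefined, "f1"); 0
  } else 2 * prec * sens / (prec + sens)
  structure(
    list(accuracy = acc, sensitivity = sens, precision = prec,
         specificity = spec, f1 = f1, undefined = undefined,
         confusion = c(TP = tp, FN = fn, FP = fp, TN = tn)),
    class = "prr_metrics"
  )
}

METRIC_NAMES <- c("accuracy", "sensitivity", "precision", "specificity", "f1")

# Task definitions: classes involved and, for binary tasks, the positive
# class.
cv_task_classes <- function(task) {
  switch(task,
    sev_vs_no  = c("severe_pain", "no_pain"),
    sev_vs_mod = c("severe_pain", "moderate_pain"),
    mod_vs_no  = c("moderate_pain", "no_pain"),
    multiclass = PAIN_CLASSES,
    stop("unknown task: ", task)
  )
}

#' Cross-validated evaluation of a pain-reaction classifier
#'
#' Runs one of the four experiments: three binary tasks
#' (`sev_vs_no`, `sev_vs_mod`, `mod_vs_no`) or the three-class
#' `multiclass` task, under either scheme:
#' \describe{
#'   \item{`kfold10`}{frames pooled over subjects, undersampled to class
#'     balance, then split into 10 class-stratified folds;}
#'   \item{`one_patient_out`}{every subject in turn is the test set
#'     (balanced within itself), the remaining subjects form the balanced
#'     training set; a subject missing a task class is skipped with a
#'     warning.}
#' }
#' The whole procedure is repeated `runs` times with freshly drawn
#' balanced subsets; metrics are computed per class (one-vs-rest for the
#' multiclass task, positive class first for binary tasks) and aggregated
#' as mean and standard deviation over all fold-times-run evaluations,
#' with the between-run sd of run means reported alongside.
#'
#' @param features Numeric matrix (frames x features), typically
#'   z-scored per subject.
#' @param labels Factor of frame classes (levels among
#'   `no_pain`, `moderate_pain`, `severe_pain`).
#' @param subjects Character/factor vector of subject ids per frame.
#' @param task One of `"sev_vs_no"`, `"sev_vs_mod"`, `"mod_vs_no"`,
#'   `"multiclass"`.
#' @param scheme `"kfold10"` or `"one_patient_out"`.
#' @param classifier A [classifier_spec()].
#' @param runs Number of repetitions (default 10).
#' @param k Number of folds for `kfold10` (default 10).
#' @param seed Integer seed governing balancing and fold assignment.
#' @return An object of class `cv_result`: a data frame with columns
#'   `task`, `scheme`, `classifier`, `class`, `metric`, `mean`, `sd`,
#'   `sd_between_runs`, `n_evals`, with the per-evaluation values in
#'   attribute `"evaluations"`.
#' @export
run_cv <- function(features, labels, subjects,
                   task = c("multiclass", "sev_vs_no", "sev_vs_mod",
                            "mod_vs_no"),
                   scheme = c("kfold10", "one_patient_out"),
                   classifier = classifier_spec(), runs = 10, k = 10,
                   seed = 1) {
  task <- match.arg(task)
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = PAIN_CLASSES)
  subjects <- as.character(subjects)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(subjects))
  cls <- cv_task_classes(task)
  keep <- labels %in% cls
  features <- features[keep, , drop = FALSE]
  labels <- factor(as.character(labels[keep]), levels = cls)
  subjects <- subjects[keep]
  if (scheme == "one_patient_out" && length(unique(subjects)) < 2)
    stop("one_patient_out requires at least 2 subjects")
  metric_classes <- if (task == "multiclass") cls else cls[1]

  evals <- list()
  for (run in seq_len(runs)) {
    run_seed <- child_seed(seed, run)
    if (scheme == "kfold10") {
      bal <- balance_classes(labels, classes = cls, seed = run_seed)
      fx <- features[bal, , drop = FALSE]
      fy <- droplevels(labels[bal])
      folds <- with_seed(child_seed(run_seed, 1), {
        f <- integer(length(fy))
        for (kk in levels(fy)) {
          i <- which(fy == kk)
          f[i] <- sample(rep_len(seq_len(k), length(i)))
        }
        f
      })
      for (fold in seq_len(k)) {
        test <- folds == fold
        if (!all(cls %in% fy[!test]) || !any(test)) next
        model <- fit_classifier(fx[!test, , drop = FALSE], fy[!test],
                                classifier, child_seed(run_seed, 100 + fold))
        pred <- predict(model, fx[test, , drop = FALSE])
        evals[[length(evals) + 1]] <-
          eval_metrics(fy[test], pred, metric_classes, run, fold)
      }
    } else {
      subj_ids <- sort(unique(subjects))
      for (si in seq_along(subj_ids)) {
        s <- subj_ids[si]
        test_idx <- which(subjects == s)
        if (!all(cls %in% labels[test_idx])) {
          warning("subject ", s, " lacks a class required by task ", task,
                  "; skipped", call. = FALSE)
          next
        }
        train_idx <- which(subjects != s)
        bal_tr <- train_idx[balance_classes(labels[train_idx], classes = cls,
                                            seed = child_seed(run_seed, si))]
        bal_te <- test_idx[balance_classes(labels[test_idx], classes = cls,
                                           seed = child_seed(run_seed, 1000 + si))]
        stopifnot(!any(bal_tr %in% test_idx))   # no subject leakage
        model <- fit_classifier(features[bal_tr, , drop = FALSE],
                                droplevels(labels[bal_tr]), classifier,
                                child_seed(run_seed, 2000 + si))
        pred <- predict(model, features[bal_te, , drop = FALSE])
        evals[[length(evals) + 1]] <-
          eval_metrics(labels[bal_te], pred, metric_classes, run, si)
      }
    }
  }
  if (!length(evals)) stop("no evaluation could be performed")
  ev <- do.call(rbind, evals)

  agg <- do.call(rbind, lapply(metric_classes, function(kk) {
    do.call(rbind, lapply(METRIC_NAMES, function(mm) {
      v <- ev$value[ev$class == kk & ev$metric == mm]
      run_means <- tapply(v, ev$run[ev$class == kk & ev$metric == mm], mean)
      data.frame(task = task, scheme = scheme, classifier = classifier$kind,
                 class = kk, metric = mm,
                 mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                 sd_between_runs = if (length(run_means) > 1) sd(run_means) else 0,
                 n_evals = length(v))
    }))
  }))
  rownames(agg) <- NULL
  attr(agg, "evaluations") <- ev
  class(agg) <- c("cv_result", "data.frame")
  agg
}

fit_classifier <- function(features, labels, spec, seed) {
  if (spec$kind == "adaboost") train_adaboost(features, labels, spec, seed)
  else train_svm(features, labels, spec)
}

eval_metrics <- function(y_true, y_pred, metric_classes, run, fold) {
  do.call(rbind, lapply(metric_classes, function(kk) {
    m <- compute_metrics(as.character(y_true), as.character(y_pred), kk)
    data.frame(run = run, fold = fold, class = kk,
               metric = METRIC_NAMES,
               value = unlist(m[METRIC_NAMES], use.names = FALSE))
  }))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s / %s / %s; %d evaluations>\n",
              x$task[1], x$scheme[1], x$classifier[1], x$n_evals[1]))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Macro-averaged F1 score of a multiclass cv_result
#'
#' @param result A [run_cv()] result.
#' @return Mean of the per-class F1 means.
#' @export
macro_f1 <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  mean(result$mean[result$metric == "f1"])
}
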