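# Evaluation protocol for signature datasets: stratified 70/30 split,
# seven classifier families with the protocol's published hyperparameters,
# replicate-averaged metrics.

#' Construct a labeled signature dataset
#'
#' @param ids Character vector of peptide ids (no duplicates).
#' @param values Numeric matrix, one row per peptide, shared feature schema
#'   as column names.
#' @param labels Class labels (coerced to factor).
#' @return A `labeled_dataset` list (`ids`, `x`, `y`).
#' @export
labeled_dataset <- function(ids, values, labels) {
  stopifnot(length(ids) == nrow(values), length(labels) == nrow(values))
  if (anyDuplicated(ids)) stop("duplicate peptide ids")
  x <- as.matrix(values)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(ids = as.character(ids), x = x, y = factor(labels)),
            class = "labeled_dataset")
}

#' Attach labels from a table to a signature dataset
#'
#' @param signatures List with `ids` and `values` (as returned by
#'   [read_signature_csv()]).
#' @param labels Data.frame with columns `peptide_id` and `class`, or the
#'   path of a tab-separated file with those columns.
#' @return A `labeled_dataset` restricted to ids present in both inputs.
#' @export
label_signatures <- function(signatures, labels) {
  if (is.character(labels)) {
    labels <- utils::read.delim(labels, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("peptide_id", "class") %in% names(labels)))
  idx <- match(signatures$ids, labels$peptide_id)
  keep <- !is.na(idx)
  labeled_dataset(signatures$ids[keep],
                  signatures$values[keep, , drop = FALSE],
                  labels$class[idx[keep]])
}

#' Stratified train/test split
#'
#' Samples `round(train_fraction * n_k)` training rows within each class
#' stratum. Classes with fewer than two members are kept whole in the
#' training set with a warning.
#'
#' @param d A `labeled_dataset`.
#' @param train_fraction Training share (default 0.70).
#' @param seed Integer seed; a fixed seed reproduces the partition.
#' @return List with `train` and `test` `labeled_dataset`s (disjoint,
#'   union = input).
#' @export
split_dataset <- function(d, train_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(d, "labeled_dataset"), train_fraction > 0, train_fraction < 1)
  n <- length(d$ids)
  if (!n) stop("empty dataset")
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in levels(d$y)) {
      rows <- which(d$y == cl)
      if (length(rows) < 2L) {
        warning(sprintf("class '%s' has <2 members: kept whole in training set", cl))
        train_idx <- c(train_idx, rows)
      } else {
        k <- round(train_fraction * length(rows))
        k <- min(max(k, 1L), length(rows) - 1L)
        train_idx <- c(train_idx, sample(rows, k))
      }
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_ld <- function(i) {
    structure(list(ids = d$ids[i], x = d$x[i, , drop = FALSE],
                   y = factor(d$y[i], levels = levels(d$y))),
              class = "labeled_dataset")
  }
  list(train = subset_ld(train_idx), test = subset_ld(test_idx))
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class universe (default: levels of `truth`); labels
#'   outside it are an error.
#' @return Integer matrix with class dimnames; total count equals the
#'   input length.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- levels(factor(truth))
  outside <- setdiff(unique(c(as.character(truth), as.character(predicted))), classes)
  if (length(outside)) {
    stop("label(s) outside the class universe: ", paste(outside, collapse = ", "))
  }
  tab <- table(factor(truth, levels = classes), factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

# Macro-averaged metrics from a confusion matrix; empty classes are
# excluded from macro means, absent precision denominators count as 0.
cm_metrics <- function(cm) {
  present <- rowSums(cm) > 0
  recall <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
  precision <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  list(
    ca = sum(diag(cm)) / sum(cm),
    precision = mean(precision[present]),
    recall = mean(recall[present]),
    f1 = mean(f1[present]),
    per_class_accuracy = 100 * recall
  )
}

# Macro one-vs-rest AUC from a class-probability matrix.
macro_auc <- function(truth, prob) {
  classes <- colnames(prob)
  aucs <- vapply(classes, function(cl) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# ---- model families -------------------------------------------------------

# Distance-weighted k-nearest-neighbour classifier with Manhattan metric
# (the protocol's kNN settings: k = 3, metric Manhattan, weight Distance).
# Implemented here: no installed package offers this combination.
knn_manhattan_predict <- function(train_x, train_y, test_x, k = 3L) {
  classes <- levels(train_y)
  prob <- matrix(0, nrow(test_x), length(classes), dimnames = list(NULL, classes))
  tx <- t(train_x)
  for (i in seq_len(nrow(test_x))) {
    dist_i <- colSums(abs(tx - test_x[i, ]))
    nn <- order(dist_i)[seq_len(min(k, length(dist_i)))]
    dn <- dist_i[nn]
    if (any(dn == 0)) {
      w <- as.numeric(dn == 0)
    } else {
      w <- 1 / dn
    }
    for (j in seq_along(nn)) {
      prob[i, as.character(train_y[nn[j]])] <-
        prob[i, as.character(train_y[nn[j]])] + w[j]
    }
    prob[i, ] <- prob[i, ] / sum(prob[i, ])
  }
  list(class = factor(classes[max.col(prob, ties.method = "first")],
                      levels = classes),
       prob = prob)
}

#' Default model roster
#'
#' The seven classifier families of the evaluation protocol with its
#' published hyperparameters as defaults: kNN (k = 3, Manhattan,
#' distance-weighted), linear SVM (C = 1, tolerance 0.001), neural network
#' (one hidden layer, 300 neurons, L2 alpha 0.001, 200 iterations),
#' gradient boosting (100 trees, learning rate 0.1, depth 3), ridge
#' logistic regression (C = 1), decision tree (min leaf 2, min split 5)
#' and random forest (10 trees, min node 5). Each spec is a list with a
#' `fit(x, y, seed)` closure returning a `predict(fit, x)` input; `fit`
#' output is passed to `predict` which returns `list(class, prob)`.
#'
#' @param models Subset of
#'   `c("knn", "svm", "neural_network", "gradient_boosting",
#'   "logistic_regression", "decision_tree", "random_forest")`.
#' @param nn_hidden Hidden-layer size for the neural network (default 300;
#'   reduce for very high-dimensional inputs).
#' @return Named list of model specs.
#' @export
default_model_specs <- function(models = c("knn", "svm", "neural_network",
                                           "gradient_boosting",
                                           "logistic_regression",
                                           "decision_tree", "random_forest"),
                                nn_hidden = 300L) {
  all_specs <- list(
    knn = list(
      fit = function(x, y, seed) list(x = x, y = y),
      predict = function(fit, x) knn_manhattan_predict(fit$x, fit$y, x, k = 3L)
    ),
    svm = list(
      fit = function(x, y, seed) {
        with_seed(seed, e1071::svm(x, y, kernel = "linear", cost = 1,
                                   tolerance = 0.001, probability = TRUE,
                                   scale = FALSE))
      },
      predict = function(fit, x) {
        pr <- stats::predict(fit, x, probability = TRUE)
        prob <- attr(pr, "probabilities")
        list(class = pr, prob = prob[, levels(pr), drop = FALSE])
      }
    ),
    neural_network = list(
      fit = function(x, y, seed) {
        with_seed(seed, nnet::nnet(
          x, nnet::class.ind(y), size = nn_hidden, decay = 0.001,
          maxit = 200, MaxNWts = 1e7, softmax = TRUE, trace = FALSE))
      },
      predict = function(fit, x) {
        prob <- stats::predict(fit, x)
        list(class = factor(colnames(prob)[max.col(prob, ties.method = "first")],
                            levels = colnames(prob)),
             prob = prob)
      }
    ),
    gradient_boosting = list(
      fit = function(x, y, seed) {
        xgboost::xgboost(x, y, nrounds = 100, learning_rate = 0.1,
                         max_depth = 3, min_child_weight = 1,
                         nthreads = 1, seed = seed, verbosity = 0)
      },
      predict = function(fit, x) {
        prob <- stats::predict(fit, x, type = "response")
        lv <- attr(fit, "class_levels")
        if (is.null(dim(prob))) {
          prob <- cbind(1 - prob, prob)
          colnames(prob) <- lv
        }
        prob <- prob[, lv, drop = FALSE]
        list(class = factor(lv[max.col(prob, ties.method = "first")], levels = lv),
             prob = prob)
      }
    ),
    logistic_regression = list(
      fit = function(x, y, seed) {
        fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
        with_seed(seed, glmnet::glmnet(x, y, family = fam, alpha = 0,
                                       lambda = 1 / nrow(x)))
      },
      predict = function(fit, x) {
        prob <- stats::predict(fit, x, type = "response")
        if (length(dim(prob)) == 3) prob <- prob[, , 1]
        lv <- attr(fit, "class_levels")
        if (is.null(dim(prob)) || ncol(prob) == 1) {
          prob <- cbind(1 - as.numeric(prob), as.numeric(prob))
          colnames(prob) <- lv
        }
        prob <- prob[, lv, drop = FALSE]
        list(class = factor(lv[max.col(prob, ties.method = "first")], levels = lv),
             prob = prob)
      }
    ),
    decision_tree = list(
      fit = function(x, y, seed) {
        df <- data.frame(x, check.names = FALSE)
        df$.class <- y
        with_seed(seed, rpart::rpart(
          .class ~ ., data = df, method = "class",
          control = rpart::rpart.control(minbucket = 2, minsplit = 5,
                                         maxdepth = 30, cp = 0)))
      },
      predict = function(fit, x) {
        df <- data.frame(x, check.names = FALSE)
        prob <- stats::predict(fit, df, type = "prob")
        list(class = factor(colnames(prob)[max.col(prob, ties.method = "first")],
                            levels = attr(fit, "class_levels")),
             prob = prob)
      }
    ),
    random_forest = list(
      fit = function(x, y, seed) {
        with_seed(seed, randomForest::randomForest(x, y, ntree = 10, nodesize = 5))
      },
      predict = function(fit, x) {
        prob <- stats::predict(fit, x, type = "prob")
        list(class = stats::predict(fit, x, type = "response"), prob = prob)
      }
    )
  )
  models <- match.arg(models, names(all_specs), several.ok = TRUE)
  all_specs[models]
}

fit_and_score <- function(spec, train, test, seed) {
  fit <- spec$fit(train$x, train$y, seed)
  attr(fit, "class_levels") <- levels(train$y)
  pred <- spec$predict(fit, test$x)
  cm <- confusion_matrix(test$y, pred$class, classes = levels(train$y))
  met <- cm_metrics(cm)
  met$auc <- macro_auc(test$y, pred$prob)
  met$cm <- cm
  met
}

#' Evaluate classifier families on a fixed train/test split
#'
#' Fits each model `replicates` times with seeds `seeds` (model-level
#' randomness only; the split is fixed) and reports replicate-averaged
#' AUC (macro one-vs-rest), CA, macro F1, precision and recall, per-class
#' accuracy (%) and the summed confusion matrix.
#'
#' @param train,test `labeled_dataset`s sharing schema and class universe.
#' @param models Model specs (default: [default_model_specs()]).
#' @param replicates Number of replicate fits (default 3).
#' @param seeds Replicate seeds (default `1:replicates`).
#' @return An `eval_report`: list with `metrics` (data.frame, one row per
#'   model), `per_class` (matrix, models x classes, %), `confusion`
#'   (list of summed matrices) and `seeds`.
#' @export
evaluate_models <- function(train, test, models = default_model_specs(),
                            replicates = 3L, seeds = seq_len(replicates)) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  if (nlevels(droplevels(train$y)) < 2) stop("training split has a single class")
  scores <- lapply(names(models), function(mn) {
    reps <- lapply(seeds, function(sd) fit_and_score(models[[mn]], train, test, sd))
    list(name = mn, reps = reps)
  })
  summarize_scores(scores, seeds, levels(train$y))
}

summarize_scores <- function(scores, seeds, classes) {
  avg <- function(reps, field) mean(vapply(reps, function(r) r[[field]], numeric(1)))
  metrics <- do.call(rbind, lapply(scores, function(s) {
    data.frame(model = s$name,
               auc = avg(s$reps, "auc"), ca = avg(s$reps, "ca"),
               f1 = avg(s$reps, "f1"), precision = avg(s$reps, "precision"),
               recall = avg(s$reps, "recall"), stringsAsFactors = FALSE)
  }))
  per_class <- do.call(rbind, lapply(scores, function(s) {
    colMeans(do.call(rbind, lapply(s$reps, function(r) r$per_class_accuracy)))
  }))
  rownames(per_class) <- metrics$model
  colnames(per_class) <- classes
  confusion <- lapply(scores, function(s) Reduce(`+`, lapply(s$reps, `[[`, "cm")))
  names(confusion) <- metrics$model
  structure(list(metrics = metrics, per_class = per_class,
                 confusion = confusion, seeds = seeds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_report> %d model(s), %d replicate(s) (seeds: %s)\n",
              nrow(x$metrics), length(x$seeds), paste(x$seeds, collapse = ", ")))
  m <- x$metrics
  m[-1] <- lapply(m[-1], round, digits)
  print(m, row.names = FALSE)
  cat("per-class accuracy (%):\n")
  print(round(x$per_class, 1))
  invisible(x)
}

#' Run the full split/train/evaluate protocol
#'
#' The published protocol: for each replicate, draw a stratified 70/30
#' split and fit every model; report metrics averaged over the
#' replicates (triplicate by default, seeds \{1, 2, 3\}).
#'
#' @param d A `labeled_dataset`.
#' @param models Model specs.
#' @param train_fraction Training share (default 0.70).
#' @param replicates Number of replicate splits (default 3).
#' @param seeds Per-replicate seeds (default `1:replicates`).
#' @return An `eval_report` (see [evaluate_models()]).
#' @export
run_protocol <- function(d, models = default_model_specs(),
                         train_fraction = 0.70, replicates = 3L,
                         seeds = seq_len(replicates)) {
  stopifnot(inherits(d, "labeled_dataset"), length(seeds) == replicates)
  per_rep <- lapply(seeds, function(sd) {
    parts <- split_dataset(d, train_fraction, seed = sd)
    lapply(models, function(spec) fit_and_score(spec, parts$train, parts$test, sd))
  })
  scores <- lapply(seq_along(models), function(i) {
    list(name = names(models)[i], reps = lapply(per_rep, `[[`, i))
  })
  summarize_scores(scores, seeds, levels(d$y))
}
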