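make_blobs <- function(n_per_class, centers, sd = 0.5, seed = 1, n_feat = 5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(centers, function(mu) {
    matrix(rnorm(n_per_class * n_feat, mu, sd), ncol = n_feat)
  }))
  colnames(x) <- paste0("f", seq_len(n_feat))
  labeled_dataset(paste0("p", seq_len(nrow(x))), x,
                  rep(paste0("c", seq_along(centers)), each = n_per_class))
}

test_that("stratified split honours the 70/30 protocol and partition laws", {
  d <- make_blobs(500, c(0, 5), seed = 2)
  parts <- split_dataset(d, 0.70, seed = 1)
  expect_length(parts$train$ids, 700L)
  expect_length(parts$test$ids, 300L)
  expect_equal(as.integer(table(parts$train$y)), c(350L, 350L))
  # determinism and partition laws
  parts2 <- split_dataset(d, 0.70, seed = 1)
  expect_identical(parts$train$ids, parts2$train$ids)
  expect_length(intersect(parts$train$ids, parts$test$ids), 0L)
  expect_setequal(c(parts$train$ids, parts$test$ids), d$ids)
  parts3 <- split_dataset(d, 0.70, seed = 2)
  expect_false(identical(parts$train$ids, parts3$train$ids))
})

test_that("singleton classes stay whole in the training split with a warning", {
  d <- make_blobs(10, c(0, 5), seed = 3)
  d$y <- factor(c(as.character(d$y)[-20], "rare"), levels = c("c1", "c2", "rare"))
  expect_warning(parts <- split_dataset(d, 0.70, seed = 1), "rare")
  expect_true("rare" %in% parts$train$y)
  expect_false("rare" %in% parts$test$y)
})

test_that("confusion matrix conserves counts and defines CA", {
  truth <- c("a", "a", "b", "b", "b")
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(diag(cm)), c(2L, 3L))
  expect_equal(sum(cm), 5L)
  cm2 <- confusion_matrix(truth, rep("a", 5), classes = c("a", "b"))
  expect_equal(unname(colSums(cm2)), c(5L, 0L))
  expect_error(confusion_matrix(truth, c("a", "a", "b", "b", "z"),
                                classes = c("a", "b")), "outside")
  # trace / n = classification accuracy
  pred <- c("a", "b", "b", "a", "b")
  cm3 <- confusion_matrix(truth, pred)
  expect_equal(sum(diag(cm3)) / sum(cm3), mean(truth == pred))
})

test_that("all seven families are perfect on two linearly separated blobs", {
  d <- make_blobs(100, c(0, 8), sd = 1, seed = 1)   # n = 200
  parts <- split_dataset(d, 0.70, seed = 1)
  rep <- evaluate_models(parts$train, parts$test,
                         default_model_specs(nn_hidden = 25),
                         replicates = 1)
  expect_equal(nrow(rep$metrics), 7L)
  expect_true(all(rep$metrics$ca == 1))
  expect_true(all(rep$metrics$auc == 1))
  expect_true(all(rep$per_class == 100))
  for (cm in rep$confusion) expect_equal(sum(cm) - sum(diag(cm)), 0L)
})

test_that("shuffled labels score at the binomial chance level", {
  d <- make_blobs(200, c(0, 3), sd = 0.5, seed = 5)   # n = 400, n_test = 120
  set.seed(11)
  d$y <- factor(sample(as.character(d$y)), levels = levels(d$y))
  rep <- run_protocol(d, default_model_specs(c("knn", "decision_tree",
                                               "random_forest")),
                      replicates = 3)
  expect_true(all(abs(rep$metrics$ca - 0.5) <= 0.08))
})

test_that("a constant-majority predictor shows the 100%/0% per-class pattern", {
  majority_spec <- list(majority = list(
    fit = function(x, y, seed) names(which.max(table(y))),
    predict = function(fit, x) {
      lv <- attr(fit, "class_levels")
      prob <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
      prob[, fit] <- 1
      list(class = factor(rep(unclass(fit)[1], nrow(x)), levels = lv), prob = prob)
    }
  ))
  d <- make_blobs(10, c(0, 5), seed = 6)
  d$y <- factor(rep(c("maj", "min"), c(18, 2)))  # 90/10 imbalance
  parts <- split_dataset(d, 0.70, seed = 1)
  rep <- evaluate_models(parts$train, parts$test, majority_spec, replicates = 1)
  expect_equal(unname(rep$per_class["majority", ]), c(100, 0))
  expect_equal(rep$metrics$ca, sum(parts$test$y == "maj") / length(parts$test$y))
})

test_that("metrics stay inside their ranges and macro-F1 is bracketed", {
  d <- make_blobs(60, c(0, 1.5, 3), sd = 1, seed = 7)
  parts <- split_dataset(d, 0.70, seed = 2)
  rep <- evaluate_models(parts$train, parts$test,
                         default_model_specs(c("knn", "random_forest")),
                         replicates = 2)
  m <- rep$metrics
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_true(all(m$ca >= 0 & m$ca <= 1))
  expect_true(all(m$f1 >= 0 & m$f1 <= 1))
  expect_true(all(rep$per_class >= 0 & rep$per_class <= 100))
  for (cm in rep$confusion) {
    expect_equal(unname(rowSums(cm) / length(rep$seeds)),
                 unname(as.integer(table(parts$test$y))))
  }
})

test_that("run_protocol averages over replicate splits reproducibly", {
  d <- make_blobs(30, c(0, 6), sd = 0.4, seed = 8)
  r1 <- run_protocol(d, default_model_specs("knn"), replicates = 3)
  r2 <- run_protocol(d, default_model_specs("knn"), replicates = 3)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$seeds, 1:3)
  expect_equal(r1$metrics$ca, 1)
})

test_that("degenerate single-class training is an error", {
  d <- make_blobs(10, c(0, 5), seed = 9)
  one <- list(ids = d$ids[1:10], x = d$x[1:10, ], y = droplevels(d$y[1:10]))
  class(one) <- "labeled_dataset"
  expect_error(evaluate_models(one, one, default_model_specs("knn")), "single class")
})
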