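# Training/testing-set construction, KNN mechanics (against a brute-force
# oracle), k tuning, metrics, and cross-individual transfer.

test_that("training set follows the 50-per-scent-class + 500-other design", {
  sim <- simulate_accel(sim_config(seed = 1, duration_s = 3600, sex = "male"))
  tr <- build_training_set(sim$trace, sim$labels, seed = 5)
  expect_equal(nrow(tr), 50 + 50 + 500)
  expect_equal(as.vector(table(tr$class)[c("left_leg", "right_leg", "other")]),
               c(50L, 50L, 500L))
  expect_false(any(duplicated(tr$index)))
  # reproducible under the same seed
  tr2 <- build_training_set(sim$trace, sim$labels, seed = 5)
  expect_identical(tr$index, tr2$index)
})

test_that("toy design sizes and train/test disjointness hold", {
  toy <- toy_labelled_trace(per_class = 10,
                            classes = c("left_leg", "right_leg", "other"))
  tr <- build_training_set(toy$trace, toy$labels, n_scent = 2, n_other = 4,
                           seed = 1)
  expect_equal(nrow(tr), 8)
  te <- build_testing_set(toy$trace, toy$labels, tr, n_other_test = 3,
                          seed = 2)
  expect_length(intersect(tr$index, te$index), 0)
  # all non-training scent samples are in the test set
  expect_equal(sum(te$class == "left_leg"), 10 - 2)
  expect_equal(sum(te$class == "right_leg"), 10 - 2)
})

test_that("insufficient class samples raise a named error; capping warns", {
  toy <- toy_labelled_trace(per_class = 10,
                            classes = c("left_leg", "right_leg", "other"))
  expect_error(build_training_set(toy$trace, toy$labels, n_scent = 11,
                                  n_other = 4, seed = 1),
               "left_leg.*10 samples.*n_scent = 11")
  tr <- build_training_set(toy$trace, toy$labels, n_scent = 2, n_other = 4,
                           seed = 1)
  expect_warning(build_testing_set(toy$trace, toy$labels, tr,
                                   n_other_test = 3000, seed = 2),
                 "only 6 'other' records available")
})

test_that("KNN basics: zero distance, clear majorities, empty query", {
  tr <- data.frame(x = c(0, 0, 0, 0, 0, 0), y = c(-1, -1, -1, 1, 1, 1),
                   z = 0, class = rep(c("left_leg", "right_leg"), each = 3),
                   stringsAsFactors = FALSE)
  m1 <- knn_classifier(tr, k = 1)
  expect_equal(knn_predict(m1, data.frame(x = 0, y = -1, z = 0)), "left_leg")
  m3 <- knn_classifier(tr, k = 3)
  expect_equal(knn_predict(m3, data.frame(x = 0, y = -0.9, z = 0)), "left_leg")
  expect_equal(knn_predict(m3, data.frame(x = numeric(0), y = numeric(0),
                                          z = numeric(0))), character(0))
  expect_error(knn_classifier(tr, k = 2), "odd")
  expect_error(knn_classifier(tr, k = 7), "exceeds")
})

test_that("KNN matches the exhaustive-distance-sort oracle on random instances", {
  set.seed(101)
  for (rep in 1:8) {
    n_tr <- sample(20:120, 1)
    tr <- data.frame(x = runif(n_tr, -2, 2), y = runif(n_tr, -2, 2),
                     z = runif(n_tr, -2, 2),
                     class = sample(c("left_leg", "right_leg", "other"),
                                    n_tr, replace = TRUE),
                     stringsAsFactors = FALSE)
    k <- sample(c(1, 3, 5, 7), 1)
    q <- data.frame(x = runif(40, -2, 2), y = runif(40, -2, 2),
                    z = runif(40, -2, 2))
    for (vote in c("majority", "distance_weighted")) {
      model <- knn_classifier(tr, k, vote)
      expect_identical(knn_predict(model, q), knn_oracle(tr, k, q, vote),
                       info = sprintf("rep %d k %d vote %s", rep, k, vote))
    }
  }
})

test_that("k = 1 self-prediction reproduces training labels", {
  set.seed(7)
  tr <- data.frame(x = runif(60), y = runif(60), z = runif(60),
                   class = sample(c("left_leg", "other"), 60, TRUE),
                   stringsAsFactors = FALSE)
  model <- knn_classifier(tr, 1)
  expect_identical(knn_predict(model, tr), tr$class)
})

test_that("distance-weighted voting lets an exact match win outright", {
  tr <- data.frame(x = c(0, 0.01, 0.02), y = 0, z = 0,
                   class = c("left_leg", "other", "other"),
                   stringsAsFactors = FALSE)
  model <- knn_classifier(tr, 3, "distance_weighted")
  expect_equal(knn_predict(model, data.frame(x = 0, y = 0, z = 0)), "left_leg")
})

test_that("k tuning is deterministic, prefers small k on separable data, and validates folds", {
  sim <- simulate_accel(sim_config(seed = 9, duration_s = 1200,
                                   noise_sd_g = 0, marks_per_hour = 12))
  tk <- tune_k(sim$trace, sim$labels, seed = 3)
  expect_equal(tk$k_best, 1L)                     # ties break to smallest k
  expect_true(all(tk$cv_table$mean_accuracy == 1))
  tk2 <- tune_k(sim$trace, sim$labels, seed = 3)
  expect_identical(tk$cv_table, tk2$cv_table)
  expect_identical(tk$training, tk2$training)

  toy <- toy_labelled_trace(per_class = 10,
                            classes = c("left_leg", "right_leg", "other"))
  expect_error(tune_k(toy$trace, toy$labels, folds = 5, n_scent = 3,
                      n_other = 6, seed = 1),
               "folds = 5 exceeds")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # identity
  y <- c("left_leg", "other", "other", "right_leg")
  r <- evaluate(y, y)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$f1 == 1))

  # class A: TP=2 FP=1 FN=2 TN=5 -> precision 2/3, recall 1/2, F1 4/7
  y_true <- c("A", "A", "A", "A", rep("B", 6))
  y_pred <- c("A", "A", "B", "B", "A", rep("B", 5))
  r <- evaluate(y_true, y_pred)
  a <- r$per_class[r$per_class$class == "A", ]
  expect_equal(a$tp, 2); expect_equal(a$fp, 1)
  expect_equal(a$fn, 2); expect_equal(a$tn, 5)
  expect_equal(a$precision, 2 / 3)
  expect_equal(a$recall, 1 / 2)
  expect_equal(a$f1, 4 / 7)
  # one-vs-rest counts always sum to n
  expect_true(all(rowSums(r$per_class[, c("tp", "fp", "tn", "fn")]) ==
                    r$n_samples))
})

test_that("zero-denominator precision is 0 with a warning and still weighted", {
  y_true <- c("A", "A", "B")
  y_pred <- c("B", "B", "B")          # A never predicted -> TP+FP = 0
  expect_warning(r <- evaluate(y_true, y_pred), "A \\(precision\\)")
  expect_equal(r$per_class$precision[r$per_class$class == "A"], 0)
  expect_equal(r$recall, r$accuracy)  # identity must survive the edge case
})

test_that("AUC equals the Mann-Whitney oracle, including edge cases", {
  # perfect rank separation
  scores <- cbind(A = c(0.9, 0.8, 0.2, 0.1), B = c(0.1, 0.2, 0.8, 0.9))
  r <- evaluate(c("A", "A", "B", "B"), c("A", "A", "B", "B"), scores)
  expect_equal(r$per_class$auc, c(1, 1))

  # random scores hover near 0.5 at large n
  set.seed(55)
  n <- 1e4
  y <- sample(c("A", "B"), n, TRUE)
  s <- cbind(A = runif(n), B = runif(n))
  r <- evaluate(y, y, s)
  expect_lt(abs(r$per_class$auc[1] - 0.5), 0.05)

  # exhaustive-comparison oracle on small random instances with ties
  for (rep in 1:20) {
    yy <- sample(c("A", "B"), 30, TRUE)
    ss <- cbind(A = sample(seq(0, 1, 0.25), 30, TRUE))
    pos <- yy == "A"
    expect_equal(scentmark:::rank_auc(ss[, "A"], pos),
                 auc_oracle(ss[, "A"], pos))
  }
})

test_that("metric invariants hold on randomly generated reports", {
  set.seed(77)
  for (rep in 1:15) {
    n <- sample(30:200, 1)
    classes <- c("left_leg", "right_leg", "other")
    y_true <- sample(classes, n, TRUE)
    y_pred <- ifelse(runif(n) < 0.7, y_true, sample(classes, n, TRUE))
    r <- suppressWarnings(evaluate(y_true, y_pred))
    # prevalence-weighted recall == accuracy (algebraic identity)
    expect_equal(r$recall, r$accuracy, tolerance = 1e-12)
    expect_equal(sum(r$per_class$prevalence), 1, tolerance = 1e-12)
    # F1 between min and max of precision and recall, all rates in [0, 1]
    pc <- r$per_class
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
    expect_true(all(pc$recall >= 0 & pc$recall <= 1))
  }
})

test_that("cross-individual transfer: exchangeable dogs match, rotated dogs degrade", {
  mk <- function(seed, roll = 0) {
    simulate_accel(sim_config(seed = seed, duration_s = 1800,
                              marks_per_hour = 10, mount_roll_deg = roll))
  }
  d1 <- mk(41); d2 <- mk(42)
  res <- cross_individual_matrix(list(list(trace = d1$trace, labels = d1$labels),
                                      list(trace = d2$trace, labels = d2$labels)),
                                 k = 3, n_other_test = 500, seed = 1)
  expect_equal(dim(res$accuracy), c(2, 2))
  expect_true(all(abs(res$accuracy - diag(res$accuracy)[1]) < 0.05))

  # a 30-degree mounting rotation separates self from transfer accuracy
  d3 <- mk(43, roll = 30)
  res2 <- cross_individual_matrix(list(list(trace = d1$trace, labels = d1$labels),
                                       list(trace = d3$trace, labels = d3$labels)),
                                  k = 3, n_other_test = 500, seed = 1)
  expect_lt(res2$accuracy[1, 2], res2$accuracy[2, 2])
  expect_lt(res2$accuracy[2, 1], res2$accuracy[1, 1])

  # class-vocabulary mismatch (male vs female classes) is an error
  f <- simulate_accel(sim_config(seed = 44, duration_s = 1800,
                                 marks_per_hour = 10, sex = "female"))
  expect_error(
    cross_individual_matrix(list(list(trace = d1$trace, labels = d1$labels),
                                 list(trace = f$trace, labels = f$labels)),
                            k = 3, seed = 1),
    "vocabulary mismatch")
})
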