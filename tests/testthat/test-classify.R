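test_that("image-level splits honor the 2:1 ratio and reserve externals", {
  # 54 images per class split 2:1 with no external reservation
  plan <- split_by_image(1:54, ratio = c(2, 1), rng_seed = 1, n_external = 0)
  expect_length(plan$calibration_ids, 36L)
  expect_length(plan$prediction_ids, 18L)
  expect_length(plan$external_ids, 0L)

  # 55 images: one external reserved, remainder 36/18
  plan55 <- split_by_image(1:55, rng_seed = 1)
  expect_length(plan55$calibration_ids, 36L)
  expect_length(plan55$prediction_ids, 18L)
  expect_length(plan55$external_ids, 1L)
  all_ids <- c(plan55$calibration_ids, plan55$prediction_ids,
               plan55$external_ids)
  expect_setequal(all_ids, 1:55)
  expect_identical(anyDuplicated(all_ids), 0L)

  # tiny split
  plan3 <- split_by_image(1:3, rng_seed = 2, n_external = 0)
  expect_length(plan3$calibration_ids, 2L)
  expect_length(plan3$prediction_ids, 1L)

  # determinism
  expect_identical(split_by_image(1:55, rng_seed = 9),
                   split_by_image(1:55, rng_seed = 9))

  # per-class grouping: each class splits independently
  cls <- rep(1:3, each = 6)
  planc <- split_by_image(1:18, image_classes = cls, rng_seed = 3)
  expect_length(planc$external_ids, 3L)

  expect_error(split_by_image(1:3, rng_seed = 1, n_external = 1),
               "need at least")
})

test_that("grid search separates separable classes perfectly", {
  set.seed(41)
  X <- rbind(matrix(stats::rnorm(40, 0, 0.3), ncol = 2),
             matrix(stats::rnorm(40, 5, 0.3), ncol = 2))
  y <- rep(c(1L, 2L), each = 20)
  model <- grid_search_svm(X, y, cost_exponents = -2:6,
                           gamma_exponents = -4:2, cv_folds = 3, rng_seed = 1)
  rep <- evaluate(model, X, y)
  expect_equal(rep$overall_accuracy, 1)
  # grid record covers the full grid
  expect_identical(nrow(model$grid_record), 9L * 7L)
  expect_true(all(c(model$cost, model$gamma) %in%
                    c(model$grid_record$cost, model$grid_record$gamma)))
})

test_that("the RBF kernel can represent XOR", {
  set.seed(42)
  n <- 30
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(stats::rnorm(2 * n, 0, 0.08), ncol = 2), 2,
          centers[i, ], "+")))
  y <- rep(c(1L, 1L, 2L, 2L), each = n)
  model <- grid_search_svm(X, y, cost_exponents = seq(-2, 8, 2),
                           gamma_exponents = seq(-2, 6, 2), cv_folds = 3,
                           rng_seed = 2)
  expect_gt(max(model$grid_record$cv_accuracy), 0.9)
})

test_that("information-free inputs cannot beat the majority class", {
  X <- matrix(1, nrow = 30, ncol = 3)  # identical rows across classes
  y <- rep(c(1L, 2L, 3L), times = c(14, 10, 6))
  model <- grid_search_svm(X, y, cost_exponents = c(-2, 0, 2),
                           gamma_exponents = c(-2, 0), cv_folds = 3,
                           rng_seed = 3)
  expect_lte(max(model$grid_record$cv_accuracy), 14 / 30)
  expect_error(grid_search_svm(X, rep(1L, 30)), "at least 2 classes")
})

test_that("grid search is reproducible and ties break to small (c, g)", {
  set.seed(44)
  X <- rbind(matrix(stats::rnorm(30, 0, 0.2), ncol = 2),
             matrix(stats::rnorm(30, 4, 0.2), ncol = 2))
  y <- rep(1:2, each = 15)
  a <- grid_search_svm(X, y, cost_exponents = 0:4, gamma_exponents = -2:2,
                       cv_folds = 3, rng_seed = 7)
  b <- grid_search_svm(X, y, cost_exponents = 0:4, gamma_exponents = -2:2,
                       cv_folds = 3, rng_seed = 7)
  expect_identical(a$grid_record, b$grid_record)
  expect_identical(c(a$cost, a$gamma), c(b$cost, b$gamma))
  # with everything at 100%, the smallest cost then gamma must win
  top <- a$grid_record[a$grid_record$cv_accuracy ==
                         max(a$grid_record$cv_accuracy), ]
  expect_identical(a$cost, min(top$cost))
  expect_identical(a$gamma, min(top$gamma[top$cost == a$cost]))
})

test_that("confusion matrices tally predictions exactly and conserve counts", {
  set.seed(45)
  y <- sample(1:3, 200, replace = TRUE)
  pred <- sample(1:3, 200, replace = TRUE)
  conf <- matrix(0L, 3, 3)
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  rep <- eval_report(conf)
  expect_identical(sum(rep$confusion), 200L)
  expect_equal(unname(rowSums(rep$confusion)),
               as.vector(unname(table(y))))
  expect_equal(rep$overall_accuracy, mean(y == pred), tolerance = 1e-12)
  expect_equal(unname(rep$per_class_accuracy),
               vapply(1:3, function(k) mean(pred[y == k] == k), numeric(1)),
               tolerance = 1e-12)
})

test_that("perfect predictions give an identity-patterned report", {
  conf <- diag(c(10L, 20L, 30L))
  rep <- eval_report(conf)
  expect_equal(rep$overall_pct, 100)
  expect_equal(unname(rep$per_class_pct), c(100, 100, 100))
})

test_that("object prediction is deterministic and matches the decision sign", {
  set.seed(46)
  X <- rbind(matrix(stats::rnorm(30, 0, 0.2), ncol = 2),
             matrix(stats::rnorm(30, 3, 0.2), ncol = 2))
  y <- rep(1:2, each = 15)
  model <- grid_search_svm(X, y, cost_exponents = 0:3, gamma_exponents = -1:1,
                           cv_folds = 3, rng_seed = 1)
  p <- predict_objects(model, X)
  expect_identical(nrow(p), 30L)
  # two-class oracle: predicted class follows the sign of the decision value
  dv <- unname(attr(stats::predict(model$svm, X, decision.values = TRUE),
                    "decision.values")[, "1/2"])
  expect_identical(p$predicted, ifelse(dv > 0, 1L, 2L))
  # single-row prediction
  p1 <- predict_objects(model, X[1, , drop = FALSE])
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$predicted, p$predicted[1])
  # training predictions consistent with the reported calibration accuracy
  rep <- evaluate(model, X, y)
  expect_equal(mean(p$predicted == y), rep$overall_accuracy, tolerance = 1e-12)

  expect_error(evaluate(model, X, rep(c(1L, 9L), 15)), "\\{1, 2, 3\\}")
  wide <- cbind(X, X)
  expect_error(predict_objects(model, wide), "band mismatch")
})
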