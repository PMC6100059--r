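# Object-wise discriminant modelling: image-level sample split, RBF-SVM
# with (cost, gamma) grid search scored by stratified cross-validation, and
# confusion-matrix evaluation. Variety codes are fixed at 1, 2 and 3.

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Split images into calibration / prediction / external sets
#'
#' The split unit is the whole image: every object in an image shares its
#' fold. Per class group, `n_external` images are first reserved for
#' external validation, then the remainder is split `ratio[1]:ratio[2]`
#' into calibration and prediction.
#'
#' @param image_ids vector of image identifiers.
#' @param image_classes optional class per image; images of the same class
#'   are split together. `NULL` treats all images as one group.
#' @param ratio length-2 calibration:prediction ratio (default `c(2, 1)`).
#' @param rng_seed seed for the (reproducible) shuffle.
#' @param n_external external-validation images reserved per group.
#' @return list of class `split_plan` with disjoint `calibration_ids`,
#'   `prediction_ids`, `external_ids` and `unit = "image"`.
#' @export
split_by_image <- function(image_ids, image_classes = NULL, ratio = c(2, 1),
                           rng_seed = 1, n_external = 1) {
  if (is.null(image_classes)) image_classes <- rep(1L, length(image_ids))
  if (length(image_classes) != length(image_ids))
    stop("image_classes must align with image_ids")
  cal <- pred <- ext <- list()
  for (g in unique(image_classes)) {
    ids <- image_ids[image_classes == g]
    n <- length(ids)
    if (n - n_external < sum(ratio))
      stop("class group ", g, " has ", n, " image(s); need at least ",
           n_external + sum(ratio), " for an external + ", ratio[1L], ":",
           ratio[2L], " split")
    ids <- with_local_seed(rng_seed, sample(ids))
    e <- if (n_external > 0L) ids[seq_len(n_external)] else ids[0L]
    rest <- setdiff(ids, e)
    n_cal <- round(length(rest) * ratio[1L] / sum(ratio))
    n_cal <- min(max(n_cal, 1L), length(rest) - 1L)
    cal[[as.character(g)]] <- rest[seq_len(n_cal)]
    pred[[as.character(g)]] <- rest[(n_cal + 1L):length(rest)]
    ext[[as.character(g)]] <- e
  }
  structure(list(calibration_ids = unlist(cal, use.names = FALSE),
                 prediction_ids = unlist(pred, use.names = FALSE),
                 external_ids = unlist(ext, use.names = FALSE),
                 unit = "image"),
            class = "split_plan")
}

stratified_folds <- function(y, k, rng_seed) {
  folds <- integer(length(y))
  with_local_seed(rng_seed, {
    for (cl in unique(y)) {
      i <- which(y == cl)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  folds
}

#' Grid-search an RBF support vector machine
#'
#' Searches `cost = 2^cost_exponents` by `gamma = 2^gamma_exponents`
#' (defaults -8..8 for both), scoring each cell by stratified
#' cross-validated accuracy on the calibration data; ties are broken
#' towards the smaller cost, then the smaller gamma. The winning model is
#' refitted on the full calibration set. No feature scaling is applied
#' unless `standardize = TRUE`. Multiclass handling is libsvm's
#' one-vs-one voting.
#'
#' @param X numeric matrix of calibration spectra (rows = objects).
#' @param y integer class labels in `{1, 2, 3}`.
#' @param cost_exponents,gamma_exponents base-2 exponent grids.
#' @param cv_folds cross-validation folds (default 5).
#' @param rng_seed seed controlling fold assignment.
#' @param refine if `TRUE`, a second pass searches a factor-2^(1/4) grid
#'   around the best coarse cell.
#' @param standardize optional column standardization (off by default).
#' @return list of class `discriminant_model`: fitted `svm`, chosen
#'   `cost`/`gamma`, the full `grid_record` (cost, gamma, cv_accuracy) and
#'   training metadata.
#' @export
grid_search_svm <- function(X, y, cost_exponents = -8:8,
                            gamma_exponents = -8:8, cv_folds = 5,
                            rng_seed = 1, refine = FALSE,
                            standardize = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("grid search needs at least 2 classes, got ", length(unique(y)))
  if (!all(y %in% 1:3)) stop("class labels must be in {1, 2, 3}")
  scale_center <- scale_sd <- NULL
  if (standardize) {
    scale_center <- colMeans(X)
    scale_sd <- apply(X, 2L, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2L, scale_center), 2L, scale_sd, "/")
  }
  yf <- factor(y, levels = sort(unique(y)))
  folds <- stratified_folds(y, cv_folds, rng_seed)
  cv_accuracy <- function(cost, gamma) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      correct <- correct +
        sum(stats::predict(fit, X[!tr, , drop = FALSE]) == yf[!tr])
    }
    correct / length(y)
  }
  grid <- expand.grid(cost = 2^cost_exponents, gamma = 2^gamma_exponents,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- mapply(cv_accuracy, grid$cost, grid$gamma)
  pick <- function(g) {
    g <- g[order(-g$cv_accuracy, g$cost, g$gamma), ]
    g[1L, ]
  }
  best <- pick(grid)
  record <- grid
  if (refine) {
    qs <- 2^seq(-0.75, 0.75, by = 0.25)
    fine <- expand.grid(cost = best$cost * qs, gamma = best$gamma * qs,
                        KEEP.OUT.ATTRS = FALSE)
    fine$cv_accuracy <- mapply(cv_accuracy, fine$cost, fine$gamma)
    record <- rbind(record, fine)
    best <- pick(record)
  }
  fit <- e1071::svm(X, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  structure(list(svm = fit, cost = best$cost, gamma = best$gamma,
                 cv_accuracy = best$cv_accuracy, grid_record = record,
                 cv_folds = cv_folds, rng_seed = rng_seed,
                 feature_names = colnames(X), n_features = ncol(X),
                 standardize = standardize,
                 scale_center = scale_center, scale_sd = scale_sd,
                 levels = levels(yf)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> RBF-SVM, cost = %g, gamma = %g, CV accuracy = %.3f (%d-fold)\n",
              x$cost, x$gamma, x$cv_accuracy, x$cv_folds))
  invisible(x)
}

model_features <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    wl_cols <- grep("^wl_", names(newdata), value = TRUE)
    if (!is.null(model$feature_names)) {
      miss <- setdiff(model$feature_names, names(newdata))
      if (length(miss))
        stop("band mismatch with training EWs; missing: ",
             paste(miss, collapse = ", "))
      newdata <- as.matrix(newdata[, model$feature_names, drop = FALSE])
    } else newdata <- as.matrix(newdata[, wl_cols, drop = FALSE])
  } else newdata <- as.matrix(newdata)
  if (ncol(newdata) != model$n_features)
    stop("band mismatch: model trained on ", model$n_features,
         " wavelengths, got ", ncol(newdata))
  if (isTRUE(model$standardize))
    newdata <- sweep(sweep(newdata, 2L, model$scale_center), 2L,
                     model$scale_sd, "/")
  newdata
}

#' Predict the class of each object
#'
#' @param model a [grid_search_svm()] model.
#' @param table a [spectra_table()] (or bare matrix) restricted to the
#'   model's training wavelengths.
#' @return data.frame with `id`, `predicted` class and `score` (fraction of
#'   one-vs-one votes won by the predicted class).
#' @export
predict_objects <- function(model, table) {
  stopifnot(inherits(model, "discriminant_model"))
  Xn <- model_features(model, table)
  pred <- stats::predict(model$svm, Xn, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  k <- length(model$levels)
  votes <- matrix(0, nrow(Xn), k, dimnames = list(NULL, model$levels))
  if (k > 1L) for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/")[[1]]
    win <- ifelse(dv[, cn] > 0, pair[1L], pair[2L])
    votes[cbind(seq_len(nrow(Xn)), match(win, model$levels))] <-
      votes[cbind(seq_len(nrow(Xn)), match(win, model$levels))] + 1
  }
  score <- votes[cbind(seq_len(nrow(Xn)), match(as.character(pred), model$levels))] /
    max(k - 1L, 1L)
  ids <- if (is.data.frame(table) && "id" %in% names(table)) table$id
         else seq_len(nrow(Xn))
  data.frame(id = ids, predicted = as.integer(as.character(pred)), score = score)
}

#' Evaluation report from a confusion matrix
#'
#' Rows are true classes 1..K, columns predicted. Per-class accuracy is the
#' row-normalized diagonal; overall accuracy is trace over total. Percent
#' values are reported to one decimal.
#'
#' @param confusion square count matrix.
#' @return list of class `eval_report`: `confusion`, `per_class_accuracy`,
#'   `overall_accuracy` (fractions), `per_class_pct`, `overall_pct`.
#' @export
eval_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  per_class <- diag(confusion) / rowSums(confusion)
  overall <- sum(diag(confusion)) / sum(confusion)
  structure(list(confusion = confusion, per_class_accuracy = per_class,
                 overall_accuracy = overall,
                 per_class_pct = round(100 * per_class, 1),
                 overall_pct = round(100 * overall, 1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  cat(sprintf("per-class accuracy: %s\noverall accuracy: %.1f%%\n",
              paste(sprintf("%.1f%%", x$per_class_pct), collapse = " / "),
              x$overall_pct))
  invisible(x)
}

#' Evaluate a model on labeled objects
#'
#' @param model a [grid_search_svm()] model.
#' @param X spectra table or matrix.
#' @param y true classes in `{1, 2, 3}`.
#' @return an [eval_report()].
#' @export
evaluate <- function(model, X, y) {
  y <- as.integer(y)
  if (!all(y %in% 1:3)) stop("class labels must be in {1, 2, 3}")
  pred <- predict_objects(model, X)$predicted
  classes <- sort(unique(c(y, pred)))
  confusion <- table(factor(y, levels = classes),
                     factor(pred, levels = classes))
  eval_report(unclass(confusion))
}
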