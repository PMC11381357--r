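#' @title Statistical evaluation layer
#' @name ml_eval
#' @description Random-forest variable importance, Pearson correlations, and
#'   three-class rate prediction (logistic regression, SVM, decision tree)
#'   evaluated by stratified split accuracy, cross-validation and one-vs-rest
#'   ROC with micro- and macro-averaged AUC.
NULL

MODEL_SPECS <- c("logistic_regression", "svm", "decision_tree")

#' Assemble the labeled dataset from features and rate fits
#'
#' Inner join on \code{sample_id}; every id must appear exactly once on each
#' side. Rows are ordered by id so the result is independent of input order.
#'
#' @param features data.frame with \code{sample_id} and X1...X16 columns.
#' @param rates data.frame with \code{sample_id}, \code{k} and
#'   \code{rate_class} (and optionally further columns, kept).
#' @return data.frame of class \code{labeled_dataset}.
#' @export
assemble_dataset <- function(features, rates) {
  need <- c("sample_id", feature_names())
  miss <- setdiff(need, names(features))
  if (length(miss) > 0L)
    stop("features lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("sample_id", "k", "rate_class") %in% names(rates)))
    stop("rates must contain sample_id, k, rate_class", call. = FALSE)
  if (anyDuplicated(features$sample_id) || anyDuplicated(rates$sample_id))
    stop("duplicate sample_id", call. = FALSE)
  if (!setequal(features$sample_id, rates$sample_id))
    stop("sample_id sets differ (orphan ids: ",
         paste(utils::head(c(setdiff(features$sample_id, rates$sample_id),
                             setdiff(rates$sample_id, features$sample_id)), 5L),
               collapse = ", "), ")", call. = FALSE)
  if (anyNA(features[feature_names()])) stop("missing feature values", call. = FALSE)
  if (!all(rates$rate_class %in% 0:2))
    stop("rate_class must be in {0, 1, 2}", call. = FALSE)
  ds <- merge(features, rates, by = "sample_id", sort = TRUE)
  ds <- ds[order(ds$sample_id), , drop = FALSE]
  rownames(ds) <- NULL
  class(ds) <- c("labeled_dataset", class(ds))
  ds
}

ds_x <- function(ds) as.matrix(ds[, feature_names(), drop = FALSE])
ds_y <- function(ds) factor(ds$rate_class, levels = 0:2)

#' Random-forest variable importance
#'
#' Impurity-based (mean decrease in Gini) importances from a seeded random
#' forest over the 16 features, normalized to sum to 1 and sorted descending.
#'
#' @param ds a \code{labeled_dataset} with >= 2 classes present.
#' @param n_trees forest size (default 500).
#' @param seed RNG seed.
#' @return data.frame (class \code{importance_ranking}) with columns
#'   \code{feature}, \code{weight}, descending.
#' @export
feature_importance <- function(ds, n_trees = 500L, seed = 1L) {
  y <- droplevels(ds_y(ds))
  if (nlevels(y) < 2L) stop("need >= 2 classes for importance", call. = FALSE)
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = ds_x(ds), y = y, ntree = n_trees))
  imp <- rf$importance[, "MeanDecreaseGini"]
  w <- imp / sum(imp)
  out <- data.frame(feature = names(w), weight = unname(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Pearson correlations among features (and log10 k)
#'
#' @param ds a \code{labeled_dataset} with >= 3 rows.
#' @param include_k append a \code{log10_k} column (default TRUE).
#' @return symmetric correlation matrix; zero-variance columns give NA rows.
#' @export
pearson_correlations <- function(ds, include_k = TRUE) {
  if (nrow(ds) < 3L) stop("need >= 3 rows", call. = FALSE)
  x <- ds_x(ds)
  if (include_k) x <- cbind(x, log10_k = log10(ds$k))
  suppressWarnings(stats::cor(x, method = "pearson"))
}

# stratified assignment of fold ids 1..nfold within each class
stratified_folds <- function(y, nfold, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
    }
  })
  fold
}

standardizer <- function(xtr) {
  mu <- colMeans(xtr)
  sd <- apply(xtr, 2L, stats::sd)
  sd[sd == 0] <- 1
  function(x) sweep(sweep(x, 2L, mu), 2L, sd, "/")
}

# fit one classifier, returning a predict(xnew) -> list(class, prob) closure
fit_classifier <- function(model_spec, xtr, ytr, seed) {
  lev <- levels(ytr)
  if (model_spec == "logistic_regression") {
    # one-vs-rest binomial fits, matching the one-vs-rest ROC construction
    scale_fn <- standardizer(xtr)
    xs <- scale_fn(xtr)
    fits <- lapply(lev, function(cl) {
      df <- data.frame(y = as.integer(ytr == cl), xs)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    })
    function(xnew) {
      df <- data.frame(scale_fn(xnew))
      pr <- vapply(fits, function(f)
        suppressWarnings(stats::predict(f, newdata = df, type = "response")),
        numeric(nrow(df)))
      pr <- matrix(pr, nrow = nrow(df), dimnames = list(NULL, lev))
      pr <- pr / pmax(rowSums(pr), .Machine$double.eps)
      list(class = factor(lev[max.col(pr, ties.method = "first")], levels = lev),
           prob = pr)
    }
  } else if (model_spec == "svm") {
    scale_fn <- standardizer(xtr)
    fit <- withr::with_seed(seed,
      e1071::svm(x = scale_fn(xtr), y = ytr, kernel = "radial",
                 probability = TRUE, scale = FALSE))
    function(xnew) {
      pred <- stats::predict(fit, scale_fn(xnew), probability = TRUE)
      pr <- attr(pred, "probabilities")[, lev, drop = FALSE]
      list(class = factor(as.character(pred), levels = lev), prob = pr)
    }
  } else if (model_spec == "decision_tree") {
    df <- data.frame(y = ytr, xtr)
    fit <- withr::with_seed(seed, rpart::rpart(y ~ ., data = df, method = "class"))
    function(xnew) {
      dfn <- data.frame(xnew)
      pr <- stats::predict(fit, dfn, type = "prob")[, lev, drop = FALSE]
      list(class = factor(lev[max.col(pr, ties.method = "first")], levels = lev),
           prob = pr)
    }
  } else stop("unknown model_spec: ", model_spec, call. = FALSE)
}

binary_auc <- function(pos, score) {
  if (length(unique(pos)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = pos, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

# per-class one-vs-rest AUCs plus micro (pooled decisions) and macro (mean)
ovr_aucs <- function(y, prob) {
  lev <- colnames(prob)
  per_class <- vapply(lev, function(cl) binary_auc(y == cl, prob[, cl]),
                      numeric(1L))
  micro <- binary_auc(as.vector(vapply(lev, function(cl) y == cl,
                                       logical(length(y)))),
                      as.vector(prob))
  list(per_class = per_class, micro = micro,
       macro = mean(per_class, na.rm = TRUE))
}

#' Train and evaluate a rate-class predictor
#'
#' Stratified train/validation split, k-fold cross-validated accuracy, and
#' one-vs-rest ROC AUC (per class, micro-averaged over pooled decisions,
#' macro-averaged over classes) for one of three classifiers. Features are
#' standardized on training statistics for logistic regression and the
#' RBF-kernel SVM, and passed raw to the decision tree. If a split leaves a
#' class absent from training, it is reshuffled with the next seed.
#'
#' @param ds a \code{labeled_dataset}.
#' @param model_spec "logistic_regression", "svm" or "decision_tree".
#' @param split_frac training fraction (default 0.8).
#' @param cv_folds folds for cross-validation (default 5); each class needs
#'   at least this many members.
#' @param seed RNG seed governing split, folds and any model randomness.
#' @return list of class \code{eval_report}: accuracies, CV mean/sd, AUCs,
#'   confusion matrix (validation), seeds used.
#' @export
train_and_evaluate <- function(ds, model_spec = MODEL_SPECS, split_frac = 0.8,
                               cv_folds = 5L, seed = 1L) {
  model_spec <- match.arg(model_spec)
  x <- ds_x(ds)
  y <- ds_y(ds)
  present <- levels(droplevels(y))
  if (any(table(y)[present] < cv_folds))
    stop("each present class needs >= cv_folds members", call. = FALSE)
  # stratified split; reshuffle with next seed if a class drops out of training
  split_seed <- seed
  repeat {
    tr_idx <- withr::with_seed(split_seed, {
      unlist(lapply(present, function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(split_frac * length(idx))))
      }))
    })
    if (all(present %in% y[tr_idx]) && length(tr_idx) < length(y)) break
    split_seed <- split_seed + 1L
  }
  va_idx <- setdiff(seq_along(y), tr_idx)
  ytr <- droplevels(y[tr_idx]); yva <- factor(y[va_idx], levels = levels(ytr))
  pred <- fit_classifier(model_spec, x[tr_idx, , drop = FALSE], ytr, seed)
  tr_out <- pred(x[tr_idx, , drop = FALSE])
  va_out <- pred(x[va_idx, , drop = FALSE])
  train_acc <- mean(tr_out$class == ytr)
  val_acc <- mean(va_out$class == yva)
  aucs <- ovr_aucs(yva, va_out$prob)
  conf <- table(truth = yva, predicted = va_out$class)
  # stratified k-fold CV on the full dataset
  fold <- stratified_folds(droplevels(y), cv_folds, seed)
  cv_acc <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    p <- fit_classifier(model_spec, x[tr, , drop = FALSE],
                        droplevels(y[tr]), seed)
    mean(p(x[!tr, , drop = FALSE])$class == as.character(y[!tr]))
  }, numeric(1L))
  structure(
    list(model = model_spec, n_train = length(tr_idx), n_val = length(va_idx),
         train_accuracy = train_acc, val_accuracy = val_acc,
         cv_accuracy_mean = mean(cv_acc), cv_accuracy_sd = stats::sd(cv_acc),
         auc_per_class = aucs$per_class, auc_micro = aucs$micro,
         auc_macro = aucs$macro, confusion = conf,
         split_seed = split_seed, seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s: train acc %.3f, val acc %.3f, CV %.3f +/- %.3f>\n",
              x$model, x$train_accuracy, x$val_accuracy,
              x$cv_accuracy_mean, x$cv_accuracy_sd))
  cat(sprintf("  AUC per class: %s; micro %.3f; macro %.3f\n",
              paste(sprintf("%s=%.3f", names(x$auc_per_class), x$auc_per_class),
                    collapse = ", "),
              x$auc_micro, x$auc_macro))
  invisible(x)
}

#' Apply models trained on the full training set to an external test set
#'
#' Each requested model is fitted once on all training rows and applied to the
#' test rows. If both datasets carry an \code{invader_len} column, test rows
#' whose strand length differs from the (modal) training length are flagged:
#' the feature construction assumes a fixed strand geometry and such samples
#' fall outside the training distribution.
#'
#' @param ds_train,ds_test \code{labeled_dataset}s with identical feature
#'   schema.
#' @param model_specs models to fit (default all three).
#' @param seed RNG seed.
#' @return list with \code{predictions} (data.frame: sample_id, truth, one
#'   column per model, \code{length_mismatch}) and \code{accuracy} (named
#'   vector per model).
#' @export
external_test <- function(ds_train, ds_test, model_specs = MODEL_SPECS,
                          seed = 1L) {
  if (!identical(feature_names() %in% names(ds_train),
                 feature_names() %in% names(ds_test)) ||
      !all(feature_names() %in% names(ds_test)))
    stop("feature schema mismatch between train and test", call. = FALSE)
  xtr <- ds_x(ds_train); ytr <- droplevels(ds_y(ds_train))
  xte <- ds_x(ds_test);  yte <- factor(ds_test$rate_class, levels = levels(ytr))
  preds <- data.frame(sample_id = ds_test$sample_id,
                      truth = ds_test$rate_class, stringsAsFactors = FALSE)
  acc <- stats::setNames(numeric(length(model_specs)), model_specs)
  for (ms in model_specs) {
    p <- fit_classifier(ms, xtr, ytr, seed)(xte)$class
    preds[[ms]] <- as.integer(as.character(p))
    acc[ms] <- mean(preds[[ms]] == preds$truth)
  }
  if ("invader_len" %in% names(ds_train) && "invader_len" %in% names(ds_test)) {
    ref_len <- as.integer(names(sort(table(ds_train$invader_len),
                                     decreasing = TRUE))[1L])
    preds$length_mismatch <- ds_test$invader_len != ref_len
  } else {
    preds$length_mismatch <- NA
  }
  list(predictions = preds, accuracy = acc)
}
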