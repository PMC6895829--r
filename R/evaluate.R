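# Task 1 (one-step regression) and Task 2 (remission classification via an
# autoregressive rollout of the one-step predictor), plus a thin comparison
# harness over generic regressors.

#' Root mean squared error
#'
#' @param y,yhat Numeric vectors of equal positive length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) sqrt(mse_loss(y, yhat))

#' Coefficient of determination
#'
#' `1 - RSS/TSS`; errors when the observed values are constant (zero total
#' sum of squares).
#'
#' @param y,yhat Numeric vectors of equal positive length.
#' @return R-squared (may be negative for fits worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) == 0L) stop("r_squared is undefined for empty input")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("r_squared is undefined for constant y")
  1 - sum((y - yhat)^2) / tss
}

#' Binary classification metrics from labels and predictions
#'
#' Computes the confusion counts and sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, F1 `2TP/(2TP+FN+FP)` and accuracy
#' `(TP+TN)/n`. A zero denominator yields `NaN` with a warning rather than
#' an arbitrary 0.
#'
#' @param labels,predictions Binary (0/1) vectors of equal length.
#' @return List with `counts` (tp, tn, fp, fn) and the five metrics.
#' @export
classification_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  list(counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
       sensitivity = safe_div(tp, tp + fn, "sensitivity"),
       specificity = safe_div(tn, tn + fp, "specificity"),
       precision   = safe_div(tp, tp + fp, "precision"),
       f1          = safe_div(2 * tp, 2 * tp + fn + fp, "F1"),
       accuracy    = safe_div(tp + tn, tp + tn + fp + fn, "accuracy"))
}

# Resolve a predictor: either a fitted "adrnet" model or a function
# f(example_row, features) -> predicted next-visit HAM-D.
as_predictor <- function(object, features) {
  if (inherits(object, "adrnet")) {
    function(example, features_) predict(object, example, features_)
  } else if (is.function(object)) {
    object
  } else stop("predictor must be an 'adrnet' model or a function")
}

#' Remission prediction by autoregressive rollout
#'
#' Chains the one-step predictor along each patient's own visit sequence:
#' starting from the observed initial score, each predicted next-visit score
#' is fed forward as the current score of the following step, while the
#' recorded prescription and interval of each step are used as-is. The final
#' predicted score is compared with the observed initial score by the
#' half-score remission rule.
#'
#' @param object A fitted `"adrnet"` model, or a predictor function
#'   `f(example_row, features)` returning the predicted next score (the
#'   example row carries `patient_id`, `from_visit`, `hamd_now`, `interval`,
#'   `drugs`).
#' @param visits Visit table (patients with a single visit are skipped).
#' @param features Imputed covariate blocks.
#' @param clamp Clamp intermediate predictions at 0 (scores are non-negative
#'   by construction of the scale)? Default FALSE: the raw rollout.
#' @return Data frame with one row per evaluable patient: `patient_id`,
#'   `label` (observed), `label_pred`, `hamd_first`, `hamd_final_pred`.
#' @export
rollout_remission <- function(object, visits, features, clamp = FALSE) {
  visits <- check_visits(visits)
  predictor <- as_predictor(object, features)
  out <- list()
  for (pid in unique(visits$patient_id)) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    nv <- nrow(v)
    if (nv < 2L) next
    h1 <- v$hamd[1L]
    if (h1 <= 0)
      stop("initial HAM-D score must be positive (patient ", pid, ")")
    h <- h1
    for (i in seq_len(nv - 1L)) {
      ex <- data.frame(patient_id = pid, from_visit = v$visit_index[i],
                       hamd_now = h, interval = v$weeks_since_prev[i + 1L],
                       drugs = v$drugs[i], stringsAsFactors = FALSE)
      h <- as.numeric(predictor(ex, features))
      if (clamp) h <- max(h, 0)
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid, label = remission_label(v$hamd),
      label_pred = as.integer(h / h1 <= 0.5),
      hamd_first = h1, hamd_final_pred = h, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(patient_id = character(0), label = integer(0),
                      label_pred = integer(0), hamd_first = numeric(0),
                      hamd_final_pred = numeric(0))
  rownames(res) <- NULL
  res
}

#' Evaluate a model on both tasks
#'
#' Task 1: one-step regression RMSE and R-squared on held-out examples.
#' Task 2: remission classification metrics from the rollout over full visit
#' sequences.
#'
#' @param object A fitted `"adrnet"` model or predictor function.
#' @param examples Held-out one-step examples (with `hamd_next`).
#' @param features Imputed covariate blocks.
#' @param visits Visit table for the rollout task; `NULL` skips Task 2.
#' @return Object of class `"eval_report"`: list with `rmse`, `r_squared`,
#'   `classification` (metric list or `NULL`), `n_examples`, `n_cases`.
#' @export
evaluate_model <- function(object, examples, features, visits = NULL) {
  predictor <- as_predictor(object, features)
  yhat <- as.numeric(predictor(examples, features))
  rep_ <- list(rmse = rmse(examples$hamd_next, yhat),
               r_squared = r_squared(examples$hamd_next, yhat),
               classification = NULL,
               n_examples = nrow(examples), n_cases = 0L)
  if (!is.null(visits)) {
    ro <- rollout_remission(object, visits, features)
    rep_$classification <- classification_metrics(ro$label, ro$label_pred)
    rep_$n_cases <- nrow(ro)
  }
  structure(rep_, class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Task 1 (one-step regression, n=%d): RMSE %.4f, R-squared %.4f\n",
              x$n_examples, x$rmse, x$r_squared))
  if (!is.null(x$classification)) {
    cm <- x$classification
    cat(sprintf("Task 2 (remission rollout, n=%d): sens %.4f spec %.4f prec %.4f F1 %.4f acc %.4f\n",
                x$n_cases, cm$sensitivity, cm$specificity, cm$precision,
                cm$f1, cm$accuracy))
  }
  invisible(x)
}

#' Generic regressor suite for baseline comparisons
#'
#' Builds the comparison suite of standard regressors (linear-kernel SVR,
#' ridge, gradient boosting, multilayer perceptron, k-nearest neighbours,
#' random forest), each as a `fit(X, y)` / `predict(fit, X)` pair over the
#' flattened feature vector `[covariates; H; interval; drug multi-hot]`.
#' Members whose backing package is not installed are dropped with a message.
#'
#' @param members Character subset of
#'   `c("linear_svr", "ridge", "gradient_boosting", "mlp", "knn",
#'   "random_forest")`.
#' @return Named list of `list(fit =, predict =)` pairs.
#' @export
baseline_suite <- function(members = c("linear_svr", "ridge",
                                       "gradient_boosting", "mlp", "knn",
                                       "random_forest")) {
  all <- list(
    linear_svr = list(
      pkg = "e1071",
      fit = function(X, y) e1071::svm(X, y, kernel = "linear"),
      predict = function(fit, X) as.numeric(predict(fit, X))),
    ridge = list(
      pkg = "glmnet",
      fit = function(X, y) glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5),
      predict = function(fit, X)
        as.numeric(predict(fit, X, s = "lambda.min"))),
    gradient_boosting = list(
      pkg = "xgboost",
      fit = function(X, y)
        xgboost::xgboost(data = X, label = y, nrounds = 100,
                         max_depth = 3, eta = 0.1, verbose = 0,
                         nthread = 1),
      predict = function(fit, X) as.numeric(predict(fit, X))),
    mlp = list(
      pkg = "nnet",
      fit = function(X, y)
        nnet::nnet(X, y, size = 16, linout = TRUE, maxit = 300,
                   decay = 1e-3, trace = FALSE, MaxNWts = 20000),
      predict = function(fit, X) as.numeric(predict(fit, X))),
    knn = list(
      pkg = "caret",
      fit = function(X, y) caret::knnreg(X, y, k = 5),
      predict = function(fit, X) as.numeric(predict(fit, X))),
    random_forest = list(
      pkg = "randomForest",
      fit = function(X, y) randomForest::randomForest(X, y, ntree = 300),
      predict = function(fit, X) as.numeric(predict(fit, X))))
  suite <- list()
  for (nm in intersect(members, names(all))) {
    if (requireNamespace(all[[nm]]$pkg, quietly = TRUE))
      suite[[nm]] <- all[[nm]][c("fit", "predict")]
    else message("baseline '", nm, "' skipped: package ", all[[nm]]$pkg,
                 " not installed")
  }
  suite
}

# Flattened baseline design: [covariate blocks; H; interval; drug multi-hot].
baseline_design <- function(examples, features, vocabulary) {
  cbind(build_design(features, examples),
        drug_incidence(examples$drugs, vocabulary))
}

#' Run baseline regressors on both tasks
#'
#' Fits each suite member on the flattened feature vector the network
#' consumes and evaluates it with the same Task 1 and Task 2 procedures
#' (Task 2 via the same rollout). A baseline whose fit fails is recorded with
#' `NA` metrics and the others continue.
#'
#' @param train,test One-step example sets (with `hamd_next`).
#' @param features Imputed covariate blocks.
#' @param vocabulary Drug name vector.
#' @param suite Named list from [baseline_suite()] (possibly a subset).
#' @param visits Visit table for Task 2; `NULL` skips it.
#' @param seed Integer seed set before each fit.
#' @return Data frame, one row per baseline, with the Task 1 and Task 2
#'   metrics.
#' @export
run_baselines <- function(train, test, features, vocabulary,
                          suite = baseline_suite(), visits = NULL,
                          seed = 1L) {
  if (length(suite) == 0L)
    return(data.frame(model = character(0), rmse = numeric(0),
                      r_squared = numeric(0)))
  Xtr <- baseline_design(train, features, vocabulary)
  Xte <- baseline_design(test, features, vocabulary)
  rows <- lapply(names(suite), function(nm) {
    mem <- suite[[nm]]
    fit <- try(with_seed(seed, mem$fit(Xtr, train$hamd_next)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("baseline '", nm, "' failed to fit: ",
              attr(fit, "condition")$message)
      return(data.frame(model = nm, rmse = NA_real_, r_squared = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        precision = NA_real_, f1 = NA_real_,
                        accuracy = NA_real_, stringsAsFactors = FALSE))
    }
    predictor <- function(example, features_)
      mem$predict(fit, baseline_design(example, features_, vocabulary))
    rep_ <- evaluate_model(predictor, test, features, visits)
    cm <- rep_$classification
    data.frame(model = nm, rmse = rep_$rmse, r_squared = rep_$r_squared,
               sensitivity = if (is.null(cm)) NA_real_ else cm$sensitivity,
               specificity = if (is.null(cm)) NA_real_ else cm$specificity,
               precision = if (is.null(cm)) NA_real_ else cm$precision,
               f1 = if (is.null(cm)) NA_real_ else cm$f1,
               accuracy = if (is.null(cm)) NA_real_ else cm$accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated evaluation protocol
#'
#' Trains and evaluates the network `times` times under different seeds and
#' reports the per-metric mean, mirroring the repeated-run protocol used to
#' damp initialisation randomness.
#'
#' @param train,test,features,vocabulary,visits As for [adrnet()] /
#'   [evaluate_model()].
#' @param times Number of repeats.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param ... Hyperparameters passed to [adrnet()].
#' @return List with `mean` (averaged metrics) and `runs` (per-run data
#'   frame).
#' @export
evaluate_repeated <- function(train, test, features, vocabulary,
                              visits = NULL, times = 5L, seed = 1L, ...) {
  runs <- lapply(seq_len(times), function(i) {
    fit <- adrnet(train, features, vocabulary, seed = seed + i - 1L, ...)
    rep_ <- evaluate_model(fit, test, features, visits)
    cm <- rep_$classification
    data.frame(run = i, rmse = rep_$rmse, r_squared = rep_$r_squared,
               sensitivity = if (is.null(cm)) NA_real_ else cm$sensitivity,
               specificity = if (is.null(cm)) NA_real_ else cm$specificity,
               precision = if (is.null(cm)) NA_real_ else cm$precision,
               f1 = if (is.null(cm)) NA_real_ else cm$f1,
               accuracy = if (is.null(cm)) NA_real_ else cm$accuracy)
  })
  runs <- do.call(rbind, runs)
  list(mean = colMeans(runs[, -1L, drop = FALSE]), runs = runs)
}
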