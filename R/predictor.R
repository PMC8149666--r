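#' Control options for the default gradient-boosted predictor
#'
#' Hyperparameters are chosen by fivefold cross-validation over a small grid;
#' the boosting-round count is taken from the cross-validated optimum. The
#' scoring metric is RMSE for regression and AUC for classification.
#'
#' @param grid data frame of candidate `max_depth` / `eta` combinations.
#' @param nrounds maximum boosting rounds evaluated per candidate.
#' @param nfold cross-validation folds (default 5).
#' @param nthread threads for xgboost (1 keeps fits deterministic).
#' @return list of class `ap_predictor_control`.
#' @export
predictor_control <- function(grid = expand.grid(max_depth = c(2L, 4L, 6L),
                                                 eta = c(0.1, 0.3)),
                              nrounds = 150L, nfold = 5L, nthread = 1L) {
  structure(list(grid = grid, nrounds = nrounds, nfold = nfold,
                 nthread = nthread),
            class = "ap_predictor_control")
}

# One-hot design matrix over explanatory variables, with factor levels pinned
# to the schema categories so unseen rows encode consistently.
encode_onehot <- function(df, schema) {
  cvars <- continuous_vars(schema, role = "explanatory")
  dvars <- discrete_vars(schema, role = "explanatory")
  cols <- list()
  for (v in cvars) cols[[v]] <- as.numeric(df[[v]])
  for (v in dvars) {
    cats <- var_categories(schema, v)
    f <- factor(df[[v]], levels = cats)
    for (c in cats) cols[[paste0(v, "=", c)]] <- as.numeric(f == c)
  }
  do.call(cbind, cols)
}

new_prediction_model <- function(task, engine, predict_fn, schema,
                                 params = list()) {
  m <- new.env(parent = emptyenv())
  m$task <- task
  m$engine <- engine
  m$predict_fn <- predict_fn
  m$schema <- schema
  m$fingerprint <- fnv1a_hash(paste(schema$name, schema$kind, collapse = "|"))
  m$params <- params
  m$metrics <- list()
  class(m) <- "prediction_model"
  m
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("<prediction_model> task:", x$task, " engine:", x$engine, "\n")
  if (length(x$metrics))
    cat("  metrics:", paste(names(x$metrics), signif(unlist(x$metrics), 4),
                            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Fit the prediction model (Step 1)
#'
#' Fits a gradient-boosted tree model to the explanatory variables (discrete
#' variables one-hot encoded internally), with hyperparameters selected by
#' fivefold cross-validation. The returned object exposes a pure predict
#' contract - explanatory rows in, real value (regression) or positive-class
#' probability (classification) out - and any object honouring that contract
#' (see [as_predictor()]) can drive the surrogate and planner in its place.
#'
#' For classification the response must be a discrete variable with two
#' categories; the second schema category is the positive class.
#'
#' @param train training `ap_dataset` (no missing cells; impute first).
#' @param task `"regression"` or `"classification"`.
#' @param control an [predictor_control()].
#' @param seed integer seed for fold assignment and tree fitting.
#' @return An object of class `prediction_model`.
#' @export
fit_predictor <- function(train, task = c("regression", "classification"),
                          control = predictor_control(), seed = 1L) {
  task <- match.arg(task)
  schema <- train$schema
  if (n_instances(train) < 20L) stop("need at least 20 training rows")
  if (any(train$mask)) stop("training data has missing cells; impute first")
  yvar <- response_var(schema)
  if (task == "regression") {
    y <- as.numeric(train$data[[yvar]])
    if (stats::sd(y) == 0) stop("response is constant; cannot fit")
    objective <- "reg:squarederror"
    metric <- "rmse"
  } else {
    if (schema$kind[schema$name == yvar] == "discrete") {
      cats <- var_categories(schema, yvar)
      if (length(cats) != 2L)
        stop("classification requires a binary response")
      y <- as.numeric(train$data[[yvar]] == cats[2])
    } else {
      y <- as.numeric(train$data[[yvar]])
      if (!all(y %in% c(0, 1))) stop("numeric response must be 0/1")
    }
    if (length(unique(y)) < 2L) stop("response has a single class; cannot fit")
    objective <- "binary:logistic"
    metric <- "auc"
  }
  X <- encode_onehot(train$data, schema)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  grid <- control$grid
  cv_score <- rep(NA_real_, nrow(grid))
  cv_best_iter <- rep(NA_integer_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                   objective = objective, eval_metric = metric,
                   nthread = control$nthread, seed = derive_seed(seed, g))
    cv <- local_seed(derive_seed(seed, g), suppressWarnings(
      xgboost::xgb.cv(params = params, data = dtrain,
                      nrounds = control$nrounds, nfold = control$nfold,
                      verbose = 0)))
    log <- as.data.frame(cv$evaluation_log)
    col <- paste0("test_", metric, "_mean")
    best <- if (metric == "rmse") which.min(log[[col]]) else which.max(log[[col]])
    cv_score[g] <- log[[col]][best]
    cv_best_iter[g] <- best
  }
  g <- if (metric == "rmse") which.min(cv_score) else which.max(cv_score)
  params <- list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                 objective = objective, nthread = control$nthread,
                 seed = derive_seed(seed, g))
  booster <- local_seed(derive_seed(seed, g),
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = cv_best_iter[g], verbose = 0))
  feat <- colnames(X)
  predict_fn <- function(newdata) {
    Xn <- encode_onehot(newdata, schema)
    stats::predict(booster, xgboost::xgb.DMatrix(Xn[, feat, drop = FALSE]))
  }
  model <- new_prediction_model(task, "xgboost", predict_fn, schema,
                                params = c(params, nrounds = cv_best_iter[g]))
  model$booster <- booster
  model$feature_names <- feat
  model$cv <- data.frame(grid, score = cv_score, best_iter = cv_best_iter)
  model
}

#' Wrap an arbitrary predict function as a prediction model
#'
#' The surrogate and planner are model-agnostic: any function mapping a data
#' frame of explanatory variables to a numeric vector (a real response for
#' regression, a positive-class probability for classification) can stand in
#' for a fitted model. Useful for closed-form stubs in tests and for plugging
#' in engines fitted outside this package.
#'
#' @param fun function(data.frame) -> numeric vector.
#' @param task `"regression"` or `"classification"`.
#' @param schema the [variable_schema()] the function expects.
#' @param rmse_test for regression, the held-out RMSE to use for the
#'   surrogate's fixed response noise (may instead be set later via
#'   [evaluate_predictor()]).
#' @return A `prediction_model`.
#' @export
as_predictor <- function(fun, task = c("regression", "classification"),
                         schema, rmse_test = NULL) {
  task <- match.arg(task)
  model <- new_prediction_model(task, "function", fun, schema)
  if (!is.null(rmse_test)) model$metrics$rmse_test <- rmse_test
  model
}

#' Predict the response for every row of a dataset
#'
#' Prediction is a pure function of the explanatory columns; the returned
#' vector (not the observed response) is what the surrogate is trained on.
#'
#' @param model a `prediction_model`.
#' @param data an `ap_dataset` or data frame with the fitted schema's
#'   explanatory columns.
#' @return Numeric vector, one prediction per row; probabilities in `[0, 1]`
#'   for classification.
#' @export
predict_table <- function(model, data) {
  df <- if (inherits(data, "ap_dataset")) data$data else data
  missing_cols <- setdiff(explanatory_vars(model$schema), names(df))
  if (length(missing_cols))
    stop("data lacks fitted explanatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(numeric(0))
  preds <- as.numeric(model$predict_fn(df))
  if (model$task == "classification" &&
      (any(preds < 0) || any(preds > 1)))
    stop("classification predictor returned values outside [0, 1]")
  preds
}

#' Evaluate a prediction model on held-out data
#'
#' Regression: root-mean-squared error and R-squared. Classification: area
#' under the ROC curve. The held-out RMSE is stored into the model
#' (`model$metrics$rmse_test`) because the surrogate's fixed response noise is
#' defined as half of it.
#'
#' @param model a `prediction_model`.
#' @param test nonempty `ap_dataset` with no missing cells.
#' @return Named list of metrics (`rmse` and `r2`, or `auc`).
#' @export
evaluate_predictor <- function(model, test) {
  if (n_instances(test) == 0L) stop("test set is empty")
  if (any(test$mask)) stop("test data has missing cells; impute first")
  yvar <- response_var(model$schema)
  preds <- predict_table(model, test)
  if (model$task == "regression") {
    y <- as.numeric(test$data[[yvar]])
    rmse <- sqrt(mean((y - preds)^2))
    r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
    model$metrics$rmse_test <- rmse
    model$metrics$r2 <- r2
    list(rmse = rmse, r2 = r2)
  } else {
    sch <- model$schema
    if (sch$kind[sch$name == yvar] == "discrete") {
      cats <- var_categories(sch, yvar)
      y <- as.numeric(test$data[[yvar]] == cats[2])
    } else {
      y <- as.numeric(test$data[[yvar]])
    }
    if (length(unique(y)) < 2L)
      stop("test set has a single response class; AUC undefined")
    auc <- as.numeric(pROC::auc(pROC::roc(y, preds, quiet = TRUE,
                                          direction = "<",
                                          levels = c(0, 1))))
    model$metrics$auc <- auc
    list(auc = auc)
  }
}
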