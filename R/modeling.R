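# Per-region signature models: six classifiers behind one train/predict
# surface, with strict train-only fitting and frozen application.

algo_ids <- function() c("lr", "svm", "rf", "et", "xgb", "lgb")

# small documented hyperparameter grids per algorithm
algo_grid <- function(algorithm) {
  switch(algorithm,
         lr  = list(list()),
         svm = list(list(cost = 0.5), list(cost = 2)),
         rf  = list(list(ntree = 300)),
         et  = list(list(num.trees = 300)),
         xgb = list(list(max_depth = 2, nrounds = 100, eta = 0.1),
                    list(max_depth = 3, nrounds = 100, eta = 0.1)),
         lgb = list(list(max_leaves = 7, nrounds = 100, eta = 0.1),
                    list(max_leaves = 15, nrounds = 100, eta = 0.1)),
         stop("unknown algorithm: ", algorithm))
}

fit_one <- function(X, y, algorithm, hyper, seed) {
  with_seed(seed, function() {
    switch(algorithm,
      lr = {
        df <- data.frame(X, check.names = FALSE)
        df$.y <- y
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      },
      svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                       cost = hyper$cost, probability = TRUE, scale = TRUE),
      rf = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                      ntree = hyper$ntree),
      et = ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(X),
                          num.trees = hyper$num.trees,
                          splitrule = "extratrees", probability = TRUE,
                          num.random.splits = 1, seed = seed),
      xgb = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hyper$max_depth, eta = hyper$eta,
                      nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = hyper$nrounds, verbose = 0),
      lgb = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      grow_policy = "lossguide", max_depth = 0,
                      max_leaves = hyper$max_leaves, tree_method = "hist",
                      eta = hyper$eta, nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = hyper$nrounds, verbose = 0))
  })
}

predict_one <- function(obj, algorithm, X) {
  switch(algorithm,
    lr = as.numeric(predict(obj, newdata = data.frame(X, check.names = FALSE),
                            type = "response")),
    svm = {
      pr <- attr(predict(obj, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    rf = as.numeric(predict(obj, X, type = "prob")[, "1"]),
    et = as.numeric(predict(obj, data = as.data.frame(X))$predictions[, "1"]),
    xgb = ,
    lgb = as.numeric(predict(obj, xgboost::xgb.DMatrix(X, nthread = 1))))
}

#' Train a signature model
#'
#' Fits one of six classifiers (logistic regression `lr`, RBF SVM `svm`,
#' random forest `rf`, extremely randomized trees `et`, depth-wise
#' gradient boosting `xgb`, leaf-wise gradient boosting `lgb`) on training
#' rows only. Hyperparameters come from a small documented grid tuned by
#' seeded k-fold cross-validated AUC; the feature list is frozen at fit
#' time. Deterministic given the seed.
#'
#' @param table training data.frame with a `response` column.
#' @param features character vector: the signature's feature columns.
#' @param algorithm one of `algo_ids()`.
#' @param cv_folds folds for the internal tuning CV (only used when the
#'   grid has more than one point).
#' @param seed RNG seed.
#' @return A `fitted_model`.
#' @export
train_model <- function(table, features, algorithm = "xgb", cv_folds = 5,
                        seed = 1L) {
  if (!algorithm %in% algo_ids()) stop("unknown algorithm: ", algorithm)
  if (length(unique(table$response)) < 2)
    stop("training labels contain a single class")
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature columns: ",
                         paste(head(miss, 5), collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  y <- as.numeric(table$response)
  grid <- algo_grid(algorithm)
  if (length(grid) > 1) {
    folds <- with_seed(seed, function() {
      sample(rep(seq_len(cv_folds), length.out = nrow(X)))
    })
    cv_auc <- vapply(grid, function(h) {
      aucs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
          return(NA_real_)
        m <- fit_one(X[tr, , drop = FALSE], y[tr], algorithm, h, seed)
        auc_mw(predict_one(m, algorithm, X[!tr, , drop = FALSE]), y[!tr])
      }, 0)
      mean(aucs, na.rm = TRUE)
    }, 0)
    hyper <- grid[[which.max(cv_auc)]]
  } else hyper <- grid[[1]]
  obj <- fit_one(X, y, algorithm, hyper, seed)
  train_pred <- predict_one(obj, algorithm, X)
  structure(list(algorithm = algorithm, hyper = hyper, features = features,
                 object = obj, seed = seed,
                 train_pred = setNames(train_pred, rownames(table))),
            class = "fitted_model")
}

#' Predict response probabilities from a fitted model
#'
#' No refitting; missing feature columns are an error (never silently
#' imputed at predict time).
#'
#' @param object a `fitted_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric probabilities in `[0, 1]`.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("missing feature columns at predict time: ",
         paste(head(miss, 5), collapse = ", "))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  p <- predict_one(object$object, object$algorithm, X)
  pmin(pmax(p, 0), 1)
}

#' Compare algorithms on a signature
#'
#' Trains every algorithm on the training cohort and reports AUC with
#' DeLong 95% CI per cohort. The selection rule is the best mean AUC over
#' the non-training cohorts.
#'
#' @param train training data.frame (`response` + features).
#' @param cohorts named list of evaluation data.frames (may include the
#'   training cohort).
#' @param features signature feature names.
#' @param algorithms algorithms to compare (default all six).
#' @param seed RNG seed.
#' @return list with `report` (long data.frame), `ranking`, and `models`.
#' @export
compare_algorithms <- function(train, cohorts, features,
                               algorithms = algo_ids(), seed = 1L) {
  if (length(algorithms) < 1) stop("need at least one algorithm")
  models <- lapply(algorithms, function(a)
    train_model(train, features, a, seed = seed))
  names(models) <- algorithms
  rows <- list()
  for (a in algorithms) {
    for (cn in names(cohorts)) {
      p <- predict(models[[a]], cohorts[[cn]])
      de <- auc_delong(p, cohorts[[cn]]$response)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = a, cohort = cn, auc = de$auc,
        ci_low = de$ci[1], ci_high = de$ci[2])
    }
  }
  report <- do.call(rbind, rows)
  eval_cohorts <- setdiff(names(cohorts), "train")
  if (!length(eval_cohorts)) eval_cohorts <- names(cohorts)
  mean_auc <- vapply(algorithms, function(a) {
    mean(report$auc[report$algorithm == a & report$cohort %in% eval_cohorts])
  }, 0)
  ranking <- algorithms[order(-mean_auc)]
  list(report = report, ranking = ranking,
       mean_validation_auc = setNames(mean_auc, algorithms), models = models)
}
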