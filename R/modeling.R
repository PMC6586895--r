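## The five regression backends, XGBoost tuning, and binarization.

MODEL_KINDS <- c("linear", "lasso", "svm", "random_forest", "xgboost")

#' XGBoost parameter presets
#'
#' `"paper-tuned"` is the coordinate-search optimum used for the headline
#' results (`n_estimators = 500`, `max_depth = 8`, `subsample = 0.75`,
#' `colsample_bytree = 1.0`); `"paper-default"` is the untuned comparison
#' baseline (`n_estimators = 250`, `max_depth = 8`, `subsample = 1.0`,
#' `colsample_bytree = 1.0`).  The learning rate is fixed at 0.1 in both.
#'
#' @param preset preset name.
#' @return named list of parameters.
#' @export
xgboostPreset <- function(preset = c("paper-tuned", "paper-default")) {
  preset <- match.arg(preset)
  switch(preset,
         "paper-tuned" = list(n_estimators = 500, max_depth = 8,
                              subsample = 0.75, colsample_bytree = 1.0,
                              eta = 0.1),
         "paper-default" = list(n_estimators = 250, max_depth = 8,
                                subsample = 1.0, colsample_bytree = 1.0,
                                eta = 0.1))
}

#' Specify a synergy model
#'
#' @param kind one of `"linear"`, `"lasso"`, `"svm"`, `"random_forest"`,
#'   `"xgboost"`.
#' @param params named list of backend parameters; for xgboost see
#'   [xgboostPreset()].
#' @param task `"regression"` or `"classification"` (classification is
#'   used with [binarizeSynergy()]-ed labels for ROC analysis).
#' @param seed integer seed for stochastic backends.
#' @return a model specification list.
#' @export
modelSpec <- function(kind = MODEL_KINDS, params = list(),
                      task = c("regression", "classification"),
                      seed = 1L) {
  kind <- match.arg(kind)
  task <- match.arg(task)
  if (kind == "xgboost")
    params <- utils::modifyList(xgboostPreset("paper-tuned"), params)
  list(kind = kind, params = params, task = task, seed = as.integer(seed))
}

#' Fit a synergy model
#'
#' Dispatches to the backend named by the spec: `stats::lm` (ordinary
#' least squares), `glmnet` (lasso, regularization strength by internal
#' cross-validation unless `lambda` is supplied), `e1071::svm`
#' (epsilon-insensitive regression, radial kernel by default), `ranger`
#' (random forest) or `xgboost`.  Stochastic backends are seeded from the
#' spec, so refitting reproduces identical predictions.
#'
#' @param spec a [modelSpec()].
#' @param X experiments x features matrix (dense or `dgCMatrix`), or a
#'   [SynergyFeatureMatrix-class].
#' @param y response vector (defaults to the synergy scores when `X` is a
#'   feature matrix object); for classification a 0/1 vector.
#' @return a [SynergyModel-class].
#' @export
fitModel <- function(spec, X, y = NULL) {
  groups <- character()
  if (is(X, "SynergyFeatureMatrix")) {
    if (is.null(y)) y <- synergyScores(X)
    groups <- featureGroups(X)
    X <- featureValues(X, sparse = spec$kind == "xgboost")
  }
  stopIfNot(nrow(X) == length(y),
            "X has %d rows but y has %d values", nrow(X), length(y))
  stopIfNot(!anyNA(y) && !anyNA(if (methods::is(X, "sparseMatrix"))
    X@x else X), "fitModel requires complete data")
  classify <- spec$task == "classification"
  fit <- switch(
    spec$kind,
    linear = {
      Xd <- as.matrix(X)
      list(coef = stats::lm.fit(cbind(`(Intercept)` = 1, Xd), y)$coefficients)
    },
    lasso = {
      Xd <- as.matrix(X)
      set.seed(spec$seed)
      if (!is.null(spec$params$lambda))
        glmnet::glmnet(Xd, y, alpha = 1, lambda = spec$params$lambda,
                       family = if (classify) "binomial" else "gaussian")
      else glmnet::cv.glmnet(Xd, y, alpha = 1,
                             family = if (classify) "binomial" else "gaussian")
    },
    svm = {
      set.seed(spec$seed)
      kernel <- spec$params$kernel %||% "radial"
      e1071::svm(as.matrix(X), if (classify) factor(y) else y,
                 kernel = kernel, probability = classify)
    },
    random_forest = {
      df <- data.frame(.y = if (classify) factor(y) else y, as.matrix(X),
                       check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = spec$params$num.trees %||% 500,
        probability = classify, importance = "impurity",
        seed = spec$seed, num.threads = 1L)
    },
    xgboost = {
      p <- spec$params
      d <- xgboost::xgb.DMatrix(
        if (methods::is(X, "sparseMatrix")) X else as.matrix(X), label = y)
      xgboost::xgb.train(
        params = list(max_depth = p$max_depth %||% 8,
                      subsample = p$subsample %||% 1,
                      colsample_bytree = p$colsample_bytree %||% 1,
                      eta = p$eta %||% 0.1,
                      objective = if (classify) "binary:logistic"
                                  else "reg:squarederror",
                      nthread = 1L, tree_method = "hist",
                      seed = spec$seed),
        data = d, nrounds = p$n_estimators %||% 500, verbose = 0)
    },
    stop("unknown model kind: ", spec$kind, call. = FALSE))
  new("SynergyModel", spec = spec, fit = fit,
      featureNames = colnames(X),
      featureGroups = if (length(groups)) groups else
        stats::setNames(rep("ungrouped", ncol(X)), colnames(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict synergy scores (or class probabilities) from a fitted model
#'
#' @param object a [SynergyModel-class].
#' @param newdata experiments x features matrix or
#'   [SynergyFeatureMatrix-class] with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predictions (class-1 probabilities for
#'   classification models).
#' @export
setMethod("predict", "SynergyModel", function(object, newdata, ...) {
  if (is(newdata, "SynergyFeatureMatrix"))
    newdata <- featureValues(newdata, sparse = object@spec$kind == "xgboost")
  missing <- setdiff(object@featureNames, colnames(newdata))
  stopIfNot(length(missing) == 0,
            "newdata lacks %d training feature(s)", length(missing))
  newdata <- newdata[, object@featureNames, drop = FALSE]
  classify <- object@spec$task == "classification"
  fit <- object@fit
  out <- switch(
    object@spec$kind,
    linear = {
      co <- fit$coef
      co[is.na(co)] <- 0
      drop(cbind(1, as.matrix(newdata)) %*% co)
    },
    lasso = {
      p <- stats::predict(fit, newx = as.matrix(newdata),
                          type = if (classify) "response" else "link",
                          s = if (inherits(fit, "cv.glmnet")) "lambda.min"
                              else NULL)
      drop(p)
    },
    svm = {
      if (classify) {
        p <- stats::predict(fit, as.matrix(newdata), probability = TRUE)
        attr(p, "probabilities")[, "1"]
      } else unname(stats::predict(fit, as.matrix(newdata)))
    },
    random_forest = {
      p <- stats::predict(fit,
                          data = data.frame(as.matrix(newdata),
                                            check.names = FALSE),
                          num.threads = 1L)$predictions
      if (classify) p[, "1"] else p
    },
    xgboost = {
      nd <- if (methods::is(newdata, "sparseMatrix")) newdata
            else as.matrix(newdata)
      stats::predict(fit, xgboost::xgb.DMatrix(nd))
    })
  unname(out)
})

#' Binarize synergy scores at the challenge threshold
#'
#' Any score strictly above the threshold maps to 1, all others to 0
#' (threshold 20.0, as used for the ROC analysis of binary synergy calls).
#'
#' @param y numeric synergy scores.
#' @param threshold cut point (default 20).
#' @return integer 0/1 vector.
#' @export
binarizeSynergy <- function(y, threshold = 20) as.integer(y > threshold)

#' Coordinate-descent tuning of the four sensitive XGBoost parameters
#'
#' Mirrors the tuning protocol used for the headline model: hold
#' `n_estimators` fixed and sweep the other axes jointly for the best
#' cross-validation error, freeze the best `max_depth`, then re-sweep the
#' remaining axes (including `n_estimators`).  Returns the best parameter
#' set observed; the evaluated grid and its CV errors are attached as the
#' `"search"` attribute (the argmin over that table by construction).
#'
#' @param X experiments x features matrix or [SynergyFeatureMatrix-class].
#' @param y response (defaults to synergy scores).
#' @param grid named list of candidate vectors for `n_estimators`,
#'   `max_depth`, `subsample`, `colsample_bytree`.
#' @param cvFolds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return named list of tuned parameters (plus `eta = 0.1`).
#' @export
tuneXgboost <- function(X, y = NULL,
                        grid = list(n_estimators = c(250, 500),
                                    max_depth = c(4, 8),
                                    subsample = c(0.75, 1),
                                    colsample_bytree = c(0.75, 1)),
                        cvFolds = 5L, seed = 1L) {
  need <- c("n_estimators", "max_depth", "subsample", "colsample_bytree")
  missing <- setdiff(need, names(grid))
  stopIfNot(length(missing) == 0, "tuning grid lacks axis(es): %s",
            paste(missing, collapse = ", "))
  stopIfNot(all(lengths(grid[need]) >= 1L), "empty tuning grid axis")
  if (is(X, "SynergyFeatureMatrix")) {
    if (is.null(y)) y <- synergyScores(X)
    X <- featureValues(X, sparse = TRUE)
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cvFolds), length(y)))
  cvError <- function(p) {
    errs <- vapply(seq_len(cvFolds), function(f) {
      spec <- modelSpec("xgboost", params = p, seed = seed)
      m <- fitModel(spec, X[folds != f, , drop = FALSE], y[folds != f])
      pred <- predict(m, X[folds == f, , drop = FALSE])
      mean((pred - y[folds == f])^2)
    }, numeric(1))
    mean(errs)
  }
  evalGrid <- function(axes, fixed) {
    tab <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
    tab$error <- vapply(seq_len(nrow(tab)), function(i)
      cvError(utils::modifyList(fixed, as.list(tab[i, , drop = FALSE]))),
      numeric(1))
    tab
  }
  # pass 1: n_estimators held at its first candidate
  fixed1 <- list(n_estimators = grid$n_estimators[[1L]], eta = 0.1)
  pass1 <- evalGrid(grid[c("max_depth", "subsample", "colsample_bytree")],
                    fixed1)
  bestDepth <- pass1$max_depth[which.min(pass1$error)]
  # pass 2: max_depth frozen, re-sweep the rest including n_estimators
  fixed2 <- list(max_depth = bestDepth, eta = 0.1)
  pass2 <- evalGrid(grid[c("n_estimators", "subsample",
                           "colsample_bytree")], fixed2)
  best <- pass2[which.min(pass2$error), , drop = FALSE]
  out <- list(n_estimators = best$n_estimators, max_depth = bestDepth,
              subsample = best$subsample,
              colsample_bytree = best$colsample_bytree, eta = 0.1)
  attr(out, "search") <- list(pass1 = pass1, pass2 = pass2)
  out
}

#' Save / load a fitted model archive
#'
#' Serializes the spec, feature names and groups, and the backend fit (as
#' a raw blob for xgboost boosters) to an RDS archive.
#'
#' @param model a [SynergyModel-class].
#' @param path archive path.
#' @return `path` (save) or the restored [SynergyModel-class] (load).
#' @export
saveModel <- function(model, path) {
  fit <- model@fit
  if (model@spec$kind == "xgboost")
    fit <- xgboost::xgb.save.raw(fit)
  saveRDS(list(version = 1L, spec = model@spec, fit = fit,
               featureNames = model@featureNames,
               featureGroups = model@featureGroups), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  a <- readRDS(path)
  fit <- a$fit
  if (a$spec$kind == "xgboost") fit <- xgboost::xgb.load.raw(fit)
  new("SynergyModel", spec = a$spec, fit = fit,
      featureNames = a$featureNames, featureGroups = a$featureGroups)
}
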