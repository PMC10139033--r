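# Pluggable regression harness: every learner is consumed through a
# two-method interface (fit(x, y) -> model; predict(model, x) -> numeric),
# so cross-validation, external validation and model ranking are agnostic
# to the learner. Adapters to common R learners are provided; the reference
# models (mean, ols, knn1) have no dependencies.

#' Describe a regression model for the harness
#'
#' @param name learner name; one of the built-ins (`"mean"`, `"ols"`,
#'   `"knn"`/`"knn1"`) or an adapter (`"rf"`, `"svm"`, `"rbf"`,
#'   `"adaboost"`, `"mlp"`), or any name when `fit`/`predict` are supplied
#'   directly.
#' @param hyperparameters named list passed to the underlying learner.
#' @param fit,predict optional functions overriding the registry:
#'   `fit(x, y)` returns a fitted object, `predict(model, x)` a numeric
#'   vector.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, hyperparameters = list(),
                       fit = NULL, predict = NULL) {
  if (!nzchar(name)) .err("model name must be non-empty")
  structure(list(name = name, hyperparameters = hyperparameters,
                 fit = fit, predict = predict),
            class = "model_spec")
}

# resolve a model_spec to a list(fit=, predict=)
.resolve_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$fit) && !is.null(spec$predict)) {
    return(list(fit = spec$fit, predict = spec$predict))
  }
  hp <- spec$hyperparameters
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      .err("model '%s' needs the optional package '%s'", spec$name, pkg)
    }
  }
  switch(spec$name,
    mean = list(
      fit = function(x, y) mean(y),
      predict = function(m, x) rep(m, nrow(x))
    ),
    ols = list(
      fit = function(x, y) {
        stats::lm.fit(cbind(1, as.matrix(x)), y)
      },
      predict = function(m, x) {
        b <- m$coefficients
        b[is.na(b)] <- 0
        as.numeric(cbind(1, as.matrix(x)) %*% b)
      }
    ),
    knn1 = ,
    knn = {
      k <- if (is.null(hp$k)) 1L else hp$k
      list(
        fit = function(x, y) list(x = as.matrix(x), y = y, k = k),
        predict = function(m, x) {
          x <- as.matrix(x)
          apply(x, 1, function(q) {
            d <- sqrt(colSums((t(m$x) - q)^2))
            mean(m$y[order(d)[seq_len(m$k)]])
          })
        }
      )
    },
    rf = {
      need("randomForest")
      list(
        fit = function(x, y) {
          do.call(randomForest::randomForest,
                  c(list(x = as.matrix(x), y = y), hp))
        },
        predict = function(m, x) {
          as.numeric(stats::predict(m, as.matrix(x)))
        }
      )
    },
    svm = {
      need("e1071")
      list(
        fit = function(x, y) {
          do.call(e1071::svm, c(list(x = as.matrix(x), y = y), hp))
        },
        predict = function(m, x) as.numeric(stats::predict(m, as.matrix(x)))
      )
    },
    rbf = {
      need("kernlab")
      list(
        fit = function(x, y) {
          do.call(kernlab::gausspr, c(list(x = as.matrix(x), y = y), hp))
        },
        predict = function(m, x) {
          as.numeric(kernlab::predict(m, as.matrix(x)))
        }
      )
    },
    adaboost = {
      need("xgboost")
      list(
        fit = function(x, y) {
          args <- utils::modifyList(
            list(data = as.matrix(x), label = y, nrounds = 50,
                 verbose = 0, objective = "reg:squarederror"), hp)
          do.call(xgboost::xgboost, args)
        },
        predict = function(m, x) as.numeric(stats::predict(m, as.matrix(x)))
      )
    },
    mlp = {
      need("nnet")
      list(
        fit = function(x, y) {
          args <- utils::modifyList(
            list(x = as.matrix(x), y = y, size = 5, linout = TRUE,
                 trace = FALSE, maxit = 200), hp)
          do.call(nnet::nnet, args)
        },
        predict = function(m, x) as.numeric(stats::predict(m, as.matrix(x)))
      )
    },
    .err("unknown model '%s' and no fit/predict supplied", spec$name)
  )
}

#' Cross-validated predictions
#'
#' Trains the model on each fold's complement and predicts the held-out
#' rows, so every row is predicted exactly once by a model that never saw
#' it. Row order is preserved. With `k = n` folds this is leave-one-out.
#'
#' @param ds a [fingerprint_dataset()] (or list with `bits` and `activity`).
#' @param folds integer fold assignment from [make_folds()].
#' @param model a [model_spec()].
#' @return A [prediction_set()] of kind `"cv"` (or `"loo"` when every fold
#'   is a singleton).
#' @export
cross_validate <- function(ds, folds, model) {
  x <- ds$bits
  y <- ds$activity
  if (length(folds) != nrow(x)) .err("folds length must match rows")
  eng <- .resolve_model(model)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    hold <- which(folds == f)
    tr <- which(folds != f)
    fit <- tryCatch(eng$fit(x[tr, , drop = FALSE], y[tr]),
                    error = function(e) .err("model failed on fold %s: %s",
                                             f, conditionMessage(e)))
    p <- tryCatch(eng$predict(fit, x[hold, , drop = FALSE]),
                  error = function(e) .err("prediction failed on fold %s: %s",
                                           f, conditionMessage(e)))
    pred[hold] <- p
  }
  kind <- if (max(tabulate(folds)) == 1L) "loo" else "cv"
  prediction_set(y, pred, kind = kind, train_observed = y,
                 ids = ds$ids)
}

#' Fit on a training set and predict an external set
#'
#' @param train,test [fingerprint_dataset()]s with identical columns.
#' @param model a [model_spec()].
#' @return A [prediction_set()] of kind `"external"` carrying the
#'   training-set mean, sum of squares and size for the QFn statistics.
#' @export
fit_predict_external <- function(train, test, model) {
  if (ncol(train$bits) != ncol(test$bits) ||
      !identical(colnames(train$bits), colnames(test$bits))) {
    .err("train and test fingerprint columns do not match")
  }
  eng <- .resolve_model(model)
  fit <- eng$fit(train$bits, train$activity)
  pred <- eng$predict(fit, test$bits)
  prediction_set(test$activity, pred, kind = "external",
                 train_observed = train$activity, ids = test$ids)
}

#' Rank candidate models by cross-validated Q2, then MAE
#'
#' Primary sort: descending cross-validated Q2. Ties broken by ascending
#' MAE, then alphabetically by model name for determinism.
#'
#' @param reports named list of [validation_report()]s, each carrying
#'   `q2_cv` (or `r2` of a CV-kind report) and `mae`.
#' @return A data frame ordered best-first with columns `name`, `q2_cv`,
#'   `mae`.
#' @export
select_best_model <- function(reports) {
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    .err("reports must be a named list")
  }
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    q2 <- if (!is.null(r$q2_cv) && !is.na(r$q2_cv)) r$q2_cv else r$r2
    if (is.null(q2) || is.na(q2) || is.null(r$mae) || is.na(r$mae)) {
      .err("report '%s' lacks q2_cv or mae", nm)
    }
    data.frame(name = nm, q2_cv = q2, mae = r$mae, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(-df$q2_cv, df$mae, df$name), , drop = FALSE]
}
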