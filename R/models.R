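# Model registry for the evaluation harness.
#
# A model contract is a list with two functions:
#   fit(x, y)        -> fitted state   (x: samples x genes matrix; y: numeric
#                                       ages or a 3-level age-group factor)
#   predict(state, x) -> predictions   (numeric, or factor with y's levels)
# Contracts must be deterministic given the RNG state the harness sets, so
# seeded libraries (xgboost, ranger) take their seed from the harness RNG.

#' Look up or validate a model contract
#'
#' The default model is a gradient-boosted decision-tree ensemble (xgboost,
#' library defaults: 100 rounds, depth 6, eta 0.3, histogram trees, one
#' thread). Other registered names cover common alternatives; a custom
#' contract (a list with `fit` and `predict` functions) is accepted
#' anywhere a model name is, which is how baseline and oracle models are
#' plugged in.
#'
#' @param spec A registered model name (see [model_names()]) or a custom
#'   contract list.
#' @param task `"regression"` or `"classification"`.
#' @return A model contract list.
#' @export
age_model <- function(spec = "xgboost", task = c("regression", "classification")) {
  task <- match.arg(task)
  if (is.list(spec)) {
    if (!all(c("fit", "predict") %in% names(spec)) ||
        !is.function(spec$fit) || !is.function(spec$predict)) {
      stop_config("model", "a custom model needs `fit` and `predict` functions")
    }
    return(spec)
  }
  registry <- model_registry(task)
  if (!spec %in% names(registry)) {
    stop_config("model", paste0("unknown model `", spec, "`; registered: ",
                                paste(names(registry), collapse = ", ")))
  }
  registry[[spec]]
}

#' @rdname age_model
#' @export
model_names <- function(task = c("regression", "classification")) {
  names(model_registry(match.arg(task)))
}

model_registry <- function(task) {
  if (task == "regression") {
    list(
      xgboost = xgb_contract("reg:squarederror"),
      linear = list(
        fit = function(x, y) stats::lm.fit(cbind(1, x), y),
        predict = function(state, x) as.vector(cbind(1, x) %*% state$coefficients)),
      mean_baseline = list(
        fit = function(x, y) mean(y),
        predict = function(state, x) rep(state, nrow(x))),
      random_forest = ranger_contract(classification = FALSE),
      svm = svm_contract())
  } else {
    list(
      xgboost = xgb_contract("multi:softmax"),
      majority_baseline = list(
        fit = function(x, y) {
          tab <- table(y)
          factor(names(tab)[which.max(tab)], levels = levels(y))
        },
        predict = function(state, x) rep(state, nrow(x))),
      random_forest = ranger_contract(classification = TRUE),
      lda = lda_contract(),
      svm = svm_contract())
  }
}

xgb_contract <- function(objective) {
  classify <- objective == "multi:softmax"
  list(
    fit = function(x, y) {
      seed <- sample.int(.Machine$integer.max, 1)
      label <- if (classify) as.integer(y) - 1L else y
      params <- list(objective = objective, tree_method = "hist",
                     nthread = 1, seed = seed, max_depth = 6, eta = 0.3)
      if (classify) params$num_class <- nlevels(y)
      dtrain <- xgboost::xgb.DMatrix(x, label = label, nthread = 1)
      list(booster = xgboost::xgb.train(params = params, data = dtrain,
                                        nrounds = 100, verbose = 0),
           levels = if (classify) levels(y))
    },
    predict = function(state, x) {
      p <- predict(state$booster, xgboost::xgb.DMatrix(x, nthread = 1))
      if (!is.null(state$levels)) factor(state$levels[p + 1], levels = state$levels) else p
    })
}

ranger_contract <- function(classification) {
  list(
    fit = function(x, y) {
      if (!requireNamespace("ranger", quietly = TRUE)) {
        stop_config("model", "model `random_forest` needs the ranger package")
      }
      df <- as.data.frame(x); df$.y <- y
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.threads = 1, seed = sample.int(.Machine$integer.max, 1))
    },
    predict = function(state, x) predict(state, as.data.frame(x),
                                         num.threads = 1)$predictions)
}

lda_contract <- function() {
  list(
    fit = function(x, y) {
      if (!requireNamespace("MASS", quietly = TRUE)) {
        stop_config("model", "model `lda` needs the MASS package")
      }
      keep <- apply(x, 2, sd) > 0
      list(fit = MASS::lda(x[, keep, drop = FALSE], grouping = y), keep = keep)
    },
    predict = function(state, x) predict(state$fit, x[, state$keep, drop = FALSE])$class)
}

svm_contract <- function() {
  list(
    fit = function(x, y) {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop_config("model", "model `svm` needs the e1071 package")
      }
      e1071::svm(x, y)
    },
    predict = function(state, x) predict(state, x))
}
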