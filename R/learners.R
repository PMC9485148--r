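#' Encode staging records as numeric features
#'
#' Machine-learning models use sex and the seven tooth stages as
#' independent variables. Sex is coded 0 (female) / 1 (male); stages
#' are coded ordinally A = 1 ... H = 8 (staging is ordinal, so trees
#' can split on thresholds), with missing teeth coded 0, below A.
#'
#' @param cohort a cohort tibble.
#' @return a numeric matrix with columns `sex`, `t31`...`t37`.
#' @examples
#' coh <- generate_cohort(seed = 3)$cohort
#' head(encode_features(coh))
#' @export
encode_features <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  m <- cbind(
    sex = as.numeric(cohort$sex == "male"),
    vapply(tooth_columns(), function(cl) as.numeric(stage_code(cohort[[cl]])),
           numeric(nrow(cohort)))
  )
  colnames(m) <- c("sex", tooth_columns())
  m
}

learner_names <- function() {
  c("decision_tree", "random_forest", "extra_trees", "adaboost_r2",
    "gbdt", "knn")
}

#' Train one of the native learners on a cohort
#'
#' Fits the requested learner on [encode_features()] of the cohort with
#' the package's default (published) hyperparameters: decision tree
#' (depth 10, 50 leaves, min leaf 2), AdaBoost.R2 (100 rounds, learning
#' rate 1, decision-tree base), random forest and extra trees (100
#' trees, min leaf 1), GBDT (100 trees, learning rate 0.1, no
#' subsampling, min leaf 1) and 5-nearest neighbours.
#'
#' @param cohort a cohort tibble (typically the training split).
#' @param learner one of `"decision_tree"`, `"random_forest"`,
#'   `"extra_trees"`, `"adaboost_r2"`, `"gbdt"`, `"knn"`.
#' @param seed integer seed for the stochastic learners.
#' @param ... overrides passed to the underlying fit function.
#' @return the fitted model with attribute `"learner"`.
#' @seealso [predict_ages()]
#' @export
train_learner <- function(cohort, learner = learner_names(), seed = 1L, ...) {
  learner <- match.arg(learner)
  x <- encode_features(cohort)
  y <- cohort$age
  model <- switch(
    learner,
    decision_tree = fit_regression_tree(x, y, ...),
    random_forest = fit_forest(x, y, variant = "random_forest", seed = seed, ...),
    extra_trees = fit_forest(x, y, variant = "extra_trees", seed = seed, ...),
    adaboost_r2 = fit_adaboost_r2(x, y, seed = seed, ...),
    gbdt = fit_gbdt(x, y, seed = seed, ...),
    knn = fit_knn(x, y, ...)
  )
  attr(model, "learner") <- learner
  model
}

#' Predict dental ages for a cohort with a fitted learner
#'
#' @param model a model from [train_learner()] (or any of the native
#'   fit functions).
#' @param cohort a cohort tibble.
#' @return a tibble with columns `id`, `sex`, `age` (CA), `dental_age`
#'   (DA) and `method`.
#' @export
predict_ages <- function(model, cohort) {
  cohort <- tibble::as_tibble(cohort)
  tibble::tibble(
    id = cohort$id, sex = cohort$sex, age = cohort$age,
    dental_age = as.numeric(predict(model, encode_features(cohort))),
    method = attr(model, "learner") %||% class(model)[1]
  )
}

# ---- model JSON serialization ----------------------------------------

tree_to_list_ <- function(tr) {
  list(
    type = "tree",
    feature = tr$feature, threshold = tr$threshold, left = tr$left,
    right = tr$right, value = tr$value, n_node = tr$n_node,
    depth = tr$depth, is_leaf = tr$is_leaf,
    control = unclass(tr$control), splitter = tr$splitter,
    mtry = tr$mtry, feature_names = tr$feature_names
  )
}

tree_from_list_ <- function(obj) {
  structure(
    list(
      feature = as.integer(obj$feature), threshold = as.numeric(obj$threshold),
      left = as.integer(obj$left), right = as.integer(obj$right),
      value = as.numeric(obj$value), n_node = as.integer(obj$n_node),
      depth = as.integer(obj$depth), is_leaf = as.logical(obj$is_leaf),
      control = do.call(tree_control, obj$control),
      splitter = obj$splitter, mtry = as.integer(obj$mtry),
      feature_names = obj$feature_names
    ),
    class = "dae_tree"
  )
}

#' Save and load fitted models as JSON
#'
#' Trees and tree ensembles (and KNN) serialize to a versioned JSON
#' dump of their structure, leaf values and weights; loading reproduces
#' a model with identical predictions.
#'
#' @param model a fitted `dae_tree`, `dae_gbdt`, `dae_forest`,
#'   `dae_adaboost` or `dae_knn`.
#' @param path file path of the JSON dump.
#' @return `load_model()` returns the reconstructed model.
#' @export
save_model <- function(model, path) {
  obj <- switch(
    class(model)[1],
    dae_tree = tree_to_list_(model),
    dae_gbdt = list(
      type = "gbdt", init = model$init,
      learning_rate = model$learning_rate, subsample = model$subsample,
      train_mse = model$train_mse, control = unclass(model$control),
      trees = purrr::map(model$trees, tree_to_list_)
    ),
    dae_forest = list(
      type = "forest", variant = model$variant, bootstrap = model$bootstrap,
      seed = model$seed, control = unclass(model$control),
      trees = purrr::map(model$trees, tree_to_list_)
    ),
    dae_adaboost = list(
      type = "adaboost", alphas = model$alphas,
      learning_rate = model$learning_rate, seed = model$seed,
      stopped_early = model$stopped_early, control = unclass(model$control),
      trees = purrr::map(model$trees, tree_to_list_)
    ),
    dae_knn = list(
      type = "knn", k = model$k, x = model$x, y = model$y,
      feature_names = colnames(model$x)
    ),
    abort(paste0("cannot serialize model of class ", class(model)[1]))
  )
  obj$format_version <- 1L
  obj$learner <- attr(model, "learner")
  # 17 significant digits: lossless round trip for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  model <- switch(
    obj$type,
    tree = tree_from_list_(obj),
    gbdt = structure(
      list(init = obj$init, trees = purrr::map(obj$trees, tree_from_list_),
           learning_rate = obj$learning_rate, subsample = obj$subsample,
           train_mse = as.numeric(obj$train_mse),
           control = do.call(tree_control, obj$control)),
      class = "dae_gbdt"
    ),
    forest = structure(
      list(trees = purrr::map(obj$trees, tree_from_list_),
           variant = obj$variant, bootstrap = obj$bootstrap,
           control = do.call(tree_control, obj$control), seed = obj$seed),
      class = "dae_forest"
    ),
    adaboost = structure(
      list(trees = purrr::map(obj$trees, tree_from_list_),
           alphas = as.numeric(obj$alphas),
           control = do.call(tree_control, obj$control),
           learning_rate = obj$learning_rate, seed = obj$seed,
           stopped_early = obj$stopped_early),
      class = "dae_adaboost"
    ),
    knn = {
      xm <- if (is.matrix(obj$x)) obj$x else do.call(rbind, obj$x)
      colnames(xm) <- obj$feature_names
      fit_knn(xm, as.numeric(obj$y), k = obj$k)
    },
    abort(paste0("unknown model type: ", obj$type))
  )
  if (!is.null(obj$learner)) attr(model, "learner") <- obj$learner
  model
}
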