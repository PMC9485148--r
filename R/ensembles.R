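#' Gradient boosting decision trees (GBDT)
#'
#' Stagewise additive regression under squared loss: the model starts
#' at the training mean, then each round fits a CART tree to the
#' current residuals and adds it scaled by the learning rate. With a
#' learning rate of at most 1 and trees fit by squared-error reduction,
#' the training MSE is nonincreasing across rounds; the per-round
#' training MSE path is stored on the fitted model.
#'
#' @param x numeric feature matrix.
#' @param y numeric response (ages in years).
#' @param n_trees number of boosting rounds.
#' @param learning_rate shrinkage applied to every tree's contribution.
#' @param subsample fraction of rows (sampled without replacement)
#'   used per round; 1 disables stochastic subsampling.
#' @param control [tree_control()] for the base trees (leaves of size
#'   1 are allowed by default, as is conventional for boosted trees).
#' @param seed integer seed; only consulted when `subsample < 1`.
#' @return an object of class `dae_gbdt`.
#' @examples
#' coh <- generate_cohort(seed = 3)$cohort
#' fit <- fit_gbdt(encode_features(coh), coh$age, n_trees = 10)
#' all(diff(fit$train_mse) <= 1e-12)
#' @export
fit_gbdt <- function(x, y, n_trees = 100L, learning_rate = 0.1,
                     subsample = 1,
                     control = tree_control(min_leaf = 1L),
                     seed = NULL) {
  stopifnot(n_trees >= 1, learning_rate > 0, subsample > 0, subsample <= 1)
  x <- as.matrix(x)
  if (length(y) < 2) abort("need at least two training points")
  fit_one <- function() {
    init <- mean(y)
    pred <- rep(init, length(y))
    trees <- vector("list", n_trees)
    train_mse <- numeric(n_trees)
    n <- length(y)
    for (m in seq_len(n_trees)) {
      resid <- y - pred
      if (subsample < 1) {
        idx <- sample.int(n, max(1L, floor(subsample * n)))
        tr <- fit_regression_tree(x[idx, , drop = FALSE], resid[idx],
                                  control = control)
      } else {
        tr <- fit_regression_tree(x, resid, control = control)
      }
      pred <- pred + learning_rate * predict_tree_matrix_(tr, x)
      trees[[m]] <- tr
      train_mse[m] <- mean((y - pred)^2)
    }
    structure(
      list(init = init, trees = trees, learning_rate = learning_rate,
           subsample = subsample, train_mse = train_mse, control = control),
      class = "dae_gbdt"
    )
  }
  if (subsample < 1 && !is.null(seed)) with_seed_(seed, fit_one()) else fit_one()
}

#' @export
predict.dae_gbdt <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  pred <- rep(object$init, nrow(xm))
  for (tr in object$trees) {
    pred <- pred + object$learning_rate * predict_tree_matrix_(tr, xm)
  }
  pred
}

#' @export
print.dae_gbdt <- function(x, ...) {
  cat(sprintf("<dae_gbdt> %d trees, learning rate %.3g, final train MSE %.4f\n",
              length(x$trees), x$learning_rate, tail(x$train_mse, 1)))
  invisible(x)
}

#' @method glance dae_gbdt
#' @export
glance.dae_gbdt <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees), learning_rate = x$learning_rate,
    subsample = x$subsample, train_mse = tail(x$train_mse, 1)
  )
}

#' Random forest / extra trees regression
#'
#' Averages `n_trees` CART trees. The `random_forest` variant fits each
#' tree on a bootstrap ("put-back") resample with exhaustive split
#' search; the `extra_trees` variant fits on the full sample with one
#' uniformly random threshold per candidate feature. Predictions are
#' the mean of the trees' predictions, deterministic given the seed.
#'
#' @inheritParams fit_gbdt
#' @param variant `"random_forest"` or `"extra_trees"`.
#' @param bootstrap resample rows with replacement per tree; defaults
#'   to `TRUE` for random forest and `FALSE` for extra trees.
#' @param mtry features considered per node (default: all).
#' @param seed integer seed for resampling/threshold randomness.
#' @return an object of class `dae_forest`.
#' @export
fit_forest <- function(x, y, n_trees = 100L,
                       variant = c("random_forest", "extra_trees"),
                       bootstrap = NULL, mtry = NULL,
                       control = tree_control(min_leaf = 1L),
                       seed = 1L) {
  variant <- match.arg(variant)
  bootstrap <- bootstrap %||% (variant == "random_forest")
  stopifnot(n_trees >= 1)
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("empty training data")
  splitter <- if (variant == "extra_trees") "random" else "best"
  trees <- with_seed_(seed, {
    purrr::map(seq_len(n_trees), function(i) {
      if (bootstrap) {
        idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
        fit_regression_tree(x[idx, , drop = FALSE], y[idx], control = control,
                            splitter = splitter, mtry = mtry)
      } else {
        fit_regression_tree(x, y, control = control,
                            splitter = splitter, mtry = mtry)
      }
    })
  })
  structure(
    list(trees = trees, variant = variant, bootstrap = bootstrap,
         control = control, seed = seed),
    class = "dae_forest"
  )
}

#' @export
predict.dae_forest <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  preds <- vapply(object$trees, predict_tree_matrix_, numeric(nrow(xm)), xm = xm)
  if (nrow(xm) == 1) mean(preds) else rowMeans(preds)
}

#' @export
print.dae_forest <- function(x, ...) {
  cat(sprintf("<dae_forest> %s, %d trees, bootstrap = %s\n",
              x$variant, length(x$trees), x$bootstrap))
  invisible(x)
}

#' @method glance dae_forest
#' @export
glance.dae_forest <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_trees = length(x$trees),
                 bootstrap = x$bootstrap, seed = x$seed)
}

#' AdaBoost.R2 boosted regression trees
#'
#' Drucker's AdaBoost.R2 with linear loss. Each round draws a weighted
#' resample of the training data (when the weights are exactly uniform
#' the identity sample is used, so a one-round ensemble reduces to the
#' base tree), fits a CART tree, computes per-sample linear losses
#' scaled by the largest absolute error, and the weighted average loss
#' `Lbar`. Rounds with `Lbar >= 0.5` stop boosting (the round is kept
#' only if it is the first). Otherwise `beta = Lbar / (1 - Lbar)`
#' updates the sample weights (`w <- w * beta^(lr * (1 - L))`) and the
#' learner enters the ensemble with weight `lr * log(1 / beta)`.
#' Prediction is the weighted median of the learners' predictions.
#'
#' @inheritParams fit_gbdt
#' @param n_estimators maximum number of boosting rounds.
#' @param learning_rate shrinkage of the weight updates.
#' @param control [tree_control()] for the base trees.
#' @param seed integer seed for the weighted resampling.
#' @return an object of class `dae_adaboost`; element `stopped_early`
#'   records whether boosting halted before `n_estimators` rounds.
#' @export
fit_adaboost_r2 <- function(x, y, n_estimators = 100L, learning_rate = 1,
                            control = tree_control(), seed = 1L) {
  stopifnot(n_estimators >= 1, learning_rate > 0)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("need at least two training points")
  eps <- 1e-10
  with_seed_(seed, {
    w <- rep(1 / n, n)
    trees <- list()
    alphas <- numeric(0)
    stopped_early <- FALSE
    for (m in seq_len(n_estimators)) {
      uniform <- diff(range(w)) < 1e-15
      idx <- if (uniform) seq_len(n) else {
        sample.int(n, n, replace = TRUE, prob = w)
      }
      tr <- fit_regression_tree(x[idx, , drop = FALSE], y[idx],
                                control = control)
      pred <- predict_tree_matrix_(tr, x)
      err <- abs(y - pred)
      d <- max(err)
      if (d < eps) {
        # perfect fit: dominate the ensemble and stop
        trees[[length(trees) + 1L]] <- tr
        alphas <- c(alphas, learning_rate * log(1 / eps))
        stopped_early <- m < n_estimators
        break
      }
      loss <- err / d
      lbar <- sum(w * loss)
      if (lbar >= 0.5) {
        if (length(trees) == 0) {
          trees[[1L]] <- tr
          alphas <- learning_rate * log((1 - lbar) / max(lbar, eps))
        }
        stopped_early <- TRUE
        break
      }
      beta <- max(lbar / (1 - lbar), eps)
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, learning_rate * log(1 / beta))
      w <- w * beta^(learning_rate * (1 - loss))
      w <- w / sum(w)
    }
    structure(
      list(trees = trees, alphas = alphas, control = control,
           learning_rate = learning_rate, seed = seed,
           stopped_early = stopped_early),
      class = "dae_adaboost"
    )
  })
}

#' @export
predict.dae_adaboost <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  k <- length(object$trees)
  preds <- vapply(object$trees, predict_tree_matrix_, numeric(nrow(xm)), xm = xm)
  preds <- matrix(preds, nrow = nrow(xm), ncol = k)
  a <- object$alphas
  half <- sum(a) / 2
  out <- numeric(nrow(xm))
  for (i in seq_len(nrow(xm))) {
    ord <- order(preds[i, ])
    cum <- cumsum(a[ord])
    out[i] <- preds[i, ord[which(cum >= half)[1]]]
  }
  out
}

#' @export
print.dae_adaboost <- function(x, ...) {
  cat(sprintf("<dae_adaboost> %d learners%s\n", length(x$trees),
              if (x$stopped_early) " (stopped early)" else ""))
  invisible(x)
}

#' @method glance dae_adaboost
#' @export
glance.dae_adaboost <- function(x, ...) {
  tibble::tibble(n_learners = length(x$trees),
                 learning_rate = x$learning_rate,
                 stopped_early = x$stopped_early, seed = x$seed)
}
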