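#' K-nearest-neighbour age regression
#'
#' Predicts a query's age as the mean age of its `k` nearest training
#' subjects under Euclidean distance on the encoded features (sex code
#' plus seven ordinal stage codes). Ties at the k-th distance are
#' broken by training-set order.
#'
#' @param x numeric feature matrix (training).
#' @param y numeric response (ages).
#' @param k number of neighbours; must not exceed the training size.
#' @return an object of class `dae_knn`.
#' @examples
#' coh <- generate_cohort(seed = 3)$cohort
#' fit <- fit_knn(encode_features(coh), coh$age, k = 5)
#' head(predict(fit, encode_features(coh)))
#' @export
fit_knn <- function(x, y, k = 5L) {
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("empty training data")
  if (k < 1 || k > nrow(x)) abort("`k` must be between 1 and the training size")
  structure(
    list(x = x, y = y, k = as.integer(k)),
    class = "dae_knn"
  )
}

#' @export
predict.dae_knn <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  train <- object$x
  tsq <- rowSums(train^2)
  out <- numeric(nrow(xm))
  for (i in seq_len(nrow(xm))) {
    d2 <- tsq - 2 * drop(train %*% xm[i, ]) + sum(xm[i, ]^2)
    nn <- order(d2, method = "radix")[seq_len(object$k)] # stable: ties by order
    out[i] <- mean(object$y[nn])
  }
  out
}

#' @export
print.dae_knn <- function(x, ...) {
  cat(sprintf("<dae_knn> k = %d, n = %d\n", x$k, nrow(x$x)))
  invisible(x)
}

#' @method glance dae_knn
#' @export
glance.dae_knn <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$x))
}
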