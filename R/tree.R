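#' Regression-tree hyperparameters
#'
#' Controls for the native CART regression tree. Defaults mirror a
#' common published configuration for staged-tooth age models: depth
#' at most 10, at most 50 leaves, internal nodes need at least 2
#' samples to split, leaves hold at least `min_leaf` samples, and a
#' split must decrease the node's summed squared error by more than
#' `min_impurity_decrease`.
#'
#' @param max_depth maximum tree depth (root = depth 0).
#' @param max_leaf_nodes leaf budget, enforced by best-first growth
#'   (the split with the greatest impurity decrease anywhere on the
#'   frontier is taken first).
#' @param min_split minimum node size to consider splitting.
#' @param min_leaf minimum samples per leaf.
#' @param min_impurity_decrease minimum summed-squared-error decrease
#'   for a split to be admitted.
#' @return a list of class `tree_control`.
#' @export
tree_control <- function(max_depth = 10L, max_leaf_nodes = 50L,
                         min_split = 2L, min_leaf = 2L,
                         min_impurity_decrease = 0) {
  stopifnot(max_depth >= 1, max_leaf_nodes >= 1, min_split >= 2,
            min_leaf >= 1, min_impurity_decrease >= 0)
  structure(
    list(max_depth = as.integer(max_depth),
         max_leaf_nodes = as.integer(max_leaf_nodes),
         min_split = as.integer(min_split),
         min_leaf = as.integer(min_leaf),
         min_impurity_decrease = min_impurity_decrease),
    class = "tree_control"
  )
}

# Best split of one node. Returns NULL if no admissible split exists.
# splitter "best": exhaustive over midpoints of consecutive distinct
# values; "random": one uniform random threshold per feature (the
# extra-trees variant). Ties in impurity decrease break toward the
# lower feature index, then the lower threshold.
node_best_split_ <- function(xm, y, idx, ctrl, splitter = "best",
                             mtry = ncol(xm)) {
  m <- length(idx)
  if (m < ctrl$min_split || m < 2L * ctrl$min_leaf) return(NULL)
  ysub <- y[idx]
  stot <- sum(ysub)
  base_sse <- stot^2 / m
  feats <- if (mtry < ncol(xm)) sort(sample.int(ncol(xm), mtry)) else seq_len(ncol(xm))
  best <- NULL
  best_dec <- max(ctrl$min_impurity_decrease, 1e-10)
  for (j in feats) {
    xj <- xm[idx, j]
    if (splitter == "best") {
      ord <- order(xj, method = "radix")
      xs <- xj[ord]
      cs <- cumsum(ysub[ord])
      nl <- seq_len(m - 1L)
      valid <- (xs[-m] < xs[-1L]) & nl >= ctrl$min_leaf &
        (m - nl) >= ctrl$min_leaf
      if (!any(valid)) next
      sl <- cs[-m]
      dec <- sl^2 / nl + (stot - sl)^2 / (m - nl) - base_sse
      dec[!valid] <- -Inf
      i <- which.max(dec)
      if (dec[i] > best_dec) {
        best_dec <- dec[i]
        best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2,
                     decrease = dec[i])
      }
    } else {
      lo <- min(xj); hi <- max(xj)
      if (lo >= hi) next
      thr <- runif(1, lo, hi)
      left <- xj <= thr
      nl <- sum(left)
      if (nl < ctrl$min_leaf || m - nl < ctrl$min_leaf) next
      sl <- sum(ysub[left])
      dec <- sl^2 / nl + (stot - sl)^2 / (m - nl) - base_sse
      if (dec > best_dec) {
        best_dec <- dec
        best <- list(feature = j, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

#' Fit a CART regression tree
#'
#' Binary regression tree minimizing squared error, grown best-first:
#' at each step the frontier leaf whose best split yields the greatest
#' decrease in summed squared error is expanded, until the leaf budget,
#' depth limit or minimum-size rules stop growth. Leaf predictions are
#' training-response means. The fit is deterministic for
#' `splitter = "best"`; `splitter = "random"` draws one uniform
#' threshold per candidate feature (extra-trees style) and uses the
#' caller's RNG stream.
#'
#' @param x numeric feature matrix (e.g. from [encode_features()]).
#' @param y numeric response (ages in years).
#' @param control a [tree_control()].
#' @param splitter `"best"` or `"random"`.
#' @param mtry number of features sampled per node (default: all).
#' @return an object of class `dae_tree`.
#' @examples
#' coh <- generate_cohort(seed = 3)$cohort
#' tr <- fit_regression_tree(encode_features(coh), coh$age)
#' glance(tr)
#' @export
fit_regression_tree <- function(x, y, control = tree_control(),
                                splitter = c("best", "random"),
                                mtry = NULL) {
  splitter <- match.arg(splitter)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0) abort("empty training data")
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  mtry <- as.integer(mtry %||% ncol(x))
  stopifnot(mtry >= 1, mtry <= ncol(x))
  ctrl <- control

  cap <- 2L * ctrl$max_leaf_nodes
  feature <- integer(cap); threshold <- numeric(cap)
  left <- integer(cap); right <- integer(cap)
  value <- numeric(cap); n_node <- integer(cap); depth <- integer(cap)
  is_leaf <- rep(TRUE, cap)

  node_idx <- vector("list", cap)
  node_idx[[1L]] <- seq_along(y)
  value[1L] <- mean(y); n_node[1L] <- length(y); depth[1L] <- 0L
  n_nodes <- 1L
  n_leaves <- 1L

  # frontier: candidate splits keyed by node id (ascending insertion order)
  frontier_ids <- integer(0)
  frontier_dec <- numeric(0)
  frontier_split <- list()

  push_candidate <- function(id) {
    if (depth[id] >= ctrl$max_depth) return()
    sp <- node_best_split_(x, y, node_idx[[id]], ctrl, splitter, mtry)
    if (is.null(sp)) return()
    frontier_ids <<- c(frontier_ids, id)
    frontier_dec <<- c(frontier_dec, sp$decrease)
    frontier_split[[length(frontier_ids)]] <<- sp
  }
  push_candidate(1L)

  while (n_leaves < ctrl$max_leaf_nodes && length(frontier_ids) > 0) {
    k <- which.max(frontier_dec) # first max -> smallest node id on ties
    id <- frontier_ids[k]
    sp <- frontier_split[[k]]
    frontier_ids <- frontier_ids[-k]
    frontier_dec <- frontier_dec[-k]
    frontier_split <- frontier_split[-k]

    idx <- node_idx[[id]]
    go_left <- x[idx, sp$feature] <= sp$threshold
    lid <- n_nodes + 1L; rid <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    node_idx[[lid]] <- idx[go_left]
    node_idx[[rid]] <- idx[!go_left]
    node_idx[id] <- list(NULL) # free the parent's index cache

    feature[id] <- sp$feature; threshold[id] <- sp$threshold
    left[id] <- lid; right[id] <- rid; is_leaf[id] <- FALSE
    for (cid in c(lid, rid)) {
      ci <- node_idx[[cid]]
      value[cid] <- mean(y[ci]); n_node[cid] <- length(ci)
      depth[cid] <- depth[id] + 1L
    }
    n_leaves <- n_leaves + 1L
    push_candidate(lid)
    push_candidate(rid)
  }

  keep <- seq_len(n_nodes)
  structure(
    list(
      feature = feature[keep], threshold = threshold[keep],
      left = left[keep], right = right[keep], value = value[keep],
      n_node = n_node[keep], depth = depth[keep], is_leaf = is_leaf[keep],
      control = ctrl, splitter = splitter, mtry = mtry,
      feature_names = colnames(x)
    ),
    class = "dae_tree"
  )
}

predict_tree_matrix_ <- function(tree, xm) {
  node <- rep(1L, nrow(xm))
  for (i in seq_along(tree$feature)) {
    if (tree$is_leaf[i]) next
    at <- which(node == i)
    if (length(at) == 0) next
    go_left <- xm[at, tree$feature[i]] <= tree$threshold[i]
    node[at] <- ifelse(go_left, tree$left[i], tree$right[i])
  }
  tree$value[node]
}

#' @export
predict.dae_tree <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  predict_tree_matrix_(object, xm)
}

#' @export
print.dae_tree <- function(x, ...) {
  cat(sprintf("<dae_tree> %d nodes (%d leaves), depth %d, splitter = %s\n",
              length(x$feature), sum(x$is_leaf), max(x$depth), x$splitter))
  invisible(x)
}

#' @method glance dae_tree
#' @export
glance.dae_tree <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$feature), n_leaves = sum(x$is_leaf),
    depth = max(x$depth), min_leaf_n = min(x$n_node[x$is_leaf]),
    splitter = x$splitter
  )
}

#' Structural audit of a fitted tree
#'
#' Verifies that a fitted tree honours its configuration: depth and
#' leaf-count limits and the minimum leaf size.
#'
#' @param tree a `dae_tree`.
#' @return `TRUE` invisibly; errors describing any violation otherwise.
#' @export
audit_tree <- function(tree) {
  stopifnot(inherits(tree, "dae_tree"))
  ctrl <- tree$control
  if (max(tree$depth) > ctrl$max_depth) abort("tree exceeds max_depth")
  if (sum(tree$is_leaf) > ctrl$max_leaf_nodes) abort("tree exceeds max_leaf_nodes")
  if (min(tree$n_node[tree$is_leaf]) < ctrl$min_leaf) abort("leaf below min_leaf")
  invisible(TRUE)
}
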