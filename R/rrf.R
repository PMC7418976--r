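# Multi-output random regression forest.  Classical CART regression trees
# with bootstrap resampling and per-node random feature subsets; the split
# criterion is the summed variance reduction across all output dimensions
# (equivalently, minimal total within-child sum of squares).  Leaves store
# the mean target vector of their training rows, so forest predictions are
# averages of observed targets and can never leave their elementwise range.

#' Random-regression-forest baseline specification
#'
#' @param n_trees number of trees.
#' @param mtry features tried per split; default `max(1, floor(p / 3))`.
#' @param min_node minimum node size to attempt a split.
#' @param max_depth depth cap.
#' @return A `model_spec` of kind `"rrf"`.
#' @export
rrf_spec <- function(n_trees = 100L, mtry = NULL, min_node = 5L,
                     max_depth = 25L) {
  n_trees <- as.integer(n_trees)
  stopifnot(n_trees >= 1L, min_node >= 1L, max_depth >= 1L)
  .new_spec("rrf", n_trees = n_trees, mtry = mtry,
            min_node = as.integer(min_node), max_depth = as.integer(max_depth))
}

# Best split of the rows `idx` on feature f, scored by the gain
# ||sum_L||^2 / n_L + ||sum_R||^2 / n_R (total SS is constant).
.best_split_on <- function(x, Y, idx) {
  xs <- x[idx]
  ord <- order(xs)
  xs <- xs[ord]
  n <- length(idx)
  distinct <- which(xs[-n] < xs[-1L])
  if (length(distinct) == 0L) return(NULL)
  Ys <- Y[idx[ord], , drop = FALSE]
  cs <- apply(Ys, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  total <- cs[n, ]
  nl <- distinct
  left2 <- rowSums(cs[distinct, , drop = FALSE]^2)
  right <- matrix(total, length(distinct), length(total), byrow = TRUE) -
    cs[distinct, , drop = FALSE]
  gain <- left2 / nl + rowSums(right^2) / (n - nl)
  best <- which.max(gain)
  list(gain = gain[best],
       value = (xs[distinct[best]] + xs[distinct[best] + 1L]) / 2)
}

.build_tree <- function(X, Y, idx, mtry, min_node, max_depth, depth = 0L) {
  if (length(idx) < 2L * min_node || depth >= max_depth ||
      length(unique(idx)) == 1L) {
    return(list(leaf = TRUE, pred = colMeans(Y[idx, , drop = FALSE])))
  }
  # sorted so that exact gain ties (common in tiny nodes) break by feature
  # index, not by the order the subset happened to be drawn in
  feats <- sort(sample.int(ncol(X), min(mtry, ncol(X))))
  best <- NULL; best_f <- NA_integer_
  for (f in feats) {
    cand <- .best_split_on(X[, f], Y, idx)
    if (!is.null(cand) && (is.null(best) || cand$gain > best$gain)) {
      best <- cand; best_f <- f
    }
  }
  if (is.null(best))
    return(list(leaf = TRUE, pred = colMeans(Y[idx, , drop = FALSE])))
  go_left <- X[idx, best_f] <= best$value
  if (!any(go_left) || all(go_left))
    return(list(leaf = TRUE, pred = colMeans(Y[idx, , drop = FALSE])))
  list(leaf = FALSE, var = best_f, value = best$value,
       left = .build_tree(X, Y, idx[go_left], mtry, min_node, max_depth,
                          depth + 1L),
       right = .build_tree(X, Y, idx[!go_left], mtry, min_node, max_depth,
                           depth + 1L))
}

.fit_rrf <- function(X, Y, spec, seed = 1L) {
  mtry <- spec$mtry
  if (is.null(mtry)) mtry <- max(1L, ncol(X) %/% 3L)
  set.seed(seed)
  trees <- lapply(seq_len(spec$n_trees), function(i) {
    boot <- if (spec$n_trees == 1L) seq_len(nrow(X)) else
      sample.int(nrow(X), replace = TRUE)
    .build_tree(X, Y, boot, mtry, spec$min_node, spec$max_depth)
  })
  list(trees = trees, output_dim = ncol(Y))
}

.tree_predict_row <- function(tree, x) {
  while (!tree$leaf)
    tree <- if (x[tree$var] <= tree$value) tree$left else tree$right
  tree$pred
}

.predict_rrf <- function(fitted, X) {
  out <- matrix(0, nrow(X), fitted$output_dim)
  for (tree in fitted$trees) {
    p <- apply(X, 1L, .tree_predict_row, tree = tree)
    out <- out + if (fitted$output_dim == 1L) matrix(p, ncol = 1L) else t(p)
  }
  out / length(fitted$trees)
}
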