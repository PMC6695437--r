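#' Boosted regression trees with cross-validated size and relative influence
#'
#' Least-squares stagewise boosting of shallow regression trees (exact greedy
#' splits, bag subsampling). The number of trees is chosen by k-fold
#' cross-validation (minimum out-of-fold squared error, at least `min_trees`
#' trees); `cv_r2 = 1 - SSE_oof / TSS`, floored at 0. Relative influence is
#' Friedman's: the total squared-error reduction attributable to splits on
#' each variable across the selected ensemble, normalised to sum to 100.
#'
#' @param X Numeric matrix or data frame of predictors (n x p). Rows with
#'   any missing value are dropped and counted.
#' @param y Numeric response.
#' @param cv_folds Number of folds; values below 2 skip cross-validation and
#'   fit `n_trees` trees directly (`cv_r2` is then `NA`).
#' @param learning_rate Shrinkage per tree.
#' @param max_depth Maximum tree depth.
#' @param subsample Bag fraction per tree.
#' @param n_trees Maximum number of trees.
#' @param min_trees Minimum number of trees the selection may pick.
#' @param min_node Minimum observations per terminal node.
#' @param seed Integer seed (folds and bags).
#' @return An object of class `brt_fit`: `ri` (named, sums to 100), `cv_r2`,
#'   `n_train`, `n_trees` (selected), `n_dropped`, `fitted`, `hyperparams`.
#' @export
fit_brt <- function(X, y, cv_folds = 10L, learning_rate = 0.01,
                    max_depth = 3L, subsample = 0.5, n_trees = 3000L,
                    min_trees = 50L, min_node = 10L, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  keep <- stats::complete.cases(X) & is.finite(y)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  if (cv_folds >= 2 && n < cv_folds)
    stop("need at least cv_folds rows after dropping missing values")
  if (n < 2 || var(y) == 0)
    stop("degenerate response: zero variance in y")
  min_trees <- min(min_trees, n_trees)
  tss <- sum((y - mean(y))^2)
  empty <- matrix(numeric(0), 0L, ncol(X))

  if (cv_folds >= 2) {
    set.seed(pixel_seed(seed, 3L, 0L))
    folds <- sample(rep_len(seq_len(cv_folds), n))
    sse_path <- numeric(n_trees)
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      fit <- brt_boost_cpp(X[!te, , drop = FALSE], y[!te],
                           X[te, , drop = FALSE], y[te],
                           n_trees, learning_rate, max_depth, subsample,
                           min_node, pixel_seed(seed, 4L, f))
      sse_path <- sse_path + fit$test_sse
    }
    best_m <- which.min(sse_path[min_trees:n_trees]) + min_trees - 1L
    cv_r2 <- max(0, 1 - sse_path[best_m] / tss)
  } else {
    sse_path <- NULL
    best_m <- n_trees
    cv_r2 <- NA_real_
  }

  final <- brt_boost_cpp(X, y, empty, numeric(0), best_m, learning_rate,
                         max_depth, subsample, min_node,
                         pixel_seed(seed, 5L, 0L))
  imp <- final$importance
  if (sum(imp) <= 0)
    stop("no informative splits: every predictor is constant")
  ri <- 100 * imp / sum(imp)
  names(ri) <- colnames(X)
  structure(
    list(ri = ri, cv_r2 = cv_r2, n_train = n, n_trees = best_m,
         n_dropped = n_dropped, fitted = final$train_pred,
         oof_sse_path = sse_path,
         hyperparams = list(learning_rate = learning_rate,
                            max_depth = max_depth, subsample = subsample,
                            n_trees_max = n_trees, min_trees = min_trees,
                            min_node = min_node, cv_folds = cv_folds)),
    class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("<brt_fit> %d trees on %d rows; CV R2 = %s\n", x$n_trees,
              x$n_train,
              if (is.na(x$cv_r2)) "NA" else sprintf("%.3f", x$cv_r2)))
  ri <- sort(x$ri, decreasing = TRUE)
  cat("  relative influence (%):",
      paste(sprintf("%s %.1f", names(ri), ri), collapse = ", "), "\n")
  invisible(x)
}
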