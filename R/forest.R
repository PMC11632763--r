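# Gini random forest over clique count features.
#
# The forest is an ensemble of 64 (by default) independently seeded CART
# trees, each grown by Gini-impurity minimization on a bootstrap sample with
# mtry = floor(sqrt(p)) candidate features per split and nodes grown out to
# purity - the standard classification defaults. Trees are fitted one at a
# time (single-tree ranger forests) so that each tree's impurity-decrease
# importances are available individually; the ensemble is statistically
# identical to a single 64-tree forest, and the per-tree vectors give both
# the mean decrease in impurity (MDI) and its spread across trees.

#' Fit a clique random forest
#'
#' @param x integer feature matrix (molecules x cliques).
#' @param y binary labels (0/1), both classes present.
#' @param num_trees number of trees (default 64).
#' @param mtry candidate features per split; default `floor(sqrt(ncol(x)))`.
#' @param seed integer seed; the forest is reproducible given the seed.
#' @return a `clique_rf` object with components `trees` (per-tree fits),
#'   `importance` (cliques x trees matrix of per-tree normalized impurity
#'   decreases), `features`, `num_trees`, `seed`.
#' @seealso [predict.clique_rf()], [mdi_importances()]
#' @export
clique_rf <- function(x, y, num_trees = 64, mtry = NULL, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("both classes must be present to train", call. = FALSE)
  }
  if (num_trees < 1) stop("num_trees must be >= 1", call. = FALSE)
  features <- colnames(x)
  if (is.null(features)) {
    features <- sprintf("V%d", seq_len(ncol(x)))
  }
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))  # syntactically safe names
  df$.y <- factor(y, levels = c(0, 1))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  tree_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                           num_trees))
  trees <- vector("list", num_trees)
  imp <- matrix(0, nrow = ncol(x), ncol = num_trees,
                dimnames = list(features, NULL))
  for (t in seq_len(num_trees)) {
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = 1, mtry = mtry, replace = TRUE,
                          sample.fraction = 1, splitrule = "gini",
                          importance = "impurity", seed = tree_seeds[t],
                          num.threads = 1, verbose = FALSE)
    trees[[t]] <- fit
    vi <- fit$variable.importance
    if (sum(vi) > 0) vi <- vi / sum(vi)  # per-tree MDI normalized to sum 1
    imp[, t] <- vi
  }
  structure(list(trees = trees, importance = imp, features = features,
                 num_trees = num_trees, mtry = mtry, seed = seed,
                 n_train = nrow(x)),
            class = "clique_rf")
}

#' Predict BBBP scores from a clique forest
#'
#' The score of a molecule is the fraction of trees voting for the positive
#' (BBBP+) class; the hard label is positive when the score reaches the
#' threshold (ties at exactly 0.5 classify as positive).
#'
#' @param object a [clique_rf()] fit.
#' @param x feature matrix with the same width as the training matrix.
#' @param type `"score"` (vote fraction) or `"class"` (0/1 at `threshold`).
#' @param threshold decision threshold for `type = "class"`.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`, or integer labels.
#' @export
predict.clique_rf <- function(object, x, type = c("score", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  if (ncol(x) != length(object$features)) {
    stop("feature width (", ncol(x), ") does not match training vocabulary (",
         length(object$features), ")", call. = FALSE)
  }
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  votes <- matrix(0L, nrow = nrow(x), ncol = object$num_trees)
  for (t in seq_len(object$num_trees)) {
    p <- stats::predict(object$trees[[t]], data = df,
                        num.threads = 1, verbose = FALSE)$predictions
    votes[, t] <- as.integer(as.character(p))
  }
  score <- rowMeans(votes)
  if (type == "score") score else as.integer(score >= threshold)
}

#' @export
print.clique_rf <- function(x, ...) {
  cat(sprintf("Clique random forest: %d trees, %d features, mtry %d, %d training molecules\n",
              x$num_trees, length(x$features), x$mtry, x$n_train))
  invisible(x)
}

#' Mean-decrease-in-impurity importances
#'
#' Per-clique MDI averaged over trees, with each tree's impurity-decrease
#' vector first normalized to sum to one so that the full importance vector
#' sums to one; the standard deviation across trees is reported alongside.
#' Cliques occurring in fewer than `min_doc_freq` molecules are excluded
#' from the ranked report (but not from the normalization); they remain in
#' the full table with `reported = FALSE`.
#'
#' @param model a [clique_rf()] fit.
#' @param vocab optional [build_vocabulary()] table supplying document
#'   frequencies; required for the `min_doc_freq` filter.
#' @param min_doc_freq occurrence filter for the ranked report (default 50
#'   molecules).
#' @return data.frame sorted by decreasing `mdi_mean` with columns
#'   `fragment`, `mdi_mean`, `mdi_sd`, `doc_freq`, `reported`.
#' @export
mdi_importances <- function(model, vocab = NULL, min_doc_freq = 50) {
  stopifnot(inherits(model, "clique_rf"))
  imp <- model$importance
  out <- data.frame(fragment = model$features,
                    mdi_mean = rowMeans(imp),
                    mdi_sd = apply(imp, 1, stats::sd),
                    stringsAsFactors = FALSE)
  if (!is.null(vocab)) {
    out$doc_freq <- vocab$doc_freq[match(out$fragment, vocab$fragment)]
  } else {
    out$doc_freq <- NA_integer_
  }
  out$reported <- is.na(out$doc_freq) | out$doc_freq >= min_doc_freq
  out <- out[order(-out$mdi_mean, out$fragment, method = "radix"), ]
  rownames(out) <- NULL
  out
}
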