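# Repeated k-fold cross-validation of clique classifiers.
#
# Each repeat draws a fresh shuffled plain k-fold partition (stratification
# is available but off by default, matching the standard k-fold splitter).
# Within a fold, the vocabulary is built from the training fold only (or
# from the full dataset, for parity with a full-dataset featurization),
# SMOTE - if enabled - is applied to the training fold only, and the
# untouched validation fold is scored. Per-repeat split seeds are
# `base_seed + repeat`; forest seeds are derived independently of the split
# seeds so the two sources of randomness never alias.

#' Repeated k-fold evaluation of a clique classifier
#'
#' @param dataset a `bbb_dataset` from [read_bbb_table()], or a list of
#'   `clique_decomposition` objects / fragment-string vectors (then `y` must
#'   be given).
#' @param y binary labels; taken from `dataset$label` when `dataset` is a
#'   `bbb_dataset`.
#' @param k number of folds (default 5).
#' @param repeats number of independent repeats (default 10).
#' @param num_trees forest size (default 64).
#' @param use_smote balance each training fold by discretized SMOTE.
#' @param vocab_scope `"fold"` (vocabulary from the training fold only,
#'   default) or `"full"` (built once from every molecule).
#' @param classifier `"rf"` (random forest) or `"nb"` (Bernoulli naive
#'   Bayes on binarized features).
#' @param alpha naive-Bayes smoothing (used when `classifier = "nb"`).
#' @param stratified preserve class proportions across folds (off by
#'   default; the plain shuffled splitter is the reference protocol).
#' @param threshold decision threshold for SN/SP/MCC.
#' @param seed base seed; the full run is reproducible given the seed.
#' @return a `bbb_cv` object: `folds` (per-fold SN/SP/MCC/AUC),
#'   `aggregate` (mean and sd over all `k * repeats` folds), `assignments`
#'   (repeats x molecules fold-membership matrix), `config`.
#' @export
repeated_kfold <- function(dataset, y = NULL, k = 5, repeats = 10,
                           num_trees = 64, use_smote = TRUE,
                           vocab_scope = c("fold", "full"),
                           classifier = c("rf", "nb"), alpha = 1,
                           stratified = FALSE, threshold = 0.5, seed = 1) {
  vocab_scope <- match.arg(vocab_scope)
  classifier <- match.arg(classifier)
  if (inherits(dataset, "bbb_dataset")) {
    if (is.null(y)) y <- dataset$label
    keep <- !is.na(y)
    frags <- fragment_lists(decompose_molecules(dataset$canonical_smiles[keep]))
    y <- as.integer(y[keep])
  } else {
    if (is.null(y)) stop("y must be supplied with precomputed decompositions",
                         call. = FALSE)
    frags <- fragment_lists(dataset)
    y <- as.integer(y)
  }
  n <- length(frags)
  stopifnot(length(y) == n)
  if (n < k) stop("fewer records (", n, ") than folds (", k, ")",
                  call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }

  full_vocab <- if (vocab_scope == "full") build_vocabulary(frags) else NULL
  fold_rows <- list()
  assignments <- matrix(NA_integer_, nrow = repeats, ncol = n)
  for (r in seq_len(repeats)) {
    split_seed <- seed + r
    assignment <- with_seed(split_seed, make_folds(y, k, stratified))
    assignments[r, ] <- assignment
    for (f in seq_len(k)) {
      val <- which(assignment == f)
      train <- which(assignment != f)
      vocab <- if (vocab_scope == "fold") {
        build_vocabulary(frags[train])
      } else full_vocab
      x_train <- featurize(frags[train], vocab)
      x_val <- featurize(frags[val], vocab)
      y_train <- y[train]
      if (use_smote) {
        bal <- balance_training_set(x_train, y_train,
                                    seed = seed + 1000L * r + f)
        x_train <- bal$x
        y_train <- bal$y
        # leakage guard: the validation matrix was built before balancing
        stopifnot(nrow(x_val) == length(val))
      }
      forest_seed <- seed + 100000L + 1000L * r + f
      scores <- if (classifier == "rf") {
        fit <- clique_rf(x_train, y_train, num_trees = num_trees,
                         seed = forest_seed)
        predict(fit, x_val, type = "score")
      } else {
        fit <- clique_nb(binarize(x_train), y_train, alpha = alpha)
        predict(fit, binarize(x_val), type = "posterior")
      }
      row <- data.frame(repeat_ = r, fold = f, n_val = length(val),
                        sn = NA_real_, sp = NA_real_, mcc = NA_real_,
                        auc = NA_real_)
      if (length(unique(y[val])) == 2) {
        m <- compute_metrics(y[val], scores, threshold)
        row$sn <- m$sn; row$sp <- m$sp; row$mcc <- m$mcc; row$auc <- m$auc
      } else {
        warning("validation fold ", f, " of repeat ", r,
                " contains a single class; metrics undefined for this fold",
                call. = FALSE)
      }
      fold_rows[[length(fold_rows) + 1L]] <- row
    }
  }
  folds <- do.call(rbind, fold_rows)
  metrics <- c("sn", "sp", "mcc", "auc")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]], na.rm = TRUE),
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(aggregate) <- NULL
  structure(list(folds = folds, aggregate = aggregate,
                 assignments = assignments,
                 config = list(k = k, repeats = repeats,
                               num_trees = num_trees, use_smote = use_smote,
                               vocab_scope = vocab_scope,
                               classifier = classifier, alpha = alpha,
                               stratified = stratified,
                               threshold = threshold, seed = seed, n = n)),
            class = "bbb_cv")
}

# Fold assignment 1..k for n records; plain shuffled equal-size folds, or
# stratified within class. Uses the current RNG stream.
make_folds <- function(y, k, stratified = FALSE) {
  n <- length(y)
  if (!stratified) {
    sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
    assignment <- integer(n)
    assignment[sample.int(n)] <- rep(seq_len(k), times = sizes)
    return(assignment)
  }
  assignment <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    m <- length(idx)
    sizes <- rep(m %/% k, k) + c(rep(1, m %% k), rep(0, k - m %% k))
    assignment[idx[sample.int(m)]] <- rep(seq_len(k), times = sizes)
  }
  assignment
}

#' @export
print.bbb_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Repeated %d-fold CV, %d repeats (%s%s, vocabulary: %s fold)\n",
              cfg$k, cfg$repeats,
              if (cfg$classifier == "rf")
                sprintf("random forest, %d trees", cfg$num_trees)
              else sprintf("naive Bayes, alpha %g", cfg$alpha),
              if (cfg$use_smote) ", SMOTE" else ", no SMOTE",
              cfg$vocab_scope))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-4s %.3f +/- %.3f\n", toupper(agg$metric[i]),
                agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}
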