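# Bernoulli naive Bayes over binarized clique features, and the per-clique
# marginal probability P(BBB+ | clique present).
#
# The classifier assumes cliques are conditionally independent given the
# class. Its interest here is less prediction than inversion: because each
# feature is Bernoulli, P(x_i = 1) = sum_y P(x_i = 1 | y) P(y) is tractable,
# and Bayes' rule gives the marginal probability that a molecule permeates
# the blood-brain barrier given that clique i is present - a direct
# probabilistic structure-function statistic per fragment.

#' Fit a Bernoulli naive-Bayes model
#'
#' Priors are the empirical class frequencies. Conditionals use additive
#' (Laplace) smoothing: `P(x_i = 1 | y) = (n_{iy} + alpha) / (n_y +
#' 2 alpha)`. With `alpha = 0` the conditionals - and hence the marginals -
#' are exact empirical frequencies.
#'
#' @param x_binary 0/1 matrix (molecules x cliques), e.g. from [binarize()].
#' @param y binary labels (0/1), both classes present.
#' @param alpha smoothing pseudo-count, `>= 0` (default 1, Laplace).
#' @return a `clique_nb` object: `prior` (P(y=1)), `cond` (2 x V matrix of
#'   P(x_i=1|y) for y = 0, 1), `alpha`, `features`, and the raw class and
#'   presence counts for auditing.
#' @export
clique_nb <- function(x_binary, y, alpha = 1) {
  stopifnot(is.matrix(x_binary))
  if (any(!x_binary %in% c(0L, 1L))) {
    stop("x_binary must be a 0/1 matrix (see binarize())", call. = FALSE)
  }
  y <- as.integer(y)
  stopifnot(nrow(x_binary) == length(y))
  if (length(unique(y)) < 2) {
    stop("both classes must be present to fit", call. = FALSE)
  }
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  c1 <- colSums(x_binary[y == 1L, , drop = FALSE])
  c0 <- colSums(x_binary[y == 0L, , drop = FALSE])
  features <- colnames(x_binary)
  if (is.null(features)) {
    features <- sprintf("V%d", seq_len(ncol(x_binary)))  # character(0) at V=0
  }
  cond <- matrix(c((c0 + alpha) / (n0 + 2 * alpha),
                   (c1 + alpha) / (n1 + 2 * alpha)),
                 nrow = 2, ncol = ncol(x_binary), byrow = TRUE,
                 dimnames = list(c("0", "1"), features))
  structure(list(prior = n1 / (n1 + n0), cond = cond, alpha = alpha,
                 features = features,
                 counts = list(n1 = n1, n0 = n0, present_pos = c1,
                               present_neg = c0)),
            class = "clique_nb")
}

#' Posterior class probability from a naive-Bayes model
#'
#' Restores the normalizer usually dropped from the naive-Bayes decision
#' rule, so a probability P(y = 1 | x) is returned. Computed in log space.
#'
#' @param object a [clique_nb()] fit.
#' @param x 0/1 matrix (or vector) with the model's feature width.
#' @param type `"posterior"` for P(y=1|x), `"class"` for hard 0/1 labels
#'   (posterior >= 0.5 is positive).
#' @param ... unused.
#' @return numeric vector of posteriors, or integer labels.
#' @export
predict.clique_nb <- function(object, x, type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$features)) {
    stop("feature width (", ncol(x), ") does not match model (",
         length(object$features), ")", call. = FALSE)
  }
  if (any(!x %in% c(0L, 1L))) {
    stop("x must be binary (see binarize())", call. = FALSE)
  }
  p1 <- object$cond["1", ]; p0 <- object$cond["0", ]
  # guard exact 0/1 conditionals under alpha = 0
  l1 <- x %*% log(pmax(p1, .Machine$double.xmin)) +
    (1 - x) %*% log(pmax(1 - p1, .Machine$double.xmin))
  l0 <- x %*% log(pmax(p0, .Machine$double.xmin)) +
    (1 - x) %*% log(pmax(1 - p0, .Machine$double.xmin))
  lp1 <- as.numeric(l1) + log(object$prior)
  lp0 <- as.numeric(l0) + log(1 - object$prior)
  post <- 1 / (1 + exp(lp0 - lp1))
  if (type == "posterior") post else as.integer(post >= 0.5)
}

#' @export
print.clique_nb <- function(x, ...) {
  cat(sprintf("Bernoulli naive Bayes: %d cliques, prior P(BBB+) = %.3f, alpha = %g\n",
              length(x$features), x$prior, x$alpha))
  invisible(x)
}

#' Marginal probability of BBB permeation given a clique
#'
#' `P(y = 1 | x_i = 1) = P(x_i=1|y=1) P(y=1) / sum_y P(x_i=1|y) P(y)`,
#' with `P(x_i = 1)` computed exactly from the Bernoulli conditionals. With
#' `alpha = 0` this equals the empirical fraction
#' `count(x_i = 1, y = 1) / count(x_i = 1)`.
#'
#' @param model a [clique_nb()] fit.
#' @param clique either a column index (1-based), a fragment string, or
#'   `NULL` for all cliques.
#' @return named numeric vector of marginals in `[0, 1]`.
#' @export
marginal_probability <- function(model, clique = NULL) {
  stopifnot(inherits(model, "clique_nb"))
  j <- if (is.null(clique)) {
    seq_along(model$features)
  } else if (is.character(clique)) {
    jj <- match(clique, model$features)
    if (anyNA(jj)) stop("unknown clique: ",
                        paste(clique[is.na(jj)], collapse = ", "),
                        call. = FALSE)
    jj
  } else {
    jj <- as.integer(clique)
    if (any(jj < 1 | jj > length(model$features))) {
      stop("clique index out of range", call. = FALSE)
    }
    jj
  }
  p1 <- model$cond["1", j] * model$prior
  p0 <- model$cond["0", j] * (1 - model$prior)
  px <- p1 + p0
  if (any(px == 0)) {
    stop("marginal undefined: clique absent from every molecule under alpha = 0",
         call. = FALSE)
  }
  stats::setNames(p1 / px, model$features[j])
}

#' Per-clique structure-function report
#'
#' Splits the vocabulary into permeation *enhancers* (marginal P(BBB+ |
#' clique) at or above `hi`) and *suppressors* (at or below `lo`), each row
#' carrying the clique's document frequency and fragment clogP. Cliques
#' below the document-frequency filter are excluded from the two labelled
#' tables but retained in the full export.
#'
#' @param model a [clique_nb()] fit.
#' @param vocab a [build_vocabulary()] table aligned with the model features.
#' @param min_doc_freq labelled-report occurrence filter (default 50).
#' @param hi,lo marginal-probability thresholds (defaults 0.8 and 0.2).
#' @param compute_clogp logical; compute Wildman-Crippen clogP for each
#'   fragment (needs OpenBabel; disable for speed in programmatic use).
#' @return a `clique_report`: list with data.frames `full` (one row per
#'   vocabulary clique), `enhancers`, `suppressors`.
#' @export
clique_report <- function(model, vocab, min_doc_freq = 50, hi = 0.8,
                          lo = 0.2, compute_clogp = TRUE) {
  stopifnot(inherits(model, "clique_nb"),
            inherits(vocab, "clique_vocabulary"))
  if (hi <= lo) stop("hi must be greater than lo", call. = FALSE)
  if (!identical(vocab$fragment, model$features)) {
    stop("model and vocabulary do not share feature indexing", call. = FALSE)
  }
  marg <- marginal_probability(model)
  full <- data.frame(fragment = vocab$fragment,
                     doc_freq = vocab$doc_freq,
                     p_bbb_pos = unname(marg),
                     stringsAsFactors = FALSE)
  full$fragment_clogp <- if (compute_clogp) {
    mol_descriptors(full$fragment)$clogp
  } else NA_real_
  full$reported <- full$doc_freq >= min_doc_freq
  enh <- full[full$p_bbb_pos >= hi & full$reported, , drop = FALSE]
  sup <- full[full$p_bbb_pos <= lo & full$reported, , drop = FALSE]
  enh <- enh[order(-enh$p_bbb_pos, enh$fragment, method = "radix"), ]
  sup <- sup[order(sup$p_bbb_pos, sup$fragment, method = "radix"), ]
  rownames(full) <- rownames(enh) <- rownames(sup) <- NULL
  structure(list(full = full, enhancers = enh, suppressors = sup,
                 min_doc_freq = min_doc_freq, hi = hi, lo = lo),
            class = "clique_report")
}

#' @export
print.clique_report <- function(x, ...) {
  cat(sprintf("Clique report: %d cliques; %d enhancers (P >= %.2f), %d suppressors (P <= %.2f) at doc freq >= %d\n",
              nrow(x$full), nrow(x$enhancers), x$hi, nrow(x$suppressors),
              x$lo, x$min_doc_freq))
  invisible(x)
}
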