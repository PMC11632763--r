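# Clique vocabulary and count-matrix featurization.

#' Build a clique vocabulary
#'
#' Collects the distinct fragment strings across a set of decompositions into
#' an ordered vocabulary. Document frequency counts molecules containing a
#' clique at least once (not occurrences). Ordering is descending document
#' frequency with lexicographic tie-break, so the index map is deterministic
#' for a given dataset.
#'
#' @param decompositions a list of `clique_decomposition` objects (or plain
#'   character vectors of fragment strings, one element per molecule).
#' @return a `clique_vocabulary`: data.frame with columns `index` (0-based),
#'   `fragment` and `doc_freq`.
#' @export
build_vocabulary <- function(decompositions) {
  frag_lists <- fragment_lists(decompositions)
  if (length(frag_lists) == 0) stop("no molecules supplied", call. = FALSE)
  df_tab <- table(unlist(lapply(frag_lists, unique)))
  if (length(df_tab) == 0) stop("no cliques found", call. = FALSE)
  frag <- names(df_tab)
  dfreq <- as.integer(df_tab)
  ord <- order(-dfreq, frag, method = "radix")
  out <- data.frame(index = seq_along(frag) - 1L,
                    fragment = frag[ord],
                    doc_freq = dfreq[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("clique_vocabulary", "data.frame")
  out
}

fragment_lists <- function(decompositions) {
  if (inherits(decompositions, "clique_decomposition")) {
    decompositions <- list(decompositions)
  }
  lapply(decompositions, function(d) {
    if (inherits(d, "clique_decomposition")) d$fragments
    else as.character(d)
  })
}

#' Featurize decompositions against a vocabulary
#'
#' A molecule's feature vector is the sum of the one-hot vectors of its
#' clique occurrences: entry j counts how many times vocabulary fragment j
#' occurs in the molecule. Fragments absent from the vocabulary are dropped;
#' the total number of such out-of-vocabulary occurrences is recorded in the
#' `oov_count` attribute.
#'
#' @param decompositions list of `clique_decomposition` objects or fragment
#'   string vectors.
#' @param vocab a [build_vocabulary()] result.
#' @return integer matrix (molecules x vocabulary), columns named by
#'   fragment, with attribute `oov_count`.
#' @export
featurize <- function(decompositions, vocab) {
  stopifnot(inherits(vocab, "clique_vocabulary"), nrow(vocab) > 0)
  frag_lists <- fragment_lists(decompositions)
  v <- nrow(vocab)
  x <- matrix(0L, nrow = length(frag_lists), ncol = v,
              dimnames = list(NULL, vocab$fragment))
  oov <- 0L
  for (i in seq_along(frag_lists)) {
    j <- match(frag_lists[[i]], vocab$fragment)
    oov <- oov + sum(is.na(j))
    j <- j[!is.na(j)]
    if (length(j) > 0) {
      tab <- tabulate(j, nbins = v)
      x[i, ] <- tab
    }
  }
  storage.mode(x) <- "integer"
  attr(x, "oov_count") <- oov
  x
}

#' Binarize a count matrix
#'
#' Presence/absence transform used by the Bernoulli naive-Bayes analysis:
#' an entry becomes 1 iff the clique occurs at least once. Idempotent.
#'
#' @param x non-negative integer matrix.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(x) {
  stopifnot(is.matrix(x), all(x >= 0))
  out <- (x > 0) + 0L
  dimnames(out) <- dimnames(x)
  out
}
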