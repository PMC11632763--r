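# Discretized SMOTE for integer count features.
#
# The oversampler follows the two-point variant: pick two distinct minority
# rows a and b uniformly at random, draw t ~ Uniform(0,1) (endpoints
# included), and take round(a + t*(b - a)) coordinate-wise. Rounding is
# half-away-from-zero; on the non-negative count features this is floor(x +
# 0.5), so every synthetic entry is an integer lying within the parental
# coordinate bounds. This differs from classical k-nearest-neighbour SMOTE
# on purpose. Only the minority class is synthesized; majority rows are
# never removed.

#' Generate synthetic minority rows by discretized interpolation
#'
#' @param minority_rows integer matrix of minority-class feature rows
#'   (at least 2 rows).
#' @param n_synthetic number of synthetic rows to generate.
#' @return integer matrix with `n_synthetic` rows; each coordinate of each
#'   row lies within `[min(a_j, b_j), max(a_j, b_j)]` for its two parents.
#' @export
smote_discrete <- function(minority_rows, n_synthetic) {
  stopifnot(is.matrix(minority_rows))
  if (nrow(minority_rows) < 2) {
    stop("need at least 2 minority rows to interpolate", call. = FALSE)
  }
  if (length(n_synthetic) != 1 || is.na(n_synthetic) || n_synthetic < 0) {
    stop("n_synthetic must be a non-negative integer", call. = FALSE)
  }
  n_synthetic <- as.integer(n_synthetic)
  v <- ncol(minority_rows)
  out <- matrix(0L, nrow = n_synthetic, ncol = v,
                dimnames = list(NULL, colnames(minority_rows)))
  n_min <- nrow(minority_rows)
  for (s in seq_len(n_synthetic)) {
    pair <- sample.int(n_min, 2, replace = FALSE)
    a <- minority_rows[pair[1], ]
    b <- minority_rows[pair[2], ]
    t <- stats::runif(1)
    out[s, ] <- as.integer(floor(a + t * (b - a) + 0.5))
  }
  out
}

#' Equalize class counts on a training set
#'
#' Oversamples the minority class with [smote_discrete()] until both classes
#' have equal counts. Original rows are returned unmodified as the prefix of
#' the output; appended synthetic rows are flagged. Intended for training
#' folds only - validation data must never pass through this function.
#'
#' @param x integer feature matrix.
#' @param y binary labels (0/1), one per row of `x`.
#' @param seed optional integer seed for reproducible oversampling.
#' @return list with `x` (original rows then synthetic rows), `y`, and
#'   `synthetic` (logical flag per row, `TRUE` for interpolated rows).
#' @export
balance_training_set <- function(x, y, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to balance", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  deficit <- abs(n1 - n0)
  if (deficit == 0) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  minority <- if (n1 < n0) 1L else 0L
  synth <- smote_discrete(x[y == minority, , drop = FALSE], deficit)
  list(x = rbind(x, synth),
       y = c(y, rep(minority, deficit)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, deficit)))
}

# RNG bookkeeping: run seeded code without disturbing the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  force(code)
}
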