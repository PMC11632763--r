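# Reading and writing B3DB-style molecule tables, and the exploratory
# statistics computed on them.

#' Default column map for B3DB-style tables
#'
#' Maps the record roles onto table columns. Values may be column names
#' (matched against the header) or integer positions. The default follows
#' the B3DB column order: name, SMILES, InChI, BBB+/- label, quality grade,
#' log BB.
#'
#' @param name,smiles,inchi,label,grade,logbb column name or 1-based position;
#'   `NA` marks a column as absent (only `smiles` and `label` are required
#'   by [read_bbb_table()]).
#' @return named list of class `bbb_column_map`.
#' @export
b3db_columns <- function(name = 1L, smiles = 2L, inchi = 3L, label = 4L,
                         grade = 5L, logbb = 6L) {
  structure(list(name = name, smiles = smiles, inchi = inchi, label = label,
                 grade = grade, logbb = logbb),
            class = "bbb_column_map")
}

# yes-like / no-like label vocabularies (case-insensitive)
.label_pos <- c("bbb+", "yes", "1", "true")
.label_neg <- c("bbb-", "no", "0", "false")

parse_bbb_labels <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[lx %in% .label_pos] <- 1L
  out[lx %in% .label_neg] <- 0L
  bad <- !is.na(x) & nzchar(lx) & is.na(out)
  if (any(bad)) {
    stop("unrecognized BBB permeability label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

.resolve_col <- function(df, spec, role, required = FALSE) {
  if (is.null(spec) || (length(spec) == 1 && is.na(spec))) {
    if (required) stop("column map does not name the ", role, " column",
                       call. = FALSE)
    return(NA_integer_)
  }
  if (is.character(spec)) {
    j <- match(spec, names(df))
    if (is.na(j)) {
      if (required) stop("mapped ", role, " column '", spec,
                         "' not found in header", call. = FALSE)
      return(NA_integer_)
    }
    return(j)
  }
  j <- as.integer(spec)
  if (j < 1 || j > ncol(df)) {
    if (required) stop("mapped ", role, " column ", j, " out of range",
                       call. = FALSE)
    return(NA_integer_)
  }
  j
}

#' Read a B3DB-style molecule table
#'
#' Reads a tab-separated table with a header row, maps yes-like labels to 1
#' and no-like to 0 (accepted vocabulary: BBB+/yes/1/true and
#' BBB-/no/0/false, case-insensitive), canonicalizes every SMILES
#' (stereochemistry stripped), and drops - with a warning and a recorded
#' count - any row whose SMILES fails to parse.
#'
#' @param path path to the TSV file.
#' @param column_map a [b3db_columns()] map; positions or header names.
#' @return a `bbb_dataset`: a data.frame with columns `row_index` (0-based,
#'   contiguous), `name`, `smiles`, `canonical_smiles`, `label` (1 =
#'   permeates the blood-brain barrier, 0 = does not, `NA` unknown),
#'   `quality_grade` (A-D or `NA`) and `log_bb`; attributes `n_excluded`
#'   (rows dropped for unparseable SMILES) and `provenance` (source path and
#'   resolved column map).
#' @export
read_bbb_table <- function(path, column_map = b3db_columns()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "")
  if (nrow(df) == 0) stop("input file has no data rows: ", path, call. = FALSE)
  j_smiles <- .resolve_col(df, column_map$smiles, "SMILES", required = TRUE)
  j_label <- .resolve_col(df, column_map$label, "label", required = TRUE)
  j_name <- .resolve_col(df, column_map$name, "name")
  j_grade <- .resolve_col(df, column_map$grade, "grade")
  j_logbb <- .resolve_col(df, column_map$logbb, "log BB")

  smiles <- as.character(df[[j_smiles]])
  label <- parse_bbb_labels(df[[j_label]])
  name <- if (is.na(j_name)) rep("", nrow(df)) else {
    x <- as.character(df[[j_name]]); x[is.na(x)] <- ""; x
  }
  grade <- if (is.na(j_grade)) rep(NA_character_, nrow(df)) else {
    g <- toupper(trimws(as.character(df[[j_grade]])))
    g[!g %in% c("A", "B", "C", "D")] <- NA_character_
    g
  }
  log_bb <- if (is.na(j_logbb)) rep(NA_real_, nrow(df)) else
    suppressWarnings(as.numeric(df[[j_logbb]]))

  canon <- canonical_smiles(smiles)
  keep <- !is.na(canon)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    warning(n_excluded, " row(s) with unparseable SMILES excluded",
            call. = FALSE)
  }
  out <- data.frame(row_index = seq_len(sum(keep)) - 1L,
                    name = name[keep],
                    smiles = smiles[keep],
                    canonical_smiles = canon[keep],
                    label = label[keep],
                    quality_grade = grade[keep],
                    log_bb = log_bb[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "provenance") <- list(path = path, column_map = column_map)
  class(out) <- c("bbb_dataset", "data.frame")
  out
}

#' Write a dataset back to a B3DB-style TSV
#'
#' Inverse of [read_bbb_table()]: emits the B3DB column order (name, SMILES,
#' InChI, label, grade, log BB) with labels written as `BBB+`/`BBB-`.
#'
#' @param dataset a `bbb_dataset` (or compatible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bbb_table <- function(dataset, path) {
  lab <- ifelse(is.na(dataset$label), "",
                ifelse(dataset$label == 1L, "BBB+", "BBB-"))
  out <- data.frame(compound_name = dataset$name,
                    SMILES = dataset$smiles,
                    InChI = "",
                    `BBB+/BBB-` = lab,
                    group = ifelse(is.na(dataset$quality_grade), "",
                                   dataset$quality_grade),
                    logBB = ifelse(is.na(dataset$log_bb), "",
                                   format(dataset$log_bb, digits = 10)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brain-to-blood partition: log BB
#'
#' `log BB = log10(C_brain / C_blood)`, the base-10 log of the steady-state
#' concentration ratio between brain and blood. B3DB classifies molecules
#' with `log BB >= -1` as BBB-permeable.
#'
#' @param c_brain,c_blood strictly positive concentrations in the same units.
#' @return numeric vector of log BB values.
#' @export
log_bb <- function(c_brain, c_blood) {
  if (any(!is.finite(c_brain)) || any(!is.finite(c_blood)) ||
      any(c_brain <= 0) || any(c_blood <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  log10(c_brain / c_blood)
}

#' Pearson correlation with validity checks
#'
#' Sample Pearson correlation coefficient; errors on degenerate input rather
#' than silently returning `NA`.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Exploratory summary of a BBBP dataset
#'
#' Per-class molecular weight and Wildman-Crippen clogP samples with their
#' \[min, max\] ranges and Gaussian-kernel density estimates (Scott's-rule
#' bandwidth), plus the four log BB correlation cells: Pearson correlation of
#' molecular weight and of clogP with log BB, restricted to each permeability
#' class, over the records for which log BB is available. Records lacking
#' log BB contribute to the densities but not to the correlations.
#'
#' @param dataset a `bbb_dataset` with at least one labelled record.
#' @param kde_n number of evaluation points for each density estimate.
#' @return a `bbb_eda` object: list with `samples` (per molecule: class, MW,
#'   clogP, log BB), `ranges`, `kde` (per class and feature; `NULL` with a
#'   `degenerate` flag where a class has zero variance), and `correlations`
#'   (a 2 feature x 2 class data.frame).
#' @export
eda_summary <- function(dataset, kde_n = 512) {
  if (nrow(dataset) == 0) stop("empty dataset", call. = FALSE)
  lab <- dataset$label
  if (all(is.na(lab))) stop("no labelled records", call. = FALSE)
  keep <- !is.na(lab)
  d <- mol_descriptors(dataset$canonical_smiles[keep])
  samples <- data.frame(class = ifelse(lab[keep] == 1, "BBBP+", "BBBP-"),
                        mw = d$mw, clogp = d$clogp,
                        log_bb = dataset$log_bb[keep],
                        stringsAsFactors = FALSE)
  classes <- c("BBBP-", "BBBP+")
  features <- c("mw", "clogp")
  ranges <- expand.grid(class = classes, feature = features,
                        stringsAsFactors = FALSE)
  ranges$min <- NA_real_; ranges$max <- NA_real_
  kde <- list()
  for (r in seq_len(nrow(ranges))) {
    v <- samples[samples$class == ranges$class[r], ranges$feature[r]]
    v <- v[is.finite(v)]
    key <- paste(ranges$class[r], ranges$feature[r], sep = ".")
    if (length(v) == 0) next
    ranges$min[r] <- min(v); ranges$max[r] <- max(v)
    if (length(v) >= 2 && stats::sd(v) > 0) {
      h <- stats::sd(v) * length(v)^(-1 / 5)  # Scott's rule
      den <- stats::density(v, bw = h, n = kde_n)
      kde[[key]] <- list(x = den$x, y = den$y, bw = h, degenerate = FALSE)
    } else {
      kde[[key]] <- list(x = NULL, y = NULL, bw = NA_real_, degenerate = TRUE)
    }
  }
  corr <- expand.grid(feature = features, class = classes,
                      stringsAsFactors = FALSE)
  corr$pcc <- NA_real_; corr$n <- NA_integer_
  for (r in seq_len(nrow(corr))) {
    sel <- samples$class == corr$class[r] & is.finite(samples$log_bb) &
      is.finite(samples[[corr$feature[r]]])
    corr$n[r] <- sum(sel)
    if (sum(sel) >= 3) {
      v <- samples[sel, corr$feature[r]]
      if (stats::sd(v) > 0 && stats::sd(samples$log_bb[sel]) > 0) {
        corr$pcc[r] <- pearson(v, samples$log_bb[sel])
      }
    }
  }
  structure(list(samples = samples, ranges = ranges, kde = kde,
                 correlations = corr),
            class = "bbb_eda")
}

#' @export
print.bbb_eda <- function(x, ...) {
  cat("Exploratory summary:", nrow(x$samples), "labelled molecules\n")
  cat("Class counts:\n")
  print(table(x$samples$class))
  cat("log BB correlations (records with log BB only):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
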