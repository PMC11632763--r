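# High-level pipeline stages and the command-line entry point.
#
# Each stage writes its outputs plus a resolved run configuration
# (config.json: options, seeds, input hash, exclusion counts, versions) into
# the output directory, so any run can be reproduced from its artifacts
# alone. Files are written atomically (temp file + rename).

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

write_json <- function(x, path) {
  write_atomic(function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

run_log <- function(out_dir, subcommand, opts, extra = list()) {
  cfg <- c(list(subcommand = subcommand,
                package_version = as.character(utils::packageVersion("bbbcliques")),
                r_version = as.character(getRversion())),
           opts, extra)
  if (!is.null(opts$input) && file.exists(opts$input)) {
    cfg$input_md5 <- unname(tools::md5sum(opts$input))
  }
  write_json(cfg, file.path(out_dir, "config.json"))
  cfg
}

#' Pipeline stages
#'
#' Programmatic equivalents of the command-line subcommands; each returns
#' (invisibly) the paths it wrote. `pipeline_simulate` emits a synthetic
#' B3DB-style TSV plus its analytic ground truth; `pipeline_eda` writes the
#' exploratory tables; `pipeline_featurize` the vocabulary and sparse count
#' matrix; `pipeline_evaluate` the repeated-CV metrics JSON and the
#' full-data MDI ranking; `pipeline_interpret` the naive-Bayes clique
#' report.
#'
#' @param out output directory (created if missing).
#' @param n,imbalance,seed generator size, target positive rate, seed.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(out, n = 2000, imbalance = 4956 / 7807,
                              seed = 7) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- bbb_generator_spec(n_molecules = n, positive_rate = imbalance,
                             seed = seed)
  gen <- generate_bbb_dataset(spec)
  data_path <- file.path(out, "molecules.tsv")
  write_atomic(function(p) write_bbb_table(gen$dataset, p), data_path)
  truth_path <- file.path(out, "truth.tsv")
  write_tsv(gen$truth, truth_path)
  run_log(out, "simulate",
          list(n = n, imbalance = imbalance, seed = seed),
          list(intercept = spec$intercept))
  invisible(c(data_path, truth_path))
}

#' @rdname pipeline
#' @param input path to a B3DB-style TSV.
#' @param smiles_col,label_col column names or positions overriding the
#'   default B3DB layout.
#' @export
pipeline_eda <- function(input, out, smiles_col = NULL, label_col = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cmap <- b3db_columns()
  if (!is.null(smiles_col)) cmap$smiles <- smiles_col
  if (!is.null(label_col)) cmap$label <- label_col
  ds <- read_bbb_table(input, cmap)
  eda <- eda_summary(ds)
  write_tsv(eda$correlations, file.path(out, "eda_correlations.tsv"))
  write_tsv(eda$ranges, file.path(out, "eda_ranges.tsv"))
  kde_rows <- do.call(rbind, lapply(names(eda$kde), function(k) {
    e <- eda$kde[[k]]
    if (e$degenerate) return(data.frame(cell = k, x = NA_real_, y = NA_real_,
                                        degenerate = TRUE))
    data.frame(cell = k, x = e$x, y = e$y, degenerate = FALSE)
  }))
  write_tsv(kde_rows, file.path(out, "eda_kde.tsv"))
  write_tsv(eda$samples, file.path(out, "eda_samples.tsv"))
  run_log(out, "eda", list(input = input),
          list(n_records = nrow(ds), n_excluded = attr(ds, "n_excluded")))
  invisible(out)
}

#' @rdname pipeline
#' @param vocab optional path to an existing vocabulary TSV to featurize
#'   against (out-of-vocabulary cliques are dropped and tallied).
#' @export
pipeline_featurize <- function(input, out, vocab = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ds <- read_bbb_table(input)
  decs <- decompose_molecules(ds$canonical_smiles)
  if (is.null(vocab)) {
    voc <- build_vocabulary(decs)
  } else {
    vt <- utils::read.delim(vocab, stringsAsFactors = FALSE)
    voc <- structure(vt[, c("index", "fragment", "doc_freq")],
                     class = c("clique_vocabulary", "data.frame"))
  }
  x <- featurize(decs, voc)
  trip <- which(x > 0, arr.ind = TRUE)
  write_tsv(data.frame(row_id = ds$row_index[trip[, 1]],
                       clique_index = voc$index[trip[, 2]],
                       count = x[trip]),
            file.path(out, "features.tsv"))
  write_tsv(voc, file.path(out, "vocabulary.tsv"))
  run_log(out, "featurize", list(input = input, vocab = vocab),
          list(n_records = nrow(ds), n_excluded = attr(ds, "n_excluded"),
               oov_count = attr(x, "oov_count"), vocabulary_size = nrow(voc)))
  invisible(out)
}

#' @rdname pipeline
#' @param k,repeats,trees cross-validation plan and forest size.
#' @param smote balance training folds by discretized SMOTE.
#' @param vocab_scope `"fold"` or `"full"`.
#' @param classifier `"rf"` or `"nb"`.
#' @export
pipeline_evaluate <- function(input, out, k = 5, repeats = 10, trees = 64,
                              smote = TRUE, vocab_scope = "fold",
                              classifier = "rf", seed = 1234) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ds <- read_bbb_table(input)
  keep <- !is.na(ds$label)
  decs <- decompose_molecules(ds$canonical_smiles[keep])
  y <- ds$label[keep]
  cv <- repeated_kfold(decs, y, k = k, repeats = repeats, num_trees = trees,
                       use_smote = smote, vocab_scope = vocab_scope,
                       classifier = classifier, seed = seed)
  write_json(list(aggregate = cv$aggregate, folds = cv$folds,
                  config = cv$config),
             file.path(out, "metrics.json"))
  # full-data importance ranking (the interpretation model)
  voc <- build_vocabulary(decs)
  x <- featurize(decs, voc)
  if (classifier == "rf") {
    xy <- if (smote) balance_training_set(x, y, seed = seed) else
      list(x = x, y = y)
    fit <- clique_rf(xy$x, xy$y, num_trees = trees, seed = seed)
    write_tsv(mdi_importances(fit, voc), file.path(out, "mdi.tsv"))
  }
  run_log(out, "evaluate",
          list(input = input, k = k, repeats = repeats, trees = trees,
               smote = smote, vocab_scope = vocab_scope,
               classifier = classifier, seed = seed),
          list(n_records = sum(keep), n_excluded = attr(ds, "n_excluded")))
  invisible(out)
}

#' @rdname pipeline
#' @param alpha naive-Bayes smoothing pseudo-count.
#' @param min_df document-frequency filter for the labelled report.
#' @param hi,lo marginal thresholds for enhancers and suppressors.
#' @export
pipeline_interpret <- function(input, out, alpha = 1, min_df = 50, hi = 0.8,
                               lo = 0.2) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ds <- read_bbb_table(input)
  keep <- !is.na(ds$label)
  decs <- decompose_molecules(ds$canonical_smiles[keep])
  voc <- build_vocabulary(decs)
  xb <- binarize(featurize(decs, voc))
  nb <- clique_nb(xb, ds$label[keep], alpha = alpha)
  rep <- clique_report(nb, voc, min_doc_freq = min_df, hi = hi, lo = lo)
  write_tsv(rep$full, file.path(out, "cliques_full.tsv"))
  write_tsv(rep$enhancers, file.path(out, "enhancers.tsv"))
  write_tsv(rep$suppressors, file.path(out, "suppressors.tsv"))
  run_log(out, "interpret",
          list(input = input, alpha = alpha, min_df = min_df, hi = hi,
               lo = lo),
          list(n_records = sum(keep), n_excluded = attr(ds, "n_excluded"),
               vocabulary_size = nrow(voc)))
  invisible(out)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `eda`, `featurize`, `evaluate` and `interpret`
#' subcommands; `inst/cli/bbbcliques` is the executable wrapper. Exit codes:
#' 0 success, 2 usage error, 3 input error, 4 numeric/runtime failure.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly.
#' @export
bbb_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: bbbcliques <simulate|eda|featurize|evaluate|interpret> [options]\n",
        file = stderr())
  }
  if (length(argv) < 1) {
    usage()
    return(invisible(2L))
  }
  sub <- argv[1]
  rest <- argv[-1]
  mk <- optparse::make_option
  specs <- switch(
    sub,
    simulate = list(
      mk("--n", type = "integer", default = 2000),
      mk("--imbalance", type = "double", default = 4956 / 7807),
      mk("--seed", type = "integer", default = 7),
      mk("--out", type = "character", default = "sim_out")),
    eda = list(
      mk("--input", type = "character"),
      mk("--smiles-col", type = "character", default = NULL,
         dest = "smiles_col"),
      mk("--label-col", type = "character", default = NULL,
         dest = "label_col"),
      mk("--out", type = "character", default = "eda_out")),
    featurize = list(
      mk("--input", type = "character"),
      mk("--vocab", type = "character", default = NULL),
      mk("--out", type = "character", default = "features_out")),
    evaluate = list(
      mk("--input", type = "character"),
      mk("--k", type = "integer", default = 5),
      mk("--repeats", type = "integer", default = 10),
      mk("--trees", type = "integer", default = 64),
      mk("--smote", action = "store_true", default = TRUE),
      mk("--no-smote", action = "store_false", dest = "smote"),
      mk("--vocab-scope", type = "character", default = "fold",
         dest = "vocab_scope"),
      mk("--classifier", type = "character", default = "rf"),
      mk("--seed", type = "integer", default = 1234),
      mk("--out", type = "character", default = "eval_out")),
    interpret = list(
      mk("--input", type = "character"),
      mk("--alpha", type = "double", default = 1),
      mk("--min-df", type = "integer", default = 50, dest = "min_df"),
      mk("--hi", type = "double", default = 0.8),
      mk("--lo", type = "double", default = 0.2),
      mk("--out", type = "character", default = "interpret_out")),
    {
      usage()
      return(invisible(2L))
    })
  opts <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = specs),
                         args = rest),
    error = function(e) e)
  if (inherits(opts, "error")) {
    usage()
    return(invisible(2L))
  }
  needs_input <- sub != "simulate"
  if (needs_input && (is.null(opts$input) || !file.exists(opts$input))) {
    cat("input file missing or not found\n", file = stderr())
    return(invisible(3L))
  }
  status <- tryCatch({
    switch(sub,
           simulate = pipeline_simulate(opts$out, n = opts$n,
                                        imbalance = opts$imbalance,
                                        seed = opts$seed),
           eda = pipeline_eda(opts$input, opts$out,
                              smiles_col = opts$smiles_col,
                              label_col = opts$label_col),
           featurize = pipeline_featurize(opts$input, opts$out,
                                          vocab = opts$vocab),
           evaluate = pipeline_evaluate(opts$input, opts$out, k = opts$k,
                                        repeats = opts$repeats,
                                        trees = opts$trees,
                                        smote = opts$smote,
                                        vocab_scope = opts$vocab_scope,
                                        classifier = opts$classifier,
                                        seed = opts$seed),
           interpret = pipeline_interpret(opts$input, opts$out,
                                          alpha = opts$alpha,
                                          min_df = opts$min_df,
                                          hi = opts$hi, lo = opts$lo))
    0L
  }, error = function(e) {
    cat("error: ", conditionMessage(e), "\n", sep = "", file = stderr())
    4L
  })
  invisible(status)
}
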