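test_that("reading a toy table maps yes/no labels and populates all fields", {
  p <- write_toy_tsv(c("CCO", "c1ccccc1", "CCN"), c("yes", "no", "yes"),
                     grades = c("A", "B", "C"),
                     log_bb = c(0.5, -1.2, 0.1))
  ds <- read_bbb_table(p)
  expect_s3_class(ds, "bbb_dataset")
  expect_equal(ds$label, c(1L, 0L, 1L))
  expect_equal(ds$row_index, 0:2)
  expect_equal(ds$quality_grade, c("A", "B", "C"))
  expect_equal(ds$log_bb, c(0.5, -1.2, 0.1))
  expect_equal(ds$name, c("mol01", "mol02", "mol03"))
  expect_true(all(nzchar(ds$canonical_smiles)))
  expect_identical(attr(ds, "n_excluded"), 0L)
})

test_that("label vocabulary accepts the documented synonyms and rejects junk", {
  p <- write_toy_tsv(c("C", "C", "C", "C"), c("BBB+", "FALSE", "1", "No"))
  ds <- read_bbb_table(p)
  expect_equal(ds$label, c(1L, 0L, 1L, 0L))
  p2 <- write_toy_tsv("C", "maybe")
  expect_error(read_bbb_table(p2), "unrecognized")
})

test_that("unparseable SMILES rows are dropped, counted and warned about", {
  p <- write_toy_tsv(c("CCO", "not_a_smiles", "CC"), c("yes", "no", "no"))
  expect_warning(ds <- read_bbb_table(p), "unparseable")
  expect_equal(nrow(ds), 2L)
  expect_identical(attr(ds, "n_excluded"), 1L)
  expect_equal(ds$row_index, 0:1)  # reindexed contiguous
})

test_that("column map errors are raised for missing mapped columns", {
  p <- write_toy_tsv("CCO", "yes")
  expect_error(read_bbb_table(p, b3db_columns(smiles = "nope")),
               "not found in header")
  expect_error(read_bbb_table(p, b3db_columns(label = 99L)), "out of range")
  empty <- tempfile(fileext = ".tsv")
  writeLines("compound_name\tSMILES\tInChI\tBBB+/BBB-\tgroup\tlogBB", empty)
  expect_error(read_bbb_table(empty), "no data rows")
})

test_that("write/read round trip preserves every populated field", {
  p <- write_toy_tsv(c("CCO", "CC1CCCCC1"), c("yes", "no"),
                     grades = c("A", "D"), log_bb = c(0.25, ""))
  ds <- read_bbb_table(p)
  p2 <- tempfile(fileext = ".tsv")
  write_bbb_table(ds, p2)
  ds2 <- read_bbb_table(p2)
  for (col in c("name", "smiles", "canonical_smiles", "label",
                "quality_grade", "log_bb")) {
    expect_equal(ds2[[col]], ds[[col]], info = col)
  }
})

test_that("canonicalization unifies atom order, ring numbering and stereo", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize("C1CCCCC1"), canonicalize("C2CCCCC2"))
  expect_identical(canonicalize("C1CCCC1"), canonicalize("C(CC1)CC1"))
  expect_identical(canonicalize("F/C=C/F"), canonicalize("FC=CF"))
  expect_identical(canonicalize("C[C@H](N)O"), canonicalize("CC(N)O"))
  expect_error(canonicalize("not_a_smiles"), "failed to parse")
})

test_that("canonicalize is idempotent on 200 random valid SMILES", {
  smis <- random_small_molecules(200)
  c1 <- canonical_smiles(smis)
  c2 <- canonical_smiles(c1)
  expect_false(anyNA(c1))
  expect_identical(c2, c1)
})

test_that("log BB is log10 of the brain/blood ratio and unit invariant", {
  expect_equal(log_bb(1, 1), 0)
  expect_equal(log_bb(10, 1), 1)
  expect_equal(log_bb(1, 10), -1)  # the B3DB class threshold value
  expect_error(log_bb(0, 1), "strictly positive")
  expect_error(log_bb(1, -2), "strictly positive")
  set.seed(99)
  for (i in 1:20) {
    a <- runif(1, 0.01, 100); cb <- runif(1, 0.01, 50); cv <- runif(1, 0.01, 50)
    expect_equal(log_bb(a * cb, a * cv), log_bb(cb, cv), tolerance = 1e-12)
  }
})

test_that("molecular weight matches atomic-mass sums with implicit hydrogens", {
  expect_equal(mol_weight("C"), 16.04, tolerance = 0.01)
  expect_equal(mol_weight("O"), 18.02, tolerance = 0.01)
  expect_equal(mol_weight("CCO"), 46.07, tolerance = 0.01)
  expect_error(mol_weight(""), "empty")
  # data.frame records are accepted
  p <- write_toy_tsv("O", "yes")
  ds <- read_bbb_table(p)
  expect_equal(mol_weight(ds[1, ]), 18.02, tolerance = 0.01)
})

test_that("clogp is deterministic, tracks lipophilicity, and covers fragments", {
  expect_identical(clogp("CC(=O)Oc1ccccc1C(=O)O"),
                   clogp("CC(=O)Oc1ccccc1C(=O)O"))
  expect_lt(clogp("CCO"), clogp("CCCCCCCC"))
  expect_true(is.finite(clogp("C1CCNCC1")))  # piperidine fragment
  expect_error(clogp("not_a_smiles"), "failed to parse")
})

test_that("pearson matches the closed form and a covariance/sigma oracle", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
    expect_equal(pearson(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("eda summary emits 4 correlation cells over log BB records only", {
  smis <- c("CCO", "CCCO", "CCCCO", "CCCCCO", "c1ccccc1", "Cc1ccccc1",
            "CCc1ccccc1", "CCCc1ccccc1")
  labs <- c("yes", "yes", "yes", "yes", "no", "no", "no", "no")
  lbb <- c(0.2, 0.1, 0.4, "", -1.2, -1.4, -1.1, -1.6)
  p <- write_toy_tsv(smis, labs, log_bb = lbb)
  eda <- eda_summary(read_bbb_table(p))
  expect_equal(nrow(eda$correlations), 4L)
  expect_setequal(unique(eda$correlations$feature), c("mw", "clogp"))
  expect_setequal(unique(eda$correlations$class), c("BBBP-", "BBBP+"))
  # the record lacking log BB is excluded from the positive-class cells
  expect_equal(unique(eda$correlations$n[eda$correlations$class == "BBBP+"]), 3L)
  # but included in the density samples
  expect_equal(sum(eda$samples$class == "BBBP+"), 4L)
})

test_that("degenerate per-class distributions raise the KDE flag", {
  p <- write_toy_tsv(c("CCO", "OCC", "c1ccccc1"), c("yes", "yes", "no"))
  eda <- eda_summary(read_bbb_table(p))
  cell <- eda$kde[["BBBP+.mw"]]
  expect_true(cell$degenerate)
  rng <- eda$ranges[eda$ranges$class == "BBBP+" & eda$ranges$feature == "mw", ]
  expect_equal(rng$min, rng$max)
  p2 <- write_toy_tsv("CCO", "yes")
  ds2 <- read_bbb_table(p2)
  ds2$label <- NA_integer_
  expect_error(eda_summary(ds2), "no labelled records")
})
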