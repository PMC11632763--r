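# The decomposition rule set: each smallest ring (bridged systems merged)
# plus each non-ring bond, fragments as kekulized stereo-free canonical
# SMILES. Expected fragment strings are written via canonical_smiles() so
# the assertions express chemical identity, not a SMILES dialect.

frag_of <- function(s) canonical_smiles(s, kekulize = TRUE)

test_that("single rings, single bonds and their combinations decompose correctly", {
  expect_identical(decompose("C1CCCC1")$fragments, frag_of("C1CCCC1"))
  expect_identical(decompose("CF")$fragments, frag_of("CF"))
  expect_setequal(decompose("CCO")$fragments, frag_of(c("CC", "CO")))
  expect_identical(decompose("C1COCCN1")$fragments, frag_of("C1COCCN1"))
  d <- decompose("CC1CCCCC1")
  expect_setequal(d$fragments, frag_of(c("C1CCCCC1", "CC")))
  expect_length(d$fragments, 2L)
})

test_that("repeated cliques are counted per occurrence", {
  d <- decompose("FCF")
  expect_identical(sort(d$fragments), rep(frag_of("CF"), 2))
  dd <- decompose("OCC(O)CO")  # glycerol: 2x CC, 3x CO
  expect_equal(sum(dd$fragments == frag_of("CC")), 2L)
  expect_equal(sum(dd$fragments == frag_of("CO")), 3L)
})

test_that("rings sharing more than two atoms merge into one bridged clique", {
  d <- decompose("C1CC2CCC1C2")  # norbornane
  expect_length(d$fragments, 1L)
  expect_identical(d$fragments, frag_of("C1CC2CCC1C2"))
  expect_equal(d$cliques[[1]]$type, "ring")
  expect_length(d$cliques[[1]]$atoms, 7L)
})

test_that("fused rings sharing one bond stay separate; the bond is owned once", {
  d <- decompose("c1ccc2ccccc2c1")  # naphthalene
  expect_length(d$fragments, 2L)
  owned <- sort(unlist(lapply(d$cliques, `[[`, "bonds")))
  expect_identical(owned, seq_len(d$n_bonds))  # 11 bonds, each owned once
  # both ring substructures contain the shared bond
  expect_equal(sum(lengths(lapply(d$cliques, `[[`, "bonds_all"))), 12L)
})

test_that("single heavy atoms and salt components yield single-atom cliques", {
  expect_identical(decompose("C")$fragments, frag_of("C"))
  d <- decompose("[Na+].OC(=O)c1ccccc1")
  expect_true(frag_of("[Na+]") %in% d$fragments)
  expect_true(frag_of("c1ccccc1") %in% d$fragments)
})

test_that("fragment strings retain formal charges", {
  d <- decompose("C[N+](C)(C)C")
  expect_length(d$fragments, 4L)
  expect_true(all(grepl("\\+", d$fragments)))
})

test_that("every atom is covered and every bond owned exactly once (random molecules)", {
  smis <- random_small_molecules(80)
  decs <- decompose_molecules(smis)
  for (i in seq_along(decs)) {
    d <- decs[[i]]
    atoms <- sort(unique(unlist(lapply(d$cliques, `[[`, "atoms"))))
    expect_identical(atoms, seq_len(d$n_atoms), info = smis[i])
    owned <- sort(unlist(lapply(d$cliques, `[[`, "bonds")))
    expect_identical(as.integer(owned), seq_len(d$n_bonds), info = smis[i])
    expect_length(d$fragments, length(d$cliques))
  }
})

test_that("fragment multisets are invariant under random atom reorderings", {
  smis <- random_small_molecules(25)
  graphs <- bbbcliques:::parse_smiles_graphs(smis)
  set.seed(314)
  for (i in seq_along(smis)) {
    ref <- sort(decompose(smis[i])$fragments)
    for (rep in 1:2) {
      perm <- sample(nrow(graphs[[i]]$atoms))
      pg <- bbbcliques:::permute_graph(graphs[[i]], perm)
      expect_identical(decompose_graph_fragments(pg), ref,
                       info = paste(smis[i], "perm", rep))
    }
  }
})

test_that("vocabulary collapses duplicates and counts documents, not occurrences", {
  voc <- build_vocabulary(list(c("CC", "CO"), c("CC", "CO")))
  expect_equal(nrow(voc), 2L)
  expect_equal(voc$doc_freq, c(2L, 2L))
  voc2 <- build_vocabulary(list("CF", "CC"))
  expect_equal(nrow(voc2), 2L)
  voc3 <- build_vocabulary(list(c("CF", "CF", "CF")))
  expect_equal(voc3$doc_freq, 1L)
  expect_error(build_vocabulary(list()), "no molecules")
})

test_that("vocabulary ordering is deterministic: doc freq desc, then lexicographic", {
  frags <- list(c("CO", "CC"), c("CC", "CF"), c("CO"))
  voc <- build_vocabulary(frags)
  expect_equal(voc$fragment, c("CC", "CO", "CF"))
  expect_equal(voc$index, 0:2)
  expect_identical(build_vocabulary(frags), voc)
})

test_that("featurize counts occurrences and tallies out-of-vocabulary cliques", {
  voc <- build_vocabulary(list("CC", "CO", "CF"))
  x <- featurize(list(c("CC", "CO")), voc)
  expect_equal(as.integer(x[1, c("CC", "CO", "CF")]), c(1L, 1L, 0L))
  x2 <- featurize(list(c("CF", "CF")), voc)
  expect_equal(as.integer(x2[1, "CF"]), 2L)
  x3 <- featurize(list(c("CC", "ZZ")), voc)
  expect_equal(attr(x3, "oov_count"), 1L)
  expect_equal(sum(x3), 1L)
})

test_that("feature row sums equal decomposition lengths", {
  smis <- random_small_molecules(40)
  decs <- decompose_molecules(smis)
  voc <- build_vocabulary(decs)
  x <- featurize(decs, voc)
  expect_equal(unname(rowSums(x)),
               vapply(decs, function(d) length(d$fragments), numeric(1)))
  expect_equal(attr(x, "oov_count"), 0L)
})

test_that("binarize thresholds counts at presence and is idempotent", {
  m <- matrix(c(0L, 1L, 5L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
  b <- binarize(m)
  expect_equal(b[1, ], c(0L, 1L, 1L))
  expect_equal(b[2, ], c(0L, 0L, 0L))
  expect_identical(binarize(b), b)
})
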