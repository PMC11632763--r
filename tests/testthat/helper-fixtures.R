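# Shared fixtures: tiny TSV tables and random small molecules.

# Write a minimal labelled molecule table; returns the path.
write_toy_tsv <- function(smiles, labels,
                          names = sprintf("mol%02d", seq_along(smiles)),
                          grades = NULL, log_bb = NULL,
                          path = tempfile(fileext = ".tsv")) {
  df <- data.frame(compound_name = names,
                   SMILES = smiles,
                   InChI = "",
                   `BBB+/BBB-` = labels,
                   group = if (is.null(grades)) "" else grades,
                   logBB = if (is.null(log_bb)) "" else log_bb,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A deterministic pool of random drug-like small molecules (<= 20 heavy
# atoms): generator molecules plus hand-picked diverse structures covering
# fused/bridged/spiro rings, charges, salts and multiple components.
random_small_molecules <- function(n, seed = 421) {
  gen <- generate_bbb_dataset(bbb_generator_spec(n_molecules = max(n, 50),
                                                 seed = seed))
  extra <- c("c1ccc2ccccc2c1",        # fused aromatic
             "C1CC2CCC1C2",           # bridged bicyclic
             "C1CCC2(CC1)CCCC2",      # spiro
             "CC(=O)Oc1ccccc1C(=O)O", # aspirin
             "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", # caffeine
             "C[N+](C)(C)C",          # quaternary ammonium
             "[Na+].OC(=O)c1ccccc1",  # salt, two components
             "OCC(O)CO",              # glycerol
             "FC(F)(F)c1ccccc1",      # trifluoromethylbenzene
             "O=[N+]([O-])c1ccccc1",  # nitrobenzene
             "C1CSCN1",               # thiazolidine
             "C1CCOCC1")              # oxane
  smis <- c(extra, gen$dataset$smiles)
  head(smis, n)
}

# Fragment multiset of a decomposition or graph, as a sorted string vector.
decompose_graph_fragments <- function(graph) {
  sk <- bbbcliques:::decompose_graph_skeleton(graph)
  for (j in seq_along(sk$blocks)) sk$blocks[[j]][1] <- paste0("g", j)
  sort(bbbcliques:::molblocks_to_canonical(sk$blocks))
}
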