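# bbbcliques

Transparent clique-fragment models of blood-brain barrier permeability
(BBBP), for cheminformaticians and CNS drug-discovery scientists who want
classifiers whose every decision can be traced to a named piece of
chemistry.

Most accurate BBBP predictors blend hundreds of opaque descriptors. This
package instead represents a molecule purely as counts of **cliques** —
interpretable molecular fragments: each smallest ring (bridged ring systems
merged), every non-ring bond as a two-atom fragment, and isolated atoms.
On top of that single descriptor it provides:

- a **Gini random forest** (64 trees, standard defaults, no tuning)
  evaluated by repeated 5-fold × 10 cross-validation with sensitivity,
  specificity, Matthews correlation coefficient (MCC) and ROC AUC;
- **discretized SMOTE**: minority-class balancing of training folds by
  interpolating two random minority rows and rounding,
  `round(a + t·(b − a))`, so synthetic rows stay integer count vectors;
  never applied to validation data;
- **mean-decrease-in-impurity (MDI)** fragment importances, normalized to
  sum to one, with their spread across trees;
- a **Bernoulli naive-Bayes** analysis that inverts the classifier into a
  per-fragment statistic

  P(BBB+ | clique present) = P(clique | BBB+)·P(BBB+) / P(clique),

  the marginal probability that a molecule permeates the barrier given the
  fragment is present — with α = 0 exactly the empirical fraction
  count(clique, BBB+) / count(clique);
- a reader/writer for **B3DB-style** tab-separated molecule tables
  (name, SMILES, InChI, yes/no label, quality grade A–D, optional
  log BB = log10(C_brain/C_blood)) and exploratory statistics (molecular
  weight, Wildman–Crippen clogP, per-class densities, log BB
  correlations);
- a **synthetic-data generator** with planted fragment effects whose true
  marginals are computable exactly by enumeration — the package's built-in
  ground truth.

Chemistry (SMILES parsing, canonicalization, kekulization, MW, clogP) runs
through OpenBabel's `obabel`, which must be on the PATH; ring perception
uses ChemmineR; trees use ranger.

## Worked example

```r
library(bbbcliques)

# synthetic B3DB-style table with planted fragment effects
dir <- tempfile(); pipeline_simulate(dir, n = 500, seed = 42)
ds <- read_bbb_table(file.path(dir, "molecules.tsv"))

decompose("CC1CCNCC1")   # methylpiperidine
#> Clique decomposition of CC1CCNCC1
#>   7 heavy atoms, 7 bonds, 2 cliques
#>   C1CCCNC1 x1
#>   CC x1
```

The two cliques are the piperidine ring (canonical form `C1CCCNC1`) and
the exocyclic C–C bond. Featurize and evaluate:

```r
decs <- decompose_molecules(ds$canonical_smiles)
cv <- repeated_kfold(decs, ds$label, k = 5, repeats = 3,
                     num_trees = 64, seed = 1)
cv
#> Repeated 5-fold CV, 3 repeats (random forest, 64 trees, SMOTE, vocabulary: fold fold)
#>   SN   0.898 +/- 0.040
#>   SP   0.906 +/- 0.074
#>   MCC  0.788 +/- 0.065
#>   AUC  0.945 +/- 0.024
```

Each fold trains on four fifths of the data (SMOTE-balanced), scores the
untouched fifth, and the table aggregates all 15 folds: the forest detects
~90% of permeating and ~91% of non-permeating molecules here. The
naive-Bayes marginals then name the responsible fragments:

```r
voc <- build_vocabulary(decs)
nb <- clique_nb(binarize(featurize(decs, voc)), ds$label)
rep <- clique_report(nb, voc, min_doc_freq = 50)
rep$enhancers
#>   fragment doc_freq p_bbb_pos fragment_clogp
#> 1  C1CCCC1       95 0.9692386         1.9505
#> 2 C1CCCNC1       96 0.9594011         1.0887
#> 3 C1CNCCO1      108 0.9366946        -0.0650
#> 4       CF      138 0.8649374         0.5857
#> 5      C=N      111 0.8414521         0.3655
rep$suppressors
#>    fragment doc_freq p_bbb_pos fragment_clogp
#> 1 C1=NN=NN1       92 0.1175978        -0.8003
```

A molecule containing cyclopentane permeated in 97% of cases in this
sample; the tetrazole ring in only 12% — recovering the effects the
generator planted, with each fragment's clogP as a lipophilicity
indicator.

A command-line front end wraps the same stages:

```sh
Rscript inst/cli/bbbcliques simulate --n 2000 --seed 7 --out sim
Rscript inst/cli/bbbcliques evaluate --input sim/molecules.tsv --k 5 --repeats 10 --trees 64 --out eval
Rscript inst/cli/bbbcliques interpret --input sim/molecules.tsv --out interp
```

Every output directory contains a `config.json` with the resolved options,
seeds and input hash; identical configurations reproduce outputs
bit-identically.

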