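# Clique decomposition of molecules.
#
# A molecule is dissected into "cliques": (i) each smallest ring, with rings
# sharing more than two atoms merged into one bridged ring system, and
# (ii) every bond that does not belong to any ring, as a two-atom fragment.
# Isolated heavy atoms (single-heavy-atom molecules, counter-ions in salts)
# yield single-atom cliques so that no record is featureless. The union of
# clique atom sets covers all heavy atoms; every bond is *owned* by exactly
# one clique (a bond shared by two fused rings appears in both ring fragments
# but is counted once, for its first owner, in the bond partition).
#
# Fragment strings are canonical SMILES of the induced substructure,
# kekulized and stereo-free, with formal charges retained and hydrogens
# implicit.

#' Decompose molecules into clique fragments
#'
#' @param smiles a single SMILES string (`decompose`) or a character vector
#'   (`decompose_molecules`).
#' @return `decompose` returns a `clique_decomposition` object: a list with
#'   `fragments` (canonical kekulized fragment SMILES, one per clique),
#'   `cliques` (per clique: `atoms`, owned `bonds`, `bonds_all`, `type` among
#'   ring/bond/atom), `n_atoms`, `n_bonds` and the input `smiles`.
#'   `decompose_molecules` returns a list of such objects (entries are `NA`
#'   for unparseable SMILES, with a warning).
#' @examples
#' \dontrun{
#' decompose("CCO")$fragments        # "CC", "CO"
#' decompose("C1CCCC1")$fragments    # one ring clique
#' }
#' @export
decompose <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- decompose_molecules(smiles)[[1]]
  if (!inherits(res, "clique_decomposition")) {
    stop("SMILES failed to parse: ", smiles, call. = FALSE)
  }
  res
}

#' @rdname decompose
#' @export
decompose_molecules <- function(smiles) {
  graphs <- parse_smiles_graphs(smiles)
  out <- vector("list", length(smiles))
  skeletons <- vector("list", length(smiles))
  molblocks <- list()
  for (i in seq_along(graphs)) {
    if (is.null(graphs[[i]])) next
    sk <- decompose_graph_skeleton(graphs[[i]])
    for (j in seq_along(sk$blocks)) {
      sk$blocks[[j]][1] <- paste0("f", i, "_", j)
    }
    skeletons[[i]] <- sk
    molblocks <- c(molblocks, sk$blocks)
  }
  frags <- molblocks_to_canonical(molblocks)
  names(frags) <- vapply(molblocks, `[`, character(1), 1L)
  for (i in seq_along(graphs)) {
    if (is.null(skeletons[[i]])) {
      out[[i]] <- NA
      next
    }
    sk <- skeletons[[i]]
    ids <- paste0("f", i, "_", seq_along(sk$cliques))
    dec <- list(smiles = smiles[i],
                fragments = unname(frags[ids]),
                cliques = sk$cliques,
                n_atoms = sk$n_atoms,
                n_bonds = sk$n_bonds)
    class(dec) <- "clique_decomposition"
    out[[i]] <- dec
  }
  n_bad <- sum(vapply(out, function(x) !inherits(x, "clique_decomposition"),
                      logical(1)))
  if (n_bad > 0) {
    warning(n_bad, " SMILES failed to parse and were not decomposed",
            call. = FALSE)
  }
  out
}

#' @export
print.clique_decomposition <- function(x, ...) {
  cat("Clique decomposition of", x$smiles, "\n")
  cat(sprintf("  %d heavy atoms, %d bonds, %d cliques\n",
              x$n_atoms, x$n_bonds, length(x$fragments)))
  tab <- table(x$fragments)
  cat(paste0("  ", names(tab), " x", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

# Decomposition on a parsed graph. Returns clique structure plus the mol
# blocks still awaiting canonicalization (titles are placeholders).
decompose_graph_skeleton <- function(graph) {
  n_atoms <- nrow(graph$atoms)
  n_bonds <- nrow(graph$bonds)
  ring_atom_sets <- smallest_rings(graph)
  groups <- merge_bridged_rings(ring_atom_sets)

  cliques <- list()
  blocks <- list()
  ring_bond_rows <- integer(0)
  # ring-system cliques, ordered by smallest atom index for determinism
  if (length(groups) > 0) {
    groups <- groups[order(vapply(groups, function(g) min(g$atoms),
                                  integer(1)))]
    for (grp in groups) {
      rows <- group_bond_rows(graph$bonds, grp$rings)
      ring_bond_rows <- c(ring_bond_rows, rows)
      cliques[[length(cliques) + 1L]] <-
        list(atoms = sort(grp$atoms), bonds_all = rows, type = "ring")
      blocks[[length(blocks) + 1L]] <-
        subgraph_molblock(graph, grp$atoms, rows)
    }
  }
  # non-ring bonds
  nonring <- setdiff(seq_len(n_bonds), unique(ring_bond_rows))
  for (r in nonring) {
    at <- c(graph$bonds$from[r], graph$bonds$to[r])
    cliques[[length(cliques) + 1L]] <-
      list(atoms = sort(at), bonds_all = r, type = "bond")
    blocks[[length(blocks) + 1L]] <- subgraph_molblock(graph, at, r)
  }
  # isolated atoms
  deg <- tabulate(c(graph$bonds$from, graph$bonds$to), nbins = n_atoms)
  for (a in which(deg == 0)) {
    cliques[[length(cliques) + 1L]] <-
      list(atoms = a, bonds_all = integer(0), type = "atom")
    blocks[[length(blocks) + 1L]] <- subgraph_molblock(graph, a, integer(0))
  }
  # bond ownership: first clique containing the bond owns it
  owned <- rep(FALSE, n_bonds)
  for (j in seq_along(cliques)) {
    b <- cliques[[j]]$bonds_all
    cliques[[j]]$bonds <- b[!owned[b]]
    owned[cliques[[j]]$bonds] <- TRUE
  }
  list(cliques = cliques, blocks = blocks,
       n_atoms = n_atoms, n_bonds = n_bonds)
}

# All smallest rings as a list of integer atom-index vectors.
smallest_rings <- function(graph) {
  if (!is_cyclic(graph$atoms, graph$bonds)) return(list())
  stopifnot(!is.null(graph$sdf))
  rl <- ChemmineR::rings(graph$sdf, type = "all", inner = TRUE)
  lapply(rl, function(r) sort(as.integer(sub("^.*_", "", r))))
}

n_components <- function(n_atoms, bonds) {
  parent <- seq_len(n_atoms)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(bonds))) {
    ri <- find(bonds$from[r]); rj <- find(bonds$to[r])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n_atoms), find, integer(1))))
}

# Merge smallest rings sharing more than two atoms (bridged systems) into
# one clique; rings sharing at most two atoms (fused or spiro) stay separate.
merge_bridged_rings <- function(ring_atom_sets) {
  n <- length(ring_atom_sets)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (length(intersect(ring_atom_sets[[i]], ring_atom_sets[[j]])) > 2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(members) {
    list(atoms = sort(unique(unlist(ring_atom_sets[members]))),
         rings = ring_atom_sets[members])
  })
}

# Bond rows of a ring group: bonds whose two endpoints lie within a single
# constituent smallest ring (chords cannot occur in smallest rings).
group_bond_rows <- function(bonds, ring_list) {
  rows <- integer(0)
  for (ring in ring_list) {
    inring <- bonds$from %in% ring & bonds$to %in% ring
    rows <- c(rows, which(inring))
  }
  sort(unique(rows))
}
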