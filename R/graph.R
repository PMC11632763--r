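# Molecular graphs: atoms (element, formal charge) + bonds (from, to, order).
#
# Graphs are obtained by converting SMILES to kekulized MDL mol blocks with
# OpenBabel. The fixed-format V2000 records are read directly (ChemmineR's
# SDF reader rejects valid zero-bond records such as single-atom molecules);
# ChemmineR is used for ring perception, which only ever sees cyclic - hence
# well-formed - records. Formal charges come from "M  CHG" property lines.
# Hydrogens stay implicit throughout.

# Parse a vector of SMILES into molecular graphs.
# Returns a list the same length as `smiles`; failed parses are NULL.
# Each graph: list(atoms = data.frame(element, charge),
#                  bonds = data.frame(from, to, order),
#                  sdf = ChemmineR SDF or NULL for acyclic-trivial records)
parse_smiles_graphs <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste(smiles[idx], paste0("m", seq_along(idx))), tmp_in)
  run_obabel(c(shQuote(tmp_in), "-osdf", "-O", shQuote(tmp_out), "-e"))
  if (!file.exists(tmp_out) || file.size(tmp_out) == 0) return(out)
  graphs <- molblock_lines_to_graphs(readLines(tmp_out))
  pos <- match(paste0("m", seq_along(idx)), names(graphs))
  for (k in seq_along(idx)) {
    if (!is.na(pos[k])) out[[idx[k]]] <- graphs[[pos[k]]]
  }
  out
}

# Parse concatenated SDF text (character vector of lines, records separated
# by $$$$) into a named list of graphs, keyed by record title.
molblock_lines_to_graphs <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  graphs <- vector("list", length(ends))
  titles <- character(length(ends))
  with_rings <- integer(0)
  for (i in seq_along(ends)) {
    rec <- lines[starts[i]:(ends[i] - 1L)]
    g <- parse_molblock(rec)
    titles[i] <- g$title
    graphs[[i]] <- g[c("atoms", "bonds")]
    if (is_cyclic(g$atoms, g$bonds)) with_rings <- c(with_rings, i)
  }
  # attach ChemmineR SDF objects where ring perception may be needed
  if (length(with_rings) > 0) {
    txt <- unlist(lapply(with_rings,
                         function(i) lines[starts[i]:ends[i]]))
    sdfset <- methods::as(ChemmineR::read.SDFstr(txt), "SDFset")
    for (k in seq_along(with_rings)) {
      graphs[[with_rings[k]]]$sdf <- sdfset[[k]]
    }
  }
  names(graphs) <- titles
  graphs
}

# Minimal V2000 mol block parser: atoms, bonds, formal charges.
parse_molblock <- function(rec) {
  title <- trimws(rec[1])
  counts <- rec[4]
  n_a <- as.integer(substr(counts, 1, 3))
  n_b <- as.integer(substr(counts, 4, 6))
  atom_lines <- rec[seq_len(n_a) + 4L]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(n_a)
  if (n_b > 0) {
    bond_lines <- rec[seq_len(n_b) + 4L + n_a]
    bonds <- data.frame(from = as.integer(substr(bond_lines, 1, 3)),
                        to = as.integer(substr(bond_lines, 4, 6)),
                        order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    for (p in seq_len(flds[1])) {
      charge[flds[2 * p]] <- flds[2 * p + 1]
    }
  }
  list(title = title,
       atoms = data.frame(element = element, charge = charge,
                          stringsAsFactors = FALSE),
       bonds = bonds)
}

# Build a V2000 mol block (character vector of lines, no $$$$ terminator)
# from atoms/bonds tables. Coordinates are zero; connectivity is all that
# downstream canonicalization needs.
graph_to_molblock <- function(atoms, bonds, title = "frag") {
  n_a <- nrow(atoms)
  n_b <- nrow(bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b)
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$element)
  bond_lines <- if (n_b > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order)
  } else character(0)
  chg_idx <- which(atoms$charge != 0)
  chg_lines <- if (length(chg_idx) > 0) {
    # at most 8 atom/value pairs per M CHG line
    chunks <- split(chg_idx, ceiling(seq_along(chg_idx) / 8))
    vapply(chunks, function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, atoms$charge[ix]), collapse = ""))
    }, character(1))
  } else character(0)
  c(title, "  bbbcliques", "", counts, atom_lines, bond_lines, chg_lines,
    "M  END")
}

# Induced subgraph on a set of atom indices, restricted to a given set of
# bond rows; atoms are renumbered 1..k preserving order.
subgraph_molblock <- function(graph, atom_idx, bond_rows, title = "frag") {
  atom_idx <- sort(unique(atom_idx))
  remap <- match(seq_len(nrow(graph$atoms)), atom_idx)
  b <- graph$bonds[bond_rows, , drop = FALSE]
  bonds <- data.frame(from = remap[b$from], to = remap[b$to], order = b$order)
  graph_to_molblock(graph$atoms[atom_idx, , drop = FALSE], bonds, title)
}

# Random atom-order permutation of a graph (used by invariance tests).
permute_graph <- function(graph, perm) {
  n <- nrow(graph$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  atoms <- graph$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- data.frame(from = inv[graph$bonds$from], to = inv[graph$bonds$to],
                      order = graph$bonds$order)
  g <- list(atoms = atoms, bonds = bonds)
  if (is_cyclic(atoms, bonds)) {
    g$sdf <- .molblock_to_sdf(graph_to_molblock(atoms, bonds, "perm"))
  }
  g
}

is_cyclic <- function(atoms, bonds) {
  nrow(bonds) - nrow(atoms) + n_components(nrow(atoms), bonds) > 0
}

.molblock_to_sdf <- function(molblock) {
  sdfset <- methods::as(ChemmineR::read.SDFstr(c(molblock, "$$$$")), "SDFset")
  sdfset[[1]]
}
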