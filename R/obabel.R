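# Interface to the OpenBabel command-line tool (obabel).
#
# All conversions are batched: one obabel invocation per vector of molecules,
# with per-molecule titles ("m1", "m2", ...) used to re-align output with
# input, since obabel silently skips records it cannot parse (-e keeps it
# going after an error instead of aborting the whole batch).

obabel_bin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("The 'obabel' executable was not found on PATH; OpenBabel is required.",
         call. = FALSE)
  }
  bin
}

run_obabel <- function(args, stdin_file = NULL) {
  out <- suppressWarnings(system2(obabel_bin(), args = args,
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 && length(out) == 0) {
    stop("obabel failed (exit status ", status, ")", call. = FALSE)
  }
  as.character(out)
}

# Split "SMILES\ttitle" output lines into a title -> smiles map.
.parse_titled_smiles <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1L)
  ttl <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                character(1))
  stats::setNames(smi, ttl)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES with stereochemistry
#' descriptors stripped, so that any two SMILES describing the same molecular
#' graph (regardless of atom order, ring-numbering or stereo annotation) map
#' to the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @param kekulize logical; write aromatic rings in Kekule (alternating
#'   single/double bond) form. Fragment strings in this package are always
#'   kekulized; whole-molecule canonical SMILES are not by default.
#' @return character vector of canonical SMILES; `NA` where the input did not
#'   parse. `canonicalize()` is the strict scalar variant that raises an error
#'   on unparseable input.
#' @examples
#' \dontrun{
#' canonical_smiles(c("OCC", "CCO"))  # identical outputs
#' }
#' @export
canonical_smiles <- function(smiles, kekulize = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  tmp_in <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(paste(smiles[idx], paste0("m", seq_along(idx))), tmp_in)
  args <- c(shQuote(tmp_in), "-ocan", "-xi", "-e")
  res <- .parse_titled_smiles(run_obabel(args))
  pos <- match(paste0("m", seq_along(idx)), names(res))
  out[idx] <- unname(res[pos])
  if (kekulize) out <- .kekulize_canonical(out)
  out
}

# Kekulized canonical form. OpenBabel's Kekule assignment for aromatic rings
# depends on input atom order, so kekulization runs as a second pass over
# the (order-invariant) aromatic canonical strings: identical input strings
# then yield identical Kekule strings.
.kekulize_canonical <- function(canonical) {
  ok <- which(!is.na(canonical))
  if (length(ok) == 0) return(canonical)
  uniq <- unique(canonical[ok])
  tmp_in <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(paste(uniq, paste0("k", seq_along(uniq))), tmp_in)
  res <- .parse_titled_smiles(
    run_obabel(c(shQuote(tmp_in), "-ocan", "-xi", "-xk", "-e")))
  kek <- unname(res[match(paste0("k", seq_along(uniq)), names(res))])
  canonical[ok] <- kek[match(canonical[ok], uniq)]
  canonical
}

#' @rdname canonical_smiles
#' @export
canonicalize <- function(smiles, kekulize = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- canonical_smiles(smiles, kekulize = kekulize)
  if (is.na(out)) stop("SMILES failed to parse: ", smiles, call. = FALSE)
  out
}

# Canonical kekulized stereo-free SMILES for a batch of MDL mol blocks
# (a list of character vectors, one block per fragment).
molblocks_to_canonical <- function(molblocks) {
  if (length(molblocks) == 0) return(character(0))
  tmp_in <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(unlist(lapply(molblocks, function(b) c(b, "$$$$"))), tmp_in)
  args <- c(shQuote(tmp_in), "-isdf", "-ocan", "-xi", "-e")
  res <- .parse_titled_smiles(run_obabel(args))
  titles <- vapply(molblocks, `[`, character(1), 1L)
  out <- unname(res[match(titles, names(res))])
  if (anyNA(out)) {
    stop("OpenBabel failed to canonicalize ", sum(is.na(out)),
         " fragment block(s)", call. = FALSE)
  }
  .kekulize_canonical(out)
}

#' Molecular weight and Wildman-Crippen logP
#'
#' Computes the average-atomic-mass molecular weight (g/mol, implicit
#' hydrogens included) and the Wildman-Crippen atomic-contribution logP for
#' each structure. Both come from OpenBabel's descriptor engine; its `logP`
#' implements the Wildman-Crippen model, applicable to whole molecules and to
#' fragment strings alike (fragment values are qualitative indicators of
#' lipophilicity only).
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `smiles`, `mw`, `clogp`; `NA` rows where
#'   the structure did not parse.
#' @export
mol_descriptors <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- data.frame(smiles = smiles, mw = NA_real_, clogp = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  tmp_in <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp_in), add = TRUE)
  writeLines(paste(smiles[idx], paste0("m", seq_along(idx))), tmp_in)
  lines <- run_obabel(c(shQuote(tmp_in), "-otxt", "--append", "'MW logP'", "-e"))
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  keep <- vapply(parts, length, integer(1)) >= 3
  parts <- parts[keep]
  ttl <- vapply(parts, `[`, character(1), 1L)
  mw <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  lp <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  pos <- match(paste0("m", seq_along(idx)), ttl)
  out$mw[idx] <- mw[pos]
  out$clogp[idx] <- lp[pos]
  out
}

#' @rdname mol_descriptors
#' @param record a single SMILES string (or a one-row data.frame with a
#'   `canonical_smiles` or `smiles` column, as produced by [read_bbb_table()]).
#' @export
mol_weight <- function(record) {
  smi <- .record_smiles(record)
  d <- mol_descriptors(smi)
  if (is.na(d$mw)) stop("SMILES failed to parse: ", smi, call. = FALSE)
  d$mw
}

#' @rdname mol_descriptors
#' @param structure a single SMILES string (whole molecule or fragment).
#' @export
clogp <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  d <- mol_descriptors(structure)
  if (is.na(d$clogp)) stop("SMILES failed to parse: ", structure, call. = FALSE)
  d$clogp
}

.record_smiles <- function(record) {
  if (is.data.frame(record)) {
    col <- intersect(c("canonical_smiles", "smiles"), names(record))[1]
    if (is.na(col)) stop("record has no SMILES column", call. = FALSE)
    smi <- record[[col]][1]
  } else {
    smi <- record[1]
  }
  if (is.na(smi) || !nzchar(smi)) stop("empty SMILES", call. = FALSE)
  as.character(smi)
}
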