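# Molecular layer: thin wrappers around OpenBabel (through ChemmineOB).
# All chemistry in the package funnels through this file so that one
# canonicalization procedure, one fingerprint routine and one SMARTS engine
# are used everywhere (pairing, dedup, uniqueness, filtering, rewards).
#
# ChemmineOB exports only a handful of helpers; the full OpenBabel SWIG API
# is present unexported in its namespace. The fixed set of internals used
# here is resolved once via ob_api() and nowhere else.

.chem_cache <- new.env(parent = emptyenv())

ob_api <- function() {
  if (is.null(.chem_cache$ns)) .chem_cache$ns <- getNamespace("ChemmineOB")
  .chem_cache$ns
}

# OpenBabel writes parse warnings straight to stderr; silence them once.
ob_quiet <- function() {
  if (isTRUE(.chem_cache$quiet)) return(invisible())
  ns <- ob_api()
  try(ns$OBMessageHandler_SetOutputLevel(ns$obErrorLog_get(), 0), silent = TRUE)
  .chem_cache$quiet <- TRUE
  invisible()
}

ob_mols <- function(smiles, f = identity) {
  ob_quiet()
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), f)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the single canonical form used throughout the package
#' (OpenBabel canonical SMILES). Invalid strings yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length; `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C(O)C"))
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  ob_quiet()
  out <- rep(NA_character_, length(smiles))
  key <- paste0("can:", smiles)
  hit <- vapply(key, function(k) !is.null(.chem_cache[[k]]), logical(1))
  out[hit] <- vapply(key[hit], function(k) .chem_cache[[k]], character(1))
  todo <- which(!hit & !is.na(smiles) & nzchar(smiles))
  if (length(todo)) {
    # batch-convert with numeric titles so invalid entries cannot shift rows
    src <- paste0(smiles[todo], " m", seq_along(todo), collapse = "\n")
    res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", src),
                    error = function(e) "")
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      i <- suppressWarnings(as.integer(sub("^m", "", trimws(parts[2]))))
      if (!is.na(i) && nzchar(parts[1])) out[todo[i]] <- parts[1]
    }
    # the batch reader stops at the first unparseable entry; finish singly
    for (j in todo[is.na(out[todo])]) {
      res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles[j]),
                      error = function(e) "")
      s <- strsplit(res, "[\t\n]")[[1]][1]
      if (!is.na(s) && nzchar(s)) out[j] <- s
    }
    for (j in todo) .chem_cache[[key[j]]] <- out[j]
  }
  out
}

#' Test whether SMILES strings parse
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# --- SMARTS -----------------------------------------------------------------

smarts_pattern <- function(smarts) {
  ns <- ob_api()
  key <- paste0("sp:", smarts)
  sp <- .chem_cache[[key]]
  if (is.null(sp)) {
    sp <- ns$OBSmartsPattern()
    if (!ns$OBSmartsPattern_Init(sp, smarts)) {
      stop("invalid SMARTS pattern: ", smarts)
    }
    .chem_cache[[key]] <- sp
  }
  sp
}

#' Count SMARTS matches in molecules
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @param unique Count unique (symmetry-deduplicated) matches?
#' @return Integer vector of match counts (0 for invalid molecules).
#' @export
smarts_count <- function(smiles, smarts, unique = TRUE) {
  stopifnot(length(smarts) == 1)
  ns <- ob_api()
  sp <- smarts_pattern(smarts)
  valid <- is_valid_smiles(smiles)
  key <- paste0("sc:", unique, ":", smarts, ":", smiles)
  out <- integer(length(smiles))
  todo <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    hit <- .chem_cache[[key[i]]]
    if (is.null(hit)) todo[i] <- valid[i] else out[i] <- hit
  }
  if (any(todo)) {
    out[todo] <- unlist(ob_mols(smiles[todo], function(mol) {
      ns$OBSmartsPattern_Match(sp, mol)
      if (unique) length(ns$OBSmartsPattern_GetUMapList(sp))
      else ns$OBSmartsPattern_NumMatches(sp)
    }))
    for (i in which(todo)) .chem_cache[[key[i]]] <- out[i]
  }
  out
}

#' List SMARTS match atom indices for one molecule
#'
#' Atom indices are 1-based positions in the parse order of the supplied
#' SMILES (for canonical SMILES this order is deterministic and serves as the
#' canonical atom rank).
#'
#' @param smiles A single SMILES string.
#' @param smarts A single SMARTS pattern.
#' @return List of integer vectors, one per unique match (possibly empty).
#' @export
smarts_matches <- function(smiles, smarts) {
  stopifnot(length(smiles) == 1, length(smarts) == 1)
  if (!is_valid_smiles(smiles)) stop("invalid SMILES: ", smiles)
  ns <- ob_api()
  sp <- smarts_pattern(smarts)
  ob_mols(smiles, function(mol) {
    ns$OBSmartsPattern_Match(sp, mol)
    ns$OBSmartsPattern_GetUMapList(sp)
  })[[1]]
}

# --- molecular graph --------------------------------------------------------

#' Extract the molecular graph of a molecule
#'
#' Returns heavy-atom-level atoms and bonds with perceived aromaticity and
#' ring membership; bond orders are kekulized (1/2/3) with a separate
#' aromatic flag.
#'
#' @param smiles A single SMILES string.
#' @return A list with `n` (heavy atom count), `atoms` (tibble: `z`, `symbol`,
#'   `charge`, `aromatic`, `in_ring`, `n_h`, `degree`) and `bonds` (tibble:
#'   `a1`, `a2`, `order`, `aromatic`, `in_ring`).
#' @export
mol_graph <- function(smiles) {
  stopifnot(length(smiles) == 1)
  if (!is_valid_smiles(smiles)) stop("invalid SMILES: ", smiles)
  ns <- ob_api()
  ob_mols(smiles, function(mol) {
    n <- ns$OBMol_NumAtoms(mol)
    nb <- ns$OBMol_NumBonds(mol)
    z <- integer(n); chg <- integer(n); arom <- logical(n)
    ring <- logical(n); nh <- integer(n)
    for (i in seq_len(n)) {
      a <- ns$OBMol_GetAtom(mol, i)
      z[i] <- ns$OBAtom_GetAtomicNum(a)
      chg[i] <- ns$OBAtom_GetFormalCharge(a)
      arom[i] <- ns$OBAtom_IsAromatic(a)
      ring[i] <- ns$OBAtom_IsInRing(a)
      nh[i] <- ns$OBAtom_GetImplicitHCount(a)
    }
    if (nb > 0) {
      a1 <- integer(nb); a2 <- integer(nb); ord <- integer(nb)
      barom <- logical(nb); bring <- logical(nb)
      for (i in seq_len(nb)) {
        b <- ns$OBMol_GetBond(mol, i - 1L)
        a1[i] <- ns$OBBond_GetBeginAtomIdx(b)
        a2[i] <- ns$OBBond_GetEndAtomIdx(b)
        ord[i] <- ns$OBBond_GetBondOrder(b)
        barom[i] <- ns$OBBond_IsAromatic(b)
        bring[i] <- ns$OBBond_IsInRing(b)
      }
      bonds <- tibble::tibble(a1 = a1, a2 = a2, order = ord,
                              aromatic = barom, in_ring = bring)
    } else {
      bonds <- tibble::tibble(a1 = integer(0), a2 = integer(0),
                              order = integer(0), aromatic = logical(0),
                              in_ring = logical(0))
    }
    deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
    list(
      n = n,
      atoms = tibble::tibble(z = z, symbol = element_symbol(z), charge = chg,
                             aromatic = arom, in_ring = ring, n_h = nh,
                             degree = deg),
      bonds = bonds
    )
  })[[1]]
}

.elements <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na",
               "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti",
               "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge",
               "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo",
               "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te",
               "I", "Xe")

element_symbol <- function(z) {
  out <- .elements[z]
  out[is.na(out)] <- "*"
  out
}

# --- molfile write-back (used by graph edits and scaffold extraction) -------

# atoms: tibble with symbol, charge; bonds: tibble with a1, a2, order
write_molfile <- function(atoms, bonds) {
  n <- nrow(atoms); nb <- nrow(bonds)
  hdr <- sprintf("\n synthmcts\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 n, nb)
  ab <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$symbol)
  bb <- if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                            bonds$a1, bonds$a2, bonds$order) else character(0)
  chg <- which(atoms$charge != 0)
  chgl <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf(" %3d %3d", chg, atoms$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(hdr, ab, bb, chgl, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES of an edited atoms/bonds table; NA if chemistry is invalid.
graph_to_smiles <- function(atoms, bonds) {
  ob_quiet()
  txt <- write_molfile(atoms, bonds)
  res <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                  error = function(e) "")
  s <- strsplit(res, "[\t\n]")[[1]][1]
  if (is.na(s) || !nzchar(s)) return(NA_character_)
  canonical_smiles(s)
}

# --- fingerprints and similarity --------------------------------------------

#' Circular (ECFP) fingerprint of a molecule
#'
#' Extended-connectivity fingerprints hashed to a fixed bit length. The
#' engine emits 4096 bits; these are folded by OR to the requested length.
#' Diameter 4 (pairing, diversity) and 6 (QSAR reward) are the two variants
#' used by the package.
#'
#' @param smiles A single SMILES string.
#' @param diameter Circular diameter, 4 or 6 (radius 2 or 3).
#' @param nbits Bit length (power of two, <= 4096). Default 2048.
#' @return Integer 0/1 vector of length `nbits`.
#' @export
morgan_fp <- function(smiles, diameter = 4, nbits = 2048) {
  stopifnot(length(smiles) == 1, diameter %in% c(0, 2, 4, 6),
            nbits > 0, bitwAnd(nbits, nbits - 1L) == 0, nbits <= 4096)
  key <- paste0("fp:", diameter, ":", nbits, ":", smiles)
  hit <- .chem_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!is_valid_smiles(smiles)) stop("invalid SMILES: ", smiles)
  can <- canonical_smiles(smiles)
  v <- ob_mols(can, function(mol) {
    ChemmineOB::fingerprint_OB(list(mol), paste0("ECFP", diameter))
  })[[1]]
  v <- as.integer(v > 0)
  while (length(v) > nbits) {
    half <- length(v) / 2
    v <- as.integer(v[seq_len(half)] | v[half + seq_len(half)])
  }
  .chem_cache[[key]] <- v
  v
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of SMILES.
#' @inheritParams morgan_fp
#' @return Integer matrix, one row per molecule.
#' @export
fp_matrix <- function(smiles, diameter = 4, nbits = 2048) {
  m <- vapply(smiles, morgan_fp, integer(nbits),
              diameter = diameter, nbits = nbits)
  t(matrix(m, nrow = nbits, dimnames = list(NULL, NULL)))
}

#' Tanimoto similarity between two bit vectors
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both are empty.
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

# All-pairs Tanimoto for the rows of a 0/1 matrix (self-pairs included).
tanimoto_matrix <- function(fps) {
  fps <- matrix(as.numeric(fps), nrow = nrow(fps))
  inter <- tcrossprod(fps)
  pop <- rowSums(fps)
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  sim
}

# --- simple descriptors -----------------------------------------------------

#' Molecular weight
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of average molecular weights (g/mol).
#' @export
mol_weight <- function(smiles) {
  valid <- is_valid_smiles(smiles)
  out <- rep(NA_real_, length(smiles))
  if (any(valid)) {
    props <- ChemmineOB::prop_OB(ob_mols(smiles[valid]))
    out[valid] <- props$MW
  }
  out
}

#' Heavy-atom count
#'
#' Number of non-hydrogen atoms of the molecule.
#'
#' @param smiles Character vector of SMILES.
#' @return Integer vector.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) mol_graph(s)$n, integer(1), USE.NAMES = FALSE)
}

# TRUE if the molecule has a ring atom that belongs to no ring of size <= max
has_large_ring <- function(smiles, max_size = 8) {
  pat <- paste0("[R", paste0(";!r", 3:max_size, collapse = ""), "]")
  smarts_count(smiles, pat) > 0
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus linkers: terminal atoms are pruned iteratively, keeping
#' atoms attached to the scaffold by a double bond (exocyclic carbonyls and
#' the like). Acyclic molecules have no scaffold and return `NA`.
#'
#' @param smiles A single SMILES string.
#' @return Canonical SMILES of the scaffold, or `NA` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  g <- mol_graph(smiles)
  if (!any(g$atoms$in_ring)) return(NA_character_)
  keep <- rep(TRUE, g$n)
  repeat {
    live <- keep[g$bonds$a1] & keep[g$bonds$a2]
    deg <- tabulate(c(g$bonds$a1[live], g$bonds$a2[live]), nbins = g$n)
    drop <- which(keep & deg <= 1 & !g$atoms$in_ring)
    if (length(drop) == 0) break
    keep[drop] <- FALSE
  }
  # re-attach atoms joined to the scaffold by a multiple bond (exocyclic =O etc.)
  multi <- g$bonds$order >= 2
  keep[g$bonds$a1[multi & keep[g$bonds$a2]]] <- TRUE
  keep[g$bonds$a2[multi & keep[g$bonds$a1]]] <- TRUE
  idx <- which(keep)
  remap <- match(seq_len(g$n), idx)
  bonds <- g$bonds[keep[g$bonds$a1] & keep[g$bonds$a2], , drop = FALSE]
  atoms <- g$atoms[idx, , drop = FALSE]
  graph_to_smiles(
    tibble::tibble(symbol = atoms$symbol, charge = atoms$charge),
    tibble::tibble(a1 = remap[bonds$a1], a2 = remap[bonds$a2],
                   order = bonds$order))
}

#' Is one molecule's scaffold contained in another molecule?
#'
#' Substructure containment test used by the scaffold-retention metric; the
#' query is a canonical SMILES interpreted as a SMARTS pattern.
#'
#' @param sub Canonical SMILES of the (scaffold) substructure.
#' @param mol SMILES of the candidate superstructure.
#' @return Logical.
#' @export
has_substructure <- function(mol, sub) {
  if (is.na(sub) || is.na(mol)) return(NA)
  smarts_count(mol, sub) > 0
}
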