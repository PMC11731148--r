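# Covalent (warhead) mechanics.  A dummy atom ("*" in SMILES, "R" in SDF)
# marks where the ligand bonds a protein nucleophile; the dummy and the
# warhead atoms around it are protected: never deleted, element-swapped or
# chosen as linker attachment points, and their coordinates come only from
# the covalent parent hit.

#' Atoms belonging to the warhead around a covalent attachment point
#'
#' The dummy atom, its direct neighbour, and every atom reachable from them
#' through the contiguous pi system (bonds of order > 1, or atoms that carry
#' a multiple bond, e.g. the carbonyl of a chloroacetamide) -- i.e. the
#' neighbourhood up to the first freely rotatable single bond.  An explicit
#' atom list can be supplied instead via config at the call sites.
#'
#' @param m a `positioned_mol`.
#' @param attachment_index index of the dummy atom.
#' @return integer vector of atom indices (including the dummy).
#' @export
warhead_atoms <- function(m, attachment_index) {
  adj <- neighbours(m)
  has_multiple <- vapply(seq_len(n_atoms(m)), function(i) {
    ks <- which(m$bonds$i == i | m$bonds$j == i)
    any(m$bonds$order[ks] > 1)
  }, logical(1))
  wh <- attachment_index
  frontier <- adj[[attachment_index]]
  wh <- c(wh, frontier)  # the attachment carbon is always part of the warhead
  repeat {
    grew <- FALSE
    for (i in setdiff(unique(unlist(adj[wh])), wh)) {
      links <- intersect(adj[[i]], wh)
      ords <- vapply(links, function(j) m$bonds$order[bond_index(m, i, j)[1]],
                     numeric(1))
      if (any(ords > 1) || has_multiple[i]) { wh <- c(wh, i); grew <- TRUE }
    }
    if (!grew) break
  }
  sort(unique(wh))
}

#' Parse a candidate SMILES and flag covalent mode
#'
#' A single dummy atom triggers covalent mode: it is the protein-attachment
#' point and its warhead neighbourhood is listed for protection.  More than
#' one dummy is an error; none means plain non-covalent placement.
#'
#' @param smiles candidate SMILES string.
#' @return list with `topology` (a `positioned_mol`), `attachment_index`
#'   (`NA` if non-covalent) and `warhead` (integer vector, empty if
#'   non-covalent).
#' @export
mark_covalent <- function(smiles) {
  m <- parse_smiles(smiles)
  dummies <- which(m$element == DUMMY)
  if (length(dummies) > 1)
    stop("covalent candidates must contain exactly one dummy atom")
  if (!length(dummies))
    return(list(topology = m, attachment_index = NA_integer_,
                warhead = integer(0)))
  wh <- warhead_atoms(m, dummies)
  list(topology = m, attachment_index = dummies, warhead = wh)
}

#' Protect warhead atoms in a stitched conformer
#'
#' Marks the given atoms as protected so merging, linking and rectification
#' never alter them.  If a protected atom has already been modified in a way
#' that cannot be honoured (element changed relative to its provenance),
#' a `CovalentConflict` is raised.
#'
#' @param s a `stitched_conformer`.
#' @param warhead integer vector of atom indices in `s$mol`.
#' @return `s` with protection tags set.
#' @export
protect_during_merge <- function(s, warhead) {
  if (!length(warhead)) return(s)
  if (any(warhead < 1 | warhead > n_atoms(s$mol)))
    fs_failure("CovalentConflict", "warhead atom index outside the molecule")
  for (i in warhead) {
    tg <- s$mol$tags[[i]] %||% list()
    tg$protected <- TRUE
    s$mol$tags[[i]] <- tg
  }
  s
}

#' Find the attachment residue for a covalent ligand
#'
#' Default rule: the cysteine whose S-gamma is nearest the dummy atom.
#'
#' @param protein a `protein_model`.
#' @param dummy_xyz length-3 numeric, position of the dummy atom.
#' @param residue optional explicit `"chain:resid"` override.
#' @return list `(chain, resid, resname, atom, distance)` or `NULL` if the
#'   protein has no cysteine sulfur.
#' @export
covalent_attachment_residue <- function(protein, dummy_xyz, residue = NULL) {
  cand <- protein[protein$resname == "CYS" & protein$name == "SG", , drop = FALSE]
  if (!is.null(residue)) {
    parts <- strsplit(residue, ":")[[1]]
    cand <- cand[cand$chain == parts[1] & cand$resid == as.integer(parts[2]), ,
                 drop = FALSE]
  }
  if (!nrow(cand)) return(NULL)
  d <- sqrt((cand$x - dummy_xyz[1])^2 + (cand$y - dummy_xyz[2])^2 +
              (cand$z - dummy_xyz[3])^2)
  k <- which.min(d)
  list(chain = cand$chain[k], resid = cand$resid[k], resname = "CYS",
       atom = "SG", distance = d[k])
}
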