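# A compact SMILES reader sufficient for the pipeline's inputs: organic
# subset and bracket atoms, branches, ring closures (incl. %nn), aromatic
# lower-case atoms, charges, and the `*` wildcard marking a covalent
# attachment point.  Stereo descriptors are accepted and ignored (stereo is
# out of scope for the mapping).  The result is a topology-only molecule
# (all coordinates NA) to be positioned by stitching/embedding.

#' Parse a SMILES string into a topology-only molecule
#'
#' @param smiles a SMILES string; at most one `*` dummy atom (covalent mode).
#' @param name molecule name.
#' @return a `positioned_mol` with `NA` coordinates.
#' @export
parse_smiles <- function(smiles, name = smiles) {
  chars <- strsplit(smiles, "")[[1]]
  el <- character(0); arom <- logical(0); charge <- integer(0)
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  prev <- 0L            # previous atom index (0 = none)
  pend_bond <- NA_real_ # explicit bond symbol awaiting next atom
  stack <- integer(0)
  ring_open <- list()   # label -> list(atom, order)
  pos <- 1L
  n <- length(chars)
  add_atom <- function(sym, aromatic, chg) {
    el <<- c(el, sym); arom <<- c(arom, aromatic); charge <<- c(charge, chg)
    idx <- length(el)
    if (prev > 0L) {
      o <- if (!is.na(pend_bond)) pend_bond else
        if (aromatic && arom[prev]) 1.5 else 1
      bonds <<- rbind(bonds, data.frame(i = prev, j = idx, order = o))
    }
    pend_bond <<- NA_real_
    prev <<- idx
  }
  close_ring <- function(label) {
    o <- if (!is.na(pend_bond)) pend_bond else NA_real_
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      order <- if (!is.na(o)) o else if (!is.na(op$order)) op$order else
        if (arom[op$atom] && arom[prev]) 1.5 else 1
      bonds <<- rbind(bonds, data.frame(i = op$atom, j = prev, order = order))
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- list(atom = prev, order = o)
    }
    pend_bond <<- NA_real_
  }
  two_letter <- c("Cl", "Br", "Si", "Se")
  while (pos <= n) {
    ch <- chars[pos]
    nxt <- if (pos < n) chars[pos + 1L] else ""
    if (ch == "[") {
      close_at <- pos
      while (chars[close_at] != "]") close_at <- close_at + 1L
      body <- paste(chars[(pos + 1L):(close_at - 1L)], collapse = "")
      body <- gsub("^[0-9]+", "", body)        # isotope
      mm <- regmatches(body, regexec(
        "^([A-Za-z][a-z]?|\\*)(@{0,2})(H[0-9]*)?([+-]+[0-9]*)?(:[0-9]+)?", body))[[1]]
      sym <- mm[2]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se")
      if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      chg <- 0L
      if (mm[5] != "") {
        sgn <- if (substr(mm[5], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", mm[5])
        chg <- if (digits != "") sgn * as.integer(digits) else sgn * nchar(mm[5])
      }
      add_atom(sym, aromatic, chg)
      pos <- close_at + 1L
    } else if (paste0(ch, nxt) %in% two_letter) {
      add_atom(paste0(ch, nxt), FALSE, 0L); pos <- pos + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L); pos <- pos + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L); pos <- pos + 1L
    } else if (ch == "*") {
      add_atom(DUMMY, FALSE, 0L); pos <- pos + 1L
    } else if (ch == "-") { pend_bond <- 1; pos <- pos + 1L
    } else if (ch == "=") { pend_bond <- 2; pos <- pos + 1L
    } else if (ch == "#") { pend_bond <- 3; pos <- pos + 1L
    } else if (ch == ":") { pend_bond <- 1.5; pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) { pend_bond <- 1; pos <- pos + 1L
    } else if (ch == "(") { stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == "%") {
      close_ring(paste(chars[(pos + 1L):(pos + 2L)], collapse = ""))
      pos <- pos + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); pos <- pos + 1L
    } else if (ch == ".") {
      prev <- 0L; pos <- pos + 1L
    } else {
      stop("unsupported SMILES token '", ch, "' in ", smiles)
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMILES: ", smiles)
  if (sum(el == DUMMY) > 1) stop("more than one dummy atom in SMILES: ", smiles)
  m <- positioned_mol(el, matrix(NA_real_, length(el), 3), bonds,
                      charge, arom, name)
  # aromatic bonds only between aromatic atoms inside a ring
  if (nrow(m$bonds)) {
    ring_sets <- sssr(m)
    in_same_ring <- function(i, j) any(vapply(ring_sets, function(rr)
      i %in% rr && j %in% rr, logical(1)))
    for (k in which(m$bonds$order == 1.5)) {
      if (!in_same_ring(m$bonds$i[k], m$bonds$j[k])) m$bonds$order[k] <- 1
    }
    m$aromatic <- rep(FALSE, n_atoms(m))
    for (k in which(m$bonds$order == 1.5)) {
      m$aromatic[m$bonds$i[k]] <- TRUE
      m$aromatic[m$bonds$j[k]] <- TRUE
    }
  }
  m
}
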