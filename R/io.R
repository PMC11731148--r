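# Readers and writers for the structure formats the pipeline touches:
# SDF (V2000) for hits and outputs, PDB for protein templates, and a JSON
# sidecar for scores and diagnostics.  Round-trips preserve atom count, bond
# orders, coordinates (1e-3 A: the V2000 coordinate field has 4 decimals)
# and dummy-atom annotation.

#' Read fragment hits from an SDF file
#'
#' Records are returned in file order.  Dummy atoms (`*`, `R` or `R#`) are
#' normalised to the internal sentinel and recorded as the covalent
#' attachment index.  Records that fail to parse, or that carry only 2D
#' coordinates (all z = 0 is accepted; a record with no coordinate block is
#' not), raise an error naming the record index.
#'
#' @param path path to an SDF (MDL V2000) file.
#' @param require_3d reject records whose coordinates are absent (default
#'   TRUE).
#' @return list of [fragment_hit] objects.
#' @export
read_hits <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split_sdf_records(lines)
  if (!length(recs)) stop("no SDF records found in ", path)
  hits <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    mol <- tryCatch(parse_molblock(recs[[k]]),
                    error = function(e) stop(sprintf(
                      "SDF record %d: %s", k, conditionMessage(e)), call. = FALSE))
    if (all(abs(mol$xyz) < 1e-8))
      stop(sprintf("SDF record %d: no 3D coordinates", k), call. = FALSE)
    if (mol$name == "") mol$name <- sprintf("hit_%d", k)
    hits[[k]] <- fragment_hit(mol)
  }
  hits
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) {
    if (any(grepl("V2000", lines))) return(list(lines))
    return(list())
  }
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  # trailing record without terminator
  if (ends[length(ends)] < length(lines)) {
    tail_lines <- lines[(ends[length(ends)] + 1L):length(lines)]
    if (any(grepl("V2000", tail_lines))) recs <- c(recs, list(tail_lines))
  }
  recs
}

parse_molblock <- function(lines) {
  if (length(lines) < 4) stop("truncated molblock")
  name <- trimws(lines[1])
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("unparsable counts line")
  if (length(lines) < 4 + na + nb) stop("molblock shorter than counts line claims")
  el <- character(na); xyz <- matrix(NA_real_, na, 3); charge <- integer(na)
  for (i in seq_len(na)) {
    ln <- lines[4 + i]
    x <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(ln, 21, 30)))
    if (any(is.na(c(x, y, z)))) stop(sprintf("atom %d: missing coordinates", i))
    sym <- trimws(substr(ln, 32, 34))
    if (sym %in% c("R", "R#", "*")) sym <- DUMMY
    if (sym == "") stop(sprintf("atom %d: missing element symbol", i))
    el[i] <- sym; xyz[i, ] <- c(x, y, z)
    chg <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(chg) && chg != 0) charge[i] <- c(3, 2, 1, 0, -1, -2, -3)[chg]
  }
  bonds <- data.frame(i = integer(nb), j = integer(nb), order = numeric(nb))
  for (k in seq_len(nb)) {
    ln <- lines[4 + na + k]
    bi <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (any(is.na(c(bi, bj, bo)))) stop(sprintf("bond %d: unparsable", k))
    bonds$i[k] <- bi; bonds$j[k] <- bj
    bonds$order[k] <- if (bo == 4) 1.5 else bo
  }
  # M  CHG property lines override atom-block charges
  arom <- rep(FALSE, na)
  for (ln in lines[-seq_len(4 + na + nb)]) {
    if (startsWith(ln, "M  CHG")) {
      toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nn <- toks[1]
      for (q in seq_len(nn)) {
        charge[toks[2 * q]] <- toks[2 * q + 1]
      }
    }
  }
  if (nrow(bonds)) {
    for (k in which(bonds$order == 1.5)) {
      arom[bonds$i[k]] <- TRUE; arom[bonds$j[k]] <- TRUE
    }
  }
  positioned_mol(el, xyz, bonds, charge, arom, name)
}

#' Write molecules to an SDF file
#'
#' @param mols a `positioned_mol` or list of them.
#' @param path output path.
#' @param data optional list (parallel to `mols`) of named character vectors
#'   written as SDF data fields.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, data = NULL) {
  if (inherits(mols, "positioned_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    writeLines(molblock_lines(mols[[k]]), con)
    if (!is.null(data) && length(data) >= k && length(data[[k]])) {
      for (nm in names(data[[k]])) {
        writeLines(c(sprintf(">  <%s>", nm), as.character(data[[k]][[nm]]), ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

molblock_lines <- function(m) {
  na <- n_atoms(m); nb <- nrow(m$bonds)
  out <- c(m$name, "  fragstitch", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(na)) {
    sym <- if (m$element[i] == DUMMY) "R#" else m$element[i]
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          m$xyz[i, 1], m$xyz[i, 2], m$xyz[i, 3], sym))
  }
  for (k in seq_len(nb)) {
    bo <- if (m$bonds$order[k] == 1.5) 4L else as.integer(m$bonds$order[k])
    out <- c(out, sprintf("%3d%3d%3d  0", m$bonds$i[k], m$bonds$j[k], bo))
  }
  chg <- which(m$charge != 0)
  if (length(chg)) {
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                         paste0(sprintf("%4d%4d", chg, m$charge[chg]), collapse = "")))
  }
  c(out, "M  END")
}

#' Read a protein template from a PDB file
#'
#' Keeps heavy-atom ATOM/HETATM records with chain and residue identity.
#' On altloc conflicts the highest-occupancy conformer is kept (first wins
#' ties) with a warning.
#'
#' @param path path to a PDB file.
#' @param strip_waters drop HOH/WAT residues (default TRUE).
#' @return an object of class `protein_model`: a data.frame of atoms
#'   (`serial`, `name`, `resname`, `chain`, `resid`, `x`, `y`, `z`,
#'   `element`, `occupancy`) with class attribute.
#' @export
read_template <- function(path, strip_waters = TRUE) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  lines <- lines[sel]
  f <- function(a, b) substr(lines, a, b)
  df <- data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = trimws(f(13, 16)),
    altloc = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resid = suppressWarnings(as.integer(f(23, 26))),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = trimws(f(77, 78)),
    stringsAsFactors = FALSE)
  df$occupancy[is.na(df$occupancy)] <- 1
  no_el <- df$element == ""
  df$element[no_el] <- vapply(df$name[no_el], function(nm) {
    sym <- gsub("[0-9']", "", nm)
    sub2 <- substr(sym, 1, 2)
    if (sub2 %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN"))
      paste0(substr(sub2, 1, 1), tolower(substr(sub2, 2, 2)))
    else substr(sym, 1, 1)
  }, character(1))
  if (strip_waters) df <- df[!df$resname %in% c("HOH", "WAT"), , drop = FALSE]
  df <- df[df$element != "H", , drop = FALSE]
  # altloc resolution: highest occupancy per (chain, resid, atom name)
  if (any(df$altloc != "")) {
    key <- paste(df$chain, df$resid, df$resname, df$name)
    ord <- order(key, -df$occupancy, df$altloc)
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(paste(df$chain, df$resid, df$resname, df$name))
    if (any(dup)) warning(sprintf(
      "altloc conflicts on %d atoms: keeping highest occupancy", sum(dup)))
    df <- df[!dup, , drop = FALSE]
    df <- df[order(df$serial), , drop = FALSE]
  }
  df$altloc <- NULL
  rownames(df) <- NULL
  structure(df, class = c("protein_model", "data.frame"))
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model: %d atoms, %d residues>\n", nrow(x),
              length(unique(paste(x$chain, x$resid)))))
  invisible(x)
}

#' Number of residues in a protein model
#' @param p a `protein_model`.
#' @return integer.
#' @export
n_residues <- function(p) length(unique(paste(p$chain, p$resid)))

protein_coords <- function(p) as.matrix(p[, c("x", "y", "z")])

#' Write a minimised placement as SDF plus a JSON sidecar
#'
#' The sidecar carries the snapshot binding energy, RMSD diagnostics,
#' provenance counts and (when present) score terms and the covalent
#' attachment residue.
#'
#' @param placement a `minimized_placement` (see [pocket_min_cycles]).
#' @param out_prefix output path prefix; writes `<prefix>.sdf` and
#'   `<prefix>.json`.
#' @return named list of the two paths, invisibly.
#' @export
write_result <- function(placement, out_prefix) {
  stopifnot(inherits(placement, "minimized_placement"))
  sdf <- paste0(out_prefix, ".sdf")
  js <- paste0(out_prefix, ".json")
  ok <- valence_legal(placement$mol)
  if (!isTRUE(ok)) stop("placement molecule is not chemically valid")
  write_sdf(placement$mol, sdf,
            data = list(c(dG_bind = sprintf("%.4f", placement$dG_bind))))
  side <- list(
    name = placement$mol$name,
    dG_bind = placement$dG_bind,
    rmsd_vs_hits = placement$rmsd_vs_hits,
    rmsd_vs_start = placement$rmsd_vs_start,
    cycles = placement$cycles,
    engine = placement$engine,
    acceptable = placement$acceptable,
    n_novel_atoms = placement$n_novel_atoms,
    n_mapped_atoms = placement$n_mapped_atoms,
    hits_used = placement$hits_used,
    restraint_scales = placement$restraint_scales)
  if (!is.null(placement$score_terms)) side$score_terms <- placement$score_terms
  if (!is.null(placement$covalent_residue)) side$covalent_residue <- placement$covalent_residue
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(sdf = sdf, json = js))
}
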