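# Synthetic fixture generation: positioned ring pairs at controlled centroid
# separations (the furan/benzene distance sweep), partially overlapping
# substructure pairs for mapping tests, a toy protein pocket for
# minimisation, a covalent toy system, and a seeded random "drug-like"
# molecule generator for property tests.  Everything is deterministic at a
# fixed seed and writes plain-text SDF/PDB only.

# regular n-ring in the xy-plane, first atom on +x, given bond length
.ring_coords <- function(n, bond, centre = c(0, 0, 0), phase = 0) {
  R <- bond / (2 * sin(pi / n))
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1] + R * cos(th), centre[2] + R * sin(th), centre[3] + 0)
}

#' Canonical positioned benzene
#' @param centre ring centroid (length-3 numeric).
#' @param phase rotation of the ring about z, radians.
#' @return a `positioned_mol`.
#' @export
make_benzene <- function(centre = c(0, 0, 0), phase = 0) {
  positioned_mol(rep("C", 6), .ring_coords(6, 1.39, centre, phase),
                 data.frame(i = 1:6, j = c(2:6, 1), order = 1.5),
                 aromatic = rep(TRUE, 6), name = "benzene")
}

#' Canonical positioned furan (O first)
#' @inheritParams make_benzene
#' @return a `positioned_mol`.
#' @export
make_furan <- function(centre = c(0, 0, 0), phase = 0) {
  positioned_mol(c("O", rep("C", 4)), .ring_coords(5, 1.36, centre, phase),
                 data.frame(i = 1:5, j = c(2:5, 1), order = 1.5),
                 aromatic = rep(TRUE, 5), name = "furan")
}

# benzene with one exocyclic atom attached to ring atom 1, radially outward
.mono_substituted_benzene <- function(sub_element, bond_len, name) {
  b <- make_benzene()
  dir <- b$xyz[1, ] / sqrt(sum(b$xyz[1, ]^2))
  xyz <- rbind(b$xyz, b$xyz[1, ] + dir * bond_len)
  positioned_mol(c(b$element, sub_element), xyz,
                 rbind(b$bonds, data.frame(i = 1, j = 7, order = 1)),
                 aromatic = c(b$aromatic, FALSE), name = name)
}

#' Canonical positioned toluene (methyl on ring atom 1)
#' @return a `positioned_mol`.
#' @export
make_toluene <- function() .mono_substituted_benzene("C", 1.51, "toluene")

#' Canonical positioned phenol (hydroxyl on ring atom 1)
#' @return a `positioned_mol`.
#' @export
make_phenol <- function() .mono_substituted_benzene("O", 1.36, "phenol")

#' Toluene/phenol hits superposed on the shared ring
#'
#' The standard mapping fixture: both molecules share the benzene ring
#' coordinates exactly; the methyl and hydroxyl sit on opposite ring atoms.
#' @return list of two [fragment_hit]s (toluene, phenol).
#' @export
make_overlap_pair <- function() {
  tol <- make_toluene()
  ph <- make_phenol()
  # put the hydroxyl para to the methyl: attach to ring atom 4 instead
  dir <- ph$xyz[4, ] / sqrt(sum(ph$xyz[4, ]^2))
  ph$xyz[7, ] <- ph$xyz[4, ] + dir * 1.36
  ph$bonds$i[ph$bonds$i == 1 & ph$bonds$j == 7] <- 4
  list(fragment_hit(tol, "toluene"), fragment_hit(ph, "phenol"))
}

#' Furan/benzene hit pairs at given centroid separations
#'
#' The distance-sweep fixture: a furan centred at the origin and a benzene
#' displaced along +x by each separation, both in the xy-plane.
#' @param separations numeric vector of centroid separations in Angstrom.
#' @return list (one entry per separation) of two-hit lists.
#' @export
make_ring_pair_sweep <- function(separations = c(0, 2, 4, 6, 8)) {
  lapply(separations, function(s) {
    # furan oxygen points away from the benzene so ring carbons face the gap
    list(fragment_hit(make_furan(phase = pi), "furan"),
         fragment_hit(make_benzene(centre = c(s, 0, 0)), "benzene"))
  })
}

#' A toy protein pocket surrounding the origin
#'
#' A shell of glycine-like residues (N, CA, C, O) placed on a sphere so that
#' small fixtures at the origin sit in a cavity.  Intended purely for
#' minimisation and interaction tests; it is not a real fold.
#'
#' @param radius cavity radius in Angstrom (default 6).
#' @param n_residues number of residues on the shell (default 24; 4 atoms
#'   each, so well under 300 atoms).
#' @return a `protein_model`.
#' @export
make_toy_pocket <- function(radius = 6, n_residues = 24) {
  # Fibonacci sphere for even coverage
  golden <- pi * (3 - sqrt(5))
  rows <- list()
  for (r in seq_len(n_residues)) {
    zf <- 1 - 2 * (r - 0.5) / n_residues
    rad <- sqrt(1 - zf^2)
    th <- golden * (r - 1)
    centre <- radius * c(rad * cos(th), rad * sin(th), zf)
    out <- centre / sqrt(sum(centre^2))   # outward normal
    perp <- .any_perp(out)
    atoms <- list(
      CA = centre,
      N = centre + 1.46 * (0.8 * perp + 0.6 * out),
      C = centre + 1.52 * (-0.8 * perp + 0.6 * out),
      O = centre + 1.52 * (-0.8 * perp + 0.6 * out) + 1.23 * out)
    for (nm in c("N", "CA", "C", "O")) {
      rows[[length(rows) + 1L]] <- data.frame(
        serial = length(rows) + 1L, name = nm, resname = "GLY", chain = "A",
        resid = r, x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
        occupancy = 1, element = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("protein_model", "data.frame"))
}

#' Covalent toy system: a cysteine-bearing pocket and a chloroacetamide hit
#'
#' The pocket gains one CYS residue whose S-gamma points into the cavity;
#' the hit is an acetamide fragment whose dummy atom sits on the sulfur
#' position (the attachment point), i.e. `*CC(=O)N` positioned by hand.
#' @return list with `protein` (a `protein_model`, synthetic), `hit`
#'   (a covalent [fragment_hit]) and `smiles` for the matching candidate.
#' @export
make_covalent_toy <- function() {
  pocket <- make_toy_pocket()
  sg <- c(0, 0, 4.2)
  cb <- c(0.4, 0.8, 5.8)
  ca <- c(0, 0, 6.9)
  extra <- data.frame(
    serial = max(pocket$serial) + 1:3,
    name = c("CA", "CB", "SG"), resname = "CYS", chain = "A",
    resid = max(pocket$resid) + 1L,
    x = c(ca[1], cb[1], sg[1]), y = c(ca[2], cb[2], sg[2]),
    z = c(ca[3], cb[3], sg[3]),
    occupancy = 1, element = c("C", "C", "S"), stringsAsFactors = FALSE)
  protein <- structure(rbind(as.data.frame(pocket), extra),
                       class = c("protein_model", "data.frame"))
  # *CC(=O)N with the dummy on the sulfur position
  xyz <- rbind(sg,
               sg + c(0.9, 0.6, -1.3),       # CH2 (alpha)
               sg + c(1.1, 1.9, -2.1),       # carbonyl C
               sg + c(0.4, 2.9, -1.9),       # O
               sg + c(2.2, 2.0, -2.9))       # N
  mol <- positioned_mol(c(DUMMY, "C", "C", "O", "N"), xyz,
                        data.frame(i = c(1, 2, 3, 3), j = c(2, 3, 4, 5),
                                   order = c(1, 1, 2, 1)),
                        name = "covalent_toy_hit")
  list(protein = protein, hit = fragment_hit(mol, "cov_hit"),
       smiles = "*CC(=O)NC")
}

#' Seeded random drug-like molecule with 3D coordinates
#'
#' Assembles 1-3 ring systems (benzene, furan, cyclohexane, cyclopentane,
#' pyridine) and short aliphatic chains with plausible local geometry at
#' non-overlapping positions.  Used by the collapse/expand round-trip and
#' rectifier fuzz property tests; the geometry is locally reasonable but not
#' globally minimised.
#'
#' @param seed integer seed.
#' @return a `positioned_mol`.
#' @export
random_drug_like <- function(seed = 1L) {
  set.seed(seed)
  rings <- list(
    benzene = function(ctr, ph) make_benzene(ctr, ph),
    furan = function(ctr, ph) make_furan(ctr, ph),
    cyclohexane = function(ctr, ph) positioned_mol(
      rep("C", 6), .ring_coords(6, 1.54, ctr, ph),
      data.frame(i = 1:6, j = c(2:6, 1), order = 1), name = "cyclohexane"),
    cyclopentane = function(ctr, ph) positioned_mol(
      rep("C", 5), .ring_coords(5, 1.54, ctr, ph),
      data.frame(i = 1:5, j = c(2:5, 1), order = 1), name = "cyclopentane"),
    pyridine = function(ctr, ph) positioned_mol(
      c("N", rep("C", 5)), .ring_coords(6, 1.39, ctr, ph),
      data.frame(i = 1:6, j = c(2:6, 1), order = 1.5),
      aromatic = rep(TRUE, 6), name = "pyridine"))
  n_ring <- sample(1:3, 1)
  mol <- NULL
  for (r in seq_len(n_ring)) {
    ctr <- c((r - 1) * 4.4, stats::runif(1, -0.4, 0.4), stats::runif(1, -0.4, 0.4))
    piece <- rings[[sample(length(rings), 1)]](ctr, stats::runif(1, 0, 2 * pi))
    if (is.null(mol)) {
      mol <- piece
    } else {
      # bond the closest atoms between the accumulated molecule and the piece
      off <- n_atoms(mol)
      D <- outer(seq_len(n_atoms(mol)), seq_len(n_atoms(piece)),
                 Vectorize(function(p, q) sqrt(sum((mol$xyz[p, ] - piece$xyz[q, ])^2))))
      D <- matrix(D, nrow = n_atoms(mol))
      best <- arrayInd(which.min(D), dim(D))
      mol <- positioned_mol(
        c(mol$element, piece$element), rbind(mol$xyz, piece$xyz),
        rbind(mol$bonds,
              data.frame(i = piece$bonds$i + off, j = piece$bonds$j + off,
                         order = piece$bonds$order),
              data.frame(i = best[1], j = best[2] + off, order = 1)),
        c(mol$charge, piece$charge), c(mol$aromatic, piece$aromatic),
        "random_drug_like")
    }
  }
  # sprinkle substituents on atoms with spare valence
  n_sub <- sample(0:4, 1)
  for (s in seq_len(n_sub)) {
    free <- which(implicit_h(mol) > 0 & mol$element != "H")
    if (!length(free)) break
    at <- if (length(free) == 1) free else sample(free, 1)
    elem <- sample(c("C", "N", "O", "F", "Cl"), 1)
    base <- mol$xyz[at, ]
    nbrs <- neighbours(mol)[[at]]
    dir <- if (length(nbrs)) {
      v <- -colSums(mol$xyz[nbrs, , drop = FALSE] - matrix(base, length(nbrs), 3, byrow = TRUE))
      nv <- sqrt(sum(v^2)); if (nv < 1e-6) c(0, 0, 1) else v / nv
    } else c(0, 0, 1)
    dir <- dir + stats::rnorm(3, sd = 0.15); dir <- dir / sqrt(sum(dir^2))
    blen <- .bond_length(mol$element[at], elem, 1)
    mol <- positioned_mol(
      c(mol$element, elem), rbind(mol$xyz, base + dir * blen),
      rbind(mol$bonds, data.frame(i = at, j = n_atoms(mol) + 1L, order = 1)),
      c(mol$charge, 0L), c(mol$aromatic, FALSE), mol$name)
  }
  # local geometry clean-up: relax toward ideal bond/angle/ring distances
  # (deterministic descent from the assembled coordinates; keeps the shape)
  targets <- .embed_targets(mol)
  opt <- stats::optim(as.numeric(mol$xyz), fn = .embed_obj, gr = .embed_grad,
                      targets = targets, n = n_atoms(mol),
                      method = "L-BFGS-B", control = list(maxit = 200))
  mol$xyz <- matrix(opt$par, ncol = 3)
  mol$name <- sprintf("random_drug_like_%d", seed)
  mol
}

#' Write a protein model as a PDB file
#' @param p a `protein_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(p, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    p$serial, ifelse(nchar(p$name) < 4, paste0(" ", p$name), p$name),
    p$resname, p$chain, p$resid, p$x, p$y, p$z, p$occupancy, 0, p$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate fixture files on disk
#'
#' @param kind one of `"ring_pair_sweep"`, `"overlap_pair"`, `"toy_pocket"`,
#'   `"covalent_toy"`.
#' @param dir output directory (created if needed).
#' @param separations centroid separations for the sweep (default
#'   `c(0, 2, 4, 6, 8)`).
#' @param seed integer seed (fixtures are deterministic; the seed is echoed
#'   into file names for sweep reproducibility bookkeeping).
#' @return character vector of files written.
#' @export
make_fixtures <- function(kind = c("ring_pair_sweep", "overlap_pair",
                                   "toy_pocket", "covalent_toy"),
                          dir = ".", separations = c(0, 2, 4, 6, 8),
                          seed = 42L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  out <- character(0)
  if (kind == "ring_pair_sweep") {
    pairs <- make_ring_pair_sweep(separations)
    for (k in seq_along(pairs)) {
      f <- file.path(dir, sprintf("ring_pair_sep%g.sdf", separations[k]))
      write_sdf(lapply(pairs[[k]], function(h) h$mol), f)
      out <- c(out, f)
    }
  } else if (kind == "overlap_pair") {
    f <- file.path(dir, "overlap_pair.sdf")
    write_sdf(lapply(make_overlap_pair(), function(h) h$mol), f)
    out <- f
  } else if (kind == "toy_pocket") {
    f <- file.path(dir, "toy_pocket.pdb")
    write_pdb(make_toy_pocket(), f)
    out <- f
  } else {
    toy <- make_covalent_toy()
    f1 <- file.path(dir, "covalent_pocket_synthetic.pdb")
    f2 <- file.path(dir, "covalent_hit.sdf")
    write_pdb(toy$protein, f1)
    write_sdf(toy$hit$mol, f2)
    f3 <- file.path(dir, "covalent_candidate.smi")
    writeLines(toy$smiles, f3)
    out <- c(f1, f2, f3)
  }
  out
}
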