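# Core molecular data model: a "positioned molecule" is a small molecule whose
# atoms carry Cartesian coordinates (Angstrom) in the same reference frame as
# the protein template.  All mapping and RMSD operations work on heavy atoms
# only; hydrogens are added only for minimisation and interaction geometry.

# Internal sentinel for covalent-attachment dummy atoms ("*" in SMILES,
# "R"/"R#" in SDF) -- normalised on input.
DUMMY <- "*"

# Internal sentinel element for collapsed-ring centroid placeholders; these
# exist only between collapse_rings() and expand_rings().
PLACEHOLDER <- "Rc"

#' Construct a positioned molecule
#'
#' The universal currency of the pipeline: an explicit molecular graph with
#' per-atom 3D coordinates.  Aromatic bonds are stored with order 1.5.
#'
#' @param element character vector of element symbols (`"*"` marks a
#'   covalent-attachment dummy atom).
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom; may contain
#'   `NA` for topology-only molecules (e.g. parsed SMILES).
#' @param bonds data.frame with integer columns `i`, `j` (1-based atom
#'   indices) and numeric `order` (1, 2, 3 or 1.5 for aromatic).
#' @param charge integer vector of formal charges (default all 0).
#' @param aromatic logical vector of per-atom aromatic flags.
#' @param name molecule name.
#' @param tags optional list of per-atom free-form annotations.
#' @return an object of class `positioned_mol`.
#' @export
positioned_mol <- function(element, xyz, bonds = NULL, charge = NULL,
                           aromatic = NULL, name = "", tags = NULL) {
  n <- length(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == n)
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$order <- as.numeric(bonds$order)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond indices reference non-existent atoms")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  }
  if (is.null(charge)) charge <- integer(n)
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  if (is.null(tags)) tags <- vector("list", n)
  structure(
    list(element = as.character(element), xyz = xyz,
         charge = as.integer(charge), aromatic = as.logical(aromatic),
         bonds = bonds, name = as.character(name), tags = tags),
    class = "positioned_mol")
}

#' @export
print.positioned_mol <- function(x, ...) {
  cat(sprintf("<positioned_mol '%s': %d atoms (%d heavy), %d bonds>\n",
              x$name, n_atoms(x), length(heavy_atoms(x)), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m a `positioned_mol`.
#' @return integer atom count (including hydrogens and dummies if present).
#' @export
n_atoms <- function(m) length(m$element)

#' Indices of heavy atoms
#'
#' Heavy = not hydrogen.  Dummy atoms count as heavy (they occupy a real
#' coordinate and take part in mapping and protection).
#' @param m a `positioned_mol`.
#' @return integer vector of atom indices.
#' @export
heavy_atoms <- function(m) which(m$element != "H")

#' Heavy-atom count (HAC), dummies excluded
#' @param m a `positioned_mol`.
#' @return integer.
#' @export
hac <- function(m) sum(m$element != "H" & m$element != DUMMY)

# Default (neutral, lowest standard) valence per element; used for implicit-H
# counts and as the rectifier's legality reference.
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1, Se = 2)
.max_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                  P = 5, S = 6, Cl = 1, Br = 1, I = 1, Se = 6)

# Periodic group (main groups only) for the element-relaxed MCS pass.
.periodic_group <- c(H = 1, B = 13, C = 14, Si = 14, N = 15, P = 15,
                     O = 16, S = 16, Se = 16, F = 17, Cl = 17, Br = 17, I = 17)

# Single-bond covalent radii (Angstrom), for ideal bond lengths.
.covalent_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                      F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                      Br = 1.20, I = 1.39, Se = 1.20, "*" = 0.76)

# van der Waals radii (Angstrom) for the nonbonded term and clash checks.
.vdw_radius <- c(H = 1.10, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
                 I = 1.98, Se = 1.90, "*" = 1.70)

element_property <- function(table, elements, default) {
  out <- unname(table[elements])
  out[is.na(out)] <- default
  out
}

default_valence <- function(el) {
  if (el == DUMMY) return(1)
  v <- .default_valence[[el]] %||% NA_real_
  if (is.na(v)) 4 else v
}

max_valence <- function(el, charge = 0L) {
  if (el == DUMMY) return(1)
  v <- .max_valence[[el]] %||% 4
  # a positive formal charge buys one extra bond for N/O-type elements
  if (charge > 0 && el %in% c("N", "O", "S", "P")) v + 0 else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum of bond orders at each atom
#'
#' Aromatic bonds contribute 1.5.  This is the valence as seen by the
#' rectifier; implicit hydrogens are `default_valence - bond_order_sum`
#' (floored at zero).
#' @param m a `positioned_mol`.
#' @return numeric vector, one entry per atom.
#' @export
bond_order_sums <- function(m) {
  v <- numeric(n_atoms(m))
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      o <- m$bonds$order[k]
      v[m$bonds$i[k]] <- v[m$bonds$i[k]] + o
      v[m$bonds$j[k]] <- v[m$bonds$j[k]] + o
    }
  }
  v
}

#' Effective valence per atom
#'
#' Aromatic bonds are stored with order 1.5, but summing them literally would
#' make naphthalene junctions (3 aromatic bonds, 4.5) illegal.  The
#' convention used throughout: each aromatic bond contributes 1, plus one
#' extra unit for C and N atoms that carry any aromatic bond (the distributed
#' pi contribution); O/S aromatic bonds count 1 each.  Non-aromatic bonds
#' contribute their order.  This keeps benzene, furan, pyridine and
#' naphthalene legal.  (Pyrrole-type N-H is mis-counted as pyridine-type; a
#' documented limitation.)
#'
#' @param m a `positioned_mol`.
#' @return numeric vector, one entry per atom.
#' @export
effective_valences <- function(m) {
  v <- numeric(n_atoms(m))
  n_arom <- integer(n_atoms(m))
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds$i[k]; j <- m$bonds$j[k]; o <- m$bonds$order[k]
      if (o == 1.5) {
        v[i] <- v[i] + 1; v[j] <- v[j] + 1
        n_arom[i] <- n_arom[i] + 1L; n_arom[j] <- n_arom[j] + 1L
      } else {
        v[i] <- v[i] + o; v[j] <- v[j] + o
      }
    }
  }
  pi_extra <- n_arom > 0 & m$element %in% c("C", "N")
  v[pi_extra] <- v[pi_extra] + 1
  v
}

#' Implicit hydrogen count per atom
#' @param m a `positioned_mol`.
#' @return integer vector.
#' @export
implicit_h <- function(m) {
  bos <- effective_valences(m)
  vapply(seq_len(n_atoms(m)), function(i) {
    el <- m$element[i]
    if (el == "H" || el == DUMMY || el == PLACEHOLDER) return(0L)
    dv <- default_valence(el) + max(0L, m$charge[i])
    as.integer(max(0, round(dv - bos[i])))
  }, integer(1))
}

#' Check that every atom's valence is legal
#'
#' @param m a `positioned_mol`.
#' @return logical scalar; attribute `"offenders"` lists failing atom indices.
#' @export
valence_legal <- function(m) {
  bos <- effective_valences(m)
  bad <- which(vapply(seq_len(n_atoms(m)), function(i) {
    el <- m$element[i]
    if (el == DUMMY) return(bos[i] > 1)
    if (el == PLACEHOLDER) return(FALSE)
    limit <- max_valence(el) + max(0L, m$charge[i]) * (el %in% c("N", "O"))
    bos[i] > limit + 1e-9
  }, logical(1)))
  structure(length(bad) == 0L, offenders = bad)
}

# Adjacency list: integer vector of neighbours per atom.
neighbours <- function(m) {
  adj <- vector("list", n_atoms(m))
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      i <- m$bonds$i[k]; j <- m$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

bond_index <- function(m, i, j) {
  which((m$bonds$i == i & m$bonds$j == j) | (m$bonds$i == j & m$bonds$j == i))
}

mol_graph <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds)) m$bonds[, c("i", "j")] else data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(m))))
}

#' Connected components of the molecular graph
#' @param m a `positioned_mol`.
#' @return integer vector of component membership, one entry per atom.
#' @export
mol_components <- function(m) {
  if (n_atoms(m) == 0) return(integer(0))
  igraph::components(mol_graph(m))$membership[as.character(seq_len(n_atoms(m)))]
}

# Drop atoms `idx`, remapping bonds; tags and provenance-style attributes on
# the caller's side must be remapped by the caller via the returned map.
remove_atoms <- function(m, idx) {
  if (!length(idx)) return(list(mol = m, old2new = seq_len(n_atoms(m))))
  keep <- setdiff(seq_len(n_atoms(m)), idx)
  old2new <- integer(n_atoms(m)); old2new[keep] <- seq_along(keep)
  b <- m$bonds[!(m$bonds$i %in% idx | m$bonds$j %in% idx), , drop = FALSE]
  b$i <- old2new[b$i]; b$j <- old2new[b$j]
  out <- positioned_mol(m$element[keep], m$xyz[keep, , drop = FALSE], b,
                        m$charge[keep], m$aromatic[keep], m$name, m$tags[keep])
  list(mol = out, old2new = old2new)
}

#' Heavy-atom RMSD between two conformations of the same molecule
#'
#' No superposition is performed: the method assumes one shared frame.
#' @param a,b `positioned_mol`s with identical atom ordering.
#' @param idx optional atom subset (defaults to heavy atoms of `a`).
#' @return numeric RMSD in Angstrom.
#' @export
rmsd_inplace <- function(a, b, idx = NULL) {
  if (is.null(idx)) idx <- setdiff(heavy_atoms(a), which(a$element == DUMMY))
  if (!length(idx)) return(0)
  d <- a$xyz[idx, , drop = FALSE] - b$xyz[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

# Pairwise distance between atom i of a and atom j of b.
atom_dist <- function(a, i, b, j) {
  sqrt(sum((a$xyz[i, ] - b$xyz[j, ])^2))
}

#' Add explicit hydrogens at idealised positions
#'
#' Implicit hydrogens are realised geometrically (tetrahedral / trigonal
#' placement from the existing substituent directions).  Used before
#' minimisation and interaction profiling; mapping never sees them.
#' @param m a `positioned_mol` with 3D coordinates.
#' @return a `positioned_mol` with explicit H appended after all heavy atoms.
#' @export
add_hydrogens <- function(m) {
  nh <- implicit_h(m)
  if (!any(nh > 0)) return(m)
  adj <- neighbours(m)
  el <- m$element; xyz <- m$xyz; charge <- m$charge; arom <- m$aromatic
  bonds <- m$bonds; tags <- m$tags
  for (i in which(nh > 0)) {
    base <- m$xyz[i, ]
    nbr_dirs <- if (length(adj[[i]])) {
      t(vapply(adj[[i]], function(j) {
        v <- m$xyz[j, ] - base; v / max(sqrt(sum(v^2)), 1e-6)
      }, numeric(3)))
    } else matrix(numeric(0), ncol = 3)
    dirs <- .h_directions(nbr_dirs, nh[i])
    blen <- .covalent_radius[[m$element[i]]] %||% 0.76
    blen <- blen + 0.31
    for (k in seq_len(nh[i])) {
      el <- c(el, "H")
      xyz <- rbind(xyz, base + dirs[k, ] * blen)
      charge <- c(charge, 0L); arom <- c(arom, FALSE)
      tags <- c(tags, list(NULL))
      bonds <- rbind(bonds, data.frame(i = i, j = length(el), order = 1))
    }
  }
  positioned_mol(el, xyz, bonds, charge, arom, m$name, tags)
}

# Unit directions for n new substituents given existing neighbour directions.
.h_directions <- function(nbr_dirs, n) {
  ref <- if (nrow(nbr_dirs)) -colSums(nbr_dirs) else c(0, 0, 1)
  if (sqrt(sum(ref^2)) < 1e-6) {
    # symmetric neighbours (e.g. linear): pick any perpendicular
    v <- nbr_dirs[1, ]
    ref <- c(-v[2], v[1], 0)
    if (sqrt(sum(ref^2)) < 1e-6) ref <- c(0, -v[3], v[2])
  }
  ref <- ref / sqrt(sum(ref^2))
  if (n == 1) return(matrix(ref, nrow = 1))
  # spread n directions on a cone around ref
  perp <- .any_perp(ref)
  perp2 <- .cross3(ref, perp)
  half <- 54.75 * pi / 180  # tetrahedral half-angle
  t(vapply(seq_len(n), function(k) {
    th <- 2 * pi * (k - 1) / n
    d <- cos(half) * ref + sin(half) * (cos(th) * perp + sin(th) * perp2)
    d / sqrt(sum(d^2))
  }, numeric(3)))
}

.any_perp <- function(v) {
  p <- .cross3(v, c(1, 0, 0))
  if (sqrt(sum(p^2)) < 1e-6) p <- .cross3(v, c(0, 1, 0))
  p / sqrt(sum(p^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' A fragment hit: a positioned molecule plus identity and covalent metadata
#'
#' @param mol a `positioned_mol` in the protein frame.
#' @param hit_id identifier (defaults to the molecule name).
#' @param covalent_attachment_index atom index of the dummy atom marking the
#'   covalent attachment point, or `NA`.
#' @return an object of class `fragment_hit`.
#' @export
fragment_hit <- function(mol, hit_id = mol$name,
                         covalent_attachment_index = NA_integer_) {
  n_dummy <- sum(mol$element == DUMMY)
  if (n_dummy > 1) stop("at most one covalent attachment (dummy) atom per hit")
  if (n_dummy == 1 && is.na(covalent_attachment_index))
    covalent_attachment_index <- which(mol$element == DUMMY)
  structure(list(mol = mol, hit_id = as.character(hit_id),
                 covalent_attachment_index = as.integer(covalent_attachment_index)),
            class = "fragment_hit")
}

#' @export
print.fragment_hit <- function(x, ...) {
  cov <- if (!is.na(x$covalent_attachment_index))
    sprintf(", covalent@%d", x$covalent_attachment_index) else ""
  cat(sprintf("<fragment_hit '%s': %d heavy atoms%s>\n",
              x$hit_id, length(heavy_atoms(x$mol)), cov))
  invisible(x)
}

#' Pipeline configuration
#'
#' All tunable distances, counts and weights, with the method's published
#' defaults.
#'
#' @param map_threshold positional-overlap threshold in Angstrom (default 2).
#' @param join_cutoff minimum-distance cutoff beyond which a hit is deferred
#'   and ultimately rejected, in Angstrom (default 5).
#' @param max_excluded maximum atoms droppable from an MCS match when that
#'   strictly enlarges the mapping (default 3).
#' @param linker_spacing Angstrom per linker atom in the alkyl-chain rule
#'   (default 1.22).
#' @param linker_first_element element of the first inserted linker atom
#'   (default `"N"`).
#' @param neighbourhood_padding padding added to the ligand length when
#'   selecting mobile pocket residues, in Angstrom (default 3).
#' @param max_min_cycles maximum pocket-minimisation cycles (default 15).
#' @param seed integer seed for all stochastic steps.
#' @param restraint_heavy,restraint_moderate positional restraint force
#'   constants, kcal/mol/A^2.
#' @param restraint_flat_bottom half-width of the force-free zone around the
#'   restraint target, Angstrom (default 0: pure harmonic).
#' @param mcs_levels laxity ladder for the multistep MCS, a subset of
#'   `c("strict","bond_order","element","ring")` in order.
#' @return an object of class `fs_config` (a named list).
#' @export
fs_config <- function(map_threshold = 2.0, join_cutoff = 5.0,
                      max_excluded = 3L, linker_spacing = 1.22,
                      linker_first_element = "N",
                      neighbourhood_padding = 3.0, max_min_cycles = 15L,
                      seed = 1L, restraint_heavy = 10, restraint_moderate = 2,
                      restraint_flat_bottom = 0,
                      mcs_levels = c("strict", "bond_order", "element", "ring")) {
  stopifnot(map_threshold > 0, join_cutoff > 0, linker_spacing > 0,
            neighbourhood_padding > 0, max_excluded >= 0)
  structure(list(map_threshold = map_threshold, join_cutoff = join_cutoff,
                 max_excluded = as.integer(max_excluded),
                 linker_spacing = linker_spacing,
                 linker_first_element = linker_first_element,
                 neighbourhood_padding = neighbourhood_padding,
                 max_min_cycles = as.integer(max_min_cycles),
                 seed = as.integer(seed),
                 restraint_heavy = restraint_heavy,
                 restraint_moderate = restraint_moderate,
                 restraint_flat_bottom = restraint_flat_bottom,
                 mcs_levels = mcs_levels),
            class = "fs_config")
}

# Typed failure conditions: every pipeline stage fails loudly with one of
# these, mirroring the failure taxonomy used in reporting.
fs_failure <- function(class, message, ...) {
  stop(structure(class = c(class, "fs_failure", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
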