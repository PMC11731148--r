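# Two-stage constrained minimisation under a small self-contained
# united-atom (heavy atoms only) molecular-mechanics engine: harmonic bonds
# and angles, 12-6 Lennard-Jones nonbonded terms, flat-bottom positional
# restraints toward the stitched coordinates, and a torsion penalty
# disfavouring E/cis exocyclic secondary amides.  The snapshot binding
# energy is the bound-minus-unbound difference at identical conformations,
# i.e. the restraint-free ligand-protein interaction energy.

ENGINE_NAME <- "fs_lj_harmonic"

#' Build the hit-derived restraint set for a stitched conformer
#'
#' Mapped exocyclic atoms are heavily restrained, mapped ring atoms
#' moderately, and amide/urea/ester atoms and novel (linker or unmapped)
#' atoms not at all.  Each exocyclic secondary amide contributes a torsion
#' penalty disfavouring the E/cis conformation.
#'
#' @param s a `stitched_conformer`.
#' @param cfg an [fs_config] (restraint magnitudes and flat-bottom width).
#' @return an object of class `restraint_set`: per-atom `weight`
#'   (kcal/mol/A^2), `target` coordinates, `torsions` (4-column matrix), and
#'   `scale` (global factor, 1).
#' @export
build_restraints <- function(s, cfg = fs_config()) {
  m <- s$mol
  n <- n_atoms(m)
  kinds <- vapply(s$provenance, function(p) p$kind, character(1))
  ring <- atoms_in_rings(m)
  amidic <- rep(FALSE, n)
  adj <- neighbours(m)
  # amide/urea/ester pattern: carbonyl carbon + its O plus single-bonded N/O
  for (c0 in which(m$element == "C")) {
    ks <- which(m$bonds$i == c0 | m$bonds$j == c0)
    partners <- ifelse(m$bonds$i[ks] == c0, m$bonds$j[ks], m$bonds$i[ks])
    dbl_o <- partners[m$bonds$order[ks] == 2 & m$element[partners] == "O"]
    sng_het <- partners[m$bonds$order[ks] == 1 & m$element[partners] %in% c("N", "O")]
    if (length(dbl_o) && length(sng_het))
      amidic[c(c0, dbl_o, sng_het)] <- TRUE
  }
  weight <- numeric(n)
  mapped <- kinds == "hit"
  weight[mapped & !ring] <- cfg$restraint_heavy
  weight[mapped & ring] <- cfg$restraint_moderate
  weight[amidic] <- 0
  # warhead protection overrides the amide exemption: those coordinates come
  # from the covalent hit and must hold within the heavy-restraint bound
  protected <- vapply(m$tags, function(t) isTRUE(t$protected), logical(1))
  weight[protected & mapped] <- cfg$restraint_heavy
  weight[m$element == DUMMY] <- cfg$restraint_heavy  # attachment stays put
  torsions <- matrix(integer(0), ncol = 4)
  for (c0 in which(m$element == "C")) {
    ks <- which(m$bonds$i == c0 | m$bonds$j == c0)
    partners <- ifelse(m$bonds$i[ks] == c0, m$bonds$j[ks], m$bonds$i[ks])
    o <- partners[m$bonds$order[ks] == 2 & m$element[partners] == "O"]
    nn <- partners[m$bonds$order[ks] == 1 & m$element[partners] == "N"]
    if (!length(o) || !length(nn)) next
    nn <- nn[1]
    if (ring[c0] || ring[nn]) next            # exocyclic amides only
    r_sub <- setdiff(partners[m$bonds$order[ks] == 1], nn)
    r_sub <- r_sub[m$element[r_sub] != "H"]
    n_sub <- setdiff(adj[[nn]], c0)
    n_sub <- n_sub[m$element[n_sub] != "H"]
    if (length(n_sub) == 1 && implicit_h(m)[nn] >= 1) {
      # secondary amide R-CO-NH-R': torsion R-C(=O)-N-R', trans favoured
      anchor <- if (length(r_sub)) r_sub[1] else o[1]
      torsions <- rbind(torsions, c(anchor, c0, nn, n_sub[1]))
    }
  }
  structure(list(weight = weight, target = m$xyz, torsions = torsions,
                 scale = 1, flat_bottom = cfg$restraint_flat_bottom),
            class = "restraint_set")
}

# ---------------------------------------------------------------------------
# force-field assembly
# ---------------------------------------------------------------------------

# topology terms for a ligand molecule (heavy atoms only expected)
.ff_topology <- function(m) {
  n <- n_atoms(m)
  bonds <- cbind(m$bonds$i, m$bonds$j,
                 vapply(seq_len(nrow(m$bonds)), function(k)
                   .bond_length(m$element[m$bonds$i[k]],
                                m$element[m$bonds$j[k]], m$bonds$order[k]),
                   numeric(1)))
  adj <- neighbours(m)
  angles <- matrix(numeric(0), ncol = 4)
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2) next
    th <- .ideal_angle(m, c0)
    cmb <- utils::combn(nb, 2)
    for (q in seq_len(ncol(cmb)))
      angles <- rbind(angles, c(cmb[1, q], c0, cmb[2, q], th))
  }
  # graph distances to exclude 1-2 and 1-3 pairs from LJ
  g <- mol_graph(m)
  gd <- igraph::distances(g)
  nb_pairs <- matrix(numeric(0), ncol = 3)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (is.finite(gd[i, j]) && gd[i, j] < 3) next
      rmin <- 0.95 * (element_property(.vdw_radius, m$element[i], 1.7) +
                        element_property(.vdw_radius, m$element[j], 1.7))
      nb_pairs <- rbind(nb_pairs, c(i, j, rmin))
    }
  }
  list(bonds = bonds, angles = angles, nb = nb_pairs)
}

.ff_kb <- 300; .ff_ka <- 40; .ff_eps <- 0.1; .ff_ktor <- 5
.ff_prot_restraint <- 5

# energy + gradient of the full system.
# x: flattened coords of the free atoms; layout: ligand atoms then mobile
# protein atoms.  `sys` holds everything static.
.ff_energy_grad <- function(x, sys, want_grad = TRUE, include_restraints = TRUE) {
  X <- matrix(x, ncol = 3)
  coords <- sys$coords            # full system coords (lig + protein)
  coords[sys$free_idx, ] <- X
  n_all <- nrow(coords)
  G <- matrix(0, n_all, 3)
  E <- 0
  scatter_add <- function(G, idx, contrib) {
    agg <- rowsum(contrib, idx)
    rows <- as.integer(rownames(agg))
    G[rows, ] <- G[rows, ] + agg
    G
  }
  # bonds
  B <- sys$bonds
  if (nrow(B)) {
    dv <- coords[B[, 1], , drop = FALSE] - coords[B[, 2], , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv^2)), 1e-8)
    err <- r - B[, 3]
    E <- E + .ff_kb * sum(err^2)
    if (want_grad) {
      g <- dv * (2 * .ff_kb * err / r)
      G <- scatter_add(G, B[, 1], g)
      G <- scatter_add(G, B[, 2], -g)
    }
  }
  # angles
  A <- sys$angles
  if (!want_grad && nrow(A)) {
    u <- coords[A[, 1], , drop = FALSE] - coords[A[, 2], , drop = FALSE]
    v <- coords[A[, 3], , drop = FALSE] - coords[A[, 2], , drop = FALSE]
    ru <- pmax(sqrt(rowSums(u^2)), 1e-8)
    rv <- pmax(sqrt(rowSums(v^2)), 1e-8)
    ct <- pmin(1 - 1e-9, pmax(-1 + 1e-9, rowSums(u * v) / (ru * rv)))
    E <- E + .ff_ka * sum((acos(ct) - A[, 4])^2)
    A <- A[integer(0), , drop = FALSE]
  }
  for (k in seq_len(nrow(A))) {
    i <- A[k, 1]; c0 <- A[k, 2]; j <- A[k, 3]
    u <- coords[i, ] - coords[c0, ]; v <- coords[j, ] - coords[c0, ]
    ru <- max(sqrt(sum(u^2)), 1e-8); rv <- max(sqrt(sum(v^2)), 1e-8)
    ct <- sum(u * v) / (ru * rv)
    ct <- min(1 - 1e-9, max(-1 + 1e-9, ct))
    th <- acos(ct)
    err <- th - A[k, 4]
    E <- E + .ff_ka * err^2
    st <- sqrt(1 - ct^2)
    pref <- -2 * .ff_ka * err / st
    gi <- pref * (v / (ru * rv) - ct * u / ru^2)
    gj <- pref * (u / (ru * rv) - ct * v / rv^2)
    G[i, ] <- G[i, ] + gi
    G[j, ] <- G[j, ] + gj
    G[c0, ] <- G[c0, ] - gi - gj
  }
  # Lennard-Jones (precomputed pair list with rmin)
  P <- sys$nb
  if (nrow(P)) {
    dv <- coords[P[, 1], , drop = FALSE] - coords[P[, 2], , drop = FALSE]
    r2 <- rowSums(dv^2)
    act <- r2 <= 100
    if (any(act)) {
      r <- pmax(sqrt(r2[act]), 1e-8)
      s6 <- (P[act, 3] / r)^6
      E <- E + .ff_eps * sum(s6^2 - 2 * s6)
      if (want_grad) {
        coef <- .ff_eps * 12 * (s6 - s6^2) / (r * r)
        g <- dv[act, , drop = FALSE] * coef
        G <- scatter_add(G, P[act, 1], g)
        G <- scatter_add(G, P[act, 2], -g)
      }
    }
  }
  # torsion penalties (E/cis amide): k*(1 + cos phi), minimum at trans
  Tq <- sys$torsions
  for (k in seq_len(nrow(Tq))) {
    ids <- Tq[k, ]
    phi <- .dihedral(coords[ids[1], ], coords[ids[2], ],
                     coords[ids[3], ], coords[ids[4], ])
    E <- E + .ff_ktor * (1 + cos(phi))
    if (want_grad) {
      # central-difference gradient of this 4-atom term (cheap and robust)
      h <- 1e-5
      for (a in ids) for (d in 1:3) {
        cp <- coords; cp[a, d] <- cp[a, d] + h
        e1 <- cos(.dihedral(cp[ids[1], ], cp[ids[2], ], cp[ids[3], ], cp[ids[4], ]))
        cp[a, d] <- cp[a, d] - 2 * h
        e2 <- cos(.dihedral(cp[ids[1], ], cp[ids[2], ], cp[ids[3], ], cp[ids[4], ]))
        G[a, d] <- G[a, d] + .ff_ktor * (e1 - e2) / (2 * h)
      }
    }
  }
  # positional restraints (flat-bottom harmonic, scaled)
  if (include_restraints) {
    R <- sys$restraints
    w <- R[, 2] * sys$restraint_scale
    act <- which(w > 0)
    if (length(act)) {
      dv <- coords[R[act, 1], , drop = FALSE] -
        sys$restraint_target[act, , drop = FALSE]
      r <- pmax(sqrt(rowSums(dv^2)), 1e-12)
      ex <- pmax(r - sys$flat_bottom, 0)
      E <- E + sum(w[act] * ex^2)
      if (want_grad) {
        g <- dv * (2 * w[act] * ex / r)
        G <- scatter_add(G, R[act, 1], g)
      }
    }
  }
  list(E = E, G = as.numeric(G[sys$free_idx, , drop = FALSE]))
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / max(sqrt(sum(b2^2)), 1e-8))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# assemble the minimisation system
# lig: positioned_mol; restraints: restraint_set (per lig atom);
# protein: protein_model or NULL; mobile_prot: indices into protein rows
# allowed to move; cross_bonds: matrix (lig_idx, prot_row, r0) for covalent
# links.
.ff_system <- function(lig, restraints, protein = NULL,
                       mobile_prot = integer(0),
                       cross_bonds = matrix(numeric(0), ncol = 3),
                       restraint_scale = 1) {
  topo <- .ff_topology(lig)
  nl <- n_atoms(lig)
  coords <- lig$xyz
  prot_el <- character(0)
  if (!is.null(protein) && nrow(protein)) {
    coords <- rbind(coords, protein_coords(protein))
    prot_el <- protein$element
  }
  np <- length(prot_el)
  # ligand-protein LJ pairs within 10 A (dummy atoms excluded: the dummy
  # stands for the protein attachment atom itself)
  nb <- topo$nb
  if (np) {
    pc <- coords[nl + seq_len(np), , drop = FALSE]
    for (i in seq_len(nl)) {
      if (lig$element[i] == DUMMY) next
      dd <- sqrt(rowSums(sweep(pc, 2, coords[i, ])^2))
      near <- which(dd < 10)
      if (length(near)) {
        rmin <- 0.95 * (element_property(.vdw_radius, lig$element[i], 1.7) +
                          element_property(.vdw_radius, prot_el[near], 1.7))
        nb <- rbind(nb, cbind(i, nl + near, rmin))
      }
    }
  }
  # covalent cross bonds join ligand and protein indices
  bonds <- topo$bonds
  if (nrow(cross_bonds)) {
    bonds <- rbind(bonds, cbind(cross_bonds[, 1], nl + cross_bonds[, 2],
                                cross_bonds[, 3]))
    # the attached atoms must not also repel each other
    if (nrow(nb)) {
      drop <- nb[, 1] %in% cross_bonds[, 1] & nb[, 2] %in% (nl + cross_bonds[, 2])
      nb <- nb[!drop, , drop = FALSE]
    }
  }
  free_idx <- c(seq_len(nl), nl + mobile_prot)
  Rm <- cbind(seq_len(nl), restraints$weight)
  # mobile protein atoms are softly restrained to their template positions
  if (length(mobile_prot)) {
    Rm <- rbind(Rm, cbind(nl + mobile_prot, .ff_prot_restraint))
  }
  target <- rbind(restraints$target,
                  coords[nl + mobile_prot, , drop = FALSE])
  list(coords = coords, n_lig = nl, n_free = length(free_idx),
       free_idx = free_idx, bonds = bonds, angles = topo$angles, nb = nb,
       torsions = restraints$torsions, restraints = Rm,
       restraint_target = target, flat_bottom = restraints$flat_bottom,
       restraint_scale = restraint_scale)
}

.ff_minimise <- function(sys, maxit = 300) {
  x0 <- as.numeric(sys$coords[sys$free_idx, , drop = FALSE])
  fn <- function(x) .ff_energy_grad(x, sys, want_grad = FALSE)$E
  gr <- function(x) .ff_energy_grad(x, sys)$G
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e5))
  coords <- sys$coords
  coords[sys$free_idx, ] <- matrix(opt$par, ncol = 3)
  list(coords = coords, value = opt$value)
}

# restraint-free ligand-protein interaction energy at given coordinates:
# the single-snapshot bound-minus-unbound difference.
.ff_interaction <- function(sys, coords) {
  E <- 0
  nb <- sys$nb
  cross <- nb[, 2] > sys$n_lig & nb[, 1] <= sys$n_lig
  for (k in which(cross)) {
    dv <- coords[nb[k, 1], ] - coords[nb[k, 2], ]
    r2 <- sum(dv^2)
    if (r2 > 100) next
    s6 <- (nb[k, 3] / sqrt(r2))^6
    E <- E + .ff_eps * (s6^2 - 2 * s6)
  }
  # covalent cross-bond strain counts toward the bound state
  B <- sys$bonds
  for (k in seq_len(nrow(B))) {
    if (B[k, 1] <= sys$n_lig && B[k, 2] > sys$n_lig ||
        B[k, 2] <= sys$n_lig && B[k, 1] > sys$n_lig) {
      r <- sqrt(sum((coords[B[k, 1], ] - coords[B[k, 2], ])^2))
      E <- E + .ff_kb * (r - B[k, 3])^2
    }
  }
  structure(E, engine = ENGINE_NAME)
}

#' Snapshot binding energy: bound minus unbound
#'
#' Both energies must come from the same engine and score function, with
#' restraint terms excluded.
#'
#' @param bound_energy,unbound_energy numeric energies carrying an
#'   `"engine"` attribute.
#' @return bound - unbound, in the engine's energy units (kcal/mol).
#' @export
delta_g <- function(bound_energy, unbound_energy) {
  ea <- attr(bound_energy, "engine"); eb <- attr(unbound_energy, "engine")
  if (!is.null(ea) && !is.null(eb) && !identical(ea, eb))
    stop("bound and unbound energies come from different engines")
  as.numeric(bound_energy) - as.numeric(unbound_energy)
}

#' Pre-minimisation against a frozen protein neighbourhood
#'
#' The ligand is minimised under the hit-derived restraints while the
#' protein cutout (all atoms within 8 A of the ligand) stays rigid.  The
#' molecular graph is untouched; only coordinates change.
#'
#' @param s a `stitched_conformer`.
#' @param restraints a `restraint_set` from [build_restraints].
#' @param protein optional `protein_model`.
#' @param restraint_scale global multiplier on restraint weights.
#' @param covalent optional list from [covalent_attachment_residue] plus
#'   `lig_atom` (ligand atom bonded to the protein).
#' @return the minimised `positioned_mol`.
#' @export
premin_frozen_neighbourhood <- function(s, restraints, protein = NULL,
                                        restraint_scale = 1, covalent = NULL) {
  m <- s$mol
  cutout <- NULL
  if (!is.null(protein) && nrow(protein)) {
    pc <- protein_coords(protein)
    near <- vapply(seq_len(nrow(pc)), function(q)
      min(sqrt(rowSums(sweep(m$xyz, 2, pc[q, ])^2))) < 8, logical(1))
    cutout <- protein[near, , drop = FALSE]
  }
  cross <- .covalent_cross_bonds(m, cutout, covalent)
  sys <- .ff_system(m, restraints, cutout, mobile_prot = integer(0),
                    cross_bonds = cross, restraint_scale = restraint_scale)
  res <- tryCatch(.ff_minimise(sys),
                  error = function(e) fs_failure("MinimisationFailure",
                                                 conditionMessage(e)))
  m$xyz <- res$coords[seq_len(n_atoms(m)), , drop = FALSE]
  m
}

.covalent_cross_bonds <- function(m, protein_sub, covalent) {
  if (is.null(covalent) || is.null(protein_sub) || !nrow(protein_sub))
    return(matrix(numeric(0), ncol = 3))
  row <- which(protein_sub$chain == covalent$chain &
                 protein_sub$resid == covalent$resid &
                 protein_sub$name == covalent$atom)
  if (!length(row)) return(matrix(numeric(0), ncol = 3))
  matrix(c(covalent$lig_atom, row[1], 1.81), ncol = 3)  # C-S bond length
}

#' In-pocket minimisation cycles with halving restraint weights
#'
#' Residues whose representative atom lies within (ligand length +
#' `cfg$neighbourhood_padding`) of the ligand centroid are mobile (softly
#' restrained to the template).  Each cycle minimises the system, computes
#' the snapshot binding energy restraint-free, and halves the global
#' restraint scale; cycling stops at the first cycle with a negative
#' binding energy, or after `cfg$max_min_cycles` cycles (then
#' `acceptable = FALSE` is reported, not raised).
#'
#' @param m a `stitched_conformer` (typically pre-minimised), with
#'   provenance.
#' @param restraints a `restraint_set`.
#' @param protein a `protein_model` (may be NULL for a bare ligand).
#' @param cfg an [fs_config].
#' @param hits the parent hits (for RMSD bookkeeping; optional).
#' @param covalent optional covalent attachment descriptor (see
#'   [premin_frozen_neighbourhood]).
#' @return an object of class `minimized_placement`.
#' @export
pocket_min_cycles <- function(m, restraints, protein = NULL,
                              cfg = fs_config(), hits = NULL,
                              covalent = NULL) {
  s <- m
  lig <- s$mol
  start_xyz <- lig$xyz
  hvy <- setdiff(heavy_atoms(lig), which(lig$element == DUMMY))
  liglen <- if (length(hvy) > 1)
    max(stats::dist(lig$xyz[hvy, , drop = FALSE])) else 0
  centroid <- colMeans(lig$xyz[hvy, , drop = FALSE])
  mobile <- integer(0); psub <- NULL
  if (!is.null(protein) && nrow(protein)) {
    pc <- protein_coords(protein)
    near_lig <- vapply(seq_len(nrow(pc)), function(q)
      min(sqrt(rowSums(sweep(lig$xyz, 2, pc[q, ])^2))) < 12, logical(1))
    psub <- protein[near_lig, , drop = FALSE]
    reskey <- paste(psub$chain, psub$resid)
    rep_rows <- vapply(unique(reskey), function(k) {
      rows <- which(reskey == k)
      ca <- rows[psub$name[rows] == "CA"]
      if (length(ca)) ca[1] else rows[1]
    }, integer(1))
    rc <- protein_coords(psub)[rep_rows, , drop = FALSE]
    dd <- sqrt(rowSums(sweep(rc, 2, centroid)^2))
    mobile_res <- unique(reskey)[dd <= liglen + cfg$neighbourhood_padding]
    mobile <- which(reskey %in% mobile_res)
  }
  cross <- .covalent_cross_bonds(lig, psub, covalent)
  scale <- 1
  scales <- numeric(0)
  dg <- NA_real_
  cycles <- 0L
  coords_final <- NULL
  sys <- NULL
  for (cyc in seq_len(cfg$max_min_cycles)) {
    cycles <- cyc
    scales <- c(scales, scale)
    sys <- .ff_system(lig, restraints, psub, mobile_prot = mobile,
                      cross_bonds = cross, restraint_scale = scale)
    res <- tryCatch(.ff_minimise(sys),
                    error = function(e) fs_failure("MinimisationFailure",
                                                   conditionMessage(e)))
    coords_final <- res$coords
    lig$xyz <- coords_final[seq_len(n_atoms(lig)), , drop = FALSE]
    if (!is.null(psub) && length(mobile))
      psub[mobile, c("x", "y", "z")] <- coords_final[n_atoms(lig) + mobile, ]
    dg <- delta_g(.ff_interaction(sys, coords_final),
                  structure(0, engine = ENGINE_NAME))
    if (dg < 0) break
    scale <- scale / 2
  }
  rmsd_hits <- if (!is.null(hits)) .rmsd_vs_hits(lig, s$provenance, hits) else NA_real_
  converged <- is.finite(dg) && dg < 0
  kinds <- vapply(s$provenance, function(p) p$kind, character(1))
  structure(list(
    mol = lig,
    dG_bind = dg,
    rmsd_vs_hits = rmsd_hits,
    rmsd_vs_start = {
      d <- lig$xyz[hvy, , drop = FALSE] - start_xyz[hvy, , drop = FALSE]
      sqrt(mean(rowSums(d^2)))
    },
    cycles = cycles,
    engine = ENGINE_NAME,
    acceptable = converged,          # refined by acceptability() downstream
    restraint_scales = scales,
    n_novel_atoms = sum(kinds != "hit"),
    n_mapped_atoms = sum(kinds == "hit"),
    hits_used = unique(stats::na.omit(vapply(s$provenance, function(p)
      if (p$kind == "hit") p$hit_id else NA_character_, character(1)))),
    provenance = s$provenance,
    protein_final = psub,
    covalent_residue = if (!is.null(covalent))
      paste0(covalent$chain, ":", covalent$resid) else NULL),
    class = "minimized_placement")
}

#' @export
print.minimized_placement <- function(x, ...) {
  cat(sprintf(paste0("<minimized_placement '%s': dG_bind=%.2f, ",
                     "rmsd_vs_hits=%.2f A, %d cycle(s), acceptable=%s>\n"),
              x$mol$name, x$dG_bind, x$rmsd_vs_hits, x$cycles, x$acceptable))
  invisible(x)
}

# combined heavy-atom RMSD of hit-derived atoms against their parent hit
# coordinates (one shared frame, no superposition)
.rmsd_vs_hits <- function(lig, provenance, hits) {
  ids <- vapply(hits, function(h) h$hit_id, character(1))
  sq <- c()
  for (i in seq_len(n_atoms(lig))) {
    p <- provenance[[i]]
    if (p$kind != "hit") next
    h <- hits[[match(p$hit_id, ids)]]
    if (is.na(match(p$hit_id, ids))) next
    if (lig$element[i] == "H") next
    sq <- c(sq, sum((lig$xyz[i, ] - h$mol$xyz[p$hit_atom, ])^2))
  }
  if (!length(sq)) return(NA_real_)
  sqrt(mean(sq))
}
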