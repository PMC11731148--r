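# Geometric protein-ligand interaction profiling (an in-repo stand-in for
# external profilers), the multiterm ranking score, the acceptability
# filter, and efficiency metrics.

# per-type distance cutoffs (Angstrom), config-exposed through the
# `cutoffs` argument of detect_interactions
.default_cutoffs <- c(hbond = 3.5, hydrophobic = 4.0, salt_bridge = 4.5,
                      pi_stack = 4.5, halogen = 3.5)

#' Detect protein-ligand interactions by geometric rules
#'
#' Rule-based and deterministic: hydrogen bonds (donor-acceptor <= 3.5 A,
#' D-H-A >= 120 deg on the ligand side; protein donors are judged by
#' distance only since the template carries no hydrogens), hydrophobic
#' carbon-carbon contacts (<= 4.0 A, closest per residue), salt bridges
#' between charged groups (<= 4.5 A), aromatic ring stacking (centroid
#' distance <= 4.5 A) and halogen bonds (X...O <= 3.5 A).
#'
#' @param protein a `protein_model`.
#' @param ligand a `positioned_mol`; hydrogens are added internally for
#'   donor geometry.
#' @param cutoffs named numeric vector overriding the default cutoffs.
#' @return an `interaction_profile`: data.frame with columns `type`,
#'   `lig_atom`, `residue`, `distance` (set semantics: no duplicates).
#' @export
detect_interactions <- function(protein, ligand, cutoffs = .default_cutoffs) {
  cutoffs <- utils::modifyList(as.list(.default_cutoffs), as.list(cutoffs))
  lig <- add_hydrogens(ligand)
  heavy <- setdiff(heavy_atoms(lig), which(lig$element == DUMMY))
  pc <- protein_coords(protein)
  res_id <- paste0(protein$chain, ":", protein$resid)
  adj <- neighbours(lig)
  rows <- list()
  push <- function(type, la, res, d)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, lig_atom = la,
                                             residue = res, distance = d,
                                             stringsAsFactors = FALSE)
  # precompute ligand-protein distances (heavy ligand atoms only)
  D <- matrix(NA_real_, n_atoms(lig), nrow(protein))
  for (i in heavy) D[i, ] <- sqrt(rowSums(sweep(pc, 2, lig$xyz[i, ])^2))
  prot_acceptor <- protein$element %in% c("O", "N")
  prot_donor <- protein$element == "N"
  prot_charged_neg <- protein$resname %in% c("ASP", "GLU") &
    protein$name %in% c("OD1", "OD2", "OE1", "OE2")
  prot_charged_pos <- (protein$resname == "LYS" & protein$name == "NZ") |
    (protein$resname == "ARG" & protein$name %in% c("NH1", "NH2", "NE"))
  for (i in heavy) {
    el <- lig$element[i]
    # hydrogen bonds, ligand as donor (needs an H and the angle criterion)
    if (el %in% c("N", "O")) {
      hs <- adj[[i]][lig$element[adj[[i]]] == "H"]
      for (p in which(prot_acceptor & D[i, ] <= cutoffs$hbond)) {
        ok <- FALSE
        for (h in hs) {
          v1 <- lig$xyz[i, ] - lig$xyz[h, ]
          v2 <- pc[p, ] - lig$xyz[h, ]
          ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                   (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
          if (ang * 180 / pi >= 120) ok <- TRUE
        }
        # ligand as acceptor against a protein donor: distance criterion
        if (!ok && prot_donor[p]) ok <- TRUE
        if (ok) push("hbond", i, res_id[p], D[i, p])
      }
    }
    # hydrophobic: closest carbon-carbon contact per residue
    if (el == "C" && !lig$aromatic[i]) {
      cand <- which(protein$element == "C" & D[i, ] <= cutoffs$hydrophobic)
      if (length(cand)) {
        for (rr in unique(res_id[cand])) {
          sel <- cand[res_id[cand] == rr]
          push("hydrophobic", i, rr, min(D[i, sel]))
        }
      }
    }
    # salt bridges
    chg <- lig$charge[i]
    if (chg > 0 || (el == "N" && length(adj[[i]]) &&
                    sum(lig$element[adj[[i]]] == "H") >= 2)) {
      for (p in which(prot_charged_neg & D[i, ] <= cutoffs$salt_bridge))
        push("salt_bridge", i, res_id[p], D[i, p])
    }
    if (chg < 0) {
      for (p in which(prot_charged_pos & D[i, ] <= cutoffs$salt_bridge))
        push("salt_bridge", i, res_id[p], D[i, p])
    }
    # halogen bonds
    if (el %in% c("Cl", "Br", "I")) {
      for (p in which(protein$element == "O" & D[i, ] <= cutoffs$halogen))
        push("halogen", i, res_id[p], D[i, p])
    }
  }
  # pi stacking: ligand aromatic ring centroids vs aromatic residue rings
  arom_res <- c(PHE = "benzene", TYR = "benzene", TRP = "indole", HIS = "imidazole")
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "ND1", "NE1",
                  "NE2", "CE3", "CZ2", "CZ3", "CH2")
  lig_rings <- Filter(function(rr) all(lig$aromatic[rr]), sssr(lig))
  if (length(lig_rings)) {
    key <- paste(protein$chain, protein$resid)
    for (k in unique(key[protein$resname %in% names(arom_res)])) {
      sel <- which(key == k & protein$name %in% ring_names)
      if (length(sel) < 5) next
      cen <- colMeans(pc[sel, , drop = FALSE])
      for (rr in lig_rings) {
        lcen <- colMeans(lig$xyz[rr, , drop = FALSE])
        d <- sqrt(sum((cen - lcen)^2))
        if (d <= cutoffs$pi_stack)
          push("pi_stack", rr[1], res_id[sel[1]], d)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), lig_atom = integer(0),
               residue = character(0), distance = numeric(0))
  out <- out[!duplicated(out[, c("type", "lig_atom", "residue")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_profile", "data.frame"))
}

#' Count conserved and lost interactions relative to the parent hits
#'
#' A hit contact is conserved if the ligand has a same-type contact with the
#' same residue; lost contacts are the remainder of the union over all hits
#' (set semantics: duplicate same-type same-residue contacts count once).
#'
#' @param profile_ligand `interaction_profile` of the placed ligand.
#' @param profiles_hits list of `interaction_profile`s of the hits, computed
#'   on the same protein.
#' @return list `(conserved, lost)` of integer counts.
#' @export
count_conserved <- function(profile_ligand, profiles_hits) {
  hit_keys <- unique(unlist(lapply(profiles_hits, function(p)
    paste(p$type, p$residue))))
  lig_keys <- unique(paste(profile_ligand$type, profile_ligand$residue))
  conserved <- sum(hit_keys %in% lig_keys)
  list(conserved = conserved, lost = length(hit_keys) - conserved)
}

#' Default ranking weights
#'
#' Order: lost interactions, novel atoms, binding energy, rotatable bonds
#' (each penalised), conserved atoms, conserved interactions (each
#' favoured).
#' @return named numeric vector of class `rank_weights`.
#' @export
default_rank_weights <- function() {
  structure(c(w_lost_interactions = 1, w_novel_atoms = 1, w_dG = 1,
              w_rotatable = 0.5, w_conserved_atoms = 1,
              w_conserved_interactions = 1), class = "rank_weights")
}

#' Count rotatable bonds
#'
#' Single acyclic bonds between non-terminal heavy atoms, excluding amide
#' C-N bonds.
#' @param m a `positioned_mol`.
#' @return integer.
#' @export
n_rotatable <- function(m) {
  if (!nrow(m$bonds)) return(0L)
  ring <- rep(FALSE, n_atoms(m))
  for (rr in sssr(m)) ring[rr] <- TRUE
  in_ring_bond <- function(k) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    any(vapply(sssr(m), function(rr) i %in% rr && j %in% rr, logical(1)))
  }
  adj <- neighbours(m)
  deg <- vapply(adj, function(nb) sum(m$element[nb] != "H"), integer(1))
  amide_cn <- function(i, j) {
    for (pair in list(c(i, j), c(j, i))) {
      c0 <- pair[1]; n0 <- pair[2]
      if (m$element[c0] == "C" && m$element[n0] == "N") {
        ks <- which(m$bonds$i == c0 | m$bonds$j == c0)
        partners <- ifelse(m$bonds$i[ks] == c0, m$bonds$j[ks], m$bonds$i[ks])
        if (any(m$bonds$order[ks] == 2 & m$element[partners] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  cnt <- 0L
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    if (m$bonds$order[k] != 1) next
    if (m$element[i] == "H" || m$element[j] == "H") next
    if (deg[i] < 2 || deg[j] < 2) next
    if (in_ring_bond(k)) next
    if (amide_cn(i, j)) next
    cnt <- cnt + 1L
  }
  cnt
}

#' Multiterm ranking score (lower is better)
#'
#' `score = w_lost * lost + w_novel * n_novel + w_dG * dG_bind +
#' w_rot * n_rotatable - w_cons_at * n_conserved_atoms -
#' w_cons_int * conserved`.  The per-term breakdown is attached as an
#' attribute.
#'
#' @param p a `minimized_placement`.
#' @param profile the ligand's `interaction_profile`.
#' @param hits list of [fragment_hit] (unused terms may be precomputed via
#'   `conserved`).
#' @param w a `rank_weights` vector (see [default_rank_weights]).
#' @param conserved optional precomputed result of [count_conserved].
#' @param profiles_hits optional hit profiles (computed if `conserved`
#'   missing and a protein is supplied here as attribute).
#' @return numeric score with attribute `"terms"`.
#' @export
rank_score <- function(p, profile, hits, w = default_rank_weights(),
                       conserved = NULL, profiles_hits = NULL) {
  if (is.null(conserved)) {
    conserved <- if (is.null(profiles_hits)) list(conserved = 0, lost = 0)
    else count_conserved(profile, profiles_hits)
  }
  terms <- c(
    lost_interactions = unname(w["w_lost_interactions"] * conserved$lost),
    novel_atoms = unname(w["w_novel_atoms"] * p$n_novel_atoms),
    dG = unname(w["w_dG"] * p$dG_bind),
    rotatable = unname(w["w_rotatable"] * n_rotatable(p$mol)),
    conserved_atoms = unname(-w["w_conserved_atoms"] * p$n_mapped_atoms),
    conserved_interactions = unname(-w["w_conserved_interactions"] *
                                      conserved$conserved))
  structure(sum(terms), terms = terms)
}

#' Acceptability filter for combinations and placements
#'
#' Accepted iff every hit contributed at least one mapped atom, the combined
#' heavy-atom RMSD against the hits is below 1 A, the snapshot binding
#' energy is negative, and the heavy-atom count strictly exceeds the largest
#' hit's.
#'
#' @param p a `minimized_placement`.
#' @param hits list of [fragment_hit].
#' @return list `(acceptable, reason)`; `reason` is `"ok"`, `"equal size"`,
#'   `"hit unused"` or `"strain/deviation"`.
#' @export
acceptability <- function(p, hits) {
  ids <- vapply(hits, function(h) h$hit_id, character(1))
  if (!all(ids %in% p$hits_used))
    return(list(acceptable = FALSE, reason = "hit unused"))
  if (hac(p$mol) <= max(vapply(hits, function(h) hac(h$mol), numeric(1))))
    return(list(acceptable = FALSE, reason = "equal size"))
  if (!is.finite(p$dG_bind) || p$dG_bind >= 0 ||
      !is.finite(p$rmsd_vs_hits) || p$rmsd_vs_hits >= 1)
    return(list(acceptable = FALSE, reason = "strain/deviation"))
  list(acceptable = TRUE, reason = "ok")
}

#' Ligand efficiency and interaction density
#'
#' `LE = -dG_bind / HAC` (nominally kcal/mol per heavy atom) and
#' `interactions_per_HAC = n_contacts / HAC`.  A positive binding energy
#' yields a negative LE, flagged in the result.
#'
#' @param p a `minimized_placement`.
#' @param profile the ligand's `interaction_profile`.
#' @return list `(LE, interactions_per_HAC, flagged)`.
#' @export
efficiency_metrics <- function(p, profile) {
  h <- hac(p$mol)
  if (h == 0) stop("heavy-atom count is zero")
  LE <- -p$dG_bind / h
  list(LE = LE, interactions_per_HAC = nrow(profile) / h, flagged = LE < 0)
}
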