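# Placement: build a hit-faithful conformer for an arbitrary candidate
# molecule from its MCS-cascade map onto the hits, then run the two-stage
# minimisation and scoring.

#' Stitch a candidate conformer from its hit maps
#'
#' Mapped candidate atoms take their hit atoms' coordinates (the
#' largest-coverage hit wins conflicts).  Each connected patch of unmapped
#' atoms receives coordinates from a seeded generated conformer rigidly
#' superposed onto the three mapped atoms nearest the patch attachment
#' (nearest by graph distance, then space); if the three-point fit residual
#' exceeds 1 A the best of 10 conformers is used.
#'
#' @param candidate a `positioned_mol` (topology; coordinates ignored).
#' @param maps list of [atom_map]s from [mcs_cascade_map] (candidate ->
#'   hit), named by hit id, with attribute `"primary"`.
#' @param hits list of [fragment_hit].
#' @param cfg an [fs_config].
#' @return a `stitched_conformer` whose provenance records, per atom, the
#'   donor hit or novelty.
#' @export
stitch_candidate <- function(candidate, maps, hits, cfg = fs_config()) {
  n <- n_atoms(candidate)
  ids <- vapply(hits, function(h) h$hit_id, character(1))
  xyz <- matrix(NA_real_, n, 3)
  prov <- replicate(n, list(kind = "novel-unmapped"), simplify = FALSE)
  primary <- attr(maps, "primary")
  order_ids <- c(primary, setdiff(names(maps), primary))
  for (id in order_ids) {
    mp <- maps[[id]]
    h <- hits[[match(id, ids)]]
    for (r in seq_len(nrow(mp$pairs))) {
      ci <- mp$pairs[r, 1]; hi <- mp$pairs[r, 2]
      if (!is.na(xyz[ci, 1])) next            # larger-coverage hit already won
      xyz[ci, ] <- h$mol$xyz[hi, ]
      prov[[ci]] <- list(kind = "hit", hit_id = id, hit_atom = hi)
    }
  }
  # covalent dummy inherits the covalent hit's attachment coordinates
  dummy <- which(candidate$element == DUMMY)
  if (length(dummy) && is.na(xyz[dummy[1], 1])) {
    for (h in hits) {
      if (!is.na(h$covalent_attachment_index)) {
        xyz[dummy[1], ] <- h$mol$xyz[h$covalent_attachment_index, ]
        prov[[dummy[1]]] <- list(kind = "hit", hit_id = h$hit_id,
                                 hit_atom = h$covalent_attachment_index)
        break
      }
    }
  }
  unmapped <- which(is.na(xyz[, 1]))
  if (length(unmapped) == n)
    fs_failure("MappingFailure", "no candidate atom is mapped to any hit")
  if (length(unmapped)) {
    adj <- neighbours(candidate)
    g <- mol_graph(candidate)
    gd <- igraph::distances(g)
    sub <- igraph::induced_subgraph(g, as.character(unmapped))
    comp <- igraph::components(sub)$membership
    patch_of <- stats::setNames(comp, names(comp))
    mapped_idx <- setdiff(seq_len(n), unmapped)
    for (pid in unique(patch_of)) {
      patch <- as.integer(names(patch_of)[patch_of == pid])
      # attachment: the mapped atom adjacent to the patch (closest by graph)
      ggd <- gd[patch, mapped_idx, drop = FALSE]
      att <- mapped_idx[which.min(apply(ggd, 2, min))]
      ord <- order(gd[att, mapped_idx],
                   vapply(mapped_idx, function(q)
                     sqrt(sum((xyz[q, ] - xyz[att, ])^2)), numeric(1)))
      anchors <- mapped_idx[ord][seq_len(min(3, length(mapped_idx)))]
      placed <- FALSE
      conf <- embed_conformer(candidate, seed = cfg$seed)
      fit <- kabsch(conf$xyz[anchors, , drop = FALSE],
                    xyz[anchors, , drop = FALSE])
      if (fit$rmsd > 1) {
        for (t in 2:10) {
          conf2 <- embed_conformer(candidate, seed = cfg$seed + 101L * t)
          fit2 <- kabsch(conf2$xyz[anchors, , drop = FALSE],
                         xyz[anchors, , drop = FALSE])
          if (fit2$rmsd < fit$rmsd) { conf <- conf2; fit <- fit2 }
          if (fit$rmsd <= 1) break
        }
      }
      newc <- fit$transform(conf$xyz)
      if (any(!is.finite(newc[patch, ])))
        fs_failure("PlacementFailure", "conformer generation failed for a patch")
      xyz[patch, ] <- newc[patch, , drop = FALSE]
    }
  }
  mol <- candidate
  mol$xyz <- xyz
  mol$tags <- lapply(seq_len(n), function(i) {
    tg <- mol$tags[[i]] %||% list()
    p <- prov[[i]]
    if (p$kind == "hit") { tg$src <- p$hit_id; tg$src_idx <- p$hit_atom }
    tg
  })
  stitched_conformer(mol, prov,
                     if (length(dummy)) dummy[1] else NA_integer_)
}

#' Place a candidate molecule against the fragment hits
#'
#' The full placement pipeline: parse (covalent mode if the SMILES carries a
#' dummy atom), map via the MCS cascade, stitch, pre-minimise against the
#' frozen neighbourhood, run in-pocket cycles, and score.  Every failure
#' mode raises a typed condition; no partial silent output.
#'
#' @param candidate a SMILES string or a topology `positioned_mol`.
#' @param hits list of [fragment_hit].
#' @param template optional `protein_model`.
#' @param cfg an [fs_config].
#' @param user_map optional user atom-map override (see [mcs_cascade_map]).
#' @param minimise set FALSE to return after stitching (roughly halves the
#'   runtime; `dG_bind` is then the unminimised snapshot energy).
#' @return a `minimized_placement`.
#' @export
place_candidate <- function(candidate, hits, template = NULL,
                            cfg = fs_config(), user_map = NULL,
                            minimise = TRUE) {
  if (is.character(candidate)) {
    mc <- mark_covalent(candidate)
    topo <- mc$topology
    warhead <- mc$warhead
    attach <- mc$attachment_index
  } else {
    topo <- candidate
    attach <- { d <- which(topo$element == DUMMY); if (length(d)) d[1] else NA_integer_ }
    warhead <- if (!is.na(attach)) warhead_atoms(topo, attach) else integer(0)
  }
  maps <- mcs_cascade_map(topo, hits, cfg, user_map)
  s <- stitch_candidate(topo, maps, hits, cfg)
  s <- protect_during_merge(s, warhead)
  cov <- NULL
  if (!is.na(attach) && !is.null(template)) {
    res <- covalent_attachment_residue(template, s$mol$xyz[attach, ])
    if (!is.null(res)) {
      lig_atom <- setdiff(neighbours(s$mol)[[attach]], attach)[1]
      cov <- c(res, list(lig_atom = lig_atom))
    }
  }
  restraints <- build_restraints(s, cfg)
  start <- s
  if (minimise) {
    s$mol <- premin_frozen_neighbourhood(s, restraints, template,
                                         covalent = cov)
  }
  p <- pocket_min_cycles(s, restraints, template, cfg, hits = hits,
                         covalent = cov)
  if (!minimise) {
    p$mol <- start$mol
    p$cycles <- 0L
    p$restraint_scales <- numeric(0)
  }
  p$rmsd_vs_start <- rmsd_inplace(p$mol, start$mol)
  if (!is.null(template)) {
    profile <- detect_interactions(template, p$mol)
    hit_profiles <- lapply(hits, function(h) detect_interactions(template, h$mol))
    cons <- count_conserved(profile, hit_profiles)
    w <- default_rank_weights()
    sc <- rank_score(p, profile, hits, w, conserved = cons)
    p$score <- as.numeric(sc)
    p$score_terms <- attr(sc, "terms")
    p$profile <- profile
  }
  acc <- acceptability(p, hits)
  p$acceptable <- acc$acceptable
  p$reason <- acc$reason
  p
}
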