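# Combination (merging/linking) of fragment hits by coordinate stitching.
# Rings are collapsed to placeholders, the positional overlap map is taken
# between collapsed molecules, unique atoms of the later hit are absorbed,
# rings are expanded, disconnected parts are linked with a short alkyl chain
# whose first atom is a heteroatom, and the chemistry is rectified.

#' Construct a stitched conformer
#'
#' @param mol a `positioned_mol`.
#' @param provenance list (one entry per atom): `list(kind, hit_id,
#'   hit_atom)` with kind in `"hit"`, `"novel-linker"`, `"novel-unmapped"`.
#' @param covalent_attachment_index optional atom index of the dummy atom.
#' @return an object of class `stitched_conformer`.
#' @export
stitched_conformer <- function(mol, provenance,
                               covalent_attachment_index = NA_integer_) {
  stopifnot(length(provenance) == n_atoms(mol))
  structure(list(mol = mol, provenance = provenance,
                 covalent_attachment_index = as.integer(covalent_attachment_index)),
            class = "stitched_conformer")
}

#' @export
print.stitched_conformer <- function(x, ...) {
  kinds <- vapply(x$provenance, function(p) p$kind, character(1))
  cat(sprintf("<stitched_conformer '%s': %d atoms (%d from hits, %d novel)>\n",
              x$mol$name, n_atoms(x$mol), sum(kinds == "hit"),
              sum(kinds != "hit")))
  invisible(x)
}

# provenance derived from the (src, src_idx) tags combine() plants on hit
# atoms; linker atoms are tagged `novel = "linker"`.
provenance_from_tags <- function(m) {
  lapply(seq_len(n_atoms(m)), function(i) {
    tg <- m$tags[[i]]
    if (!is.null(tg$novel)) list(kind = paste0("novel-", tg$novel))
    else if (!is.null(tg$src)) list(kind = "hit", hit_id = tg$src,
                                    hit_atom = tg$src_idx)
    else list(kind = "novel-unmapped")
  })
}

#' Merge the second collapsed molecule into the first under a positional map
#'
#' Mapped atoms keep the first molecule's identity and coordinates; unmapped
#' atoms of the second are appended with their coordinates and bonded
#' according to the original bond order where possible (valence violations
#' are deferred to [rectify]).  Mapped ring placeholders pool their stashed
#' rings, which [expand_rings] later unifies.
#'
#' @param a,b `collapsed_mol`s in the same frame.
#' @param map an [atom_map] from `a$mol` to `b$mol` (positional).
#' @return a merged `collapsed_mol`.
#' @export
merge_pair <- function(a, b, map) {
  am <- a$mol; bm <- b$mol
  is_ph_a <- am$element == PLACEHOLDER
  is_ph_b <- bm$element == PLACEHOLDER
  pairs <- map$pairs
  if (nrow(pairs)) {
    kind_ok <- is_ph_a[pairs[, 1]] == is_ph_b[pairs[, 2]]
    pairs <- pairs[kind_ok, , drop = FALSE]
  }
  b2m <- integer(n_atoms(bm))          # b index -> merged index
  b2m[pairs[, 2]] <- pairs[, 1]
  appended <- which(b2m == 0L)
  el <- am$element; xyz <- am$xyz; charge <- am$charge
  arom <- am$aromatic; tags <- am$tags
  stash <- a$stash
  for (q in appended) {
    el <- c(el, bm$element[q]); xyz <- rbind(xyz, bm$xyz[q, ])
    charge <- c(charge, bm$charge[q]); arom <- c(arom, bm$aromatic[q])
    tags <- c(tags, list(bm$tags[[q]]))
    b2m[q] <- length(el)
  }
  # pool stashes: remap b ext partners into merged indices first
  b_stash <- lapply(b$stash, function(entry) {
    entry$records <- lapply(entry$records, function(rec) {
      if (nrow(rec$ext)) rec$ext$partner <- b2m[rec$ext$partner]
      rec
    })
    entry
  })
  for (q in seq_len(n_atoms(bm))) {
    if (!is_ph_b[q]) next
    bid <- bm$tags[[q]]$placeholder
    tgt <- b2m[q]
    if (tgt <= n_atoms(am) && is_ph_a[tgt]) {
      aid <- am$tags[[tgt]]$placeholder
      stash[[aid]]$records <- c(stash[[aid]]$records, b_stash[[bid]]$records)
    } else {
      stash[[bid]] <- b_stash[[bid]]
    }
  }
  bonds <- am$bonds
  has_bond <- function(i, j)
    any((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))
  mapped_b <- pairs[, 2]
  for (k in seq_len(nrow(bm$bonds))) {
    u <- bm$bonds$i[k]; v <- bm$bonds$j[k]
    if (u %in% mapped_b && v %in% mapped_b) next  # first molecule's graph wins
    mu <- b2m[u]; mv <- b2m[v]
    if (mu != mv && !has_bond(mu, mv))
      bonds <- rbind(bonds, data.frame(i = mu, j = mv, order = bm$bonds$order[k]))
  }
  nm <- if (nzchar(am$name)) paste(am$name, bm$name, sep = "+") else bm$name
  mol <- positioned_mol(el, xyz, bonds, charge, arom, nm, tags)
  structure(list(mol = mol, stash = stash), class = "collapsed_mol")
}

# true-atom coordinates of a collapsed molecule (stash members instead of
# placeholder centroids); used for the join-distance check
all_atom_coords <- function(cm) {
  is_ph <- cm$mol$element == PLACEHOLDER
  out <- cm$mol$xyz[!is_ph, , drop = FALSE]
  for (entry in cm$stash) {
    for (rec in entry$records) {
      out <- rbind(out, as.matrix(rec$atoms[, c("x", "y", "z")]))
    }
  }
  out
}

#' Insert alkyl linkers until the molecule is connected
#'
#' While more than one connected component remains, the globally closest
#' pair of substitutable atoms (a heavy atom with an implicit hydrogen to
#' give up, not protected, not a dummy) in different components is linked by
#' a chain of `max(0, round(d / linker_spacing) - 1)` atoms evenly spaced on
#' the segment; the first inserted atom is `cfg$linker_first_element`
#' (nitrogen by default), the rest carbon, all single bonds.
#'
#' @param s a `stitched_conformer`.
#' @param cfg an [fs_config].
#' @return a `stitched_conformer`, connected.
#' @export
link_if_disconnected <- function(s, cfg = fs_config()) {
  m <- s$mol
  prov <- s$provenance
  repeat {
    comp <- mol_components(m)
    if (length(unique(comp)) <= 1) break
    subst <- which(implicit_h(m) > 0 & m$element != "H" & m$element != DUMMY &
                     !vapply(m$tags, function(t) isTRUE(t$protected), logical(1)))
    best <- NULL; best_d <- Inf
    for (i in subst) for (j in subst) {
      if (comp[i] >= comp[j]) next
      d <- sqrt(sum((m$xyz[i, ] - m$xyz[j, ])^2))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    if (is.null(best))
      fs_failure("LinkFailure", "no substitutable atom pair between components")
    i <- best[1]; j <- best[2]
    n_link <- max(0L, as.integer(round(best_d / cfg$linker_spacing)) - 1L)
    if (n_link == 0L) {
      m$bonds <- rbind(m$bonds, data.frame(i = i, j = j, order = 1))
    } else {
      seg <- m$xyz[j, ] - m$xyz[i, ]
      prev_idx <- i
      for (k in seq_len(n_link)) {
        elem <- if (k == 1L) cfg$linker_first_element else "C"
        pos <- m$xyz[i, ] + seg * k / (n_link + 1)
        m <- positioned_mol(c(m$element, elem), rbind(m$xyz, pos),
                            rbind(m$bonds, data.frame(i = prev_idx,
                                                      j = n_atoms(m) + 1L,
                                                      order = 1)),
                            c(m$charge, 0L), c(m$aromatic, FALSE), m$name,
                            c(m$tags, list(list(novel = "linker"))))
        prov <- c(prov, list(list(kind = "novel-linker")))
        prev_idx <- n_atoms(m)
      }
      m$bonds <- rbind(m$bonds, data.frame(i = prev_idx, j = j, order = 1))
    }
  }
  stitched_conformer(m, prov, s$covalent_attachment_index)
}

#' Rectify chemistry: repair valence and aromaticity violations
#'
#' Applied iteratively to fixpoint (at most `max_iter` sweeps):
#' geminal-substituted arene atoms dearomatise their ring; overfull N/O gain
#' a formal charge; other overfull aliphatic atoms migrate a substituent to
#' an adjacent atom with spare valence; pentavalent carbons ("Texas
#' carbons") lose their geometrically longest bond.  Bonds touching
#' protected (warhead) atoms are deleted only as a last resort.
#'
#' @param m a `positioned_mol`, possibly chemically invalid.
#' @param max_iter sweep limit (default 20).
#' @return a valence-legal `positioned_mol`.
#' @export
rectify <- function(m, max_iter = 20L) {
  protected <- vapply(m$tags, function(t) isTRUE(t$protected), logical(1))
  longest_bond_at <- function(m, at, avoid_protected = TRUE) {
    ks <- which(m$bonds$i == at | m$bonds$j == at)
    if (!length(ks)) return(NA_integer_)
    lens <- vapply(ks, function(k)
      sqrt(sum((m$xyz[m$bonds$i[k], ] - m$xyz[m$bonds$j[k], ])^2)), numeric(1))
    if (avoid_protected) {
      prot <- vapply(m$tags, function(t) isTRUE(t$protected), logical(1))
      free <- !(prot[m$bonds$i[ks]] | prot[m$bonds$j[ks]])
      if (any(free)) { ks <- ks[free]; lens <- lens[free] }
    }
    ks[which.max(lens)]
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # (1) geminal substituted arenes -> dearomatise the ring
    adj <- neighbours(m)
    rings <- sssr(m)
    arom_rings <- Filter(function(rr) all(m$aromatic[rr]), rings)
    for (i in which(m$aromatic)) {
      in_ring <- unique(unlist(Filter(function(rr) i %in% rr, arom_rings)))
      exo <- setdiff(adj[[i]], in_ring)
      exo <- exo[m$element[exo] != "H"]
      if (length(exo) >= 2) {
        for (rr in arom_rings) {
          if (!(i %in% rr)) next
          nrr <- length(rr)
          for (q in seq_len(nrr)) {
            k <- bond_index(m, rr[q], rr[q %% nrr + 1L])
            if (length(k) && m$bonds$order[k[1]] == 1.5) m$bonds$order[k[1]] <- 1
          }
          m$aromatic[rr] <- FALSE
        }
        changed <- TRUE
        break  # re-perceive rings after a dearomatisation
      }
    }
    if (changed) next
    # (2)/(3) valence repair
    v <- effective_valences(m)
    for (i in seq_len(n_atoms(m))) {
      el <- m$element[i]
      if (el %in% c("H", DUMMY, PLACEHOLDER)) next
      limit <- max_valence(el) + max(0L, m$charge[i]) * (el %in% c("N", "O"))
      if (v[i] <= limit + 1e-9) next
      if (el == "C") {
        k <- longest_bond_at(m, i)  # Texas carbon loses a bond
        m$bonds <- m$bonds[-k, , drop = FALSE]
        changed <- TRUE; break
      }
      if (el == "N" && m$charge[i] == 0L && v[i] <= 4 + 1e-9) {
        m$charge[i] <- 1L; changed <- TRUE; break
      }
      if (el == "O" && m$charge[i] == 0L && v[i] <= 3 + 1e-9) {
        m$charge[i] <- 1L; changed <- TRUE; break
      }
      # migrate a substituent to an adjacent atom with spare valence
      ks <- which(m$bonds$i == i | m$bonds$j == i)
      lens <- vapply(ks, function(k)
        sqrt(sum((m$xyz[m$bonds$i[k], ] - m$xyz[m$bonds$j[k], ])^2)), numeric(1))
      moved <- FALSE
      for (k in ks[order(-lens)]) {
        other <- if (m$bonds$i[k] == i) m$bonds$j[k] else m$bonds$i[k]
        o <- m$bonds$order[k]
        for (nb in setdiff(neighbours(m)[[i]], other)) {
          lim_nb <- max_valence(m$element[nb]) + max(0L, m$charge[nb])
          if (m$element[nb] %in% c("H", DUMMY)) next
          if (effective_valences(m)[nb] + o <= lim_nb + 1e-9 &&
              !length(bond_index(m, other, nb))) {
            if (m$bonds$i[k] == i) m$bonds$i[k] <- nb else m$bonds$j[k] <- nb
            moved <- TRUE; break
          }
        }
        if (moved) break
      }
      if (!moved) {
        k <- longest_bond_at(m, i)
        m$bonds <- m$bonds[-k, , drop = FALSE]
      }
      changed <- TRUE; break
    }
    if (!changed) break
  }
  ok <- valence_legal(m)
  if (!isTRUE(ok))
    fs_failure("RectificationFailure",
               sprintf("rectification did not reach a legal fixpoint (atoms %s)",
                       paste(attr(ok, "offenders"), collapse = ",")))
  m
}

#' Combine (merge/link) fragment hits into one stitched conformer
#'
#' Hits are ring-collapsed and folded pairwise in input order; a hit whose
#' minimum true-atom distance to the accumulated merger exceeds
#' `cfg$join_cutoff` is deferred to the end of the queue once, and fails
#' with a `DistanceFailure` if still too distant on its second visit.  After
#' all merges the rings are expanded, disconnected parts are linked, and the
#' result is rectified.  Covalent attachment and warhead atoms are protected
#' throughout (never deleted, element-swapped or used as linker attachment).
#'
#' @param hits list of [fragment_hit] (at least one).
#' @param cfg an [fs_config].
#' @return a `stitched_conformer`.
#' @export
combine_hits <- function(hits, cfg = fs_config()) {
  stopifnot(length(hits) >= 1)
  tagged <- lapply(hits, function(h) {
    m <- h$mol
    m$tags <- lapply(seq_len(n_atoms(m)), function(i) {
      tg <- m$tags[[i]] %||% list()
      tg$src <- h$hit_id; tg$src_idx <- i
      if (!is.na(h$covalent_attachment_index)) {
        wh <- warhead_atoms(m, h$covalent_attachment_index)
        if (i %in% wh) tg$protected <- TRUE
      }
      tg
    })
    m
  })
  acc <- collapse_rings(tagged[[1]])
  queue <- if (length(tagged) > 1) seq(2L, length(tagged)) else integer(0)
  deferred <- logical(length(tagged))
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    cb <- collapse_rings(tagged[[k]])
    A <- all_atom_coords(acc); B <- all_atom_coords(cb)
    dmin <- min(vapply(seq_len(nrow(B)), function(q)
      min(sqrt(rowSums(sweep(A, 2, B[q, ])^2))), numeric(1)))
    if (dmin > cfg$join_cutoff) {
      if (deferred[k])
        fs_failure("DistanceFailure",
                   sprintf("hit '%s' is %.2f A from the merger (cutoff %.1f A)",
                           hits[[k]]$hit_id, dmin, cfg$join_cutoff),
                   hit_id = hits[[k]]$hit_id)
      deferred[k] <- TRUE
      queue <- c(queue, k)
      next
    }
    map <- positional_atom_map(acc$mol, cb$mol, cfg$map_threshold)
    acc <- merge_pair(acc, cb, map)
  }
  expanded <- expand_rings(acc, unify_threshold = cfg$map_threshold)
  cov_idx <- which(expanded$element == DUMMY)
  s <- stitched_conformer(expanded, provenance_from_tags(expanded),
                          if (length(cov_idx)) cov_idx[1] else NA_integer_)
  s <- link_if_disconnected(s, cfg)
  mol <- rectify(s$mol)
  # rectify may delete bonds but never atoms, so provenance carries over
  stitched_conformer(mol, s$provenance, s$covalent_attachment_index)
}
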