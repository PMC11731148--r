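# Ring perception and the collapse/expand machinery.  During combination the
# positional overlap is computed with every ring replaced by a single
# placeholder pseudo-atom at the ring centroid; the ring's atoms, internal
# bonds and external attachments are stashed inside the placeholder and
# restored on expansion.  When two placeholders have been merged, their
# member atoms are unified by proximity and either a single perimeter ring is
# rebuilt (near-coincident rings) or a fused/spiro system results.

#' Smallest set of smallest rings
#'
#' Candidate rings are the shortest cycle through each edge (BFS in the graph
#' minus that edge); rings are then picked greedily by increasing size until
#' the cyclomatic number is reached.
#'
#' @param m a `positioned_mol`.
#' @return list of integer vectors, each a ring's atom indices in traversal
#'   order.
#' @export
sssr <- function(m) {
  nb <- nrow(m$bonds)
  if (!nb) return(list())
  g <- mol_graph(m)
  ncomp <- igraph::components(g)$no
  r <- nb - n_atoms(m) + ncomp
  if (r <= 0) return(list())
  cand <- list()
  seen <- character(0)
  for (k in seq_len(nb)) {
    u <- m$bonds$i[k]; v <- m$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(u), to = as.character(v))$vpath[[1]])
    if (length(sp) < 2) next
    ring <- as.integer(names(sp))
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); cand <- c(cand, list(ring)) }
  }
  ord <- order(vapply(cand, length, integer(1)),
               vapply(cand, function(x) paste(sort(x), collapse = ","), character(1)))
  cand <- cand[ord]
  ring_edges <- function(ring) {
    n <- length(ring)
    e <- cbind(ring, ring[c(2:n, 1)])
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  chosen <- list(); covered <- character(0)
  for (ring in cand) {
    if (length(chosen) >= r) break
    re <- ring_edges(ring)
    if (any(!re %in% covered)) {
      chosen <- c(chosen, list(ring))
      covered <- union(covered, re)
    }
  }
  chosen
}

#' Which atoms belong to at least one SSSR ring
#' @param m a `positioned_mol`.
#' @return logical vector, one entry per atom.
#' @export
atoms_in_rings <- function(m) {
  out <- rep(FALSE, n_atoms(m))
  for (ring in sssr(m)) out[ring] <- TRUE
  out
}

# Stable per-atom key used to stash and re-unify ring members: combine()
# tags every hit atom with (src, src_idx); untagged atoms key on themselves.
.atom_key <- function(m, i) {
  tg <- m$tags[[i]]
  if (!is.null(tg$src)) paste0(tg$src, "#", tg$src_idx) else paste0("self#", i)
}

#' Collapse every ring to a centroid placeholder
#'
#' One placeholder per SSSR ring, positioned at the arithmetic mean of the
#' member atoms.  Exocyclic bonds are re-attached to the placeholder with the
#' original partner recorded; fused rings stash shared atoms in both
#' placeholders (re-unified exactly on expansion); placeholders of rings that
#' share atoms are bonded to keep the collapsed graph connected.
#'
#' @param m a `positioned_mol`.
#' @return an object of class `collapsed_mol`: list with `mol` (the
#'   placeholder-bearing molecule) and `stash` (per-placeholder ring
#'   records).
#' @export
collapse_rings <- function(m) {
  rings <- sssr(m)
  if (!length(rings)) {
    return(structure(list(mol = m, stash = list()), class = "collapsed_mol"))
  }
  ring_atom <- rep(FALSE, n_atoms(m))
  for (ring in rings) ring_atom[ring] <- TRUE
  keep <- which(!ring_atom)
  old2new <- integer(n_atoms(m))
  old2new[keep] <- seq_along(keep)
  ph_ids <- vapply(seq_along(rings), function(r)
    sprintf("ph_%s_%d", substr(.atom_key(m, rings[[r]][1]), 1, 24), r), character(1))
  # make ids unique even for identical first-atom keys
  ph_ids <- make.unique(ph_ids, sep = "_")
  ph_index <- length(keep) + seq_along(rings)   # placeholder atom indices
  ring_of <- function(atom) which(vapply(rings, function(rr) atom %in% rr, logical(1)))
  el <- c(m$element[keep], rep(PLACEHOLDER, length(rings)))
  xyz <- rbind(m$xyz[keep, , drop = FALSE],
               t(vapply(rings, function(rr) colMeans(m$xyz[rr, , drop = FALSE]),
                        numeric(3))))
  charge <- c(m$charge[keep], integer(length(rings)))
  arom <- c(m$aromatic[keep], rep(FALSE, length(rings)))
  tags <- c(m$tags[keep], lapply(seq_along(rings), function(r)
    list(placeholder = ph_ids[r])))
  stash <- stats::setNames(vector("list", length(rings)), ph_ids)
  for (r in seq_along(rings)) {
    ring <- rings[[r]]
    atoms <- data.frame(
      element = m$element[ring],
      x = m$xyz[ring, 1], y = m$xyz[ring, 2], z = m$xyz[ring, 3],
      charge = m$charge[ring], aromatic = m$aromatic[ring],
      key = vapply(ring, function(i) .atom_key(m, i), character(1)),
      stringsAsFactors = FALSE)
    atoms$tag <- I(m$tags[ring])
    loc <- function(atom) match(atom, ring)
    internal <- m$bonds[m$bonds$i %in% ring & m$bonds$j %in% ring, , drop = FALSE]
    ib <- data.frame(li = vapply(internal$i, loc, integer(1)),
                     lj = vapply(internal$j, loc, integer(1)),
                     order = internal$order)
    half <- m$bonds[xor(m$bonds$i %in% ring, m$bonds$j %in% ring), , drop = FALSE]
    ext <- data.frame(li = integer(0), partner = integer(0),
                      partner_key = character(0), order = numeric(0))
    for (k in seq_len(nrow(half))) {
      inside <- if (half$i[k] %in% ring) half$i[k] else half$j[k]
      outside <- if (half$i[k] %in% ring) half$j[k] else half$i[k]
      if (ring_atom[outside]) {
        pr <- ring_of(outside)[1]
        ext <- rbind(ext, data.frame(
          li = loc(inside), partner = ph_index[pr],
          partner_key = .atom_key(m, outside), order = half$order[k]))
      } else {
        ext <- rbind(ext, data.frame(
          li = loc(inside), partner = old2new[outside],
          partner_key = NA_character_, order = half$order[k]))
      }
    }
    stash[[r]] <- list(records = list(list(atoms = atoms, bonds = ib, ext = ext)))
  }
  # collapsed bonds: non-ring bonds, atom-placeholder, placeholder-placeholder
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  add_bond <- function(bonds, i, j, order) {
    if (i == j) return(bonds)
    if (any((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i)))
      return(bonds)
    rbind(bonds, data.frame(i = i, j = j, order = order))
  }
  for (k in seq_len(nrow(m$bonds))) {
    u <- m$bonds$i[k]; v <- m$bonds$j[k]
    ui <- if (ring_atom[u]) ph_index[ring_of(u)[1]] else old2new[u]
    vi <- if (ring_atom[v]) ph_index[ring_of(v)[1]] else old2new[v]
    if (ring_atom[u] && ring_atom[v] &&
        length(intersect(ring_of(u), ring_of(v)))) next  # internal to a ring
    bonds <- add_bond(bonds, ui, vi, if (ring_atom[u] || ring_atom[v]) 1 else m$bonds$order[k])
  }
  # connect placeholders of rings sharing atoms (fused/spiro)
  if (length(rings) > 1) {
    for (r in seq_along(rings)) for (s in seq_along(rings)) {
      if (s > r && length(intersect(rings[[r]], rings[[s]])))
        bonds <- add_bond(bonds, ph_index[r], ph_index[s], 1)
    }
  }
  mol <- positioned_mol(el, xyz, bonds, charge, arom, m$name, tags)
  structure(list(mol = mol, stash = stash), class = "collapsed_mol")
}

#' @export
print.collapsed_mol <- function(x, ...) {
  cat(sprintf("<collapsed_mol '%s': %d atoms, %d placeholders>\n",
              x$mol$name, n_atoms(x$mol), length(x$stash)))
  invisible(x)
}

#' Expand ring placeholders back to full rings
#'
#' Stashed atoms are restored at their stashed coordinates.  Atoms stashed in
#' several rings of the same source molecule re-unify exactly (by identity
#' key).  For placeholders holding rings from different source molecules
#' (i.e. merged during combination), members are unified by minimum-distance
#' assignment within `unify_threshold`, the earlier ring winning element,
#' charge and coordinates.  If the union then still has at most one atom more
#' than the largest contributing ring, the rings are deemed coincident and a
#' single perimeter ring is rebuilt (members sorted by angle in the best-fit
#' plane); otherwise both bond sets are kept, yielding a fused, spiro or
#' bridged system whose chemistry the rectifier later repairs.
#'
#' @param c a `collapsed_mol`.
#' @param unify_threshold Angstrom; cross-molecule member unification
#'   distance (defaults to the 2 A positional threshold).
#' @return a `positioned_mol`.
#' @export
expand_rings <- function(c, unify_threshold = 2.0) {
  m <- c$mol
  is_ph <- m$element == PLACEHOLDER
  if (!any(is_ph)) return(m)
  keep <- which(!is_ph)
  el <- m$element[keep]
  xyz <- m$xyz[keep, , drop = FALSE]
  charge <- m$charge[keep]; arom <- m$aromatic[keep]
  tags <- m$tags[keep]
  old2new <- integer(n_atoms(m)); old2new[keep] <- seq_along(keep)
  keymap <- list()  # placeholder id -> named int vector: member key -> out idx
  # global registry: exact key -> out index (re-unifies atoms shared between
  # fused rings, which are stashed in several placeholders)
  global_keys <- character(0); global_idx <- integer(0)
  # phase 1: restore members
  for (pi in which(is_ph)) {
    id <- m$tags[[pi]]$placeholder
    recs <- c$stash[[id]]$records
    local_keys <- character(0); local_idx <- integer(0)
    src_of_key <- function(k) sub("#.*$", "", k)
    for (rec in recs) {
      A <- rec$atoms
      new_rows <- integer(nrow(A))
      # exact re-unification by key (fused rings, incl. across placeholders)
      for (q in seq_len(nrow(A))) {
        hit <- match(A$key[q], global_keys)
        if (!is.na(hit)) { new_rows[q] <- global_idx[hit]; next }
        new_rows[q] <- 0L
      }
      # cross-molecule unification by proximity (merged placeholders)
      pending <- which(new_rows == 0L)
      if (length(pending) && length(local_idx)) {
        existing_srcs <- src_of_key(local_keys)
        cand <- which(!duplicated(local_idx))  # candidate targets (out rows)
        tgt <- local_idx[cand]
        rec_src <- src_of_key(A$key[pending[1]])
        usable <- cand[existing_srcs[cand] != rec_src]
        if (length(usable)) {
          P <- as.matrix(A[pending, c("x", "y", "z")])
          Q <- xyz[local_idx[usable], , drop = FALSE]
          D <- outer(seq_len(nrow(P)), seq_len(nrow(Q)), Vectorize(function(p, q)
            sqrt(sum((P[p, ] - Q[q, ])^2))))
          D <- matrix(D, nrow = nrow(P))
          BIG <- 1e6
          cost <- ifelse(D <= unify_threshold, D, BIG)
          flip <- nrow(cost) > ncol(cost)
          if (flip) cost <- t(cost)
          asg <- solve_assignment(cost)
          for (rix in seq_len(nrow(cost))) {
            cix <- asg[rix]
            p <- if (flip) cix else rix
            q <- if (flip) rix else cix
            if (p <= nrow(P) && q <= nrow(Q) && D[p, q] <= unify_threshold)
              new_rows[pending[p]] <- local_idx[usable[q]]
          }
        }
      }
      for (q in seq_len(nrow(A))) {
        if (new_rows[q] == 0L) {
          el <- c(el, A$element[q])
          xyz <- rbind(xyz, as.numeric(A[q, c("x", "y", "z")]))
          charge <- c(charge, A$charge[q]); arom <- c(arom, A$aromatic[q])
          tg <- A$tag[[q]]
          tags <- c(tags, list(if (is.null(tg)) NULL else tg))
          new_rows[q] <- length(el)
        }
        local_keys <- c(local_keys, A$key[q])
        local_idx <- c(local_idx, new_rows[q])
        if (!A$key[q] %in% global_keys) {
          global_keys <- c(global_keys, A$key[q])
          global_idx <- c(global_idx, new_rows[q])
        }
      }
    }
    keymap[[id]] <- stats::setNames(local_idx, local_keys)
  }
  # phase 2: bonds
  bonds <- m$bonds
  # drop bonds touching placeholders (rebuilt from stash)
  ph_set <- which(is_ph)
  ext_bonds <- bonds[xor(bonds$i %in% ph_set, bonds$j %in% ph_set), , drop = FALSE]
  bonds <- bonds[!(bonds$i %in% ph_set | bonds$j %in% ph_set), , drop = FALSE]
  bonds$i <- old2new[bonds$i]; bonds$j <- old2new[bonds$j]
  has_bond <- function(i, j)
    any((bonds$i == i & bonds$j == j) | (bonds$i == j & bonds$j == i))
  push_bond <- function(i, j, order) {
    if (i != j && !has_bond(i, j))
      bonds <<- rbind(bonds, data.frame(i = i, j = j, order = order))
  }
  cur_val <- NULL  # lazily recomputed effective valences during fused assembly
  for (pi in which(is_ph)) {
    id <- m$tags[[pi]]$placeholder
    recs <- c$stash[[id]]$records
    km <- keymap[[id]]
    member_out <- unique(unname(km))
    srcs <- unique(sub("#.*$", "", names(km)))
    max_ring <- max(vapply(recs, function(r) nrow(r$atoms), integer(1)))
    coincident <- length(srcs) > 1 && length(member_out) <= max_ring
    if (coincident) {
      # rebuild a single perimeter ring: sort members by angle in best-fit plane
      P <- xyz[member_out, , drop = FALSE]
      ctr <- colMeans(P)
      Pc <- sweep(P, 2, ctr)
      sv <- svd(Pc)
      uv <- Pc %*% sv$v[, 1:2]
      ordv <- member_out[order(atan2(uv[, 2], uv[, 1]))]
      all_arom <- all(arom[member_out])
      n <- length(ordv)
      for (q in seq_len(n))
        push_bond(ordv[q], ordv[q %% n + 1L], if (all_arom) 1.5 else 1)
    } else {
      first_src <- sub("#.*$", "", recs[[1]]$atoms$key[1])
      for (rec in recs) {
        rec_src <- sub("#.*$", "", rec$atoms$key[1])
        for (k in seq_len(nrow(rec$bonds))) {
          i <- unname(km[rec$atoms$key[rec$bonds$li[k]]])
          j <- unname(km[rec$atoms$key[rec$bonds$lj[k]]])
          if (rec_src == first_src || length(srcs) == 1) {
            push_bond(i, j, rec$bonds$order[k])
          } else {
            # later molecule's ring bonds: only if valence allows
            tmp <- positioned_mol(el, xyz, bonds, charge, arom)
            v <- effective_valences(tmp)
            lim <- function(q) max_valence(el[q]) + max(0L, charge[q])
            o <- rec$bonds$order[k]
            oc <- if (o == 1.5) 1.5 else o
            if (i != j && !has_bond(i, j) &&
                v[i] + oc <= lim(i) + 1e-9 && v[j] + oc <= lim(j) + 1e-9)
              push_bond(i, j, o)
          }
        }
      }
    }
    # external attachments
    for (rec in recs) {
      for (k in seq_len(nrow(rec$ext))) {
        from <- unname(km[rec$atoms$key[rec$ext$li[k]]])
        partner <- rec$ext$partner[k]
        to <- if (is_ph[partner]) {
          pid <- m$tags[[partner]]$placeholder
          unname(keymap[[pid]][rec$ext$partner_key[k]])
        } else old2new[partner]
        if (!is.na(to) && !is.na(from)) push_bond(from, to, rec$ext$order[k])
      }
    }
  }
  # external bonds that were attached to the placeholder by later merging
  # (e.g. a linker bonded straight to a placeholder): reattach to the nearest
  # member atom with free valence
  for (k in seq_len(nrow(ext_bonds))) {
    pi <- if (is_ph[ext_bonds$i[k]]) ext_bonds$i[k] else ext_bonds$j[k]
    other <- if (is_ph[ext_bonds$i[k]]) ext_bonds$j[k] else ext_bonds$i[k]
    if (is_ph[other]) next  # placeholder-placeholder marker bonds vanish
    id <- m$tags[[pi]]$placeholder
    km <- keymap[[id]]
    recs <- c$stash[[id]]$records
    # already realised via an ext record?
    realised <- any(vapply(recs, function(rec)
      nrow(rec$ext) > 0 && any(is.na(rec$ext$partner_key) &
                                 rec$ext$partner == other), logical(1)))
    if (realised) next
    members <- unique(unname(km))
    oxyz <- xyz[old2new[other], ]
    dd <- sqrt(rowSums(sweep(xyz[members, , drop = FALSE], 2, oxyz)^2))
    for (q in order(dd)) {
      i <- members[q]
      tmp <- positioned_mol(el, xyz, bonds, charge, arom)
      v <- effective_valences(tmp)
      if (v[i] + ext_bonds$order[k] <= max_valence(el[i]) + max(0L, charge[i]) + 1e-9 ||
          q == length(members)) {
        push_bond(i, old2new[other], ext_bonds$order[k])
        break
      }
    }
  }
  positioned_mol(el, xyz, bonds, charge, arom, m$name, tags)
}
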