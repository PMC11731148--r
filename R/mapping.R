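# Atom correspondences.  Two flavours feed the pipeline:
#  * positional maps (hit <-> hit): one-to-one heavy-atom assignment within a
#    distance threshold, minimising total paired distance -- this drives
#    combination (merging/linking);
#  * MCS-cascade maps (candidate <-> hits): a strict maximum common
#    substructure seeds the core, then progressively laxer passes extend it,
#    constrained by the hits' mutual positional overlap -- this drives
#    placement.

#' Construct an atom map
#'
#' @param pairs two-column integer matrix: left (first molecule) and right
#'   (second molecule) atom indices; one-to-one.
#' @param kind `"positional"`, `"mcs"` or `"user"`.
#' @return an `atom_map` with `score` = number of mapped pairs.
#' @export
atom_map <- function(pairs, kind = c("positional", "mcs", "user")) {
  kind <- match.arg(kind)
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  if (nrow(pairs)) {
    if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
      stop("atom map must be one-to-one")
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(list(pairs = pairs, kind = kind, score = nrow(pairs)),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map (%s): %d pairs>\n", x$kind, x$score))
  invisible(x)
}

# right-index lookup for a left index (NA if unmapped)
map_lookup <- function(map, left) {
  hit <- match(left, map$pairs[, 1])
  ifelse(is.na(hit), NA_integer_, map$pairs[hit, 2])
}

#' Positional atom overlap map between two positioned molecules
#'
#' Returns the one-to-one assignment of heavy atoms with all paired
#' distances at or below `threshold` that minimises total paired distance;
#' atoms that cannot be paired within the threshold are left unmapped.  Any
#' heavy element may pair with any other: element identity is resolved later
#' by the merge step.  The empty map is a valid result.
#'
#' @param a,b `positioned_mol`s with 3D coordinates.
#' @param threshold pairing threshold in Angstrom (default 2.0).
#' @return an [atom_map] of kind `"positional"`.
#' @export
positional_atom_map <- function(a, b, threshold = 2.0) {
  ha <- heavy_atoms(a); hb <- heavy_atoms(b)
  if (!length(ha) || !length(hb)) return(atom_map(matrix(integer(0), ncol = 2)))
  d <- outer(seq_along(ha), seq_along(hb), Vectorize(function(p, q)
    atom_dist(a, ha[p], b, hb[q])))
  d <- matrix(d, nrow = length(ha))
  BIG <- 1e6  # >> any feasible total distance, << accumulating to Inf
  cost <- ifelse(d <= threshold, d, BIG)
  flipped <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); d <- t(d); flipped <- TRUE }
  assign <- solve_assignment(cost)
  rows <- seq_len(nrow(cost))
  keep <- d[cbind(rows, assign)] <= threshold
  li <- rows[keep]; ri <- assign[keep]
  pairs <- if (flipped) cbind(ha[ri], hb[li]) else cbind(ha[li], hb[ri])
  atom_map(pairs, "positional")
}

#' Positional overlap map between two hits, ring-aware
#'
#' The overlap is computed with rings collapsed to centroid placeholders
#' (this prevents spurious rotated ring-atom pairings: a whole ring pairs as
#' one unit via its centroid), then placeholder pairs are expanded back to
#' member-atom correspondences by minimum-distance assignment within the
#' threshold.
#'
#' @param a,b `positioned_mol`s.
#' @param threshold pairing threshold in Angstrom.
#' @return an [atom_map] of kind `"positional"` over original atom indices.
#' @export
overlap_map_ring_aware <- function(a, b, threshold = 2.0) {
  ca <- collapse_rings(a); cb <- collapse_rings(b)
  cmap <- positional_atom_map(ca$mol, cb$mol, threshold)
  # index maps back to the original molecules
  back <- function(cm, orig) {
    is_ph <- cm$mol$element == PLACEHOLDER
    idx <- integer(n_atoms(cm$mol))
    idx[!is_ph] <- which(!atoms_in_rings(orig))
    idx
  }
  back_a <- back(ca, a); back_b <- back(cb, b)
  members <- function(cm, pi) {
    keys <- cm$stash[[cm$mol$tags[[pi]]$placeholder]]$records[[1]]$atoms$key
    as.integer(sub("^.*#", "", keys))
  }
  pairs <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(cmap$pairs))) {
    i <- cmap$pairs[r, 1]; j <- cmap$pairs[r, 2]
    ph_i <- ca$mol$element[i] == PLACEHOLDER
    ph_j <- cb$mol$element[j] == PLACEHOLDER
    if (ph_i != ph_j) next
    if (!ph_i) {
      d <- sqrt(sum((ca$mol$xyz[i, ] - cb$mol$xyz[j, ])^2))
      if (d <= threshold) pairs <- rbind(pairs, c(back_a[i], back_b[j]))
    } else {
      ma <- members(ca, i); mb <- members(cb, j)
      sub_a <- a; sub_a$xyz <- a$xyz
      D <- outer(seq_along(ma), seq_along(mb), Vectorize(function(p, q)
        sqrt(sum((a$xyz[ma[p], ] - b$xyz[mb[q], ])^2))))
      D <- matrix(D, nrow = length(ma))
      cost <- ifelse(D <= threshold, D, 1e6)
      flip <- nrow(cost) > ncol(cost)
      if (flip) { cost <- t(cost); D <- t(D) }
      asg <- solve_assignment(cost)
      for (rr in seq_len(nrow(cost))) {
        if (D[rr, asg[rr]] <= threshold) {
          pr <- if (flip) c(ma[asg[rr]], mb[rr]) else c(ma[rr], mb[asg[rr]])
          pairs <- rbind(pairs, pr)
        }
      }
    }
  }
  atom_map(pairs, "positional")
}

# ---------------------------------------------------------------------------
# Maximum common (connected, induced) substructure search
# ---------------------------------------------------------------------------

# Compatibility predicates for the laxity ladder.  Each level returns a list
# of two closures: atom(iA, iB) and bond(orderA, orderB).
.mcs_level_compat <- function(level, a, b, ringA, ringB) {
  groupA <- element_property(.periodic_group, a$element, 0)
  groupB <- element_property(.periodic_group, b$element, 0)
  atom_fn <- switch(level,
    strict = function(i, j) a$element[i] == b$element[j] && ringA[i] == ringB[j],
    bond_order = function(i, j) a$element[i] == b$element[j] && ringA[i] == ringB[j],
    element = function(i, j) groupA[i] == groupB[j] && groupA[i] != 0 &&
      ringA[i] == ringB[j],
    ring = function(i, j) groupA[i] == groupB[j] && groupA[i] != 0)
  bond_fn <- switch(level,
    strict = function(oa, ob) oa == ob,
    bond_order = ,
    element = ,
    ring = function(oa, ob) TRUE)
  list(atom = atom_fn, bond = bond_fn)
}

# Backtracking maximum common connected induced subgraph between the heavy
# atoms of a and b.  `seed` (2-col matrix) pairs are forced; `allowed`
# (optional function(i, j) -> logical) further restricts candidate pairs.
# Returns a 2-column matrix of (a index, b index).
mcs_match <- function(a, b, level = "strict", seed = NULL, allowed = NULL,
                      max_nodes = 2e5) {
  ha <- setdiff(heavy_atoms(a), which(a$element == DUMMY))
  hb <- setdiff(heavy_atoms(b), which(b$element == DUMMY))
  ringA <- atoms_in_rings(a); ringB <- atoms_in_rings(b)
  compat <- .mcs_level_compat(level, a, b, ringA, ringB)
  adjA <- neighbours(a); adjB <- neighbours(b)
  bondA <- function(i, j) { k <- bond_index(a, i, j); if (length(k)) a$bonds$order[k[1]] else NA }
  bondB <- function(i, j) { k <- bond_index(b, i, j); if (length(k)) b$bonds$order[k[1]] else NA }
  ok_pair <- function(i, j) {
    compat$atom(i, j) && (is.null(allowed) || allowed(i, j))
  }
  # feasibility of adding (i, j) to mapping `mp` (named int vector a->b)
  consistent <- function(mp, i, j) {
    for (ai in as.integer(names(mp))) {
      bi <- mp[[as.character(ai)]]
      a_adj <- j_in <- NULL
      a_bonded <- i %in% adjA[[ai]]
      b_bonded <- j %in% adjB[[bi]]
      if (a_bonded != b_bonded) return(FALSE)
      if (a_bonded && !compat$bond(bondA(i, ai), bondB(j, bi))) return(FALSE)
    }
    TRUE
  }
  best <- matrix(integer(0), ncol = 2)
  nodes <- 0L
  search <- function(mp) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return()
    if (length(mp) > nrow(best)) {
      best <<- cbind(as.integer(names(mp)), unname(unlist(mp)))
    }
    mappedA <- as.integer(names(mp)); mappedB <- unname(unlist(mp))
    # frontier: unmapped a-atoms adjacent to the mapped core (or all if empty)
    candA <- if (length(mp)) {
      sort(setdiff(intersect(unique(unlist(adjA[mappedA])), ha), mappedA))
    } else ha
    remA <- setdiff(ha, mappedA)
    if (length(mp) + length(remA) <= nrow(best)) return()  # bound
    for (i in candA) {
      candB <- if (length(mp)) {
        sort(setdiff(intersect(unique(unlist(adjB[mappedB])), hb), mappedB))
      } else hb
      for (j in candB) {
        if (ok_pair(i, j) && consistent(mp, i, j)) {
          mp2 <- mp; mp2[[as.character(i)]] <- j
          search(mp2)
        }
      }
    }
  }
  mp0 <- list()
  if (!is.null(seed) && nrow(seed)) {
    for (k in seq_len(nrow(seed))) {
      i <- seed[k, 1]; j <- seed[k, 2]
      if (!consistent(mp0, i, j)) return(best)  # infeasible seed: empty
      mp0[[as.character(i)]] <- j
    }
    best <- seed
  }
  search(mp0)
  colnames(best) <- c("left", "right")
  best[order(best[, 1]), , drop = FALSE]
}

#' Multistep MCS mapping of a candidate molecule onto the fragment hits
#'
#' Implements the placement mapping cascade: a strict MCS (element- and
#' bond-order-exact, ring-membership-respecting) is computed against every
#' hit and the largest match seeds the core (the "primary" hit; coverage
#' ties broken by input order).  Remaining hits are mapped constrained by
#' their positional overlap with the primary hit, so maps agree wherever hit
#' atoms overlap in space.  Progressively laxer passes (bond order, then
#' element within the same periodic group, then ring membership) extend each
#' map, keeping already-mapped atoms fixed.  During cross-hit conflict
#' resolution up to `cfg$max_excluded` mapped atoms may be dropped from the
#' smaller-coverage hit when that resolves a disagreement ("red herring"
#' removal).  Entries of `user_map` are immutable and override all automatic
#' choices.
#'
#' @param candidate a `positioned_mol`; only its topology is used.
#' @param hits list of [fragment_hit].
#' @param cfg an [fs_config].
#' @param user_map optional named list `hit_id -> 2-column matrix` of forced
#'   (candidate index, hit index) pairs, or a path to the JSON format
#'   documented in [read_user_map].
#' @return named list of [atom_map]s (candidate -> hit), one per hit that
#'   yielded any match, in hit order; attribute `"primary"` names the
#'   largest-coverage hit.
#' @export
mcs_cascade_map <- function(candidate, hits, cfg = fs_config(),
                            user_map = NULL) {
  stopifnot(length(hits) >= 1)
  if (is.character(user_map)) user_map <- read_user_map(user_map)
  ids <- vapply(hits, function(h) h$hit_id, character(1))
  forced <- lapply(ids, function(id) {
    um <- user_map[[id]]
    if (is.null(um)) matrix(integer(0), ncol = 2) else
      matrix(as.integer(um), ncol = 2)
  })
  names(forced) <- ids
  levels <- cfg$mcs_levels
  # pass 1: strict MCS against every hit
  strict_maps <- lapply(seq_along(hits), function(k)
    mcs_match(candidate, hits[[k]]$mol, "strict", seed = forced[[k]]))
  sizes <- vapply(strict_maps, nrow, integer(1))
  if (all(sizes == 0) && all(vapply(forced, nrow, integer(1)) == 0))
    fs_failure("MappingFailure", "no hit yields any MCS match with the candidate")
  primary <- which.max(sizes)  # which.max keeps first on ties = input order
  maps <- vector("list", length(hits)); names(maps) <- ids
  maps[[primary]] <- strict_maps[[primary]]
  # overlap constraint for non-primary hits: a hit atom positionally
  # overlapping a mapped primary-hit atom must map to the same candidate atom
  make_allowed <- function(k) {
    ov <- overlap_map_ring_aware(hits[[k]]$mol, hits[[primary]]$mol,
                                 cfg$map_threshold)
    pmap <- maps[[primary]]
    function(ci, hi) {
      pj <- map_lookup(ov, hi)       # primary-hit atom overlapping hit atom hi
      if (is.na(pj)) return(TRUE)
      row <- match(pj, pmap[, 2])
      if (is.na(row)) return(TRUE)   # overlapped atom unmapped: no constraint
      pmap[row, 1] == ci
    }
  }
  for (k in seq_along(hits)) {
    if (k == primary) next
    maps[[k]] <- mcs_match(candidate, hits[[k]]$mol, "strict",
                           seed = forced[[k]], allowed = make_allowed(k))
  }
  # laxer passes extend each map, existing pairs held fixed
  for (lv in setdiff(levels, "strict")) {
    for (k in seq_along(hits)) {
      allowed <- if (k == primary) NULL else make_allowed(k)
      ext <- mcs_match(candidate, hits[[k]]$mol, lv, seed = maps[[k]],
                       allowed = allowed)
      if (nrow(ext) > nrow(maps[[k]])) maps[[k]] <- ext
    }
  }
  # cross-hit conflict resolution ("red herrings"): where two hits' atoms
  # overlap positionally but claim different candidate atoms, drop the pair
  # from the smaller-coverage hit (never a user-forced pair), re-extend.
  budget <- cfg$max_excluded
  for (k in seq_along(hits)) {
    if (k == primary || budget <= 0 || !nrow(maps[[k]])) next
    ov <- overlap_map_ring_aware(hits[[k]]$mol, hits[[primary]]$mol,
                                 cfg$map_threshold)
    pmap <- maps[[primary]]
    drop_rows <- integer(0)
    for (r in seq_len(nrow(maps[[k]]))) {
      hi <- maps[[k]][r, 2]; ci <- maps[[k]][r, 1]
      pj <- map_lookup(ov, hi)
      if (is.na(pj)) next
      prow <- match(pj, pmap[, 2])
      if (!is.na(prow) && pmap[prow, 1] != ci) {
        is_forced <- nrow(forced[[k]]) &&
          any(forced[[k]][, 1] == ci & forced[[k]][, 2] == hi)
        if (!is_forced && length(drop_rows) < budget)
          drop_rows <- c(drop_rows, r)
      }
    }
    if (length(drop_rows)) {
      maps[[k]] <- maps[[k]][-drop_rows, , drop = FALSE]
      budget <- budget - length(drop_rows)
    }
  }
  out <- lapply(maps, function(p) atom_map(p, "mcs"))
  used <- vapply(out, function(mm) mm$score > 0, logical(1))
  out <- out[used]
  if (!length(out))
    fs_failure("MappingFailure", "no hit yields any MCS match with the candidate")
  attr(out, "primary") <- ids[primary]
  out
}

#' Read a user atom-map override from JSON
#'
#' Format: `{"hit_id": [[candidate_idx, hit_idx], ...], ...}` with 0-based
#' indices (converted to 1-based internally).
#'
#' @param path JSON file path.
#' @return named list of 2-column 1-based integer matrices.
#' @export
read_user_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) {
    m <- if (is.matrix(p)) p else matrix(as.integer(unlist(p)), ncol = 2, byrow = TRUE)
    matrix(as.integer(m), ncol = 2) + 1L
  })
}
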