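# Shared test helpers: independent oracles and small builders.

# Brute-force optimal-assignment oracle for the positional atom map:
# maximum-cardinality one-to-one matching under the distance threshold,
# minimum total distance among those.  Branch-and-bound DFS over left atoms
# (match to any unused feasible right atom, or skip).
brute_force_positional <- function(A, B, threshold) {
  nA <- nrow(A); nB <- nrow(B)
  D <- matrix(Inf, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d <= threshold) D[i, j] <- d
  }
  best <- list(size = 0L, total = 0)
  used <- rep(FALSE, nB)
  feas_per_row <- vapply(seq_len(nA), function(i) sum(is.finite(D[i, ])),
                         integer(1))
  rec <- function(i, size, total) {
    if (i > nA) {
      if (size > best$size ||
          (size == best$size && total < best$total - 1e-12)) {
        best <<- list(size = size, total = total)
      }
      return()
    }
    # bound: even matching every remaining feasible row cannot beat best
    if (size + sum(feas_per_row[i:nA] > 0) < best$size) return()
    for (j in which(!used & is.finite(D[i, ]))) {
      used[j] <<- TRUE
      rec(i + 1L, size + 1L, total + D[i, j])
      used[j] <<- FALSE
    }
    rec(i + 1L, size, total)
  }
  rec(1L, 0L, 0)
  best
}

# element-coloured graph isomorphism via igraph VF2
graphs_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  g1 <- igraph::graph_from_data_frame(a$bonds[, 1:2], FALSE,
                                      data.frame(name = seq_len(n_atoms(a))))
  g2 <- igraph::graph_from_data_frame(b$bonds[, 1:2], FALSE,
                                      data.frame(name = seq_len(n_atoms(b))))
  lv <- unique(c(a$element, b$element))
  igraph::isomorphic(g1, g2, method = "vf2",
                     vertex.color1 = as.integer(factor(a$element, lv)),
                     vertex.color2 = as.integer(factor(b$element, lv)))
}

# coordinates as an order-independent sorted set (for bit-equality checks
# across atom reordering)
coord_set <- function(m) {
  x <- m$xyz
  x[order(x[, 1], x[, 2], x[, 3]), , drop = FALSE]
}

all_novel <- function(m) {
  stitched_conformer(m, replicate(n_atoms(m), list(kind = "novel-unmapped"),
                                  simplify = FALSE))
}

all_from_hit <- function(m, hit_id) {
  stitched_conformer(m, lapply(seq_len(n_atoms(m)), function(i)
    list(kind = "hit", hit_id = hit_id, hit_atom = i)))
}

# tiny 3-residue PDB text for reader tests
toy_pdb_lines <- function() {
  p <- make_toy_pocket(n_residues = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(p, f)
  readLines(f)
}
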