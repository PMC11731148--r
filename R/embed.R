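# A small deterministic distance-geometry embedder.  Placement only needs a
# "generated conformer" for patches of novel atoms, which is then rigidly
# superposed onto three mapped anchor atoms; local bond lengths and angles
# matter, global conformational sampling does not.  Target distances come
# from covalent radii (bonds), ideal angles (1-3 pairs) and regular-polygon
# geometry inside rings; all other pairs carry a lower bound.  Coordinates
# are seeded from a fixed RNG stream and refined by gradient descent on the
# distance-error objective.

.bond_length <- function(el_i, el_j, order) {
  r <- (element_property(.covalent_radius, el_i, 0.76) +
          element_property(.covalent_radius, el_j, 0.76))
  scale <- if (order >= 3) 0.78 else if (order >= 2) 0.87 else
    if (order == 1.5) 0.93 else 1.0
  r * scale
}

# hybridisation-ish ideal angle at a centre atom (radians)
.ideal_angle <- function(m, centre) {
  k <- which(m$bonds$i == centre | m$bonds$j == centre)
  orders <- m$bonds$order[k]
  if (any(orders >= 3)) return(pi)
  if (m$aromatic[centre] || any(orders >= 1.5)) return(120 * pi / 180)
  109.47 * pi / 180
}

#' Generate an approximate 3D conformer for a molecular topology
#'
#' @param m a `positioned_mol` (coordinates ignored).
#' @param seed integer seed; identical seeds give identical conformers.
#' @param n_tries conformers generated; the lowest-error one is returned.
#' @return a `positioned_mol` with embedded coordinates.
#' @export
embed_conformer <- function(m, seed = 1L, n_tries = 1L) {
  n <- n_atoms(m)
  if (n == 0) return(m)
  if (n == 1) { m$xyz <- matrix(0, 1, 3); return(m) }
  targets <- .embed_targets(m)
  best <- NULL; best_val <- Inf
  for (t in seq_len(n_tries)) {
    set.seed(seed + 7919L * (t - 1L))
    x0 <- stats::rnorm(3 * n, sd = 0.8 * sqrt(n))
    opt <- stats::optim(x0, fn = .embed_obj, gr = .embed_grad,
                        targets = targets, n = n, method = "L-BFGS-B",
                        control = list(maxit = 400))
    if (opt$value < best_val) { best_val <- opt$value; best <- opt$par }
  }
  m$xyz <- matrix(best, ncol = 3, byrow = FALSE)
  m
}

.embed_targets <- function(m) {
  n <- n_atoms(m)
  pairs <- list()
  add <- function(i, j, d, w, lower = FALSE)
    pairs[[length(pairs) + 1L]] <<- c(i, j, d, w, as.numeric(lower))
  adj <- neighbours(m)
  blen <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[k]; j <- m$bonds$j[k]
    d <- .bond_length(m$element[i], m$element[j], m$bonds$order[k])
    blen[i, j] <- blen[j, i] <- d
    add(i, j, d, 10)
  }
  # 1-3 distances via the ideal angle at the centre
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2) next
    th <- .ideal_angle(m, c0)
    cmb <- utils::combn(nb, 2)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1, q]; j <- cmb[2, q]
      d <- sqrt(blen[i, c0]^2 + blen[j, c0]^2 -
                  2 * blen[i, c0] * blen[j, c0] * cos(th))
      add(i, j, d, 4)
    }
  }
  # ring planarity: full intra-ring distance matrix from a regular polygon
  for (ring in sssr(m)) {
    nr <- length(ring)
    side <- mean(vapply(seq_len(nr), function(q)
      blen[ring[q], ring[q %% nr + 1L]], numeric(1)), na.rm = TRUE)
    R <- side / (2 * sin(pi / nr))
    for (p in seq_len(nr - 1)) for (q in (p + 1):nr) {
      sep <- min(abs(p - q), nr - abs(p - q))
      if (sep <= 1) next
      d <- 2 * R * sin(pi * sep / nr)
      add(ring[p], ring[q], d, 4)
    }
  }
  have <- vapply(pairs, function(p) paste(min(p[1], p[2]), max(p[1], p[2])),
                 character(1))
  # everything else: lower bound to avoid collapse
  if (n > 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!paste(i, j) %in% have) add(i, j, 2.6, 0.4, lower = TRUE)
    }
  }
  do.call(rbind, pairs)
}

.embed_obj <- function(x, targets, n) {
  X <- matrix(x, ncol = 3)
  dv <- X[targets[, 1], , drop = FALSE] - X[targets[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  err <- d - targets[, 3]
  lower <- targets[, 5] > 0
  err[lower & err > 0] <- 0
  sum(targets[, 4] * err^2)
}

.embed_grad <- function(x, targets, n) {
  X <- matrix(x, ncol = 3)
  G <- matrix(0, n, 3)
  dv <- X[targets[, 1], , drop = FALSE] - X[targets[, 2], , drop = FALSE]
  d <- pmax(sqrt(rowSums(dv^2)), 1e-8)
  err <- d - targets[, 3]
  lower <- targets[, 5] > 0
  err[lower & err > 0] <- 0
  coef <- 2 * targets[, 4] * err / d
  for (k in seq_len(nrow(targets))) {
    if (coef[k] == 0) next
    g <- coef[k] * dv[k, ]
    i <- targets[k, 1]; j <- targets[k, 2]
    G[i, ] <- G[i, ] + g
    G[j, ] <- G[j, ] - g
  }
  as.numeric(G)
}
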