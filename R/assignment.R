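# Minimum-cost bipartite assignment (Jonker-Volgenant style shortest
# augmenting paths, O(n^2 m)).  Used for the positional atom overlap map:
# infeasible pairs (beyond the distance threshold) carry a large constant
# cost, so minimising total cost first maximises the number of feasible
# matches and then minimises their total distance.

# cost: n x m numeric matrix with n <= m; returns integer vector `col[i]` =
# column assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)          # row potentials (index r+1)
  v <- numeric(m + 1L)          # column potentials (index c+1; 1 = virtual col 0)
  p <- integer(m + 1L)          # p[c+1] = row assigned to column c (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  col_of_row <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) col_of_row[p[j + 1L]] <- j
  col_of_row
}

# Kabsch superposition: rotation + translation of `mobile` (k x 3) onto
# `target` (k x 3), both as matrices of matched points.  Returns a function
# applying the transform to any n x 3 matrix, plus the fit RMSD.
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target), nrow(mobile) >= 1)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- sweep(A %*% t(R), 2, ct, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(transform = function(x) sweep(sweep(x, 2, cm) %*% t(R), 2, ct, "+"),
       rmsd = rmsd, rotation = R)
}
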