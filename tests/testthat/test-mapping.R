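# Atom correspondences: positional assignment and the MCS cascade.

test_that("positional map of a molecule onto itself is the identity", {
  m <- make_toluene()
  mp <- positional_atom_map(m, m, 2.0)
  expect_identical(mp$score, n_atoms(m))
  expect_identical(mp$pairs[, 1], mp$pairs[, 2])
})

test_that("infeasible third pairing is dropped; threshold is a hard 2 A", {
  A <- positioned_mol(rep("C", 3),
                      rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  B <- positioned_mol(rep("C", 3),
                      rbind(c(0.5, 0, 0), c(3.5, 0, 0), c(8.5, 0, 0)))
  mp <- positional_atom_map(A, B, 2.0)
  expect_identical(mp$score, 2L)
  expect_equal(sum(vapply(seq_len(2), function(r)
    sqrt(sum((A$xyz[mp$pairs[r, 1], ] - B$xyz[mp$pairs[r, 2], ])^2)),
    numeric(1))), 1.0)
  # exactly 2.1 A apart with the default 2 A threshold: unmapped
  a1 <- positioned_mol("C", matrix(c(0, 0, 0), 1))
  b1 <- positioned_mol("C", matrix(c(2.1, 0, 0), 1))
  expect_identical(positional_atom_map(a1, b1, 2.0)$score, 0L)
  expect_identical(positional_atom_map(a1, positioned_mol("C", matrix(c(2, 0, 0), 1)), 2.0)$score, 1L)
})

test_that("positional map equals the brute-force assignment oracle", {
  set.seed(404)
  for (t in 1:120) {
    nA <- sample(1:8, 1); nB <- sample(1:8, 1)
    A <- matrix(runif(3 * nA, 0, 6), nA, 3)
    B <- matrix(runif(3 * nB, 0, 6), nB, 3)
    ma <- positioned_mol(rep("C", nA), A)
    mb <- positioned_mol(rep("C", nB), B)
    mp <- positional_atom_map(ma, mb, 2.0)
    oracle <- brute_force_positional(A, B, 2.0)
    expect_identical(mp$score, oracle$size)
    total <- if (mp$score) sum(vapply(seq_len(mp$score), function(r)
      sqrt(sum((A[mp$pairs[r, 1], ] - B[mp$pairs[r, 2], ])^2)), numeric(1))) else 0
    expect_equal(total, oracle$total, tolerance = 1e-9)
  }
})

test_that("candidate identical to a single hit maps completely", {
  hit <- fragment_hit(make_toluene(), "tol")
  maps <- mcs_cascade_map(parse_smiles("Cc1ccccc1"), list(hit), fs_config())
  expect_length(maps, 1)
  expect_identical(maps[["tol"]]$score, 7L)
  expect_identical(attr(maps, "primary"), "tol")
})

test_that("4-methylphenol maps onto superposed toluene + phenol hits", {
  hits <- make_overlap_pair()
  cand <- parse_smiles("Cc1ccc(O)cc1")
  maps <- mcs_cascade_map(cand, hits, fs_config())
  expect_setequal(names(maps), c("toluene", "phenol"))
  # methyl (atom 1) comes from toluene, hydroxyl O from phenol
  expect_true(1 %in% maps[["toluene"]]$pairs[, 1])
  o_idx <- which(cand$element == "O")
  expect_true(o_idx %in% maps[["phenol"]]$pairs[, 1])
  # union covers all candidate heavy atoms; ring owned by the primary
  union_cov <- unique(unlist(lapply(maps, function(m) m$pairs[, 1])))
  expect_setequal(union_cov, seq_len(n_atoms(cand)))
  expect_identical(attr(maps, "primary"), "toluene")
})

test_that("a blocking hydroxyl is excluded from the mapping automatically", {
  # hit 1: phenol whose OH occupies the space where hit 2 has a carbonyl
  # carbon; the candidate carries hit 2's amide, so the OH must stay unmapped
  hits <- make_overlap_pair()
  ph <- hits[[2]]$mol
  amide <- positioned_mol(
    c(ph$element[1:6], "C", "O", "N"),
    rbind(ph$xyz[1:6, ], ph$xyz[7, ],
          ph$xyz[7, ] + c(-0.6, 1.05, 0), ph$xyz[7, ] + c(-1.15, -0.8, 0.2)),
    rbind(ph$bonds[ph$bonds$j != 7, ],
          data.frame(i = c(4, 7, 7), j = c(7, 8, 9), order = c(1, 2, 1))),
    aromatic = c(ph$aromatic[1:6], FALSE, FALSE, FALSE), name = "amide_hit")
  h <- list(fragment_hit(amide, "amide"), hits[[2]])
  cand <- parse_smiles("NC(=O)c1ccccc1")
  maps <- mcs_cascade_map(cand, h, fs_config())
  expect_identical(attr(maps, "primary"), "amide")
  if ("phenol" %in% names(maps)) {
    oh <- which(h[[2]]$mol$element == "O")
    expect_false(oh %in% maps[["phenol"]]$pairs[, 2])
  }
  # the amide group is fully mapped despite the overlapping hydroxyl
  expect_identical(maps[["amide"]]$score, 9L)
})

test_that("user map overrides force an N/S swap verbatim", {
  # aminothiazole-like ring; swapping S and N is a valid alternative reading
  th <- 2 * pi * (0:4) / 5
  ring <- cbind(1.2 * cos(th), 1.2 * sin(th), 0)
  hit_mol <- positioned_mol(c("S", "C", "N", "C", "C", "N"),
                            rbind(ring, ring[2, ] * 2.1),
                            data.frame(i = c(1:5, 2), j = c(2:5, 1, 6),
                                       order = c(1.5, 1.5, 1.5, 1.5, 1.5, 1)),
                            aromatic = c(rep(TRUE, 5), FALSE),
                            name = "aminothiazole")
  hit <- fragment_hit(hit_mol, "amth")
  cand <- hit_mol
  auto <- mcs_cascade_map(cand, list(hit), fs_config())
  expect_true(all(auto[["amth"]]$pairs[, 1] == auto[["amth"]]$pairs[, 2]))
  forced <- list(amth = rbind(c(1, 3), c(3, 1)))   # S<->N swap, 1-based
  maps <- mcs_cascade_map(cand, list(hit), fs_config(), user_map = forced)
  mp <- maps[["amth"]]$pairs
  expect_identical(unname(mp[mp[, 1] == 1, 2]), 3L)
  expect_identical(unname(mp[mp[, 1] == 3, 2]), 1L)
})

test_that("user map JSON round-trips as documented (0-based indices)", {
  f <- tempfile(fileext = ".json")
  writeLines('{"hit1": [[0, 2], [2, 0]]}', f)
  um <- read_user_map(f)
  expect_identical(um$hit1, matrix(c(1L, 3L, 3L, 1L), 2, 2))
})

test_that("cascade maps respect candidate size, overlap agreement, determinism", {
  hits <- make_overlap_pair()
  cand <- parse_smiles("Cc1ccc(O)cc1")
  cfg <- fs_config()
  m1 <- mcs_cascade_map(cand, hits, cfg)
  m2 <- mcs_cascade_map(cand, hits, cfg)
  expect_identical(m1, m2)
  for (mm in m1) expect_lte(mm$score, n_atoms(cand))
  # wherever hit atoms positionally overlap, the maps agree
  ov <- overlap_map_ring_aware(hits[[1]]$mol, hits[[2]]$mol, cfg$map_threshold)
  for (r in seq_len(nrow(ov$pairs))) {
    c1 <- m1[["toluene"]]$pairs[match(ov$pairs[r, 1],
                                      m1[["toluene"]]$pairs[, 2]), 1]
    c2 <- m1[["phenol"]]$pairs[match(ov$pairs[r, 2],
                                     m1[["phenol"]]$pairs[, 2]), 1]
    if (!is.na(c1) && !is.na(c2)) expect_identical(c1, c2)
  }
})

test_that("no common substructure raises a typed MappingFailure", {
  hit <- fragment_hit(make_benzene(), "bz")
  expect_error(mcs_cascade_map(parse_smiles("P"), list(hit), fs_config()),
               class = "MappingFailure")
})
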