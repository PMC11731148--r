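# Interaction profiling, conservation counting, ranking, acceptability,
# efficiency metrics.

# a one-atom "protein" row helper
prot_row <- function(name, resname, xyz, element, resid = 1L, chain = "A") {
  structure(data.frame(serial = 1L, name = name, resname = resname,
                       chain = chain, resid = resid, x = xyz[1], y = xyz[2],
                       z = xyz[3], occupancy = 1, element = element,
                       stringsAsFactors = FALSE),
            class = c("protein_model", "data.frame"))
}

test_that("a distant ligand has an empty profile", {
  tol <- make_toluene()
  tol$xyz <- sweep(tol$xyz, 2, c(15, 0, 0), "+")
  pr <- detect_interactions(make_toy_pocket(), tol)
  expect_identical(nrow(pr), 0L)
})

test_that("a constructed N-H...O=C geometry yields one hydrogen bond", {
  # explicit donor geometry: N-H aimed straight at the acceptor O at 2.9 A
  # (D-H-A = 180 deg, within the >= 120 deg criterion)
  lig <- positioned_mol(c("N", "C", "H", "H"),
                        rbind(c(0, 0, 0), c(-1.47, 0, 0),
                              c(1.02, 0, 0), c(-0.3, 0.97, 0)),
                        data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 1))
  prot <- prot_row("O", "GLY", c(2.9, 0, 0), "O")
  pr <- detect_interactions(prot, lig)
  hb <- pr[pr$type == "hbond", ]
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$lig_atom, 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  # beyond the 3.5 A cutoff: nothing
  prot_far <- prot_row("O", "GLY", c(3.6, 0, 0), "O")
  expect_identical(nrow(detect_interactions(prot_far, lig)), 0L)
  # H pointing away fails the 120 deg angle criterion
  lig_away <- lig
  lig_away$xyz[3, ] <- c(-0.3, -0.97, 0)
  lig_away$xyz[4, ] <- c(-0.3, 0, 0.97)
  expect_identical(nrow(detect_interactions(prot, lig_away)), 0L)
})

test_that("two parallel offset benzenes stack", {
  lig <- make_benzene()
  ring <- make_benzene(centre = c(1, 0, 3.67))  # centroid distance ~3.8
  prot <- do.call(rbind, lapply(1:6, function(i)
    prot_row(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")[i], "PHE",
             ring$xyz[i, ], "C")))
  class(prot) <- c("protein_model", "data.frame")
  pr <- detect_interactions(prot, lig)
  expect_identical(sum(pr$type == "pi_stack"), 1L)
  d <- pr$distance[pr$type == "pi_stack"]
  expect_equal(d, sqrt(1 + 3.67^2), tolerance = 1e-6)
})

test_that("the profile is invariant under rigid rotation of the complex", {
  pocket <- make_toy_pocket()
  tol <- make_toluene()
  p1 <- detect_interactions(pocket, tol)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tol2 <- tol; tol2$xyz <- tol$xyz %*% R
  pocket2 <- pocket
  pc <- as.matrix(pocket[, c("x", "y", "z")]) %*% R
  pocket2$x <- pc[, 1]; pocket2$y <- pc[, 2]; pocket2$z <- pc[, 3]
  p2 <- detect_interactions(pocket2, tol2)
  k1 <- sort(paste(p1$type, p1$lig_atom, p1$residue))
  k2 <- sort(paste(p2$type, p2$lig_atom, p2$residue))
  expect_identical(k1, k2)
})

test_that("conserved/lost counting uses set semantics over (type, residue)", {
  mk <- function(df) structure(df, class = c("interaction_profile", "data.frame"))
  hits <- list(mk(data.frame(type = c("hbond", "pi_stack"), lig_atom = 1:2,
                             residue = c("A:12", "A:41"), distance = 3)),
               mk(data.frame(type = "hbond", lig_atom = 5L,
                             residue = "A:12", distance = 3.2)))
  lig <- mk(data.frame(type = "hbond", lig_atom = 9L, residue = "A:12",
                       distance = 2.9))
  cc <- count_conserved(lig, hits)
  expect_identical(cc$conserved, 1L)   # duplicates across hits count once
  expect_identical(cc$lost, 1L)
  full <- mk(data.frame(type = c("hbond", "pi_stack"), lig_atom = 1:2,
                        residue = c("A:12", "A:41"), distance = 3))
  expect_identical(count_conserved(full, hits)$lost, 0L)
})

test_that("rank_score is the documented affine form, lower is better", {
  hits <- list(fragment_hit(make_toluene(), "toluene"))
  s <- combine_hits(hits, fs_config())
  r <- build_restraints(s, fs_config())
  p <- pocket_min_cycles(s, r, make_toy_pocket(), fs_config(), hits = hits)
  prof <- detect_interactions(make_toy_pocket(), p$mol)
  w0 <- default_rank_weights(); w0[] <- 0
  expect_equal(as.numeric(rank_score(p, prof, hits, w0)), 0)
  # adding a novel atom strictly increases the score
  s1 <- rank_score(p, prof, hits, default_rank_weights())
  p2 <- p; p2$n_novel_atoms <- p$n_novel_atoms + 1L
  s2 <- rank_score(p2, prof, hits, default_rank_weights())
  expect_gt(as.numeric(s2), as.numeric(s1))
  # affine in each term: finite differences are constant
  set.seed(31)
  for (t in 1:5) {
    w <- default_rank_weights(); w[] <- runif(6, 0, 2)
    base <- as.numeric(rank_score(p, prof, hits, w))
    pa <- p; pa$n_novel_atoms <- pa$n_novel_atoms + 1L
    pb <- p; pb$n_novel_atoms <- pb$n_novel_atoms + 2L
    d1 <- as.numeric(rank_score(pa, prof, hits, w)) - base
    d2 <- as.numeric(rank_score(pb, prof, hits, w)) -
      as.numeric(rank_score(pa, prof, hits, w))
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_equal(d1, unname(w["w_novel_atoms"]), tolerance = 1e-12)
  }
  # an otherwise identical placement conserving one more hbond ranks first
  cons_a <- list(conserved = 2, lost = 0)
  cons_b <- list(conserved = 1, lost = 1)
  sa <- rank_score(p, prof, hits, default_rank_weights(), conserved = cons_a)
  sb <- rank_score(p, prof, hits, default_rank_weights(), conserved = cons_b)
  expect_lt(as.numeric(sa), as.numeric(sb))
})

test_that("acceptability is a pure function of its four criteria", {
  hits <- make_overlap_pair()
  base <- list(mol = parse_smiles("Cc1ccc(O)cc1C"),
               hits_used = c("toluene", "phenol"),
               rmsd_vs_hits = 0.4, dG_bind = -2)
  class(base) <- "minimized_placement"
  expect_true(acceptability(base, hits)$acceptable)
  p <- base; p$rmsd_vs_hits <- 1.2; p$dG_bind <- -3
  a <- acceptability(p, hits)
  expect_false(a$acceptable); expect_identical(a$reason, "strain/deviation")
  p <- base; p$dG_bind <- 0.5
  expect_identical(acceptability(p, hits)$reason, "strain/deviation")
  p <- base; p$hits_used <- "toluene"
  expect_identical(acceptability(p, hits)$reason, "hit unused")
  # merger no larger than the biggest hit: "equal size"
  p <- base; p$mol <- parse_smiles("Cc1ccccc1")
  expect_identical(acceptability(p, hits)$reason, "equal size")
})

test_that("efficiency metrics are plain arithmetic with a sign flag", {
  p <- list(mol = embed_conformer(random_drug_like(1), seed = 1),
            dG_bind = -8)
  class(p) <- "minimized_placement"
  # force a 40-heavy-atom denominator via a fake profile of 5 contacts
  p$mol$element <- rep("C", n_atoms(p$mol))
  h <- hac(p$mol)
  prof <- data.frame(type = rep("hbond", 5), lig_atom = 1:5,
                     residue = paste0("A:", 1:5), distance = 3)
  em <- efficiency_metrics(p, prof)
  expect_equal(em$LE, 8 / h)
  expect_equal(em$interactions_per_HAC, 5 / h)
  expect_false(em$flagged)
  p$dG_bind <- 2
  expect_true(efficiency_metrics(p, prof)$flagged)
  p$mol$element[] <- "H"
  expect_error(efficiency_metrics(p, prof), "zero")
})
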