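# Restraint construction and the two-stage constrained minimisation.

test_that("all-novel molecules carry zero restraint weight", {
  m <- embed_conformer(parse_smiles("CCO"), seed = 1)
  r <- build_restraints(all_novel(m))
  expect_identical(r$weight, rep(0, 3))
})

test_that("restraint tiers: ring moderate, exocyclic heavy, amide free", {
  m <- embed_conformer(parse_smiles("CNC(=O)c1ccccc1"), seed = 2)
  cfg <- fs_config()
  r <- build_restraints(all_from_hit(m, "h"), cfg)
  ring <- atoms_in_rings(m)
  # ring atoms moderate
  expect_true(all(r$weight[ring] == cfg$restraint_moderate))
  # amide N, carbonyl C and O unrestrained
  amide_atoms <- c(which(m$element == "N"), which(m$element == "O"),
                   3L)  # the carbonyl carbon in this SMILES
  expect_true(all(r$weight[amide_atoms] == 0))
  # the exocyclic N-methyl is heavily restrained
  expect_identical(r$weight[1], cfg$restraint_heavy)
  # one exocyclic secondary amide torsion registered
  expect_identical(nrow(r$torsions), 1L)
})

test_that("a cis secondary amide relaxes to within 30 degrees of trans", {
  m <- embed_conformer(parse_smiles("CNC(=O)C"), seed = 3)
  r <- build_restraints(all_novel(m))
  expect_identical(nrow(r$torsions), 1L)
  ids <- r$torsions[1, ]
  # force the cis form, then pre-minimise restraint-free
  phi0 <- fragstitch:::.dihedral(m$xyz[ids[1], ], m$xyz[ids[2], ],
                                 m$xyz[ids[3], ], m$xyz[ids[4], ])
  out <- premin_frozen_neighbourhood(all_novel(m), r)
  phi <- fragstitch:::.dihedral(out$xyz[ids[1], ], out$xyz[ids[2], ],
                                out$xyz[ids[3], ], out$xyz[ids[4], ])
  expect_lt(abs(abs(phi) * 180 / pi - 180), 30)
})

test_that("premin: minimal ethane stays put; displaced benzene replanarises", {
  eth <- positioned_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.52, 0, 0)),
                        data.frame(i = 1, j = 2, order = 1))
  out <- premin_frozen_neighbourhood(all_novel(eth), build_restraints(all_novel(eth)))
  expect_lt(max(sqrt(rowSums((out$xyz - eth$xyz)^2))), 0.05)

  b <- make_benzene(); b$xyz[1, 3] <- 0.4
  s <- all_novel(b)
  out2 <- premin_frozen_neighbourhood(s, build_restraints(s))
  P <- sweep(out2$xyz, 2, colMeans(out2$xyz))
  sv <- svd(P)
  expect_lt(sqrt(sum((P %*% sv$v[, 3])^2) / 6), 0.1)  # out-of-plane rms
})

test_that("heavily restrained atoms never drift beyond 0.5 A", {
  cfg <- fs_config()
  for (s in 1:12) {
    m <- random_drug_like(500 + s)
    st <- all_from_hit(m, "h")
    r <- build_restraints(st, cfg)
    out <- premin_frozen_neighbourhood(st, r)
    heavy_idx <- which(r$weight == cfg$restraint_heavy)
    if (length(heavy_idx)) {
      drift <- sqrt(rowSums((out$xyz[heavy_idx, , drop = FALSE] -
                               m$xyz[heavy_idx, , drop = FALSE])^2))
      expect_lt(max(drift), 0.5)
    }
  }
})

test_that("restraint scale -> infinity reproduces the stitched conformer", {
  hits <- list(fragment_hit(make_toluene(), "toluene"))
  s <- combine_hits(hits, fs_config())
  r <- build_restraints(s, fs_config())
  out <- premin_frozen_neighbourhood(s, r, make_toy_pocket(),
                                     restraint_scale = 1e6)
  expect_lt(rmsd_inplace(out, s$mol), 0.05)
})

test_that("pocket cycles: immediate convergence stops after one cycle", {
  hits <- list(fragment_hit(make_toluene(), "toluene"))
  s <- combine_hits(hits, fs_config())
  r <- build_restraints(s, fs_config())
  p <- pocket_min_cycles(s, r, make_toy_pocket(), fs_config(), hits = hits)
  expect_identical(p$cycles, 1L)
  expect_lt(p$dG_bind, 0)
  expect_identical(p$restraint_scales, 1)
})

test_that("halving schedule is exactly geometric and stops at dG < 0", {
  # deliberate ~1.5 A clash: stitch one ring atom into the pocket wall
  pocket <- make_toy_pocket()
  wall <- as.numeric(pocket[1, c("x", "y", "z")])
  dirw <- wall / sqrt(sum(wall^2))
  tol <- make_toluene()
  tol$xyz <- sweep(tol$xyz, 2, (wall - 1.5 * dirw) - tol$xyz[1, ], "+")
  s <- all_from_hit(tol, "wall")
  cfg <- fs_config(restraint_heavy = 100, restraint_moderate = 50)
  r <- build_restraints(s, cfg)
  p <- pocket_min_cycles(s, r, pocket, cfg,
                         hits = list(fragment_hit(tol, "wall")))
  expect_gte(p$cycles, 2L)
  expect_equal(p$restraint_scales, 2^(-(seq_len(p$cycles) - 1L)))
  expect_lt(p$dG_bind, 0)   # clash resolved once the weights have halved
  # non-convergence (dG can never go negative without protein contact) is
  # reported, never raised
  cfg2 <- fs_config(max_min_cycles = 3L)
  p2 <- pocket_min_cycles(s, build_restraints(s, cfg2), NULL, cfg2,
                          hits = list(fragment_hit(tol, "wall")))
  expect_identical(p2$cycles, 3L)
  expect_equal(p2$restraint_scales, c(1, 0.5, 0.25))
  expect_false(p2$acceptable)
})

test_that("delta_g is plain arithmetic and engine-checked", {
  e1 <- structure(-10, engine = "fs_lj_harmonic")
  e2 <- structure(-4, engine = "fs_lj_harmonic")
  expect_equal(delta_g(e1, e2), -6)
  expect_equal(delta_g(e2, e2), 0)
  expect_error(delta_g(e1, structure(-4, engine = "other")), "engines")
})

test_that("a ligand far outside the pocket has near-zero binding energy", {
  tol <- make_toluene()
  tol$xyz <- sweep(tol$xyz, 2, c(40, 0, 0), "+")
  s <- all_from_hit(tol, "far")
  r <- build_restraints(s, fs_config())
  p <- pocket_min_cycles(s, r, make_toy_pocket(),
                         fs_config(max_min_cycles = 2L),
                         hits = list(fragment_hit(tol, "far")))
  expect_lt(abs(p$dG_bind), 1e-6)
})

test_that("minimisation conserves chemistry and excludes restraint energy", {
  hits <- list(fragment_hit(make_toluene(), "toluene"))
  s <- combine_hits(hits, fs_config())
  r <- build_restraints(s, fs_config())
  p <- pocket_min_cycles(s, r, make_toy_pocket(), fs_config(), hits = hits)
  expect_identical(p$mol$bonds, s$mol$bonds)
  expect_identical(p$mol$element, s$mol$element)
  # recompute the interaction energy restraint-free from scratch
  sys <- fragstitch:::.ff_system(p$mol, r, p$protein_final)
  coords <- rbind(p$mol$xyz, fragstitch:::protein_coords(p$protein_final))
  e <- fragstitch:::.ff_interaction(sys, coords)
  expect_equal(as.numeric(e), p$dG_bind, tolerance = 1e-6)
})
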