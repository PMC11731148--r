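# Core model and structure I/O.

test_that("positioned_mol enforces its invariants", {
  expect_error(positioned_mol("C", matrix(0, 2, 3)), "nrow")
  expect_error(positioned_mol(c("C", "C"), matrix(0, 2, 3),
                              data.frame(i = 1, j = 1, order = 1)),
               "self-bonds")
  expect_error(positioned_mol(c("C", "C"), matrix(0, 2, 3),
                              data.frame(i = c(1, 2), j = c(2, 1),
                                         order = c(1, 1))),
               "duplicate")
  expect_error(positioned_mol(c("C", "C"), matrix(0, 2, 3),
                              data.frame(i = 1, j = 3, order = 1)),
               "non-existent")
})

test_that("valence model accepts standard aromatics and flags overfull atoms", {
  expect_true(isTRUE(valence_legal(make_benzene())))
  expect_true(isTRUE(valence_legal(make_furan())))
  expect_identical(implicit_h(make_benzene()), rep(1L, 6))
  expect_identical(implicit_h(make_furan()), c(0L, rep(1L, 4)))
  pent <- positioned_mol(rep("C", 6), matrix(rnorm(18), 6, 3),
                         data.frame(i = rep(1, 5), j = 2:6, order = 1))
  v <- valence_legal(pent)
  expect_false(isTRUE(v))
  expect_identical(attr(v, "offenders"), 1L)
})

test_that("SDF read: records in file order, benzene identity, dummy atoms", {
  f <- tempfile(fileext = ".sdf")
  write_sdf(list(make_benzene(), make_furan()), f)
  hits <- read_hits(f)
  expect_length(hits, 2)
  expect_identical(hits[[1]]$hit_id, "benzene")
  expect_identical(hits[[2]]$hit_id, "furan")
  expect_length(heavy_atoms(hits[[1]]$mol), 6)
  # a record with a dummy atom bonded to a carbonyl carbon
  toy <- make_covalent_toy()
  f2 <- tempfile(fileext = ".sdf")
  write_sdf(toy$hit$mol, f2)
  h2 <- read_hits(f2)[[1]]
  expect_identical(h2$covalent_attachment_index,
                   which(h2$mol$element == "*"))
  expect_false(is.na(h2$covalent_attachment_index))
})

test_that("SDF read rejects malformed and coordinate-free records", {
  f <- tempfile(fileext = ".sdf")
  good <- readLines(textConnection(paste(
    fragstitch:::molblock_lines(make_benzene()), collapse = "\n")))
  bad <- c("flat", "  test", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0", "M  END")
  writeLines(c(good, "$$$$", bad, "$$$$"), f)
  expect_error(read_hits(f), "record 2")
})

test_that("SDF round-trip preserves atoms, bonds, coords and dummy atoms", {
  toy <- make_covalent_toy()
  m <- toy$hit$mol
  f <- tempfile(fileext = ".sdf")
  write_sdf(m, f)
  m2 <- read_hits(f)[[1]]$mol
  expect_identical(m2$element, m$element)
  expect_identical(m2$bonds$order, m$bonds$order)
  expect_lt(max(abs(m2$xyz - m$xyz)), 1e-3)
})

test_that("PDB read: residues parsed, altloc resolved by occupancy, errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  p <- read_template(f)
  expect_identical(n_residues(p), 3L)
  # altloc conflict: keep highest occupancy
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "END")
  f2 <- tempfile(fileext = ".pdb"); writeLines(lines, f2)
  expect_warning(p2 <- read_template(f2), "altloc")
  expect_identical(nrow(p2), 1L)
  expect_equal(p2$x, 1.0)  # the 0.70-occupancy conformer
  f3 <- tempfile(fileext = ".pdb"); writeLines("END", f3)
  expect_error(read_template(f3), "no ATOM")
})

test_that("write_result emits SDF + JSON sidecar that round-trips", {
  hits <- list(fragment_hit(make_toluene(), "toluene"))
  s <- combine_hits(hits, fs_config())
  r <- build_restraints(s, fs_config())
  p <- pocket_min_cycles(s, r, make_toy_pocket(), fs_config(), hits = hits)
  pre <- tempfile()
  out <- write_result(p, pre)
  side <- jsonlite::read_json(out$json)
  expect_true(all(c("dG_bind", "rmsd_vs_hits", "n_novel_atoms") %in%
                    names(side)))
  back <- read_hits(out$sdf)[[1]]$mol
  hv <- heavy_atoms(p$mol)
  expect_lt(max(abs(back$xyz - p$mol$xyz[hv, , drop = FALSE])), 1e-3)
})

test_that("covalent placements record the attachment residue in the sidecar", {
  toy <- make_covalent_toy()
  p <- place_candidate(toy$smiles, list(toy$hit), toy$protein, fs_config())
  pre <- tempfile()
  out <- write_result(p, pre)
  side <- jsonlite::read_json(out$json)
  expect_match(side$covalent_residue, "^A:")
})
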