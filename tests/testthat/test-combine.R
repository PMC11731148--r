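# Ring collapse/expansion, merging, linking, rectification, combination.

test_that("collapse: acyclic unchanged; benzene centroid; naphthalene shares", {
  propane <- positioned_mol(rep("C", 3),
                            rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.3, 1.3, 0)),
                            data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  cp <- collapse_rings(propane)
  expect_length(cp$stash, 0)
  expect_identical(cp$mol$xyz, propane$xyz)

  b <- make_benzene(centre = c(1, 2, 3))
  cb <- collapse_rings(b)
  expect_length(cb$stash, 1)
  ph <- which(cb$mol$element == "Rc")
  expect_equal(cb$mol$xyz[ph, ], colMeans(b$xyz), tolerance = 1e-12)

  # naphthalene: two placeholders sharing two stashed atoms
  r <- 1.39; th <- pi / 6 + 2 * pi * (0:5) / 6
  ring1 <- cbind(r * cos(th), r * sin(th), 0)
  ring2 <- cbind(2 * r * cos(pi / 6) - r * cos(th), r * sin(th), 0)
  xy <- round(rbind(ring1, ring2), 6)
  xyz <- xy[!duplicated(xy), ]
  bonds <- NULL
  for (i in 1:9) for (j in (i + 1):10) {
    if (abs(sqrt(sum((xyz[i, ] - xyz[j, ])^2)) - r) < 0.01)
      bonds <- rbind(bonds, data.frame(i = i, j = j, order = 1.5))
  }
  naph <- positioned_mol(rep("C", 10), xyz, bonds, aromatic = rep(TRUE, 10))
  cn <- collapse_rings(naph)
  expect_length(cn$stash, 2)
  shared <- intersect(cn$stash[[1]]$records[[1]]$atoms$key,
                      cn$stash[[2]]$records[[1]]$atoms$key)
  expect_length(shared, 2)
  back <- expand_rings(cn)
  expect_true(graphs_isomorphic(naph, back))
  expect_identical(coord_set(naph), coord_set(back))
})

test_that("collapse/expand round-trip is exact on seeded drug-like molecules", {
  for (s in c(3, 17, 42, 77, 91)) {
    m <- random_drug_like(s)
    e <- expand_rings(collapse_rings(m))
    expect_true(graphs_isomorphic(m, e), info = paste("seed", s))
    expect_identical(coord_set(m), coord_set(e), info = paste("seed", s))
  }
})

test_that("merge with an exact copy under the identity map is the identity", {
  a <- collapse_rings(make_toluene())
  mp <- positional_atom_map(a$mol, a$mol, 2)
  merged <- merge_pair(a, a, mp)
  expect_identical(n_atoms(merged$mol), n_atoms(a$mol))
  out <- expand_rings(merged)
  expect_true(graphs_isomorphic(out, make_toluene()))
})

test_that("fully overlapping benzenes collapse to a single ring", {
  h <- list(fragment_hit(make_benzene(), "b1"),
            fragment_hit(make_benzene(phase = 0.05), "b2"))
  s <- combine_hits(h, fs_config())
  expect_identical(n_atoms(s$mol), 6L)
  expect_length(sssr(s$mol), 1)
})

test_that("co-centred furan + benzene merge into one ring with one oxygen", {
  h <- list(fragment_hit(make_furan(phase = pi), "furan"),
            fragment_hit(make_benzene(), "benzene"))
  s <- combine_hits(h, fs_config())
  rings <- sssr(s$mol)
  expect_length(rings, 1)
  expect_identical(sum(s$mol$element == "O"), 1L)
  expect_true(isTRUE(valence_legal(s$mol)))
})

test_that("linking: connected input unchanged; 2.44 A gap gets one nitrogen", {
  eth <- positioned_mol(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                        data.frame(i = 1, j = 2, order = 1))
  s <- all_novel(eth)
  expect_identical(link_if_disconnected(s, fs_config())$mol$bonds,
                   s$mol$bonds)
  two <- all_novel(positioned_mol(c("C", "C"),
                                  rbind(c(0, 0, 0), c(2.44, 0, 0))))
  linked <- link_if_disconnected(two, fs_config())
  expect_identical(n_atoms(linked$mol), 3L)        # round(2.44/1.22) - 1 = 1
  expect_identical(linked$mol$element[3], "N")
  expect_identical(linked$provenance[[3]]$kind, "novel-linker")
  # first-atom override to oxygen (the sweep's variant)
  linked_o <- link_if_disconnected(two, fs_config(linker_first_element = "O"))
  expect_identical(linked_o$mol$element[3], "O")
})

test_that("overlapped perpendicular rings give a fused system, rectified", {
  bz <- make_benzene()
  th <- 2 * pi * (0:4) / 5
  cp <- positioned_mol(rep("C", 5),
                       cbind(1.3 + 1.31 * cos(th), 0, 1.31 * sin(th)),
                       data.frame(i = 1:5, j = c(2:5, 1), order = 1))
  s <- combine_hits(list(fragment_hit(bz, "bz"), fragment_hit(cp, "cp")),
                    fs_config())
  expect_gte(length(sssr(s$mol)), 2)
  expect_true(isTRUE(valence_legal(s$mol)))
})

test_that("rectify: valid molecules unchanged; Texas carbons lose longest bond", {
  asp <- embed_conformer(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"), seed = 11)
  r <- rectify(asp)
  expect_identical(r$bonds, asp$bonds)
  expect_identical(r$charge, asp$charge)

  pent <- positioned_mol(rep("C", 6),
                         rbind(c(0, 0, 0), c(1.54, 0, 0), c(-1.54, 0, 0),
                               c(0, 1.54, 0), c(0, -1.54, 0), c(0, 0, 1.9)),
                         data.frame(i = rep(1, 5), j = 2:6, order = 1))
  rp <- rectify(pent)
  expect_identical(sum(rp$bonds$i == 1 | rp$bonds$j == 1), 4L)
  expect_false(any((rp$bonds$i == 1 & rp$bonds$j == 6) |
                     (rp$bonds$i == 6 & rp$bonds$j == 1)))  # longest removed
})

test_that("rectify dearomatises geminal substituted arenes", {
  b <- make_benzene()
  gem <- positioned_mol(c(b$element, "C", "C"),
                        rbind(b$xyz, b$xyz[1, ] + c(1.2, 0.8, 0),
                              b$xyz[1, ] + c(1.2, -0.8, 0)),
                        rbind(b$bonds, data.frame(i = c(1, 1), j = c(7, 8),
                                                  order = 1)),
                        aromatic = c(b$aromatic, FALSE, FALSE))
  r <- rectify(gem)
  expect_false(any(r$aromatic))
  expect_false(any(r$bonds$order == 1.5))
  expect_true(isTRUE(valence_legal(r)))
})

test_that("rectifier fuzz: corrupted molecules end legal or fail loudly", {
  set.seed(99)
  for (t in 1:40) {
    m <- random_drug_like(1000 + t)
    # corruption: add a random extra bond (may create Texas carbons etc.)
    n <- n_atoms(m)
    repeat {
      ij <- sample(n, 2)
      if (!length(fragstitch:::bond_index(m, ij[1], ij[2]))) break
    }
    m$bonds <- rbind(m$bonds, data.frame(i = ij[1], j = ij[2],
                                         order = sample(1:2, 1)))
    out <- tryCatch(rectify(m), fs_failure = function(e) e)
    if (inherits(out, "fs_failure")) {
      expect_s3_class(out, "RectificationFailure")
    } else {
      expect_true(isTRUE(valence_legal(out)))
    }
  }
})

test_that("combine: single hit survives a collapse/expand round-trip", {
  tol <- fragment_hit(make_toluene(), "tol")
  s <- combine_hits(list(tol), fs_config())
  expect_true(graphs_isomorphic(s$mol, tol$mol))
  expect_identical(coord_set(s$mol), coord_set(tol$mol))
})

test_that("combine defers a distant hit and processes it after the bridge", {
  A <- fragment_hit(make_benzene(c(0, 0, 0)), "A")
  B <- fragment_hit(make_benzene(c(8.5, 0, 0)), "B")
  C <- fragment_hit(make_benzene(c(4.25, 0, 0)), "C")
  s <- combine_hits(list(A, B, C), fs_config())
  used <- unique(stats::na.omit(vapply(s$provenance, function(p)
    if (p$kind == "hit") p$hit_id else NA_character_, character(1))))
  expect_setequal(used, c("A", "B", "C"))
  expect_identical(length(unique(mol_components(s$mol))), 1L)
})

test_that("two hits beyond the 5 A cutoff raise DistanceFailure", {
  far <- list(fragment_hit(make_furan(), "furan"),
              fragment_hit(make_benzene(centre = c(9, 0, 0)), "benzene"))
  expect_error(combine_hits(far, fs_config()), class = "DistanceFailure")
})

test_that("atom conservation: every non-novel atom traces to one hit atom", {
  h <- make_overlap_pair()
  s <- combine_hits(h, fs_config())
  ids <- vapply(h, function(x) x$hit_id, character(1))
  for (i in seq_len(n_atoms(s$mol))) {
    p <- s$provenance[[i]]
    if (p$kind == "hit") {
      expect_true(p$hit_id %in% ids)
      hm <- h[[match(p$hit_id, ids)]]$mol
      expect_lte(p$hit_atom, n_atoms(hm))
    }
  }
})

test_that("combination output is always valence-legal or a typed failure", {
  set.seed(7)
  for (t in 1:10) {
    h <- list(fragment_hit(random_drug_like(2000 + t), "h1"),
              fragment_hit(random_drug_like(3000 + t), "h2"))
    out <- tryCatch(combine_hits(h, fs_config(join_cutoff = 50)),
                    fs_failure = function(e) e)
    if (inherits(out, "fs_failure")) {
      expect_true(inherits(out, "RectificationFailure") ||
                    inherits(out, "DistanceFailure") ||
                    inherits(out, "LinkFailure"))
    } else {
      expect_true(isTRUE(valence_legal(out$mol)))
    }
  }
})
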