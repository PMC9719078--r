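test_that("SDF reading perceives atoms, bonds and torsions", {
  m <- read_molecule(fixture_ethane_sdf())
  expect_equal(length(m$elem), 8)
  expect_equal(nrow(m$bonds), 7)
  expect_equal(sum(!m$is_h), 2)
  expect_equal(length(m$torsion_tree$torsions), 0)  # C-C is terminal-ish

  b <- read_molecule(fixture_benzene_sdf())
  expect_equal(length(b$rings), 1)
  expect_equal(sort(b$rings[[1]]), 1:6)
  expect_true(all(b$bonds$aromatic[b$bonds$in_ring]))
  expect_equal(sum(b$bonds$rotatable), 0)

  bu <- read_molecule(fixture_butane_sdf())
  tt <- bu$torsion_tree$torsions
  expect_equal(length(tt), 1)
  expect_setequal(c(tt[[1]]$a, tt[[1]]$b), c(2, 3))
})

test_that("torsion trees count internal single bonds correctly", {
  expect_equal(length(make_molecule("alkane", n = 6)$torsion_tree$torsions), 3)
  bip <- fixture_biphenyl()
  expect_equal(length(bip$torsion_tree$torsions), 1)
  tor <- bip$torsion_tree$torsions[[1]]
  expect_setequal(c(tor$a, tor$b), c(1, 10))
  # rotating a torsion changes geometry only across the rotated bond: the
  # internal distances within the unmoved side and within the moved side are
  # preserved, while cross distances change (poses live in a common frame up
  # to the rigid DOFs, so absolute positions are compared via distances)
  hx <- make_molecule("alkane", n = 6)
  dof <- encode(hx)
  d2 <- new_dof(dof$translation, dof$quaternion,
                dof$torsions + c(0.8, 0, 0), dof$ring_states)
  p2 <- realize(hx, d2)
  tor1 <- hx$torsion_tree$torsions[[1]]
  still <- setdiff(seq_len(6), tor1$moved)
  d_old <- as.matrix(stats::dist(hx$coords))
  d_new <- as.matrix(stats::dist(p2$coords))
  expect_lt(max(abs(d_new[still, still] - d_old[still, still])), 1e-9)
  expect_lt(max(abs(d_new[tor1$moved, tor1$moved] -
                    d_old[tor1$moved, tor1$moved])), 1e-9)
  expect_gt(max(abs(d_new[still, tor1$moved] - d_old[still, tor1$moved])),
            0.1)
})

test_that("disconnected molecules are rejected", {
  bonds <- data.frame(i = 1, j = 2, order = 1L)
  expect_error(new_molecule(c("C", "C", "C"),
                            matrix(c(0, 0, 0, 1.5, 0, 0, 9, 9, 9), 3, 3,
                                   byrow = TRUE), bonds),
               "connected")
})

test_that("2D inputs are rejected", {
  flat <- benzene_geometry(); flat[, 3] <- 0
  path <- write_sdf_fixture(rep("C", 6), flat,
                            data.frame(i = 1:6, j = c(2:6, 1),
                                       order = rep(c(2L, 1L), 3)),
                            tempfile(fileext = ".sdf"))
  expect_error(read_molecule(path), "2D")
})

test_that("Gasteiger charges sum to the formal charge with sane signs", {
  me <- read_molecule(fixture_methane_sdf())
  expect_lt(abs(sum(me$charge)), 1e-3)
  am <- read_molecule(fixture_ammonium_sdf())
  expect_lt(abs(sum(am$charge) - 1), 1e-3)
  et <- read_molecule(fixture_ethanol_sdf())
  o <- which(et$elem == "O")
  ho <- 4  # hydroxyl H in the fixture
  expect_lt(et$charge[o], 0)
  expect_gt(et$charge[ho], 0)
  expect_gt(et$charge[ho], max(et$charge[5:9]))  # more positive than C-H
})

test_that("SDF write/read round-trips structure and coordinates", {
  m <- make_molecule("druglike", seed = 42)
  path <- tempfile(fileext = ".sdf")
  write_molecule(m, path)
  m2 <- read_molecule(path)
  expect_equal(length(m2$elem), length(m$elem))
  expect_equal(m2$elem, m$elem)
  expect_equal(nrow(m2$bonds), nrow(m$bonds))
  expect_lt(max(abs(m2$coords - m$coords)), 1e-3)
})

test_that("MOL2 ligands are read with bonds and elements", {
  m <- make_molecule("alkane", n = 4)
  path <- tempfile(fileext = ".mol2")
  lines <- c("@<TRIPOS>MOLECULE", "butane",
             sprintf("%d %d 0 0 0", 4, 3), "SMALL", "GASTEIGER", "",
             "@<TRIPOS>ATOM")
  for (i in 1:4)
    lines <- c(lines, sprintf("%7d C%d %10.4f %10.4f %10.4f C.3 1 LIG %9.4f",
                              i, i, m$coords[i, 1], m$coords[i, 2],
                              m$coords[i, 3], 0))
  lines <- c(lines, "@<TRIPOS>BOND",
             sprintf("%6d %5d %5d %s", 1:3, 1:3, 2:4, "1"))
  writeLines(lines, path)
  m2 <- read_molecule(path)
  expect_equal(m2$elem, rep("C", 4))
  expect_equal(nrow(m2$bonds), 3)
  expect_lt(max(abs(m2$coords - m$coords)), 1e-3)
})

test_that("PDB receptors: residues, cofactors, altlocs", {
  p1 <- tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_lines(), p1)
  prot <- read_protein(p1)
  expect_s3_class(prot, "ProteinStructure")
  expect_equal(length(unique(prot$resno)), 3)
  expect_false(any(prot$is_cofactor))

  p2 <- tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_lines(with_het = TRUE), p2)
  prot2 <- read_protein(p2)
  expect_equal(sum(prot2$is_cofactor), 2)
  expect_equal(sum(read_protein(p2, reference_ligand_resid = "LIG")$is_cofactor), 0)

  p3 <- tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_lines(with_altloc = TRUE), p3)
  prot3 <- read_protein(p3)
  # two CB altlocs collapse to the higher-occupancy one (z = -0.4)
  cb <- which(abs(prot3$coords[, 1] - 8.6) < 0.05)
  expect_equal(length(cb), 1)
  expect_equal(prot3$coords[cb, 3], -0.4, tolerance = 1e-6)

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1        abc   0.000   0.000  1.00",
               "END"), bad)
  expect_error(read_protein(bad), "line 1")
})

test_that("symmetry RMSD equals the brute-force automorphism minimum", {
  b <- read_molecule(fixture_benzene_sdf())
  expect_equal(symmetry_rmsd(b, b$coords, b$coords)$rmsd, 0)
  # 60-degree rotation about the ring axis is a graph symmetry
  rot <- b$coords[c(2:6, 1), ]
  expect_lt(symmetry_rmsd(b, b$coords, rot)$rmsd, 1e-9)

  tol <- fixture_toluene()
  set.seed(11)
  flipped <- tol$coords[c(1, 6, 5, 4, 3, 2, 7), ]  # ring flip about C1-C4
  jitter <- tol$coords + matrix(rnorm(21, 0, 0.3), 7, 3)
  for (other in list(flipped, jitter)) {
    got <- symmetry_rmsd(tol, other, tol$coords)$rmsd
    perms <- brute_force_automorphisms(tol)
    want <- min(vapply(perms, function(p)
      sqrt(mean(rowSums((other[p, ] - tol$coords)^2))), 1.0))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("symmetry RMSD is a pseudo-metric bounded by the identity mapping", {
  for (s in 1:5) {
    m <- make_molecule("druglike", seed = s)
    set.seed(s)
    ca <- m$coords + matrix(rnorm(length(m$coords), 0, 0.5),
                            nrow(m$coords), 3)
    cb <- m$coords + matrix(rnorm(length(m$coords), 0, 0.5),
                            nrow(m$coords), 3)
    sym <- symmetry_rmsd(m, ca, cb)$rmsd
    hv <- which(!m$is_h)
    ident <- sqrt(mean(rowSums((ca[hv, ] - cb[hv, ])^2)))
    expect_lte(sym, ident + 1e-12)
    expect_equal(sym, symmetry_rmsd(m, cb, ca)$rmsd, tolerance = 1e-9)
    expect_equal(symmetry_rmsd(m, ca, ca)$rmsd, 0)
  }
})
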