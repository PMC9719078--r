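test_that("ring clustering cutoff follows the size formula", {
  expect_equal(ring_cluster_cutoff(7), 0.3)
  expect_equal(ring_cluster_cutoff(3), 0.3 * sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ring_cluster_cutoff(6), 0.3 * sqrt(5 / 6), tolerance = 1e-12)
  expect_error(ring_cluster_cutoff(2), "input error")
})

test_that("ring library: cyclohexane is flexible, small/aromatic rings rigid", {
  sat6 <- list(elem = rep("C", 6), hyb = rep(3L, 6))
  sat3 <- list(elem = rep("C", 3), hyb = rep(3L, 3))
  ar6 <- list(elem = rep("C", 6), hyb = rep(2L, 6))
  lib <- build_ring_library(list(sat6, sat3, ar6), n_embed = 120, seed = 99)
  e6 <- lib$topologies[[csalign:::topo_key(sat6)]]
  e3 <- lib$topologies[[csalign:::topo_key(sat3)]]
  ea <- lib$topologies[[csalign:::topo_key(ar6)]]
  expect_gte(length(e6$templates), 2)   # chair family + twist-boat family
  expect_equal(length(e3$templates), 1) # 3-ring is rigid
  expect_equal(length(ea$templates), 1) # aromatic ring is planar
  # planarity of the aromatic template
  tmpl <- ea$templates[[1]]
  sv <- svd(sweep(tmpl, 2, colMeans(tmpl)))$d
  expect_lt(sv[3], 0.05)
  # the chair template is the energy reference (strain 0) and lower than twist
  expect_equal(e6$energies[1], 0)
  expect_gt(e6$energies[2], 0.5)
  # library invariant: all template pairs at least cutoff(n) apart
  for (entry in lib$topologies) {
    maps <- csalign:::ring_symmetry_mappings(entry$labels)
    k <- length(entry$templates)
    if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
      expect_gte(csalign:::ring_rmsd_sym(entry$templates[[a]],
                                         entry$templates[[b]], maps),
                 entry$cutoff)
    }
  }
})

test_that("Boltzmann ring-state sampling follows the strain energies", {
  lib <- structure(list(topologies = list(one = list(
    templates = list(diag(3)), energies = 0, cutoff = 0.27,
    labels = rep("C3", 3)))), class = "RingConformerLibrary")
  expect_true(all(replicate(20, sample_ring_state(lib, "one")) == 1))
  expect_error(sample_ring_state(lib, "nope"), "unknown ring topology")

  rt <- 0.593
  two <- structure(list(topologies = list(t2 = list(
    templates = list(diag(3), 2 * diag(3)),
    energies = c(0, rt * log(3)), cutoff = 0.27,
    labels = rep("C3", 3)))), class = "RingConformerLibrary")
  set.seed(314)
  draws <- replicate(10000, sample_ring_state(two, "t2", rt = rt))
  p1 <- mean(draws == 1)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p1 - 0.75), 3 * se)

  eq <- two
  eq$topologies$t2$energies <- c(0, 0)
  set.seed(99)
  draws <- replicate(10000, sample_ring_state(eq, "t2", rt = rt))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("perturbation honors magnitude, ring probability and rigidity", {
  m <- make_molecule("druglike", seed = 31)
  dof <- encode(m)
  set.seed(1)
  same <- perturb_conformation(m, dof, magnitude = 0, p_ring = 0)
  expect_identical(same$torsions, dof$torsions)
  expect_identical(same$ring_states, dof$ring_states)

  rigid <- read_molecule(fixture_benzene_sdf())
  drig <- encode(rigid)
  set.seed(2)
  p2 <- perturb_conformation(rigid, drig, magnitude = pi, p_ring = 0.5)
  expect_lt(max(abs(realize(rigid, p2)$coords - rigid$coords)), 1e-9)

  # full randomization: realized butane torsion is uniform on (-pi, pi]
  bu <- make_molecule("alkane", n = 4)
  dbu <- encode(bu)
  set.seed(3)
  draws <- vapply(1:1000, function(i) {
    d <- perturb_conformation(bu, dbu, magnitude = pi, p_ring = 0)
    tor <- bu$torsion_tree$torsions[[1]]
    csalign:::cpp_dihedral(realize(bu, d)$coords, tor$p - 1L, tor$a - 1L,
                           tor$b - 1L, tor$q - 1L)
  }, 1.0)
  ks <- suppressWarnings(stats::ks.test(draws, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("realize applies rigid moves and exact torsion targets", {
  m <- make_molecule("druglike", seed = 8)
  dof <- encode(m)
  expect_lt(max(abs(realize(m, dof)$coords - m$coords)), 1e-9)

  shifted <- new_dof(dof$translation + c(2, -1, 3), dof$quaternion,
                     dof$torsions, dof$ring_states)
  expect_lt(max(abs(realize(m, shifted)$coords -
                    sweep(m$coords, 2, c(2, -1, 3), "+"))), 1e-9)

  nt <- length(dof$torsions)
  set.seed(4)
  targets <- runif(nt, -pi, pi)
  p <- realize(m, new_dof(dof$translation, dof$quaternion, targets,
                          dof$ring_states))
  for (t in seq_len(nt)) {
    tor <- m$torsion_tree$torsions[[t]]
    got <- csalign:::cpp_dihedral(p$coords, tor$p - 1L, tor$a - 1L,
                                  tor$b - 1L, tor$q - 1L)
    expect_equal(csalign:::wrap_angle(got - targets[t]), 0, tolerance = 1e-6)
  }
  # bond lengths and angles conserved by torsion/rigid moves
  d0 <- sqrt(rowSums((m$coords[m$bonds$i, ] - m$coords[m$bonds$j, ])^2))
  d1 <- sqrt(rowSums((p$coords[m$bonds$i, ] - p$coords[m$bonds$j, ])^2))
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("ring template swap keeps closure and exocyclic geometry", {
  m <- make_molecule("decorated", ring_size = 6, aromatic = FALSE, seed = 2)
  flex <- csalign:::flexible_ring_systems(m)
  expect_equal(length(flex), 1)
  lib <- csalign:::ring_library_for(m, csalign_config(sampling = list(
    ring_embeddings = 120, ring_seed = 20201126L, rt = 0.593, p_ring = 0.3,
    mutation_magnitude = pi / 3)))
  entry <- lib$topologies[[flex[[1]]$key]]
  expect_gte(length(entry$templates), 2)
  dof <- encode(m, ringlib = lib)
  for (st in seq_along(entry$templates)) {
    d <- new_dof(dof$translation, dof$quaternion, dof$torsions, st)
    p <- realize(m, d, ringlib = lib)
    # every bond survives the swap at (close to) its original length
    d0 <- sqrt(rowSums((m$coords[m$bonds$i, ] - m$coords[m$bonds$j, ])^2))
    d1 <- sqrt(rowSums((p$coords[m$bonds$i, ] - p$coords[m$bonds$j, ])^2))
    in_ring <- m$bonds$in_ring
    expect_lt(max(abs(d0[!in_ring] - d1[!in_ring])), 0.05)
    expect_lt(max(abs(d1[in_ring] - mean(d0[in_ring]))), 0.2)
  }
})

test_that("encode then realize is the identity for chain molecules", {
  for (s in c(1, 5)) {
    m <- make_molecule("alkane", n = 5 + s)
    rig <- random_rigid()
    x <- sweep(m$coords %*% t(rig$R), 2, rig$t, "+")
    dof <- encode(m, x)
    expect_lt(max(abs(realize(m, dof)$coords - x)), 1e-6)
  }
})
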