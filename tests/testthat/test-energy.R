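# Independent R oracle for the ligand nonbonded terms: recomputes every pair
# from the published functional forms, no shared code with the spec builder.
ligand_energy_oracle <- function(mol, coords, cfg = csalign_config()) {
  np <- csalign:::nb_params(mol$elem)
  polh <- csalign:::polar_h_flags(mol)
  sel <- which(!mol$is_h | polh)
  bd <- csalign:::bond_distances(mol)
  Si <- np$asp + 0.01097 * abs(mol$charge)
  acc <- mol$elem %in% c("N", "O")
  terms <- c(vdw = 0, hb = 0, qq = 0, ds = 0,
             vdw14 = 0, hb14 = 0, qq14 = 0, ds14 = 0)
  for (a in seq_along(sel)) for (b in seq_len(a - 1L)) {
    i <- sel[a]; j <- sel[b]
    sep <- bd[i, j]
    if (sep < 3) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r > cfg$energy$nb_cutoff) next
    rc <- max(r, 0.75)
    tag <- if (sep == 3) "14" else ""
    if ((polh[i] && acc[j]) || (polh[j] && acc[i])) {
      e <- cfg$energy$hb_eps * (5 * cfg$energy$hb_r0^12 / rc^12 -
                                6 * cfg$energy$hb_r0^10 / rc^10)
      terms[paste0("hb", tag)] <- terms[paste0("hb", tag)] + e
    } else {
      rm_ <- np$rmin_half[i] + np$rmin_half[j]
      eps <- sqrt(np$epsilon[i] * np$epsilon[j])
      e <- eps * (rm_^12 / rc^12 - 2 * rm_^6 / rc^6)
      terms[paste0("vdw", tag)] <- terms[paste0("vdw", tag)] + e
    }
    diel <- -8.5525 + 86.9525 / (1 + 7.7839 * exp(-0.003627 * 86.9525 * rc))
    terms[paste0("qq", tag)] <- terms[paste0("qq", tag)] +
      332.0637 * mol$charge[i] * mol$charge[j] / (diel * rc)
    terms[paste0("ds", tag)] <- terms[paste0("ds", tag)] +
      (Si[i] * np$volume[j] + Si[j] * np$volume[i]) * exp(-r^2 / (2 * 3.6^2))
  }
  terms
}

test_that("ligand nonbonded terms match a from-scratch pairwise oracle", {
  for (s in c(2, 9)) {
    m <- make_molecule("druglike", seed = s)
    e <- ligand_internal_energy(new_pose(m))
    o <- ligand_energy_oracle(m, m$coords)
    expect_equal(unname(e$terms["vdw_L"]), unname(o["vdw"]), tolerance = 1e-9)
    expect_equal(unname(e$terms["hb_L"]), unname(o["hb"]), tolerance = 1e-9)
    expect_equal(unname(e$terms["qq_L"]), unname(o["qq"]), tolerance = 1e-9)
    expect_equal(unname(e$terms["desolv_L"]), unname(o["ds"]), tolerance = 1e-9)
    expect_equal(unname(e$terms["vdw_14"]), unname(o["vdw14"]), tolerance = 1e-9)
    # the weighted total recombines from the breakdown
    w <- csalign_config()$weights
    want <- w$w4 * o["vdw"] + w$w5 * o["hb"] + w$w6 * o["qq"] +
      w$w7 * o["ds"] +
      w$w8 * (w$w4 * o["vdw14"] + w$w5 * o["hb14"] + w$w6 * o["qq14"] +
              w$w7 * o["ds14"]) +
      w$w11 * unname(e$terms["bonded_L"])
    expect_equal(e$total, unname(want), tolerance = 1e-9)
  }
})

test_that("molecules with no >2-bond pairs have only bonded energy", {
  m <- make_molecule("alkane", n = 2)
  e <- ligand_internal_energy(new_pose(m))
  expect_true(all(e$terms[c("vdw_L", "hb_L", "qq_L", "desolv_L",
                            "vdw_14")] == 0))
  expect_equal(e$total, unname(e$terms["bonded_L"]))
})

test_that("anti-butane is lower in energy than eclipsed", {
  m <- make_molecule("alkane", n = 4)
  dof <- encode(m)
  anti <- realize(m, new_dof(dof$translation, dof$quaternion, pi,
                             dof$ring_states))
  ecl <- realize(m, new_dof(dof$translation, dof$quaternion, 0,
                            dof$ring_states))
  expect_lt(ligand_internal_energy(anti)$total,
            ligand_internal_energy(ecl)$total)
})

test_that("ligand internal energy is rigid-motion invariant", {
  m <- make_molecule("druglike", seed = 4)
  e0 <- ligand_internal_energy(new_pose(m))$total
  set.seed(3)
  for (k in 1:5) {
    rig <- random_rigid()
    p <- new_pose(m, sweep(m$coords %*% t(rig$R), 2, rig$t, "+"))
    expect_equal(ligand_internal_energy(p)$total, e0, tolerance = 1e-6)
  }
})

test_that("receptor grids reproduce the direct pairwise sum", {
  prot <- new_protein(c("C", "O", "N", "C", "S"),
                      rbind(c(3.5, 0, 0), c(-3.4, 0.5, 0), c(0, 3.6, 0.4),
                            c(0, -3.5, 0), c(0.3, 0, 3.8)),
                      charge = c(0, -0.35, -0.3, 0, -0.1))
  grid <- build_receptor_grid(prot, center = c(0, 0, 0), edge = 10,
                              spacing = 0.375,
                              classes = c("C", "N", "O", "H"))
  me <- read_molecule(fixture_methane_sdf())

  # node identity: a single-atom probe sitting exactly on a node
  one <- new_molecule("C", matrix(0, 1, 3),
                      data.frame(i = integer(0), j = integer(0),
                                 order = integer(0)))
  node <- grid$origin + grid$spacing * c(8, 12, 10)
  probe <- new_pose(one, matrix(node, 1, 3))
  direct <- csalign:::protein_ligand_energy_direct(probe, prot)
  viagrid <- protein_ligand_energy(probe, grid)
  expect_equal(viagrid$total, direct$total,
               tolerance = 1e-6 * max(1, abs(direct$total)))

  # off-node points in the attractive/contact region: trilinear within 2 %
  # (inside the r^-12 repulsive wall the field curves faster than any grid
  # resolves; docking only ever scores poses outside it). Receptor atoms sit
  # 5-6 A out so the methane probe stays in the smooth part of the field.
  prot_far <- new_protein(c("C", "O", "N", "C"),
                          rbind(c(5.5, 0, 0), c(-5.2, 0.6, 0),
                                c(0, 5.6, 0.5), c(0, -0.4, 5.4)),
                          charge = c(0, -0.35, -0.3, 0))
  grid_far <- build_receptor_grid(prot_far, c(0, 0, 0), edge = 10,
                                  spacing = 0.375,
                                  classes = c("C", "N", "O", "H"))
  set.seed(5)
  for (k in 1:5) {
    shift <- runif(3, -0.8, 0.8)
    p <- new_pose(me, sweep(me$coords, 2, shift, "+"))
    d <- csalign:::protein_ligand_energy_direct(p, prot_far)
    g <- protein_ligand_energy(p, grid_far)
    # 2 % of the direct value, with a 0.02 kcal/mol floor for totals near 0
    expect_lt(abs(g$total - d$total), 0.02 * max(1, abs(d$total)))
  }

  # probe beyond the nonbonded cutoff sees a zero field
  grid2 <- build_receptor_grid(new_protein("C", matrix(c(40, 0, 0), 1, 3)),
                               center = c(0, 0, 0), edge = 12,
                               classes = "C")
  p <- new_pose(me)
  pl <- csalign:::pl_grid_terms(p$coords, me,
                                csalign:::ligand_energy_spec(me), grid2,
                                csalign_config())
  expect_equal(pl$vdw + pl$hb + pl$qq + pl$desolv, 0)
})

test_that("grid energy converges with spacing", {
  sc <- make_scenario("self_dock", seed = 2)
  lig <- sc$crystal
  center <- colMeans(lig$coords)
  g1 <- build_receptor_grid(sc$receptor, center, edge = 16, spacing = 0.375)
  g2 <- build_receptor_grid(sc$receptor, center, edge = 16, spacing = 0.2)
  d <- csalign:::protein_ligand_energy_direct(lig, sc$receptor)$total
  e1 <- protein_ligand_energy(lig, g1)$total
  e2 <- protein_ligand_energy(lig, g2)$total
  expect_lt(abs(e2 - d), abs(e1 - d) + 0.05)
  expect_equal(e2, d, tolerance = 0.02 * max(1, abs(d)))
})

test_that("select_energy dispatches by mode and degrades gracefully", {
  m <- make_molecule("druglike", seed = 6)
  p <- new_pose(m)
  expect_equal(select_energy("csalign", p),
               ligand_internal_energy(p)$total)
  expect_error(select_energy("csalign_dock", p), "grid")
  # far from any receptor the docking energy approaches E_L
  far_prot <- new_protein("C", matrix(c(200, 0, 0), 1, 3))
  g <- build_receptor_grid(far_prot, colMeans(p$coords), edge = 14)
  expect_equal(select_energy("csalign_dock", p, grid = g),
               select_energy("csalign", p), tolerance = 1e-6)
})

test_that("out-of-box poses are penalized, in-box poses are not", {
  m <- read_molecule(fixture_methane_sdf())
  prot <- new_protein("C", matrix(c(0, 0, 6), 1, 3))
  g <- build_receptor_grid(prot, c(0, 0, 0), edge = 10)
  inside <- protein_ligand_energy(new_pose(m), g)
  expect_false(inside$out_of_box)
  outside <- protein_ligand_energy(new_pose(m, sweep(m$coords, 2,
                                                     c(9, 0, 0), "+")), g)
  expect_true(outside$out_of_box)
  expect_gt(outside$total, inside$total + 50)
})
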