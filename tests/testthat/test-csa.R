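mini_cfg <- function(seed = 1, ...) {
  csalign_config(seed = seed,
                 csa = utils::modifyList(csalign_config()$csa,
                                         list(n_iter = 8L, n_trials = 6L,
                                              early_stop = 100L,
                                              minimize_maxit = 80L)),
                 ...)
}

test_that("the bank keeps its size and the pose pool passes through 150", {
  m <- make_molecule("druglike", seed = 21)
  sc <- make_scenario("self_align", seed = 21)
  res <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 5))
  expect_equal(length(res$bank), 30)
  expect_equal(res$n_pose_pool, 150)
  obj <- vapply(res$bank, function(b) b$objective, 1.0)
  expect_true(all(diff(obj) >= 0))  # ranked ascending
})

test_that("bank members stay internally consistent with the objective", {
  sc <- make_scenario("self_align", seed = 2)
  res <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 9))
  for (b in res$bank[c(1, 15, 30)]) {
    expect_equal(b$objective, alignment_energy(b$shape, b$energy),
                 tolerance = 1e-9)
  }
})

test_that("best objective never increases and d_cut anneals monotonically", {
  sc <- make_scenario("self_align", seed = 6)
  res <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 3))
  h <- res$history
  expect_true(all(diff(h$best) <= 1e-9))
  expect_true(all(diff(h$d_cut) <= 1e-12))
  expect_gte(min(h$d_cut), res$d_avg * csalign_config()$csa$dcut_floor_frac - 1e-12)
})

test_that("d_cut reaches its floor at half the iteration budget", {
  state <- list(d_cut = 1, d_cut_floor = 0.4,
                d_cut_ratio = (0.4 / 1)^(1 / 25))
  hits <- NA
  for (it in 1:60) {
    state <- anneal_dcut(state)
    if (is.na(hits) && state$d_cut <= 0.4 + 1e-12) hits <- it
  }
  expect_true(abs(hits - 25) <= 1)
  # at the floor it stays put
  expect_equal(anneal_dcut(state)$d_cut, 0.4)
})

test_that("bank updates never change the bank size or worsen a member", {
  m <- make_molecule("alkane", n = 5)
  ctx <- csalign:::csa_context(m, new_pose(m), "csalign",
                               cfg = csalign_config())
  dof0 <- encode(m)
  rand_member <- function() {
    d <- perturb_conformation(m, dof0, magnitude = pi, p_ring = 0)
    d$translation <- d$translation + rnorm(3, 0, 2)
    d$quaternion <- csalign:::random_quat()
    csalign:::make_member(ctx, d)
  }
  set.seed(41)
  bank <- replicate(5, rand_member(), simplify = FALSE)
  trials <- replicate(6, rand_member(), simplify = FALSE)
  got <- update_bank(list(bank = bank, ctx = ctx, d_cut = 1.5), trials)$bank
  expect_equal(length(got), 5)
  # the best objective can only improve, the worst can only improve
  expect_lte(min(vapply(got, function(b) b$objective, 1.0)),
             min(vapply(bank, function(b) b$objective, 1.0)))
  expect_lte(max(vapply(got, function(b) b$objective, 1.0)),
             max(vapply(bank, function(b) b$objective, 1.0)))
})

test_that("trivial trial generation contracts hold", {
  sc <- make_scenario("self_align", seed = 4)
  ctx <- csalign:::csa_context(sc$query, sc$reference, "csalign",
                               cfg = csalign_config())
  dof0 <- encode(sc$query)
  bank <- list(csalign:::make_member(ctx, dof0))
  state <- list(bank = bank, first_bank = bank, ctx = ctx,
                cfg = mini_cfg(), d_cut = 1)
  expect_equal(length(generate_trials(state, 0)), 0)

  # a rigid molecule's trials differ from the seed only in rigid-body DOFs
  rigid <- read_molecule(fixture_benzene_sdf())
  ctx2 <- csalign:::csa_context(rigid, new_pose(rigid), "csalign",
                                cfg = csalign_config())
  b2 <- list(csalign:::make_member(ctx2, encode(rigid)))
  st2 <- list(bank = b2, first_bank = b2, ctx = ctx2, cfg = mini_cfg(),
              d_cut = 1)
  set.seed(8)
  for (tr in generate_trials(st2, 5)) {
    expect_equal(length(tr$dof$torsions), 0)
    expect_equal(tr$dof$ring_states, b2[[1]]$dof$ring_states)
  }
})

test_that("local minimization is a descent step and converges on 1D wells", {
  sc <- make_scenario("self_align", seed = 13)
  ctx <- csalign:::csa_context(sc$query, sc$reference, "csalign",
                               cfg = csalign_config())
  set.seed(10)
  dof0 <- encode(sc$query)
  for (k in 1:5) {
    d <- perturb_conformation(sc$query, dof0, magnitude = pi, p_ring = 0)
    mem <- csalign:::make_member(ctx, d)
    out <- local_minimize(mem, ctx)
    expect_lte(out$objective, mem$objective + 1e-9)
    # minimizing twice changes little (already near a stationary point)
    out2 <- local_minimize(out, ctx)
    expect_lte(out2$objective, out$objective + 1e-9)
  }

  # 1-torsion fixture: the minimized torsion sits at the 1-degree grid optimum
  bu <- make_molecule("alkane", n = 4)
  ctxb <- csalign:::csa_context(bu, new_pose(bu), "csalign",
                                cfg = csalign_config())
  dofb <- encode(bu)
  grid <- seq(-pi, pi, by = pi / 180)
  base <- csalign:::ring_base_coords(ctxb, dofb)
  vals <- vapply(grid, function(a)
    csalign:::eval_continuous(ctxb, base, a,
                              csalign:::quat_to_rotvec(dofb$quaternion),
                              dofb$translation, want_coords = FALSE)$objective,
    1.0)
  opt <- grid[which.min(vals)]
  start <- csalign:::make_member(ctxb, new_dof(dofb$translation,
                                               dofb$quaternion,
                                               opt + 0.4, dofb$ring_states))
  fin <- local_minimize(start, ctxb, maxit = 400)
  expect_lt(abs(csalign:::wrap_angle(fin$dof$torsions - opt)), 2 * pi / 180)
})

test_that("run_csa is bit-reproducible for a fixed seed", {
  sc <- make_scenario("self_align", seed = 9)
  r1 <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 77))
  r2 <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 77))
  expect_identical(vapply(r1$bank, function(b) b$objective, 1.0),
                   vapply(r2$bank, function(b) b$objective, 1.0))
  expect_identical(r1$bank[[1]]$coords, r2$bank[[1]]$coords)
  expect_identical(r1$history, r2$history)
})

test_that("no two bank members collapse onto each other", {
  sc <- make_scenario("self_align", seed = 16)
  res <- run_csa(sc$query, sc$reference, cfg = mini_cfg(seed = 2))
  n <- length(res$bank)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d <- symmetry_rmsd(sc$query, res$bank[[a]]$coords,
                       res$bank[[b]]$coords)$rmsd
    same_obj <- abs(res$bank[[a]]$objective - res$bank[[b]]$objective) < 1e-12
    expect_true(d > 0.01 || same_obj)
  }
})
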