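## Conformational space annealing (CSA): a fixed-size bank of conformations
## evolves by crossover/mutation trial moves, every conformation is locally
## minimized, and a diversity radius d-cut (ligand RMSD) anneals from broad
## to narrow so the search starts global and focuses on the best basins.

## Static evaluation context shared by every objective call of a run.
csa_context <- function(mol, reference, mode = "csalign", grid = NULL,
                        weights = csalign_config()$weights,
                        cfg = csalign_config(), ringlib = NULL) {
  spec <- ligand_energy_spec(mol, cfg)
  sc <- cfg$shape$radius_scale
  qh <- heavy_idx(mol)
  rh <- heavy_idx(reference$mol)
  lev <- union(mol$atype[qh], reference$mol$atype[rh])
  ctx <- list(mol = mol, reference = reference, mode = mode, grid = grid,
       weights = weights, cfg = cfg, ringlib = ringlib, spec = spec,
       flex = flexible_ring_systems(mol),
       qh = qh, q_rad = mol$radius[qh] * sc,
       q_type = as.integer(factor(mol$atype[qh], levels = lev)),
       r_xyz = reference$coords[rh, , drop = FALSE],
       r_rad = reference$mol$radius[rh] * sc,
       r_type = as.integer(factor(reference$mol$atype[rh], levels = lev)),
       tor_p = vapply(mol$torsion_tree$torsions, function(t) t$p - 1L, 1L),
       tor_a = vapply(mol$torsion_tree$torsions, function(t) t$a - 1L, 1L),
       tor_b = vapply(mol$torsion_tree$torsions, function(t) t$b - 1L, 1L),
       tor_q = vapply(mol$torsion_tree$torsions, function(t) t$q - 1L, 1L),
       tor_moved = lapply(mol$torsion_tree$torsions, function(t) t$moved - 1L))
  ## static bundle for the one-shot C++ objective
  w <- weights
  cppS <- list(tor_p = ctx$tor_p, tor_a = ctx$tor_a, tor_b = ctx$tor_b,
               tor_q = ctx$tor_q, tor_moved = ctx$tor_moved,
               pi = spec$pi, pj = spec$pj, ljA = spec$ljA, ljB = spec$ljB,
               is_hb = spec$is_hb, is_14 = spec$is_14, qqc = spec$qqc,
               dsc = spec$dsc, tV = spec$tV, tn = spec$tn,
               tphase = spec$tphase, tV1 = spec$tV1,
               w = as.numeric(c(w$w1, w$w2, w$w3, w$w4, w$w5, w$w6, w$w7,
                                w$w8, w$w11)),
               dock = (mode == "csalign_dock"),
               qh = qh - 1L, q_rad = ctx$q_rad, q_type = ctx$q_type,
               r_xyz = ctx$r_xyz, r_rad = ctx$r_rad, r_type = ctx$r_type,
               cross_factor = cfg$shape$cross_type_factor,
               s_floor = cfg$shape$s_floor)
  if (mode == "csalign_dock") {
    cls <- grid_atom_class(mol$elem, spec$polar_h)
    cls[!cls %in% grid$classes] <- "C"
    cppS$grid <- grid$grid
    cppS$gdims <- as.integer(grid$dims)
    cppS$gorigin <- grid$origin
    cppS$gspacing <- grid$spacing
    cppS$ch_vdw <- as.integer(grid$channels[paste0("vdw_", cls)])
    cppS$ch_hb <- as.integer(grid$channels[paste0("hb_", cls)])
    cppS$ch_elec <- as.integer(grid$channels[["elec"]])
    cppS$ch_sv <- as.integer(grid$channels[["sv"]])
    cppS$ch_ss <- as.integer(grid$channels[["ss"]])
    cppS$qi <- mol$charge
    cppS$Si <- spec$Si
    cppS$Vi <- spec$Vi
    cppS$box_lo <- grid$origin
    cppS$box_hi <- grid$origin + grid$edge
    cppS$wall_k <- if (isTRUE(grid$active)) cfg$energy$out_of_box_k else 0
    cppS$heavy <- qh - 1L
  }
  ctx$cppS <- cppS
  ctx
}

## Base coordinates with the DOF's ring templates applied (torsion/rigid DOFs
## are continuous; ring states are discrete and fixed during minimization).
ring_base_coords <- function(ctx, dof) {
  base <- ctx$mol$coords
  if (length(ctx$flex) > 0 && !is.null(ctx$ringlib) &&
      length(dof$ring_states) > 0) {
    for (f in seq_along(ctx$flex)) {
      entry <- ctx$ringlib$topologies[[ctx$flex[[f]]$key]]
      st <- dof$ring_states[f]
      base <- apply_ring_template(ctx$mol, base, ctx$flex[[f]]$ring,
                                  entry$templates[[st]],
                                  canonical_ring_order(ctx$mol,
                                                       ctx$flex[[f]]$ring))
    }
  }
  base
}

realize_ctx <- function(ctx, base, torsions, rotvec, trans) {
  cpp_realize(base, ctx$tor_p, ctx$tor_a, ctx$tor_b, ctx$tor_q,
              ctx$tor_moved, torsions, rotvec, trans, TRUE)
}

## Full objective at given continuous DOFs (ring base precomputed).
## One C++ call; `eval_continuous_r` below is the readable reference route.
eval_continuous <- function(ctx, base, torsions, rotvec, trans,
                            energy_only = FALSE, want_coords = TRUE) {
  v <- cpp_eval_objective(ctx$cppS, base, torsions, rotvec, trans,
                          energy_only)
  list(coords = if (want_coords)
         realize_ctx(ctx, base, torsions, rotvec, trans) else NULL,
       energy = v[3], shape = v[2], objective = v[1])
}

eval_continuous_r <- function(ctx, base, torsions, rotvec, trans,
                              energy_only = FALSE) {
  coords <- realize_ctx(ctx, base, torsions, rotvec, trans)
  sp <- ctx$spec
  sums <- cpp_pair_energy(coords, sp$pi, sp$pj, sp$ljA, sp$ljB,
                          sp$is_hb, sp$is_14, sp$qqc, sp$dsc)
  bonded <- if (length(torsions) > 0)
    sum(sp$tV / 2 * (1 + cos(sp$tn * torsions - sp$tphase)) +
        sp$tV1 / 2 * (1 + cos(torsions))) else 0
  w <- ctx$weights
  e <- w$w4 * sums[1] + w$w5 * sums[2] + w$w6 * sums[3] + w$w7 * sums[4] +
    w$w8 * (w$w4 * sums[5] + w$w5 * sums[6] + w$w6 * sums[7] +
            w$w7 * sums[8]) + w$w11 * bonded
  if (ctx$mode == "csalign_dock") {
    pl <- pl_grid_terms(coords, ctx$mol, sp, ctx$grid, ctx$cfg)
    e <- e + pl$vdw + w$w1 * pl$hb + w$w2 * pl$qq + w$w3 * pl$desolv +
      pl$penalty
  }
  if (energy_only)
    return(list(coords = coords, energy = e, shape = NA_real_,
                objective = e))
  ov <- cpp_shape_overlap(coords[ctx$qh, , drop = FALSE], ctx$q_rad,
                          ctx$q_type, ctx$r_xyz, ctx$r_rad, ctx$r_type,
                          ctx$cfg$shape$cross_type_factor)
  s <- min(1, ov$numerator / max(ov$vol_query, ov$vol_ref))
  list(coords = coords, energy = e, shape = s,
       objective = alignment_energy(s, e, ctx$cfg$shape$s_floor))
}

## Build a BankMember (realized pose + cached scores) from a DOF vector.
make_member <- function(ctx, dof) {
  base <- ring_base_coords(ctx, dof)
  ev <- eval_continuous(ctx, base, dof$torsions,
                        quat_to_rotvec(dof$quaternion), dof$translation)
  list(dof = dof, coords = ev$coords, objective = ev$objective,
       energy = ev$energy, shape = ev$shape)
}

#' Locally minimize a bank member
#'
#' Nelder-Mead minimization of the alignment energy in the continuous DOFs
#' (translation, rotation, torsions; ring states stay fixed), capped at a
#' configurable number of evaluations. The result never scores worse than
#' the input: if the search fails to improve, the input member is returned.
#'
#' @param member a bank member (as produced internally from a `DOFVector`)
#' @param ctx evaluation context (internal; see [run_csa()])
#' @param energy_only minimize the plain energy E instead of the alignment
#'   energy (used for the initial conformer pool, torsions only)
#' @param maxit evaluation budget
#' @return the minimized member
#' @export
local_minimize <- function(member, ctx,
                           energy_only = FALSE,
                           maxit = csalign_config()$csa$minimize_maxit) {
  dof <- member$dof
  nt <- length(dof$torsions)
  base <- ring_base_coords(ctx, dof)
  q0 <- dof$quaternion
  if (!is.finite(member$objective)) return(member)

  if (energy_only) {
    if (nt == 0) return(member)
    fn <- function(p) eval_continuous(ctx, base, wrap_angle(dof$torsions + p),
                                      quat_to_rotvec(q0), dof$translation,
                                      energy_only = TRUE,
                                      want_coords = FALSE)$objective
    fit <- stats::optim(numeric(nt), fn, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (fit$value >= member$energy - 1e-12) return(member)
    newdof <- new_dof(dof$translation, q0,
                      wrap_angle(dof$torsions + fit$par), dof$ring_states)
    return(make_member(ctx, newdof))
  }

  fn <- function(p) {
    dq <- rotvec_to_quat(p[4:6])
    eval_continuous(ctx, base,
                    if (nt > 0) wrap_angle(dof$torsions + p[7:(6 + nt)])
                    else numeric(0),
                    quat_to_rotvec(quat_multiply(dq, q0)),
                    dof$translation + p[1:3],
                    want_coords = FALSE)$objective
  }
  fit <- stats::optim(numeric(6 + nt), fn, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (!is.finite(fit$value) || fit$value >= member$objective - 1e-12)
    return(member)
  p <- fit$par
  newdof <- new_dof(dof$translation + p[1:3],
                    quat_multiply(rotvec_to_quat(p[4:6]), q0),
                    if (nt > 0) wrap_angle(dof$torsions + p[7:(6 + nt)])
                    else numeric(0),
                    dof$ring_states)
  make_member(ctx, newdof)
}

## Bank-to-trial distance: symmetry-aware heavy-atom RMSD in the common
## (reference) frame, no re-superposition.
member_distance <- function(ctx, m1, m2) {
  symmetry_rmsd(ctx$mol, m1$coords, m2$coords,
                cap = ctx$cfg$rmsd$automorphism_cap)$rmsd
}

#' Generate the initial CSA bank
#'
#' Thirty conformers with randomized torsions and Boltzmann-sampled ring
#' states, each relaxed on the plain energy, are rigidly aligned to the
#' reference five ways by the triad overlay, giving 150 posed conformations;
#' K-means clustering of the heavy-atom coordinates reduces them to 30 (the
#' best-scoring member of each cluster), and each survivor is locally
#' minimized on the alignment energy.
#'
#' @param ctx evaluation context from [run_csa()] internals
#' @param cfg configuration
#' @return list with `bank`, `first_bank`, `d_avg`, `n_pose_pool`
#' @export
generate_initial_bank <- function(ctx, cfg = csalign_config()) {
  mol <- ctx$mol
  nb <- cfg$csa$n_init_random
  dof0 <- encode(mol, mol$coords, ctx$ringlib)
  confs <- vector("list", nb)
  for (i in seq_len(nb)) {
    d <- perturb_conformation(mol, dof0, magnitude = pi,
                              p_ring = cfg$sampling$p_ring,
                              ringlib = ctx$ringlib,
                              rt = cfg$sampling$rt)
    m <- make_member(ctx, d)
    confs[[i]] <- local_minimize(m, ctx, energy_only = TRUE,
                                 maxit = cfg$csa$minimize_maxit)
  }
  ## five rigid alignments per conformer -> pool of 150 posed conformations
  pool <- list()
  for (m in confs) {
    tfs <- best_triad_alignments(new_pose(mol, m$coords), ctx$reference,
                                 k = cfg$csa$n_align_per_conf,
                                 top_m_pairs = cfg$rigidalign$top_m_pairs,
                                 cfg = cfg)
    tfs <- rep_len(tfs, cfg$csa$n_align_per_conf)  # pad if deduplicated
    for (tf in tfs) {
      q2 <- quat_multiply(rotmat_to_quat(tf$rotation), m$dof$quaternion)
      t2 <- as.vector(tf$rotation %*% m$dof$translation) + tf$translation
      d2 <- new_dof(t2, q2, m$dof$torsions, m$dof$ring_states)
      pool[[length(pool) + 1]] <- make_member(ctx, d2)
    }
  }
  n_pool <- length(pool)

  ## K-means reduction in heavy-atom coordinate space
  X <- t(vapply(pool, function(m)
    as.vector(m$coords[ctx$qh, , drop = FALSE]), numeric(3 * length(ctx$qh))))
  k <- cfg$csa$bank_size
  distinct <- nrow(unique(round(X, 6)))
  if (distinct < k) {
    warning("fewer than ", k, " distinct poses; bank padded with duplicates")
    memb <- match(apply(round(X, 6), 1, paste, collapse = ","),
                  unique(apply(round(X, 6), 1, paste, collapse = ",")))
  } else {
    memb <- stats::kmeans(X, centers = k, iter.max = 50,
                          algorithm = "Lloyd", nstart = 1)$cluster
  }
  reps <- lapply(sort(unique(memb)), function(cl) {
    rows <- which(memb == cl)
    pool[[rows[which.min(vapply(pool[rows], function(m) m$objective, 1))]]]
  })
  ord <- order(vapply(reps, function(m) m$objective, 1))
  reps <- reps[ord]
  while (length(reps) < k) reps <- c(reps, reps[seq_len(min(length(reps),
                                                        k - length(reps)))])
  reps <- reps[seq_len(k)]
  bank <- lapply(reps, local_minimize, ctx = ctx,
                 maxit = cfg$csa$minimize_maxit)
  ## average pairwise distance sets the d-cut schedule
  nbk <- length(bank)
  dsum <- 0; npair <- 0
  for (a in seq_len(nbk - 1)) for (b in (a + 1):nbk) {
    dsum <- dsum + member_distance(ctx, bank[[a]], bank[[b]])
    npair <- npair + 1
  }
  d_avg <- if (npair > 0) dsum / npair else 1
  list(bank = bank, first_bank = bank, d_avg = max(d_avg, 1e-3),
       n_pose_pool = n_pool)
}

#' Generate trial conformations
#'
#' Each trial starts from a random bank member and is built either by
#' mutation (torsion perturbation, ring resampling and a small rigid-body
#' jitter) or by crossover with a donor drawn from the current bank or the
#' frozen initial bank, replacing either the rigid-body block or a random
#' torsion subtree. Every trial is locally minimized before it is returned.
#'
#' @param state CSA state
#' @param n_trials number of trials
#' @return list of minimized bank members
#' @export
generate_trials <- function(state, n_trials) {
  ctx <- state$ctx; cfg <- state$cfg
  if (n_trials == 0) return(list())
  trials <- vector("list", n_trials)
  nt <- length(state$bank[[1]]$dof$torsions)
  for (i in seq_len(n_trials)) {
    seed_m <- state$bank[[sample.int(length(state$bank), 1)]]
    dof <- seed_m$dof
    if (stats::runif(1) < cfg$csa$p_mutation) {
      dof <- perturb_conformation(ctx$mol, dof,
                                  magnitude = cfg$sampling$mutation_magnitude,
                                  p_ring = cfg$sampling$p_ring,
                                  ringlib = ctx$ringlib,
                                  rt = cfg$sampling$rt)
      dof$translation <- dof$translation + stats::rnorm(3, 0, 0.5)
      dof$quaternion <- quat_normalize(quat_multiply(
        rotvec_to_quat(stats::rnorm(3, 0, 0.2)), dof$quaternion))
    } else {
      donors <- c(state$bank, state$first_bank)
      donor <- donors[[sample.int(length(donors), 1)]]$dof
      if (nt == 0 || stats::runif(1) < 0.5) {
        dof <- new_dof(donor$translation, donor$quaternion,
                       dof$torsions, dof$ring_states)
      } else {
        t0 <- sample.int(nt, 1)
        block <- torsion_subtree(ctx, t0)
        tors <- dof$torsions
        tors[block] <- donor$torsions[block]
        dof <- new_dof(dof$translation, dof$quaternion, tors,
                       dof$ring_states)
      }
    }
    m <- make_member(ctx, dof)
    trials[[i]] <- local_minimize(m, ctx, maxit = cfg$csa$minimize_maxit)
  }
  trials
}

## Indices of torsion t0 and all torsions nested inside its moved set.
torsion_subtree <- function(ctx, t0) {
  moved <- ctx$tor_moved[[t0]]
  which(vapply(seq_along(ctx$tor_a), function(t)
    t == t0 || (ctx$tor_a[t] %in% moved && ctx$tor_b[t] %in% moved), TRUE))
}

#' Update the bank with trial conformations
#'
#' The CSA replacement rule: a trial within d-cut of its nearest bank member
#' replaces that member if it scores better; a trial farther than d-cut from
#' every member replaces the worst bank member if it scores better than the
#' worst. Distance is symmetry-aware heavy-atom ligand RMSD. The bank size
#' never changes.
#'
#' @param state CSA state
#' @param trials list of (minimized) trial members
#' @return updated state (with `n_replaced` bumped in the counters)
#' @export
update_bank <- function(state, trials) {
  ctx <- state$ctx
  nrep <- 0L
  for (tr in trials) {
    if (!is.finite(tr$objective)) next
    d <- vapply(state$bank, function(m) member_distance(ctx, tr, m), 1.0)
    nearest <- which.min(d)
    if (d[nearest] <= state$d_cut) {
      if (tr$objective < state$bank[[nearest]]$objective) {
        state$bank[[nearest]] <- tr
        nrep <- nrep + 1L
      }
    } else {
      worst <- which.max(vapply(state$bank, function(m) m$objective, 1.0))
      if (tr$objective < state$bank[[worst]]$objective) {
        state$bank[[worst]] <- tr
        nrep <- nrep + 1L
      }
    }
  }
  state$n_replaced <- nrep
  state
}

#' Anneal the d-cut radius
#'
#' Multiplies d-cut by the configured ratio, never dropping below the floor.
#' The schedule runs from `D_avg/2` to `D_avg/5`, with the ratio chosen so
#' the floor is reached at half the iteration budget.
#'
#' @param state CSA state
#' @return state with updated `d_cut`
#' @export
anneal_dcut <- function(state) {
  state$d_cut <- max(state$d_cut_floor, state$d_cut * state$d_cut_ratio)
  state
}

#' Run CSA global optimization
#'
#' Full protocol: initial-bank generation (30 randomized conformers, 5 rigid
#' alignments each, K-means reduction to a bank of 30, local minimization),
#' then iterations of trial generation, bank update and d-cut annealing.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param mol query `Molecule`
#' @param reference reference `Pose`
#' @param mode `"csalign"` or `"csalign_dock"`
#' @param grid `ReceptorGrid` for dock mode
#' @param cfg configuration ([csalign_config()])
#' @return list with the ranked final `bank` (objective ascending), the
#'   iteration `history` data.frame, `d_avg`, and `n_pose_pool`
#' @export
run_csa <- function(mol, reference, mode = c("csalign", "csalign_dock"),
                    grid = NULL, cfg = csalign_config()) {
  mode <- match.arg(mode)
  if (mode == "csalign_dock" && is.null(grid))
    stop("input error: dock mode requires a receptor grid")
  set.seed(cfg$seed)
  ringlib <- ring_library_for(mol, cfg)
  ctx <- csa_context(mol, reference, mode, grid, cfg$weights, cfg, ringlib)

  init <- generate_initial_bank(ctx, cfg)
  state <- list(bank = init$bank, first_bank = init$first_bank,
                ctx = ctx, cfg = cfg,
                d_cut = init$d_avg * cfg$csa$dcut_init_frac,
                d_cut_floor = init$d_avg * cfg$csa$dcut_floor_frac,
                d_cut_ratio = (cfg$csa$dcut_floor_frac /
                               cfg$csa$dcut_init_frac)^(1 /
                               max(1, cfg$csa$n_iter / 2)),
                n_replaced = 0L)

  best <- function(st) min(vapply(st$bank, function(m) m$objective, 1.0))
  worst <- function(st) max(vapply(st$bank, function(m) m$objective, 1.0))
  hist <- data.frame(iteration = integer(0), best = numeric(0),
                     worst = numeric(0), d_cut = numeric(0),
                     replaced = integer(0))
  stall <- 0L
  prev_best <- best(state)
  for (it in seq_len(cfg$csa$n_iter)) {
    trials <- generate_trials(state, cfg$csa$n_trials)
    state <- update_bank(state, trials)
    b <- best(state)
    hist <- rbind(hist, data.frame(iteration = it, best = b,
                                   worst = worst(state),
                                   d_cut = state$d_cut,
                                   replaced = state$n_replaced))
    if (isTRUE(cfg$verbose))
      message(sprintf("iter %3d  best %12.4f  worst %12.4f  d_cut %6.3f  replaced %d",
                      it, b, worst(state), state$d_cut, state$n_replaced))
    state <- anneal_dcut(state)
    if (b < prev_best - 1e-9) { stall <- 0L; prev_best <- b }
    else stall <- stall + 1L
    if (stall >= cfg$csa$early_stop) break
  }
  ## final polish: one deeper minimization of every member before ranking
  state$bank <- lapply(state$bank, local_minimize, ctx = ctx,
                       maxit = 2L * cfg$csa$minimize_maxit)
  ord <- order(vapply(state$bank, function(m) m$objective, 1.0))
  list(bank = state$bank[ord], history = hist, d_avg = init$d_avg,
       n_pose_pool = init$n_pose_pool, ringlib = ringlib, ctx = ctx)
}
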