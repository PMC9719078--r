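test_that("radial profiles count heavy neighbors in 1 A shells", {
  single <- new_molecule("C", matrix(0, 1, 3),
                         data.frame(i = integer(0), j = integer(0),
                                    order = integer(0)))
  expect_equal(radial_profile(single, 1), rep(0L, 6))

  di <- new_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                     data.frame(i = 1, j = 2, order = 1L))
  expect_equal(radial_profile(di, 1), c(0L, 1L, 0L, 0L, 0L, 0L))

  b <- read_molecule(fixture_benzene_sdf())
  # C-C distances in benzene: 2 x 1.40, 2 x 2.42, 1 x 2.80
  expect_equal(radial_profile(b, 1), c(0L, 2L, 3L, 0L, 0L, 0L))
  dists <- sort(sqrt(rowSums(sweep(b$coords[-1, ], 2, b$coords[1, ])^2)))
  want <- tabulate(floor(dists[dists < 6]) + 1, 6)
  expect_equal(radial_profile(b, 1), as.integer(want))

  expect_error(radial_profile(b, 99), "input error")
})

test_that("atom similarity is cosine with a cross-type penalty", {
  p <- c(0L, 2L, 3L, 0L, 0L, 0L)
  expect_equal(atom_similarity(p, p, TRUE), 1.0)
  expect_equal(atom_similarity(p, p, FALSE), 0.7)
  expect_equal(atom_similarity(c(1L, 0L, 0L, 0L, 0L, 0L),
                               c(0L, 1L, 0L, 0L, 0L, 0L), TRUE), 0)
  expect_equal(atom_similarity(rep(0L, 6), p, TRUE), 0)
})

test_that("atom pairing prefers same-type partners and matches brute force", {
  m <- make_molecule("druglike", seed = 12)
  pose <- new_pose(m)
  pairs <- pair_atoms(pose, pose)
  expect_true(all(pairs$similarity >= 0 & pairs$similarity <= 1))
  expect_equal(max(pairs$similarity), 1)

  # brute-force argmax oracle over explicit profiles
  hv <- which(!m$is_h)
  P <- t(vapply(hv, function(i) radial_profile(m, i), integer(6)))
  for (rix in sample(seq_along(hv), 5)) {
    got <- pairs$r[pairs$q == hv[rix]]
    sims <- vapply(seq_along(hv), function(j)
      atom_similarity(P[rix, ], P[j, ],
                      m$atype[hv[rix]] == m$atype[hv[j]]), 1.0)
    expect_equal(sims[match(got, hv)], max(sims), tolerance = 1e-12)
  }

  # same-type partner beats a different-type one with an identical profile:
  # the reference holds a C site and an N site with the same (0,1,0,...)
  # radial profile, separated so neither sees the linker atoms
  q <- new_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                    data.frame(i = 1, j = 2, order = 1L))
  relem <- c("N", "C", "C", "C", "C", "C")
  rcoords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(8, 0, 0), c(14, 0, 0),
                   c(20, 0, 0), c(21.5, 0, 0))
  rbonds <- data.frame(i = 1:5, j = 2:6, order = 1L)
  rmol <- new_molecule(relem, rcoords, rbonds)
  pr <- pair_atoms(new_pose(q), new_pose(rmol))
  # query atom 1 has profile (0,1,0,...); N site 1 matches at 0.7, C site 5
  # matches at 1.0 -> the C site wins
  expect_equal(rmol$elem[pr$r[pr$q == 1]], "C")
})

test_that("superpose solves the least-squares rigid problem", {
  set.seed(21)
  P <- matrix(rnorm(9), 3, 3)
  expect_equal(superpose(P, P)$objective, 0, tolerance = 1e-12)
  tf <- superpose(P, sweep(P, 2, c(1, -2, 3), "+"))
  expect_equal(tf$translation, c(1, -2, 3), tolerance = 1e-9)
  expect_equal(tf$objective, 0, tolerance = 1e-9)
  # proper rotation always
  for (k in 1:20) {
    P <- matrix(rnorm(9), 3, 3); Q <- matrix(rnorm(9), 3, 3)
    tf <- superpose(P, Q)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(t(tf$rotation) %*% tf$rotation - diag(3))), 1e-9)
    # never worse than a coarse rotation-grid search about the centroids
    cp <- colMeans(P); cq <- colMeans(Q)
    best_grid <- Inf
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
      for (th in seq(0, 2 * pi, by = 10 * pi / 180)) {
        R <- csalign:::quat_to_rotmat(csalign:::rotvec_to_quat(ax * th))
        obj <- sum((sweep(Q, 2, cq) - sweep(P, 2, cp) %*% t(R))^2)
        best_grid <- min(best_grid, obj)
      }
    expect_lte(tf$objective, best_grid + 1e-9)
  }
  # collinear triads are flagged
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(superpose(col, col)$degenerate)
})

test_that("triad alignment recovers a known rigid motion exactly", {
  m <- make_molecule("druglike", seed = 17)
  rig <- random_rigid()
  moved <- sweep(m$coords %*% t(rig$R), 2, rig$t, "+")
  tfs <- best_triad_alignments(new_pose(m, moved), new_pose(m))
  back <- csalign:::apply_transform(tfs[[1]], moved)
  expect_lt(sqrt(mean(rowSums((back - m$coords)^2))), 1e-6)
  # all returned transforms are proper rotations
  for (tf in tfs) expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  # deduplication: pairwise induced RMSD above the configured radius
  if (length(tfs) > 1) {
    hv <- which(!m$is_h)
    for (a in seq_along(tfs)) for (b in seq_len(a - 1)) {
      d <- csalign:::apply_transform(tfs[[a]], moved[hv, ]) -
           csalign:::apply_transform(tfs[[b]], moved[hv, ])
      expect_gt(sqrt(mean(rowSums(d * d))), 0.25)
    }
  }
})

test_that("triad search matches exhaustive enumeration on small fixtures", {
  done <- 0; s <- 0
  while (done < 4) {
    s <- s + 1
    set.seed(s)
    n <- 5
    elem <- c("C", "N", "O", "C", "S")[1:n]
    coords <- matrix(rnorm(3 * n, sd = 2), n, 3)
    bonds <- data.frame(i = 1:(n - 1), j = 2:n, order = 1L)
    mq <- new_molecule(elem, coords, bonds, perceive = TRUE)
    rig <- random_rigid()
    mr <- new_molecule(elem, sweep(coords %*% t(rig$R), 2, rig$t, "+"),
                       bonds)
    # exhaustive oracle needs an asymmetric fixture: unambiguous pairing
    pairs <- pair_atoms(new_pose(mq), new_pose(mr))
    if (!all(pairs$r == pairs$q)) next
    done <- done + 1
    got <- best_triad_alignments(new_pose(mq), new_pose(mr),
                                 top_m_pairs = n)
    best <- Inf
    idx <- utils::combn(n, 3)
    qall <- mq$coords[pairs$q, ]; rall <- mr$coords[pairs$r, ]
    for (a in seq_len(ncol(idx))) {
      qs <- idx[, a]
      for (b in seq_len(ncol(idx))) {
        for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                          c(3, 1, 2), c(3, 2, 1))) {
          rs <- idx[, b][perm]
          tf <- superpose(mq$coords[qs, ], mr$coords[rs, ])
          if (tf$degenerate) next
          obj <- sum((csalign:::apply_transform(tf, qall) - rall)^2)
          best <- min(best, obj)
        }
      }
    }
    expect_lte(got[[1]]$objective, best + 1e-6)
    expect_lt(got[[1]]$objective, 1e-6)  # exact rigid copy is recoverable
  }
})
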