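# Inline molecular fixtures (built in code, written to tempfiles on demand)
# and small independent oracles shared across the test files.

# Minimal V2000 writer, independent of the package's writer, so read/write
# tests have two routes.
write_sdf_fixture <- function(elem, coords, bonds, path, name = "fix",
                              chg = NULL, dim2d = FALSE) {
  n <- length(elem); nb <- nrow(bonds)
  lines <- c(name, if (dim2d) "  fixture 2D" else "  fixture 3D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[i, 1], coords[i, 2], coords[i, 3],
                              elem[i]))
  for (k in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$i[k], bonds$j[k],
                              bonds$order[k]))
  if (!is.null(chg)) {
    for (i in which(chg != 0))
      lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, chg[i]))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  path
}

tetrahedral_h <- function(center, along, bond = 1.09) {
  # three H completing an sp3 center whose fourth bond points `along`
  a <- along / sqrt(sum(along^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  th <- 109.47 * pi / 180
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
    center + bond * (-cos(th) * a + sin(th) * (cos(phi) * e1 +
                                               sin(phi) * e2)) * c(1, 1, 1),
    numeric(3)))
}

fixture_ethane_sdf <- function(path = tempfile(fileext = ".sdf")) {
  c1 <- c(0, 0, 0); c2 <- c(1.54, 0, 0)
  h1 <- tetrahedral_h(c1, c1 - c2); h2 <- tetrahedral_h(c2, c2 - c1)
  coords <- rbind(c1, c2, h1, h2)
  elem <- c("C", "C", rep("H", 6))
  bonds <- data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8), order = 1L)
  write_sdf_fixture(elem, coords, bonds, path, "ethane")
}

# benzene tilted off the axis planes (Kekule bond orders)
benzene_geometry <- function(d = 1.40) {
  th <- 2 * pi * (0:5) / 6
  R <- d / (2 * sin(pi / 6))
  flat <- cbind(R * cos(th), R * sin(th), 0)
  ang <- 0.6
  rot <- matrix(c(1, 0, 0, 0, cos(ang), -sin(ang), 0, sin(ang), cos(ang)),
                3, 3, byrow = TRUE)
  flat %*% t(rot)
}

fixture_benzene_sdf <- function(path = tempfile(fileext = ".sdf")) {
  coords <- benzene_geometry()
  bonds <- data.frame(i = 1:6, j = c(2:6, 1),
                      order = rep(c(2L, 1L), 3))
  write_sdf_fixture(rep("C", 6), coords, bonds, path, "benzene")
}

fixture_butane_sdf <- function(path = tempfile(fileext = ".sdf")) {
  m <- make_molecule("alkane", n = 4)
  write_sdf_fixture(m$elem, m$coords, m$bonds, path, "butane")
}

fixture_toluene <- function() {
  ring <- benzene_geometry()
  normal_dir <- -ring[1, ] / sqrt(sum(ring[1, ]^2))
  me <- ring[1, ] + 1.51 * (ring[1, ] - colMeans(ring)) /
    sqrt(sum((ring[1, ] - colMeans(ring))^2))
  coords <- rbind(ring, me)
  bonds <- data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
                      order = c(rep(c(2L, 1L), 3), 1L))
  new_molecule(c(rep("C", 6), "C"), coords, bonds, name = "toluene")
}

fixture_ethanol_sdf <- function(path = tempfile(fileext = ".sdf")) {
  c1 <- c(0, 0, 0); c2 <- c(1.54, 0, 0)
  o <- c2 + 1.43 * c(cos(70.5 * pi / 180), sin(70.5 * pi / 180), 0)
  ho <- o + 0.96 * c(1, 0.2, 0.1) / sqrt(sum(c(1, 0.2, 0.1)^2))
  h1 <- tetrahedral_h(c1, c1 - c2)
  h2 <- tetrahedral_h(c2, (c2 - c1) * 0.5 + (c2 - o) * 0.5)[1:2, ]
  coords <- rbind(c1, c2, o, ho, h1, h2)
  elem <- c("C", "C", "O", "H", rep("H", 3), rep("H", 2))
  bonds <- data.frame(i = c(1, 2, 3, 1, 1, 1, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1L)
  write_sdf_fixture(elem, coords, bonds, path, "ethanol")
}

fixture_ammonium_sdf <- function(path = tempfile(fileext = ".sdf")) {
  n <- c(0, 0, 0)
  h <- rbind(c(1.01, 0, 0), tetrahedral_h(n, -c(1.01, 0, 0) / 1.01, 1.01))
  coords <- rbind(n, h)
  bonds <- data.frame(i = rep(1, 4), j = 2:5, order = 1L)
  write_sdf_fixture(c("N", rep("H", 4)), coords, bonds, path, "ammonium",
                    chg = c(1L, 0L, 0L, 0L, 0L))
}

fixture_methane_sdf <- function(path = tempfile(fileext = ".sdf")) {
  c1 <- c(0, 0, 0)
  h <- rbind(c(1.09, 0, 0), tetrahedral_h(c1, -c(1, 0, 0)))
  write_sdf_fixture(c("C", rep("H", 4)), rbind(c1, h),
                    data.frame(i = rep(1, 4), j = 2:5, order = 1L),
                    path, "methane")
}

fixture_biphenyl <- function() {
  r1 <- benzene_geometry()
  ax <- (r1[1, ] - colMeans(r1)) / sqrt(sum((r1[1, ] - colMeans(r1))^2))
  shift <- r1[1, ] + 1.48 * ax
  # place the second ring so its atom 4 sits at `shift`, bonded to atom 1
  r2 <- benzene_geometry()
  r2 <- sweep(r2, 2, r2[4, ] - shift)
  coords <- rbind(r1, r2)
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), order = rep(c(2L, 1L), 3)),
    data.frame(i = 6 + (1:6), j = 6 + c(2:6, 1), order = rep(c(2L, 1L), 3)),
    data.frame(i = 1, j = 10, order = 1L))
  new_molecule(c(rep("C", 12)), coords, bonds, name = "biphenyl")
}

fixture_pdb_lines <- function(with_het = FALSE, with_altloc = FALSE) {
  fmt <- function(serial, name, alt, res, chain, resno, x, y, z, occ,
                  rec = "ATOM  ", elem = substr(gsub("[0-9]", "", name), 1, 1))
    sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, alt, res, chain, resno, x, y, z, occ, 0, elem)
  lines <- c(
    fmt(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1),
    fmt(2, "CA", " ", "ALA", "A", 1, 1.46, 0, 0, 1),
    fmt(3, "C", " ", "ALA", "A", 1, 2.2, 1.3, 0, 1),
    fmt(4, "O", " ", "ALA", "A", 1, 1.7, 2.4, 0, 1),
    fmt(5, "N", " ", "GLY", "A", 2, 3.5, 1.2, 0, 1),
    fmt(6, "CA", " ", "GLY", "A", 2, 4.4, 2.3, 0, 1),
    fmt(7, "C", " ", "GLY", "A", 2, 5.8, 1.8, 0, 1),
    fmt(8, "N", " ", "SER", "A", 3, 6.7, 2.8, 0, 1),
    fmt(9, "CA", " ", "SER", "A", 3, 8.1, 2.4, 0, 1),
    fmt(10, "OG", " ", "SER", "A", 3, 8.9, 3.5, 0, 1))
  if (with_altloc) {
    lines <- c(lines,
      fmt(11, "CB", "A", "SER", "A", 3, 8.5, 1.2, 0.4, 0.3),
      fmt(12, "CB", "B", "SER", "A", 3, 8.6, 1.1, -0.4, 0.7))
  }
  if (with_het) {
    lines <- c(lines,
      fmt(20, "C1", " ", "LIG", "A", 90, 12, 0, 0, 1, rec = "HETATM"),
      fmt(21, "O1", " ", "LIG", "A", 90, 13.2, 0.4, 0, 1, rec = "HETATM"))
  }
  c(lines, "END")
}

# Horn's closed-form quaternion superposition: the independent oracle for
# the SVD-based Kabsch implementation.
horn_superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
  resid <- Qc - Pc %*% t(R)
  list(rotation = R, objective = sum(resid^2))
}

# brute-force: all element/bond-preserving heavy-atom permutations
brute_force_automorphisms <- function(mol) {
  hv <- which(!mol$is_h)
  nh <- length(hv)
  adj <- matrix(0L, nh, nh)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- match(mol$bonds$i[k], hv); j <- match(mol$bonds$j[k], hv)
    if (!is.na(i) && !is.na(j)) {
      o <- if (mol$bonds$aromatic[k]) 4L else mol$bonds$order[k]
      adj[i, j] <- o; adj[j, i] <- o
    }
  }
  el <- mol$elem[hv]
  perms <- list()
  rec <- function(partial) {
    d <- length(partial)
    if (d == nh) { perms[[length(perms) + 1]] <<- partial; return(invisible()) }
    for (cand in setdiff(seq_len(nh), partial)) {
      if (el[cand] != el[d + 1]) next
      ok <- TRUE
      for (prev in seq_len(d)) {
        if (adj[d + 1, prev] != adj[cand, partial[prev]]) { ok <- FALSE; break }
      }
      if (ok) rec(c(partial, cand))
    }
  }
  rec(integer(0))
  perms
}

rand_pose_pair <- function(seed) {
  set.seed(seed)
  m1 <- make_molecule("druglike", seed = seed)
  m2 <- make_molecule("druglike", seed = seed + 5000L)
  c1 <- sweep(m1$coords, 2, stats::rnorm(3, 0, 2), "+")
  c2 <- sweep(m2$coords, 2, stats::rnorm(3, 0, 2), "+")
  list(a = new_pose(m1, c1), b = new_pose(m2, c2))
}

random_rigid <- function() {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, pi)
  th <- sqrt(sum(v^2)); a <- v / max(th, 1e-12)
  c <- cos(th); s <- sin(th); t <- 1 - c
  R <- matrix(c(t * a[1]^2 + c, t * a[1] * a[2] - s * a[3],
                t * a[1] * a[3] + s * a[2],
                t * a[1] * a[2] + s * a[3], t * a[2]^2 + c,
                t * a[2] * a[3] - s * a[1],
                t * a[1] * a[3] - s * a[2], t * a[2] * a[3] + s * a[1],
                t * a[3]^2 + c), 3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 3))
}
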