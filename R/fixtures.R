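## Programmatic fixture generator: drug-like heavy-atom molecules with
## controllable size/flexibility, abstract shell pockets, and complete test
## scenarios. Everything is deterministic per seed and needs no downloads.
## Generated molecules are synthetic abstractions (no hydrogens, idealized
## geometry); they exercise every code path of perception, scoring and
## sampling without claiming to be real chemistry.

## Place atom D from A-B-C with given bond length, angle BCD and dihedral
## ABCD (NeRF construction).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bond * (-cos(angle) * bc + sin(angle) * (cos(dihedral) * m +
                                               sin(dihedral) * n))
}

fixture_bond_length <- function(e1, e2) {
  sum(ring_cov_radius(c(e1, e2)))
}

#' Generate a fixture molecule
#'
#' Supported kinds: `"alkane"` (carbon chain of `n` atoms), `"ring"`
#' (carbocycle of `ring_size` atoms, optionally aromatic for size 6),
#' `"decorated"` (ring plus substituent chains), and `"druglike"` (random
#' decorated scaffold with 10-30 heavy atoms, 1-8 torsions and 0-2 flexible
#' rings, drawn deterministically from `seed`).
#'
#' @param kind fixture kind
#' @param n chain length for `"alkane"`
#' @param ring_size ring size for ring-based kinds
#' @param aromatic aromatic 6-ring flag
#' @param chains list of `list(len=, elems=)` substituent specs for
#'   `"decorated"` (defaults drawn from seed for `"druglike"`)
#' @param seed integer seed (private stream; the caller's RNG is untouched)
#' @return a `Molecule`
#' @export
make_molecule <- function(kind = c("alkane", "ring", "decorated", "druglike"),
                          n = 4, ring_size = 6, aromatic = FALSE,
                          chains = NULL, seed = 1L) {
  kind <- match.arg(kind)
  with_private_seed(seed, switch(kind,
    alkane = fixture_alkane(n),
    ring = fixture_ring(ring_size, aromatic),
    decorated = fixture_decorated(ring_size, aromatic, chains),
    druglike = build_from_spec(druglike_spec())))
}

fixture_alkane <- function(n, elems = rep("C", n)) {
  stopifnot(n >= 1)
  coords <- matrix(0, n, 3)
  if (n >= 2) coords[2, ] <- c(fixture_bond_length(elems[1], elems[2]), 0, 0)
  th <- 109.47 * pi / 180
  if (n >= 3)
    coords[3, ] <- place_atom(c(0, 1, 0), coords[1, ], coords[2, ],
                              fixture_bond_length(elems[2], elems[3]),
                              th, pi)
  for (i in seq_len(n)[-(1:min(3, n))]) {
    coords[i, ] <- place_atom(coords[i - 3, ], coords[i - 2, ],
                              coords[i - 1, ],
                              fixture_bond_length(elems[i - 1], elems[i]),
                              th, pi)
  }
  bonds <- if (n >= 2)
    data.frame(i = 1:(n - 1), j = 2:n, order = 1L) else
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  new_molecule(elems, coords, bonds, name = paste0("chain", n))
}

fixture_ring <- function(ring_size, aromatic = FALSE) {
  if (aromatic && ring_size != 6)
    stop("input error: aromatic fixtures support ring size 6 only")
  elems <- rep("C", ring_size)
  if (aromatic) {
    d <- 1.40
    R <- d / (2 * sin(pi / ring_size))
    th <- 2 * pi * (seq_len(ring_size) - 1) / ring_size
    coords <- cbind(R * cos(th), R * sin(th), 0)
    order <- rep(c(2L, 1L), length.out = ring_size)  # Kekule alternation
  } else {
    coords <- fixture_ring_template(ring_size)
    order <- rep(1L, ring_size)
  }
  ## tilt out of the axis planes so flat-z inputs are never produced
  rot <- rotvec_to_quat(c(0.4, 0.3, 0.2))
  Rm <- quat_to_rotmat(rot)
  coords <- coords %*% t(Rm)
  bonds <- data.frame(i = seq_len(ring_size),
                      j = c(2:ring_size, 1L), order = order)
  new_molecule(elems, coords, bonds,
               name = paste0(if (aromatic) "ar" else "cy", ring_size))
}

## Lowest-strain saturated carbocycle geometry, built once per size on its
## own fixed RNG stream (cache state therefore never shifts the main
## fixture stream) and cached for the session.
fixture_ring_template <- function(ring_size) {
  cache <- .csalign_env$fixture_ring_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .csalign_env$fixture_ring_cache <- cache
  }
  key <- as.character(ring_size)
  if (is.null(cache[[key]])) {
    topo <- list(elem = rep("C", ring_size), hyb = rep(3L, ring_size))
    entry <- with_private_seed(94111000L + ring_size,
                               build_ring_entry(topo, n_embed = 50))
    cache[[key]] <- entry$templates[[1]]
  }
  cache[[key]]
}

quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## Exocyclic attachment directions at ring atom i (sp3: out-of-plane pair,
## aromatic: in-plane bisector).
exocyclic_dir <- function(coords, ring_n, i, aromatic, updown = 1) {
  prev <- coords[if (i == 1) ring_n else i - 1, ] - coords[i, ]
  nxt <- coords[if (i == ring_n) 1 else i + 1, ] - coords[i, ]
  a <- prev / sqrt(sum(prev^2)); b <- nxt / sqrt(sum(nxt^2))
  e1 <- a + b; e1 <- e1 / sqrt(sum(e1^2))
  e3 <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  e3 <- e3 / sqrt(sum(e3^2))
  if (aromatic) -e1
  else {
    d <- -e1 * cos(54.735 * pi / 180) + updown * e3 * sin(54.735 * pi / 180)
    d / sqrt(sum(d^2))
  }
}

fixture_decorated <- function(ring_size, aromatic, chains) {
  if (is.null(chains))
    chains <- list(list(len = 2, elems = c("C", "O")),
                   list(len = 3, elems = c("C", "C", "C")),
                   list(len = 1, elems = "N"))
  ring <- fixture_ring(ring_size, aromatic)
  elems <- ring$elem
  coords <- ring$coords
  bonds <- ring$bonds[, c("i", "j", "order")]
  attach_at <- unique(round(seq(1, ring_size,
                                length.out = length(chains) + 1)))[seq_along(chains)]
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    anchor <- attach_at[ci]
    dir <- exocyclic_dir(coords[seq_len(ring_size), , drop = FALSE],
                         ring_size, anchor, aromatic,
                         updown = if (ci %% 2 == 0) -1 else 1)
    prev2 <- coords[if (anchor == 1) ring_size else anchor - 1, ]
    prev1 <- coords[anchor, ]
    for (k in seq_len(ch$len)) {
      el <- ch$elems[k]
      idx <- length(elems) + 1L
      if (k == 1) {
        pos <- prev1 + dir * fixture_bond_length(elems[anchor], el)
        from <- anchor
      } else {
        A <- if (k == 2) prev2 else if (k == 3) prev1 else coords[idx - 3, ]
        B <- if (k == 2) prev1 else coords[idx - 2, ]
        pos <- place_atom(A, B, coords[idx - 1, ],
                          fixture_bond_length(elems[idx - 1], el),
                          109.47 * pi / 180, pi)
        from <- idx - 1L
      }
      elems <- c(elems, el)
      coords <- rbind(coords, pos)
      bonds <- rbind(bonds, data.frame(i = from, j = idx, order = 1L))
    }
  }
  rownames(coords) <- NULL
  mol <- new_molecule(elems, coords, bonds,
                      name = sprintf("deco%d_%d", ring_size, length(chains)))
  resolve_clashes(mol)
}

## Relax a generated fixture into a clash-free, low-strain conformer by a
## deterministic search over staggered torsion settings (crystal-like inputs
## are relaxed structures; the generated raw geometry may self-clash).
resolve_clashes <- function(mol, min_dist = 2.3, max_tries = 40) {
  bd <- bond_distances(mol)
  nclash <- function(coords) {
    d <- as.matrix(stats::dist(coords))
    sum(d < min_dist & bd >= 3) / 2
  }
  dof <- encode(mol)
  nt <- length(dof$torsions)
  if (nt == 0 || nclash(mol$coords) == 0) return(mol)
  spec <- ligand_energy_spec(mol)
  best <- NULL; best_key <- c(Inf, Inf)
  for (t in seq_len(max_tries)) {
    delta <- (2 * pi / 3) * ((seq_len(nt) * (t + 1) + t) %% 3)
    cand <- new_dof(dof$translation, dof$quaternion, dof$torsions + delta,
                    dof$ring_states)
    pose <- realize(mol, cand)
    key <- c(nclash(pose$coords),
             ligand_internal_energy(pose, spec = spec)$total)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- pose$coords; best_key <- key
    }
    if (best_key[1] == 0 && t >= 6) break
  }
  if (best_key[1] > 0)
    warning("fixture clash could not be fully resolved for ", mol$name)
  mol$coords <- best
  relax_torsions(mol)
}

## Continuous torsion-space relaxation on the internal energy: generated
## conformers should sit at a local minimum of the package's own physics,
## as any crystal-like structure would.
relax_torsions <- function(mol, maxit = 300) {
  dof <- encode(mol)
  nt <- length(dof$torsions)
  if (nt == 0) return(mol)
  spec <- ligand_energy_spec(mol)
  fn <- function(p) {
    pose <- realize(mol, new_dof(dof$translation, dof$quaternion,
                                 wrap_angle(dof$torsions + p),
                                 dof$ring_states))
    ligand_internal_energy(pose, spec = spec)$total
  }
  fit <- stats::optim(numeric(nt), fn, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (fit$value < fn(numeric(nt))) {
    mol$coords <- realize(mol, new_dof(dof$translation, dof$quaternion,
                                       wrap_angle(dof$torsions + fit$par),
                                       dof$ring_states))$coords
  }
  mol
}

## Random decorated-scaffold spec: ring size/aromaticity + substituent
## chains, redrawn until it satisfies the benchmark conditions of 10-30
## heavy atoms and 1-8 rotatable torsions.
druglike_spec <- function() {
  repeat {
    ring_size <- sample(c(5L, 6L), 1)
    aromatic <- ring_size == 6L && stats::runif(1) < 0.4
    n_chain <- sample(2:3, 1)
    chains <- lapply(seq_len(n_chain), function(i) {
      len <- sample(1:5, 1)
      elems <- vapply(seq_len(len), function(k)
        sample(c("C", "C", "C", "N", "O"), 1), "")
      list(len = len, elems = elems)
    })
    heavy <- ring_size + sum(vapply(chains, function(c) c$len, 1L))
    torsions <- sum(vapply(chains, function(c) max(0L, c$len - 1L), 1L))
    if (heavy >= 10 && heavy <= 30 && torsions >= 1 && torsions <= 8) break
  }
  list(ring_size = ring_size, aromatic = aromatic, chains = chains)
}

build_from_spec <- function(spec) {
  fixture_decorated(spec$ring_size, spec$aromatic, spec$chains)
}

#' Build an abstract shell pocket around a ligand pose
#'
#' Places receptor atoms (element mix C/N/O) on a shell at `radius` from the
#' ligand's heavy atoms so the seeded pose sits in an attractive cavity, with
#' a guaranteed clearance of at least 2.5 Angstrom. Deterministic per seed.
#'
#' @param ligand_pose a `Pose`
#' @param n_atoms receptor atoms to place (>= 1)
#' @param radius shell distance from the nearest ligand atom (>= 3 A)
#' @param seed integer seed
#' @return a `ProteinStructure`
#' @export
make_pocket <- function(ligand_pose, n_atoms = 40, radius = 4.0, seed = 1L) {
  if (n_atoms < 1) stop("input error: need at least one receptor atom")
  if (radius < 3) stop("input error: shell radius below 3 A guarantees clashes")
  with_private_seed(seed, {
    lig <- ligand_pose$coords[heavy_idx(ligand_pose$mol), , drop = FALSE]
    placed <- matrix(numeric(0), 0, 3)
    elems <- character(0)
    tries <- 0L
    while (nrow(placed) < n_atoms && tries < n_atoms * 200L) {
      tries <- tries + 1L
      a <- lig[sample.int(nrow(lig), 1), ]
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      cand <- a + radius * v
      dlig <- sqrt(rowSums((lig - matrix(cand, nrow(lig), 3, TRUE))^2))
      if (min(dlig) < radius - 1e-9) next
      if (min(dlig) < 2.5) next
      if (nrow(placed) > 0) {
        dpk <- sqrt(rowSums((placed - matrix(cand, nrow(placed), 3,
                                             TRUE))^2))
        if (min(dpk) < 2.2) next
      }
      placed <- rbind(placed, cand)
      elems <- c(elems, sample(c("C", "C", "C", "N", "O"), 1))
    }
    charge <- c(C = 0, N = -0.3, O = -0.35)[elems]
    new_protein(elems, placed, charge = unname(charge),
                resid = "PKT", resno = seq_along(elems),
                chain = "A", is_cofactor = FALSE, name = "shell_pocket")
  })
}

#' Generate a complete test scenario
#'
#' `self_align`: the query is a torsion-randomized, rigidly displaced copy of
#' the reference molecule and the crystal pose is the reference itself.
#' `cross_align`: query and reference share a scaffold but differ in one
#' substituent. `self_dock` adds an abstract pocket built around the crystal
#' pose.
#'
#' @param kind scenario kind
#' @param seed integer seed
#' @return list with `query` (Molecule), `reference` (Pose), `crystal`
#'   (Pose), and `receptor` (ProteinStructure, `self_dock` only)
#' @export
make_scenario <- function(kind = c("self_align", "cross_align", "self_dock"),
                          seed = 1L) {
  kind <- match.arg(kind)
  ref_mol <- make_molecule("druglike", seed = seed)
  out <- with_private_seed(seed + 1000003L, {
    if (kind == "cross_align") {
      spec <- with_private_seed(seed, druglike_spec())
      ch <- spec$chains[[length(spec$chains)]]
      ch$len <- max(1, ch$len - 1 + 2 * (ch$len < 3))
      ch$elems <- rep(if (ch$elems[1] == "C") "O" else "C", ch$len)
      spec$chains[[length(spec$chains)]] <- ch
      query <- build_from_spec(spec)
      query$name <- paste0(query$name, "_variant")
      list(query = query, reference = new_pose(ref_mol), crystal = NULL)
    } else {
      query <- ref_mol
      lib <- ring_library_for(query)
      dof0 <- encode(query, ringlib = lib)
      d <- perturb_conformation(query, dof0, magnitude = pi,
                                p_ring = 0.5, ringlib = lib)
      d$translation <- d$translation + stats::rnorm(3, 0, 4)
      d$quaternion <- random_quat()
      query$coords <- realize(query, d, ringlib = lib)$coords
      query$name <- paste0(query$name, "_q")
      list(query = query, reference = new_pose(ref_mol),
           crystal = new_pose(ref_mol))
    }
  })
  if (kind == "self_dock") {
    out$receptor <- make_pocket(out$crystal, n_atoms = 40, radius = 4.0,
                                seed = seed + 7L)
  }
  out
}
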