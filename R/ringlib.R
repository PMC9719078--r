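## Ring-conformer library: representative geometries per ring topology,
## obtained by randomized puckering of an ideal polygon followed by
## internal-coordinate energy minimization, hierarchically clustered at the
## size-dependent cutoff and sampled with Boltzmann weights. The library is
## built programmatically (no external structure database is consulted) and
## cached per session; unknown topologies are built on the fly.

#' Ring clustering cutoff
#'
#' The maximum RMSD between conformational cluster centers:
#' `0.3 * sqrt((ring_size - 1) / 6)` Angstrom.
#'
#' @param ring_size number of ring atoms (>= 3)
#' @return cutoff in Angstrom
#' @export
ring_cluster_cutoff <- function(ring_size) {
  if (any(ring_size < 3)) stop("input error: ring size must be >= 3")
  0.3 * sqrt((ring_size - 1) / 6)
}

ring_cov_radius <- function(elem) {
  tab <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10, Si = 1.17)
  r <- tab[elem]; r[is.na(r)] <- 0.77
  unname(r)
}

## Simple cyclic internal-coordinate force field: harmonic bonds and angles,
## periodic torsions (3-fold for saturated bonds, stiff 2-fold planarity for
## unsaturated ones). Vectorized over the whole ring.
ring_energy_fn <- function(elem, hyb) {
  n <- length(elem)
  i1 <- seq_len(n); i2 <- c(2:n, 1); i0 <- c(n, 1:(n - 1)); i3 <- c(3:n, 1, 2)
  rcov <- ring_cov_radius(elem)
  d0 <- rcov[i1] + rcov[i2] - 0.06 * ((hyb[i1] < 3) + (hyb[i2] < 3))
  th0 <- ifelse(hyb == 3, 109.47, 120) * pi / 180
  ## internal polygon angle cannot exceed geometry for small rings
  th0 <- pmin(th0, (n - 2) * pi / n + 0.12)
  sp2bond <- hyb[i1] < 3 & hyb[i2] < 3
  kb <- 300; ka <- 60
  Vt <- ifelse(sp2bond, 10, 3)
  nt <- ifelse(sp2bond, 2, 3)
  pht <- ifelse(sp2bond, pi, 0)
  function(x) {
    X <- matrix(x, n, 3)
    b <- X[i2, ] - X[i1, ]
    dlen <- sqrt(rowSums(b * b))
    eb <- sum(kb * (dlen - d0)^2)
    u <- X[i0, ] - X[i1, ]; v <- X[i2, ] - X[i1, ]
    cosang <- rowSums(u * v) /
      pmax(sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)), 1e-12)
    ea <- sum(ka * (acos(pmax(-1, pmin(1, cosang))) - th0)^2)
    ## torsion i0-i1-i2-i3 about bond i1-i2
    b1 <- X[i1, ] - X[i0, ]; b2 <- X[i2, ] - X[i1, ]; b3 <- X[i3, ] - X[i2, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    m <- cross3(n1, b2 / pmax(sqrt(rowSums(b2 * b2)), 1e-12))
    phi <- atan2(rowSums(m * n2), rowSums(n1 * n2))
    et <- sum(Vt / 2 * (1 + cos(nt * phi - pht)))
    eb + ea + et
  }
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Label-preserving cycle mappings (rotations/reflections) of a ring.
ring_symmetry_mappings <- function(labels) {
  n <- length(labels)
  maps <- list()
  for (rev in c(FALSE, TRUE)) {
    base <- if (rev) rev(seq_len(n)) else seq_len(n)
    for (off in seq_len(n)) {
      perm <- base[c(off:n, seq_len(off - 1))]
      if (all(labels[perm] == labels))
        maps[[length(maps) + 1]] <- perm
    }
  }
  maps
}

ring_rmsd_sym <- function(A, B, mappings) {
  best <- Inf
  for (p in mappings) {
    tf <- superpose(A[p, , drop = FALSE], B)
    r <- sqrt(tf$objective / nrow(B))
    if (r < best) best <- r
  }
  best
}

#' Build a ring-conformer library
#'
#' For each ring topology (element + hybridization sequence around the
#' cycle), generates `n_embed` conformers by randomly puckering an ideal
#' polygon and minimizing a simple cyclic force field, deduplicates them,
#' clusters the distinct minima by complete linkage at
#' [ring_cluster_cutoff()], and stores the cluster medoids with strain
#' energies relative to the best conformer. Medoids closer than the cutoff
#' (possible after linkage cutting) are pruned keeping the lower-energy one,
#' so all stored template pairs satisfy the cutoff. Building is deterministic:
#' the supplied seed drives a private RNG stream and the caller's stream is
#' left untouched.
#'
#' @param topologies list of `list(elem=, hyb=)` cyclic sequences
#' @param n_embed random embeddings per topology (default 200)
#' @param seed integer seed for the private stream
#' @return an object of class `RingConformerLibrary`
#' @export
build_ring_library <- function(topologies, n_embed = 200,
                               seed = csalign_config()$sampling$ring_seed) {
  entries <- list()
  for (topo in topologies) {
    key <- topo_key(topo)
    entry <- with_private_seed(seed, build_ring_entry(topo, n_embed))
    if (is.null(entry)) {
      warning("ring topology failed to close, skipped: ", key)
      next
    }
    entries[[key]] <- entry
  }
  structure(list(topologies = entries), class = "RingConformerLibrary")
}

topo_key <- function(topo) {
  lab <- paste0(topo$elem, topo$hyb)
  n <- length(lab)
  cands <- character(0)
  for (rev in c(FALSE, TRUE)) {
    s <- if (rev) rev(lab) else lab
    for (off in seq_len(n))
      cands <- c(cands, paste(s[c(off:n, seq_len(off - 1))], collapse = "."))
  }
  paste0("R", n, ":", min(cands))
}

with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

build_ring_entry <- function(topo, n_embed) {
  n <- length(topo$elem)
  efn <- ring_energy_fn(topo$elem, topo$hyb)
  rcov <- ring_cov_radius(topo$elem)
  dmean <- mean(rcov + c(rcov[-1], rcov[1]))
  R <- dmean / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  flat <- cbind(R * cos(th), R * sin(th), 0)
  confs <- list(); energies <- numeric(0)
  for (e in seq_len(n_embed)) {
    x0 <- flat + cbind(stats::rnorm(n, 0, 0.15), stats::rnorm(n, 0, 0.15),
                       stats::rnorm(n, 0, 0.45))
    fit <- stats::optim(as.vector(x0), efn, method = "BFGS",
                        control = list(maxit = 80, reltol = 1e-10))
    X <- matrix(fit$par, n, 3)
    dlen <- sqrt(rowSums((X[c(2:n, 1), ] - X)^2))
    if (any(abs(dlen - dmean) > 0.3)) next  # failed to close cleanly
    confs[[length(confs) + 1]] <- sweep(X, 2, colMeans(X))
    energies <- c(energies, fit$value)
  }
  if (length(confs) == 0) return(NULL)
  labels <- paste0(topo$elem, topo$hyb)
  maps <- ring_symmetry_mappings(labels)
  ## deduplicate near-identical minima before clustering
  uniq <- list(); uen <- numeric(0)
  ord <- order(energies)
  for (i in ord) {
    dup <- FALSE
    for (u in uniq) {
      if (ring_rmsd_sym(confs[[i]], u, maps) < 0.02) { dup <- TRUE; break }
    }
    if (!dup) { uniq[[length(uniq) + 1]] <- confs[[i]]; uen <- c(uen, energies[i]) }
  }
  cutoff <- ring_cluster_cutoff(n)
  k <- length(uniq)
  if (k == 1) {
    med_idx <- 1L; memb <- 1L
  } else {
    D <- matrix(0, k, k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      D[a, b] <- D[b, a] <- ring_rmsd_sym(uniq[[a]], uniq[[b]], maps)
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    memb <- stats::cutree(hc, h = cutoff)
    med_idx <- vapply(unique(memb), function(cl) {
      rows <- which(memb == cl)
      rows[which.min(rowSums(D[rows, rows, drop = FALSE]))]
    }, 1L)
  }
  ord2 <- med_idx[order(uen[med_idx])]
  templates <- uniq[ord2]
  ten <- uen[ord2] - min(uen)
  ## enforce the pairwise cutoff between stored templates
  keep <- logical(length(templates))
  for (i in seq_along(templates)) {
    ok <- TRUE
    for (j in which(keep)) {
      if (ring_rmsd_sym(templates[[i]], templates[[j]], maps) < cutoff) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  list(templates = templates[keep], energies = ten[keep],
       cutoff = cutoff, labels = labels)
}

#' Boltzmann-sample a ring state
#'
#' Draws a template index for a ring topology with probability proportional
#' to `exp(-E_i / RT)` over the stored strain energies.
#'
#' @param lib a `RingConformerLibrary`
#' @param key topology key (as produced for a molecule's flexible rings)
#' @param rt temperature RT in kcal/mol (default 0.593, 300 K)
#' @return template index
#' @export
sample_ring_state <- function(lib, key, rt = 0.593) {
  entry <- lib$topologies[[key]]
  if (is.null(entry)) stop("input error: unknown ring topology: ", key)
  w <- exp(-entry$energies / rt)
  sample.int(length(w), 1, prob = w)
}

## Library covering a molecule's flexible rings, built lazily and cached.
ring_library_for <- function(mol, cfg = csalign_config()) {
  flex <- flexible_ring_systems(mol)
  if (length(flex) == 0) return(NULL)
  cache <- .csalign_env$ringlib_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .csalign_env$ringlib_cache <- cache
  }
  hyb <- atom_hybridization(mol)
  entries <- list()
  for (f in flex) {
    key <- f$key
    if (is.null(cache[[key]])) {
      ord <- canonical_ring_order(mol, f$ring)
      topo <- list(elem = mol$elem[f$ring[ord]], hyb = hyb[f$ring[ord]])
      lib1 <- build_ring_library(list(topo),
                                 n_embed = cfg$sampling$ring_embeddings,
                                 seed = cfg$sampling$ring_seed)
      cache[[key]] <- lib1$topologies[[key]]
    }
    entries[[key]] <- cache[[key]]
  }
  structure(list(topologies = entries), class = "RingConformerLibrary")
}

## Reordering of `ring` whose labels realize the canonical topology key.
canonical_ring_order <- function(mol, ring) {
  hyb <- atom_hybridization(mol)
  lab <- paste0(mol$elem[ring], hyb[ring])
  n <- length(lab)
  best <- NULL; best_str <- NULL
  for (rev in c(FALSE, TRUE)) {
    base <- if (rev) rev(seq_len(n)) else seq_len(n)
    for (off in seq_len(n)) {
      perm <- base[c(off:n, seq_len(off - 1))]
      s <- paste(lab[perm], collapse = ".")
      if (is.null(best_str) || s < best_str) { best_str <- s; best <- perm }
    }
  }
  best
}

nearest_ring_template <- function(ring_coords, entry) {
  maps <- ring_symmetry_mappings(entry$labels)
  A <- sweep(ring_coords, 2, colMeans(ring_coords))
  d <- vapply(entry$templates, function(tmpl)
    ring_rmsd_sym(A, tmpl, maps), 1.0)
  which.min(d)
}

## Swap a flexible ring's geometry for a library template, dragging each
## exocyclic substituent rigidly with its anchor ring atom's local frame.
apply_ring_template <- function(mol, coords, ring, template, order,
                                labels = NULL) {
  atoms <- ring[order]               # canonical order, matches template rows
  n <- length(atoms)
  O_old <- coords[atoms, , drop = FALSE]
  ## fit the template in the label-preserving cycle mapping that best matches
  ## the current ring geometry: otherwise a chair applied at a rotated phase
  ## would swap axial and equatorial substituent positions
  if (is.null(labels)) {
    hyb <- atom_hybridization(mol)
    labels <- paste0(mol$elem[atoms], hyb[atoms])
  }
  best <- NULL; best_obj <- Inf
  for (p in ring_symmetry_mappings(labels)) {
    tf_p <- superpose(template[p, , drop = FALSE], O_old)
    if (tf_p$objective < best_obj) {
      best_obj <- tf_p$objective
      best <- list(tf = tf_p, perm = p)
    }
  }
  T_new <- apply_transform(best$tf, template[best$perm, , drop = FALSE])

  ## substituent components hang off exactly one ring atom each
  g <- mol_graph(mol)
  g2 <- igraph::delete_vertices(g, ring)
  keepmap <- setdiff(seq_along(mol$elem), ring)
  comp <- igraph::components(g2)$membership
  nb <- mol_neighbors(mol)

  frame_at <- function(X, i) {
    prev <- X[if (i == 1) n else i - 1, ] - X[i, ]
    nxt <- X[if (i == n) 1 else i + 1, ] - X[i, ]
    a <- prev / sqrt(sum(prev^2)); b <- nxt / sqrt(sum(nxt^2))
    e1 <- a + b; e1 <- e1 / sqrt(sum(e1^2))
    e3 <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    e3 <- e3 / sqrt(sum(e3^2))
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2], e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    cbind(e1, e2, e3)
  }

  new_coords <- coords
  for (i in seq_len(n)) {
    anchor <- atoms[i]
    Fo <- frame_at(O_old, i); Fn <- frame_at(T_new, i)
    Ri <- Fn %*% t(Fo)
    subst <- integer(0)
    for (nbr in setdiff(nb[[anchor]], ring)) {
      cc <- comp[match(nbr, keepmap)]
      subst <- c(subst, keepmap[comp == cc])
    }
    subst <- unique(subst)
    if (length(subst) > 0) {
      rel <- sweep(coords[subst, , drop = FALSE], 2, O_old[i, ])
      new_coords[subst, ] <- sweep(rel %*% t(Ri), 2, T_new[i, ], "+")
    }
    new_coords[anchor, ] <- T_new[i, ]
  }
  new_coords
}
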