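## DOF vector <-> Cartesian coordinates. A conformation is parameterized by
## a translation (centroid position), an orientation quaternion, one angle
## per rotatable torsion and one discrete library index per flexible ring.

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

rotvec_to_quat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

quat_to_rotvec <- function(q) {
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  th <- 2 * acos(pmin(1, q[1]))
  if (th < 1e-12) return(c(0, 0, 0))
  axis <- q[2:4] / sqrt(sum(q[2:4]^2))
  axis * th
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

rotmat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[i, k] + R[k, i]) / s
  }
  quat_normalize(q)
}

## Uniform random unit quaternion (Shoemake), drawn from the R RNG stream.
random_quat <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

#' Construct a DOF vector
#'
#' @param translation target centroid position (3-vector, Angstrom)
#' @param quaternion unit orientation quaternion (w, x, y, z)
#' @param torsions rotatable-torsion angles in radians, wrapped to (-pi, pi]
#' @param ring_states one library index per flexible ring system
#' @return an object of class `DOFVector`
#' @export
new_dof <- function(translation = c(0, 0, 0), quaternion = c(1, 0, 0, 0),
                    torsions = numeric(0), ring_states = integer(0)) {
  structure(list(translation = as.numeric(translation),
                 quaternion = quat_normalize(as.numeric(quaternion)),
                 torsions = wrap_angle(as.numeric(torsions)),
                 ring_states = as.integer(ring_states)),
            class = "DOFVector")
}

#' Realize Cartesian coordinates from a DOF vector
#'
#' Applies ring-conformer templates to flexible ring systems (preserving each
#' exocyclic substituent's bond vectors in its ring atom's local frame), sets
#' the rotatable torsions to the requested dihedrals down the torsion tree,
#' then rotates the whole molecule about its centroid by the orientation
#' quaternion and moves the centroid to the translation. Bond lengths and
#' angles outside rings are untouched.
#'
#' @param mol a `Molecule`
#' @param dof a `DOFVector`
#' @param ringlib a `RingConformerLibrary` (NULL keeps input ring geometry)
#' @return a `Pose`
#' @export
realize <- function(mol, dof, ringlib = NULL) {
  base <- mol$coords
  flex <- flexible_ring_systems(mol)
  if (length(flex) > 0 && !is.null(ringlib) && length(dof$ring_states) > 0) {
    if (length(dof$ring_states) != length(flex))
      stop("internal error: ring-state count does not match flexible rings")
    for (f in seq_along(flex)) {
      entry <- ringlib$topologies[[flex[[f]]$key]]
      if (is.null(entry))
        stop("internal error: ring topology missing from library: ",
             flex[[f]]$key)
      st <- dof$ring_states[f]
      if (st < 1 || st > length(entry$templates))
        stop("internal error: ring state out of range")
      base <- apply_ring_template(mol, base, flex[[f]]$ring,
                                  entry$templates[[st]],
                                  canonical_ring_order(mol, flex[[f]]$ring))
    }
  }
  tors <- mol$torsion_tree$torsions
  coords <- cpp_realize(
    base,
    vapply(tors, function(t) t$p - 1L, 1L),
    vapply(tors, function(t) t$a - 1L, 1L),
    vapply(tors, function(t) t$b - 1L, 1L),
    vapply(tors, function(t) t$q - 1L, 1L),
    lapply(tors, function(t) t$moved - 1L),
    dof$torsions,
    quat_to_rotvec(dof$quaternion),
    dof$translation, TRUE)
  new_pose(mol, coords, dof = dof)
}

#' Encode coordinates as a DOF vector
#'
#' Inverse of [realize()]: measures the rotatable-torsion dihedrals, assigns
#' each flexible ring its nearest library template, and recovers the
#' orientation/translation by superposing the torsion-built body frame onto
#' the actual coordinates. `realize(mol, encode(mol, x))` reproduces `x` to
#' numerical precision for molecules without flexible rings.
#'
#' @param mol a `Molecule`
#' @param coords N x 3 coordinates (default the molecule's own)
#' @param ringlib optional `RingConformerLibrary`
#' @return a `DOFVector`
#' @export
encode <- function(mol, coords = mol$coords, ringlib = NULL) {
  tors <- mol$torsion_tree$torsions
  tvals <- vapply(tors, function(t)
    cpp_dihedral(coords, t$p - 1L, t$a - 1L, t$b - 1L, t$q - 1L), 1.0)
  flex <- flexible_ring_systems(mol)
  states <- integer(length(flex))
  if (length(flex) > 0 && !is.null(ringlib)) {
    for (f in seq_along(flex)) {
      entry <- ringlib$topologies[[flex[[f]]$key]]
      states[f] <- if (is.null(entry)) 1L else
        nearest_ring_template(coords[flex[[f]]$ring, , drop = FALSE], entry)
    }
  } else if (length(flex) > 0) {
    states[] <- 1L
  }
  body <- realize(mol, new_dof(translation = c(0, 0, 0),
                               torsions = tvals,
                               ring_states = states),
                  ringlib = ringlib)$coords
  tf <- superpose(sweep(body, 2, colMeans(body)),
                  sweep(coords, 2, colMeans(coords)))
  new_dof(translation = colMeans(coords),
          quaternion = rotmat_to_quat(tf$rotation),
          torsions = tvals, ring_states = states)
}

#' Perturb a conformation's internal DOFs
#'
#' Adds uniform draws within +/- `magnitude` to every torsion (a magnitude of
#' pi fully randomizes them) and resamples each flexible ring state with
#' probability `p_ring` from the library's Boltzmann distribution.
#' Orientation and translation are untouched. Randomness comes from the R
#' RNG stream.
#'
#' @param mol a `Molecule`
#' @param dof current `DOFVector`
#' @param magnitude torsion perturbation half-width in radians
#' @param p_ring per-ring resampling probability
#' @param ringlib `RingConformerLibrary` (required if flexible rings exist
#'   and `p_ring > 0`)
#' @param rt Boltzmann temperature RT in kcal/mol
#' @return a new `DOFVector`
#' @export
perturb_conformation <- function(mol, dof, magnitude = pi,
                                 p_ring = 0.3, ringlib = NULL, rt = 0.593) {
  nt <- length(dof$torsions)
  tors <- dof$torsions
  if (nt > 0 && magnitude > 0)
    tors <- wrap_angle(tors + stats::runif(nt, -magnitude, magnitude))
  states <- dof$ring_states
  flex <- flexible_ring_systems(mol)
  if (length(flex) > 0 && !is.null(ringlib) && p_ring > 0) {
    for (f in seq_along(flex)) {
      if (stats::runif(1) < p_ring) {
        states[f] <- sample_ring_state(ringlib, flex[[f]]$key, rt)
      }
    }
  }
  new_dof(dof$translation, dof$quaternion, tors, states)
}

## Ring strain (kcal/mol) of the states selected in a DOF vector.
dof_ring_strain <- function(mol, dof, ringlib) {
  flex <- flexible_ring_systems(mol)
  if (length(flex) == 0 || is.null(ringlib) ||
      length(dof$ring_states) == 0) return(0)
  s <- 0
  for (f in seq_along(flex)) {
    entry <- ringlib$topologies[[flex[[f]]$key]]
    if (!is.null(entry)) s <- s + entry$energies[dof$ring_states[f]]
  }
  s
}
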