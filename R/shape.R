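## Overlap-volume shape-match score and the hybrid alignment-energy
## objective that CSA minimizes.

#' Create a Pose
#'
#' A conformation of a molecule: realized coordinates plus (optionally) the
#' DOF vector it came from and cached scores.
#'
#' @param mol a `Molecule`
#' @param coords N x 3 coordinates; default the molecule's own
#' @param dof optional DOF vector (see [realize()])
#' @return an object of class `Pose`
#' @export
new_pose <- function(mol, coords = mol$coords, dof = NULL) {
  structure(list(mol = mol, coords = as.matrix(coords), dof = dof,
                 shape = NULL, energy = NULL, objective = NULL),
            class = "Pose")
}

#' Analytic sphere-sphere intersection volume
#'
#' Exact lens-formula volume of the intersection of two spheres, handling
#' full containment and the disjoint case.
#'
#' @param rA,rB sphere radii (Angstrom)
#' @param d center-center distance (Angstrom)
#' @return overlap volume in cubic Angstrom
#' @export
sphere_overlap_volume <- function(rA, rB, d) {
  if (any(rA <= 0) || any(rB <= 0) || any(d < 0))
    stop("input error: radii must be positive and distance non-negative")
  k <- max(length(rA), length(rB), length(d))
  cpp_sphere_overlap(rep_len(rA, k), rep_len(rB, k), rep_len(d, k))
}

## Pure-R reference used as the readable counterpart of the C++ kernel.
sphere_overlap_volume_r <- function(rA, rB, d) {
  if (d >= rA + rB) return(0)
  if (d <= abs(rA - rB)) return(4 / 3 * pi * min(rA, rB)^3)
  pi * (rA + rB - d)^2 *
    (d^2 + 2 * d * (rA + rB) - 3 * (rA - rB)^2) / (12 * d)
}

#' Shape-match score between two poses
#'
#' Sum of per-atom match scores: every atom contributes the sphere-overlap
#' volume with its best-matching partner in the other molecule (vdW radii
#' scaled by `radius_scale`, default 0.8 to emphasize core overlap; the
#' overlap scaled by `cross_type_factor`, default 0.7, when the atom types
#' differ), symmetrized over the two molecules and divided by the larger of
#' the two total atomic volumes. Heavy atoms only by default. The value lies
#' in [0, 1] and reaches 1 only for a perfect same-type overlay; summing over
#' all pairs instead would saturate for any dense overlay because bonded
#' neighbors' scaled spheres interpenetrate.
#'
#' @param query,reference `Pose` objects with realized coordinates
#' @param params shape parameter list (see [csalign_config()]`$shape`)
#' @return list with `value`, `numerator` (A^3) and `denominator` (A^3)
#' @export
shape_score <- function(query, reference, params = csalign_config()$shape) {
  qsel <- shape_atom_sel(query$mol, params)
  rsel <- shape_atom_sel(reference$mol, params)
  if (length(qsel) == 0 || length(rsel) == 0)
    stop("input error: empty heavy-atom set")
  sc <- params$radius_scale
  res <- cpp_shape_overlap(
    query$coords[qsel, , drop = FALSE], query$mol$radius[qsel] * sc,
    as.integer(factor(query$mol$atype[qsel],
                      levels = union(query$mol$atype[qsel],
                                     reference$mol$atype[rsel]))),
    reference$coords[rsel, , drop = FALSE], reference$mol$radius[rsel] * sc,
    as.integer(factor(reference$mol$atype[rsel],
                      levels = union(query$mol$atype[qsel],
                                     reference$mol$atype[rsel]))),
    params$cross_type_factor)
  den <- max(res$vol_query, res$vol_ref)
  list(value = min(1, res$numerator / den),
       numerator = res$numerator, denominator = den)
}

shape_atom_sel <- function(mol, params) {
  if (isTRUE(params$heavy_atoms_only)) heavy_idx(mol) else seq_along(mol$elem)
}

#' Alignment energy: the hybrid objective
#'
#' Combines the shape-match score S with the energy E as
#' `E_align = S^(-sgn(E)) * E`: for favorable energy (E < 0) the score is
#' S * E, rewarding shape match multiplicatively; for unfavorable energy
#' (E > 0) it is E / S, penalizing a poor match more strongly. S is floored
#' at a small epsilon before the negative exponent; E = 0 gives 0. The sign
#' of the result always equals the sign of E, and improving S always lowers
#' the objective.
#'
#' @param s shape score in [0, 1] (or the list returned by [shape_score()])
#' @param e energy in kcal/mol
#' @param s_floor epsilon floor applied to S (default 1e-6)
#' @return the alignment energy (signed, mixed units)
#' @export
alignment_energy <- function(s, e, s_floor = 1e-6) {
  if (is.list(s)) s <- s$value
  s <- pmax(s, s_floor)
  ifelse(e == 0, 0, s^(-sign(e)) * e)
}
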