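## Rigid overlay of a query conformation onto the reference: atoms are paired
## by the similarity of their radial neighbor-count profiles, candidate atom
## triads define least-squares superpositions, and the best few transforms
## (by total mapped-pair squared distance) seed the aligned poses.

#' Radial profile of an atom
#'
#' Counts the heavy-atom neighbors of atom `atom_idx` within 6 Angstrom,
#' binned in 1 Angstrom shells (self excluded).
#'
#' @param mol a `Molecule`
#' @param atom_idx atom index (must be a heavy atom)
#' @param coords coordinates (default the molecule's own)
#' @return integer vector of 6 shell counts
#' @export
radial_profile <- function(mol, atom_idx, coords = mol$coords) {
  if (atom_idx < 1 || atom_idx > length(mol$elem))
    stop("input error: atom index out of range")
  hv <- setdiff(heavy_idx(mol), atom_idx)
  if (length(hv) == 0) return(integer(6))
  d <- sqrt(rowSums((coords[hv, , drop = FALSE] -
                     matrix(coords[atom_idx, ], length(hv), 3, TRUE))^2))
  counts <- tabulate(findInterval(d[d < 6], 0:5), nbins = 6)
  as.integer(counts)
}

radial_profiles <- function(mol, coords = mol$coords) {
  hv <- heavy_idx(mol)
  t(vapply(hv, function(i) radial_profile(mol, i, coords), integer(6)))
}

#' Similarity of two radial profiles
#'
#' Cosine similarity of the two 6-bin shell-count vectors (0 when either is
#' all-zero), multiplied by the cross-type penalty 0.7 when the atom types
#' differ.
#'
#' @param pQ,pR radial profiles (integer 6-vectors)
#' @param same_type are the two atoms of the same type?
#' @param cross_type_factor penalty for different types (default 0.7)
#' @return similarity in [0, 1]
#' @export
atom_similarity <- function(pQ, pR, same_type = TRUE,
                            cross_type_factor = 0.7) {
  nq <- sqrt(sum(pQ^2)); nr <- sqrt(sum(pR^2))
  s <- if (nq == 0 || nr == 0) 0 else
    min(1, sum(pQ * pR) / (nq * nr))  # guard the 1 + 2e-16 rounding case
  if (!same_type) s <- s * cross_type_factor
  s
}

#' Pair query atoms with reference atoms
#'
#' For every heavy atom of the query, finds the reference heavy atom with the
#' highest [atom_similarity()]; the result is sorted by similarity descending
#' with ties broken by the lower index pair.
#'
#' @param query,reference `Pose` objects
#' @param cross_type_factor penalty for different atom types
#' @return data.frame with columns `q` (query atom index), `r` (reference
#'   atom index), `similarity`
#' @export
pair_atoms <- function(query, reference, cross_type_factor = 0.7) {
  qh <- heavy_idx(query$mol); rh <- heavy_idx(reference$mol)
  if (length(qh) == 0 || length(rh) == 0)
    stop("input error: empty molecule")
  Pq <- radial_profiles(query$mol, query$coords)
  Pr <- radial_profiles(reference$mol, reference$coords)
  ## cosine similarity matrix, all query x reference heavy pairs
  nq <- sqrt(rowSums(Pq^2)); nr <- sqrt(rowSums(Pr^2))
  S <- pmin((Pq %*% t(Pr)) / outer(pmax(nq, 1e-12), pmax(nr, 1e-12)), 1)
  S[nq == 0, ] <- 0; S[, nr == 0] <- 0
  type_diff <- outer(query$mol$atype[qh], reference$mol$atype[rh], "!=")
  S[type_diff] <- S[type_diff] * cross_type_factor
  best <- apply(S, 1, which.max)   # ties: lowest reference index (which.max)
  out <- data.frame(q = qh, r = rh[best],
                    similarity = S[cbind(seq_along(qh), best)])
  out[order(-out$similarity, out$q, out$r), , drop = FALSE]
}

#' Least-squares rigid superposition of two point sets
#'
#' Kabsch/SVD solution of the proper rotation and translation minimizing the
#' sum of squared distances mapping `P` onto `Q` (reflections excluded).
#'
#' @param P,Q n x 3 matrices of corresponding points (n >= 3 for a unique
#'   rotation; collinear input is flagged degenerate)
#' @return list of class `RigidTransform`: `rotation` (3 x 3, det +1),
#'   `translation`, `objective` (sum of squared residuals, A^2),
#'   `degenerate` flag
#' @export
superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)  # collinear/coincident
  translation <- cq - as.vector(R %*% cp)
  resid <- Qc - Pc %*% t(R)
  structure(list(rotation = R, translation = translation,
                 objective = sum(resid^2), degenerate = degenerate),
            class = "RigidTransform")
}

apply_transform <- function(tf, coords) {
  sweep(coords %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Best rigid triad alignments of a query pose onto a reference
#'
#' Forms candidate atom triads from the `top_m_pairs` highest-similarity
#' atom pairs (triangle pre-filter: each mapped side-length difference below
#' `triangle_tol`), superposes each triad mapping by least squares, ranks the
#' resulting transforms by the total squared distance over all mapped pairs,
#' and returns the `k` best after deduplication by induced RMSD on the query
#' atoms.
#'
#' @param query,reference `Pose` objects (at least 3 heavy atoms each; fewer
#'   falls back to centroid superposition with a warning)
#' @param k number of transforms to return (default 5)
#' @param top_m_pairs pair pool size (default 10)
#' @param cfg configuration (triangle tolerance, dedup radius)
#' @return list of `RigidTransform`s, best first
#' @export
best_triad_alignments <- function(query, reference, k = 5, top_m_pairs = 10,
                                  cfg = csalign_config()) {
  pairs <- pair_atoms(query, reference,
                      cfg$shape$cross_type_factor)
  if (n_heavy(query$mol) < 3 || n_heavy(reference$mol) < 3) {
    warning("fewer than 3 heavy atoms; centroid superposition fallback")
    tr <- colMeans(reference$coords[heavy_idx(reference$mol), , drop = FALSE]) -
          colMeans(query$coords[heavy_idx(query$mol), , drop = FALSE])
    return(list(structure(list(rotation = diag(3), translation = tr,
                               objective = NA_real_, degenerate = TRUE),
                          class = "RigidTransform")))
  }
  pool <- utils::head(pairs, top_m_pairs)
  tol <- cfg$rigidalign$triangle_tol
  qall <- query$coords[pairs$q, , drop = FALSE]
  rall <- reference$coords[pairs$r, , drop = FALSE]
  qh <- query$coords[heavy_idx(query$mol), , drop = FALSE]

  cand <- list()
  idx <- utils::combn(seq_len(nrow(pool)), 3)
  for (c in seq_len(ncol(idx))) {
    trio <- pool[idx[, c], ]
    if (length(unique(trio$q)) < 3 || length(unique(trio$r)) < 3) next
    Pq <- query$coords[trio$q, , drop = FALSE]
    Pr <- reference$coords[trio$r, , drop = FALSE]
    dq <- stats::dist(Pq); dr <- stats::dist(Pr)
    if (any(abs(dq - dr) > tol)) next
    tf <- superpose(Pq, Pr)
    if (tf$degenerate) next
    moved <- apply_transform(tf, qall)
    tf$objective <- sum((moved - rall)^2)
    cand[[length(cand) + 1]] <- tf
  }
  if (length(cand) == 0) {
    ## no triad survived the filter: superpose on the best three pairs
    trio <- pool[1:3, ]
    tf <- superpose(query$coords[trio$q, , drop = FALSE],
                    reference$coords[trio$r, , drop = FALSE])
    moved <- apply_transform(tf, qall)
    tf$objective <- sum((moved - rall)^2)
    cand <- list(tf)
  }
  cand <- cand[order(vapply(cand, function(t) t$objective, 1))]
  ## deduplicate by induced RMSD on the query heavy atoms
  out <- list()
  for (tf in cand) {
    dup <- FALSE
    for (kept in out) {
      d <- apply_transform(tf, qh) - apply_transform(kept, qh)
      if (sqrt(mean(rowSums(d * d))) <= cfg$rigidalign$dedup_rmsd) {
        dup <- TRUE; break
      }
    }
    if (!dup) out[[length(out) + 1]] <- tf
    if (length(out) >= k) break
  }
  out
}
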