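## Symmetry-aware heavy-atom RMSD: minimum over graph automorphisms of the
## heavy-atom molecular graph (element- and bond-order-preserving), so
## topologically equivalent atoms (benzene carbons, for example) do not
## inflate the deviation. Poses are compared in a common frame; no
## re-superposition is applied.

## Enumerate heavy-atom automorphisms as permutation rows (capped).
heavy_automorphisms <- function(mol, cap = 10000L) {
  hv <- heavy_idx(mol)
  nh <- length(hv)
  b <- mol$bonds
  keep <- !mol$is_h[b$i] & !mol$is_h[b$j]
  b <- b[keep, , drop = FALSE]
  remap <- match(seq_along(mol$elem), hv)
  g <- igraph::make_empty_graph(n = nh, directed = FALSE)
  if (nrow(b) > 0)
    g <- igraph::add_edges(g, rbind(remap[b$i], remap[b$j]))
  vcol <- as.integer(factor(mol$elem[hv]))
  ## Kekule patterns normalize: aromatic ring bonds all share one color
  ecol <- ifelse(b$aromatic, 4L, b$order)
  n_auto <- igraph::count_isomorphisms(g, g, method = "vf2",
                                       vertex.color1 = vcol,
                                       vertex.color2 = vcol,
                                       edge.color1 = ecol, edge.color2 = ecol)
  if (n_auto > cap) {
    warning(sprintf("%d heavy-atom automorphisms exceed the cap (%d); using identity mapping",
                    n_auto, cap))
    return(matrix(seq_len(nh), nrow = 1))
  }
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = vcol, vertex.color2 = vcol,
                               edge.color1 = ecol, edge.color2 = ecol)
  do.call(rbind, lapply(maps, as.integer))
}

#' Symmetry-aware heavy-atom RMSD
#'
#' Minimum RMSD between two coordinate sets of the same molecule over all
#' element- and bond-preserving permutations of the heavy atoms. This is the
#' pose-evaluation metric and the CSA bank distance measure; it is a
#' pseudo-metric (symmetric, zero on identical inputs).
#'
#' @param mol the `Molecule` both coordinate sets belong to
#' @param coordsA,coordsB N x 3 coordinate matrices (all atoms; hydrogens are
#'   ignored)
#' @param cap automorphism-enumeration cap; beyond it the identity mapping is
#'   used with a warning
#' @return list with `rmsd` (Angstrom) and `mapping` (heavy-atom permutation)
#' @export
symmetry_rmsd <- function(mol, coordsA, coordsB,
                          cap = csalign_config()$rmsd$automorphism_cap) {
  if (!all(dim(coordsA) == dim(coordsB)) ||
      nrow(coordsA) != length(mol$elem))
    stop("input error: coordinate shape mismatch")
  hv <- heavy_idx(mol)
  A <- coordsA[hv, , drop = FALSE]
  B <- coordsB[hv, , drop = FALSE]
  perms <- cached_automorphisms(mol, cap)
  vals <- cpp_rmsd_perms(A, B, perms - 1L)
  best <- which.min(vals)
  list(rmsd = vals[best], mapping = perms[best, ])
}

## Automorphism enumeration is pure topology; cache it on the molecule's
## environment key so bank updates do not recompute it.
cached_automorphisms <- function(mol, cap) {
  key <- paste0(mol$name, ":", length(mol$elem), ":", nrow(mol$bonds), ":",
                paste(mol$elem, collapse = ""), ":", cap)
  cache <- .csalign_env$auto_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .csalign_env$auto_cache <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- heavy_automorphisms(mol, cap)
  cache[[key]] <- perms
  perms
}

## Plain identity-mapping heavy-atom RMSD.
heavy_rmsd <- function(mol, coordsA, coordsB) {
  hv <- heavy_idx(mol)
  d <- coordsA[hv, , drop = FALSE] - coordsB[hv, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}
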