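## Ring, aromaticity, rotatable-bond and torsion-tree perception.

## Smallest cycle through every non-bridge bond; rings sharing an edge are
## grouped into fused systems.
perceive_rings <- function(mol) {
  g <- mol_graph(mol)
  nb <- nrow(mol$bonds)
  mol$bonds$in_ring <- rep(FALSE, nb)
  mol$bonds$aromatic <- rep(FALSE, nb)
  mol$rings <- list()
  mol$ring_systems <- list()
  if (nb == 0) return(mol)
  bridges <- igraph::bridges(g)
  ring_edge <- !(seq_len(nb) %in% as.integer(bridges))
  mol$bonds$in_ring <- ring_edge
  if (!any(ring_edge)) return(mol)

  rings <- list()
  for (e in which(ring_edge)) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
    g2 <- igraph::delete_edges(g, e)
    sp <- igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]]
    cyc <- as.integer(sp)          # ordered cycle i .. j, closed by bond e
    key <- paste(sort(cyc), collapse = "-")
    if (!key %in% names(rings)) rings[[key]] <- cyc
  }
  rings <- unname(rings[order(vapply(rings, length, 1L),
                              vapply(rings, min, 1L))])
  mol$rings <- rings

  ## fused systems: union-find over rings sharing at least one bond (edge)
  nr <- length(rings)
  parent <- seq_len(nr)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(nr)) for (b in seq_len(nr)) {
    if (a < b && length(intersect(rings[[a]], rings[[b]])) >= 2) {
      parent[find(b)] <- find(a)
    }
  }
  comp <- vapply(seq_len(nr), find, 1L)
  mol$ring_systems <- lapply(unique(comp), function(cc) {
    ridx <- which(comp == cc)
    list(rings = ridx,
         atoms = sort(unique(unlist(rings[ridx]))),
         fused = length(ridx) > 1)
  })

  ## aromatic perception: a ring is aromatic when every member atom carries a
  ## double/aromatic bond (Kekule patterns normalize to one aromatic label)
  sp2 <- atom_has_multiple_bond(mol)
  for (r in rings) {
    if (all(sp2[r])) {
      on_ring <- mol$bonds$i %in% r & mol$bonds$j %in% r & mol$bonds$in_ring
      mol$bonds$aromatic[on_ring] <- TRUE
    }
  }
  mol
}

atom_has_multiple_bond <- function(mol) {
  n <- length(mol$elem)
  out <- logical(n)
  hi <- mol$bonds$order >= 2 | mol$bonds$order == 4L
  out[mol$bonds$i[hi]] <- TRUE
  out[mol$bonds$j[hi]] <- TRUE
  out
}

## sp-hybridization guess from bond orders (3 = sp3, 2 = sp2, 1 = sp).
atom_hybridization <- function(mol) {
  n <- length(mol$elem)
  hyb <- rep(3L, n)
  ndouble <- integer(n); ntriple <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    ij <- c(mol$bonds$i[k], mol$bonds$j[k])
    if (o == 2L || o == 4L) ndouble[ij] <- ndouble[ij] + 1L
    if (o == 3L) ntriple[ij] <- ntriple[ij] + 1L
  }
  hyb[ndouble >= 1L] <- 2L
  hyb[ntriple >= 1L | ndouble >= 2L] <- 1L
  hyb
}

## Rotatable: non-ring single bonds with >= 2 heavy atoms on each side;
## amide C-N excluded by default (config convention).
perceive_rotatable <- function(mol, exclude_amide = TRUE) {
  nb <- mol_neighbors(mol)
  heavy_deg <- vapply(seq_along(mol$elem), function(a)
    sum(!mol$is_h[nb[[a]]]), 1L)
  rot <- logical(nrow(mol$bonds))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$order[k] != 1L || mol$bonds$in_ring[k]) next
    if (mol$is_h[i] || mol$is_h[j]) next
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next
    if (exclude_amide && is_amide_bond(mol, i, j, nb)) next
    rot[k] <- TRUE
  }
  mol$bonds$rotatable <- rot
  mol
}

is_amide_bond <- function(mol, i, j, nb) {
  chk <- function(c_atom, n_atom) {
    if (mol$elem[c_atom] != "C" || mol$elem[n_atom] != "N") return(FALSE)
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] == 2L) {
        a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
        if ((a == c_atom && mol$elem[b] == "O") ||
            (b == c_atom && mol$elem[a] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  chk(i, j) || chk(j, i)
}

#' Perceive the torsion tree
#'
#' Cuts all rotatable bonds, takes the largest rigid fragment as the root and
#' records, for each rotatable bond in breadth-first order from the root, the
#' axis atoms, a reference dihedral quadruple and the set of atoms moved when
#' the torsion turns. Rotating a torsion moves exactly its moved-atom set.
#'
#' @param mol a Molecule with perceived bonds
#' @param exclude_amide drop amide C-N bonds from the rotatable set
#' @return the Molecule with `torsion_tree` populated
#' @export
perceive_torsion_tree <- function(mol, exclude_amide = TRUE) {
  validate_molecule(mol)
  mol <- perceive_rotatable(mol, exclude_amide)
  g <- mol_graph(mol)
  rot_edges <- which(mol$bonds$rotatable)
  gcut <- igraph::delete_edges(g, rot_edges)
  comp <- igraph::components(gcut)$membership
  sizes <- table(comp)
  root_frag <- as.integer(names(sizes)[order(-sizes, as.integer(names(sizes)))])[1]

  torsions <- list()
  if (length(rot_edges) > 0) {
    frag_of <- comp
    visited <- root_frag
    queue <- root_frag
    nb <- mol_neighbors(mol)
    edge_frags <- cbind(frag_of[mol$bonds$i[rot_edges]],
                        frag_of[mol$bonds$j[rot_edges]])
    used_edge <- logical(length(rot_edges))
    while (length(queue) > 0) {
      f <- queue[1]; queue <- queue[-1]
      touching <- which(!used_edge &
                        (edge_frags[, 1] == f | edge_frags[, 2] == f))
      touching <- touching[order(rot_edges[touching])]
      for (t in touching) {
        e <- rot_edges[t]
        i <- mol$bonds$i[e]; j <- mol$bonds$j[e]
        if (frag_of[i] == f) { a <- i; b <- j } else { a <- j; b <- i }
        child <- frag_of[b]
        if (child %in% visited) next
        used_edge[t] <- TRUE
        visited <- c(visited, child)
        queue <- c(queue, child)
        ## moved set: atoms on b's side when the a-b bond is cut
        g2 <- igraph::delete_edges(g, e)
        cc <- igraph::components(g2)$membership
        moved <- which(cc == cc[b])
        p <- pick_ref_neighbor(mol, nb, a, exclude = b, in_set = NULL)
        q <- pick_ref_neighbor(mol, nb, b, exclude = a, in_set = moved)
        torsions[[length(torsions) + 1]] <- list(
          a = a, b = b, p = p, q = q, bond = e,
          moved = as.integer(moved))
      }
    }
  }
  mol$torsion_tree <- list(
    root = as.integer(which(comp == root_frag)),
    torsions = torsions)
  mol
}

pick_ref_neighbor <- function(mol, nb, atom, exclude, in_set = NULL) {
  cand <- setdiff(nb[[atom]], exclude)
  if (!is.null(in_set)) cand <- intersect(cand, in_set)
  if (length(cand) == 0) stop("no reference neighbor for torsion axis atom")
  hv <- cand[!mol$is_h[cand]]
  if (length(hv) > 0) min(hv) else min(cand)
}

## count of rotatable torsions
n_torsions <- function(mol) length(mol$torsion_tree$torsions)

## Flexible ring systems: isolated (non-fused) non-aromatic rings of size
## 4-8. Fused and macrocyclic systems stay rigid at their input geometry.
flexible_ring_systems <- function(mol) {
  out <- list()
  for (rs in mol$ring_systems) {
    if (rs$fused) next
    ring <- mol$rings[[rs$rings[1]]]
    n <- length(ring)
    if (n < 4 || n > 8) next
    on_ring <- which(mol$bonds$i %in% ring & mol$bonds$j %in% ring &
                     mol$bonds$in_ring)
    if (any(mol$bonds$aromatic[on_ring])) next
    if (any(mol$bonds$order[on_ring] >= 2)) next  # rigid unsaturation kept
    out[[length(out) + 1]] <- list(ring = ring, key = ring_topology_key(mol, ring))
  }
  out
}

## Topology key: size + canonical (min over rotations/reflections) element
## and hybridization sequence around the cycle.
ring_topology_key <- function(mol, ring) {
  hyb <- atom_hybridization(mol)
  lab <- paste0(mol$elem[ring], hyb[ring])
  n <- length(lab)
  cands <- character(0)
  for (rev in c(FALSE, TRUE)) {
    s <- if (rev) rev(lab) else lab
    for (off in seq_len(n)) {
      rot <- s[c(off:n, seq_len(off - 1))]
      cands <- c(cands, paste(rot, collapse = "."))
    }
  }
  paste0("R", n, ":", min(cands))
}
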