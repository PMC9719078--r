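## The Molecule S3 class: a plain list, bio3d-style.
##   elem      character element symbols
##   coords    N x 3 matrix (Angstrom)
##   bonds     data.frame(i, j, order, in_ring, aromatic, rotatable)
##   formal    integer formal charges
##   charge    numeric partial charges (e)
##   radius    numeric vdW radii (A)
##   atype     character atom-type labels (element symbol by default)
##   rings     list of atom-index cycles
##   ring_systems  list of fused-system groupings
##   torsion_tree  root fragment + rotatable-bond records

#' Construct a Molecule
#'
#' Builds the molecular data model from elements, 3D coordinates and a bond
#' list, then runs perception: ring detection, aromaticity, rotatable-bond
#' and torsion-tree assignment, vdW radii, atom types and Gasteiger partial
#' charges.
#'
#' @param elem character vector of element symbols
#' @param coords numeric N x 3 matrix of coordinates in Angstrom
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3; 4 for aromatic)
#' @param name molecule identifier
#' @param formal integer formal charges per atom (default 0)
#' @param perceive run full perception (default TRUE)
#' @return an object of class `Molecule`
#' @export
new_molecule <- function(elem, coords, bonds, name = "mol",
                         formal = integer(length(elem)), perceive = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elem)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)))
    stop("bond atom index out of range")
  mol <- structure(list(
    name = name, elem = elem, is_h = elem == "H",
    coords = coords,
    bonds = data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                       order = as.integer(bonds$order)),
    formal = as.integer(formal),
    charge = numeric(n), radius = vdw_radius(elem), atype = elem,
    rings = list(), ring_systems = list(), torsion_tree = NULL
  ), class = "Molecule")
  if (perceive) {
    mol <- perceive_rings(mol)
    mol <- perceive_torsion_tree(mol)
    mol <- assign_types_and_charges(mol)
  }
  mol
}

#' @export
print.Molecule <- function(x, ...) {
  nt <- if (is.null(x$torsion_tree)) NA else length(x$torsion_tree$torsions)
  cat(sprintf("Molecule '%s': %d atoms (%d heavy), %d bonds, %d rings, %s rotatable torsions\n",
              x$name, length(x$elem), sum(!x$is_h), nrow(x$bonds),
              length(x$rings), nt))
  invisible(x)
}

n_heavy <- function(mol) sum(!mol$is_h)
heavy_idx <- function(mol) which(!mol$is_h)

mol_graph <- function(mol, heavy_only = FALSE) {
  b <- mol$bonds
  if (heavy_only) {
    keep <- !mol$is_h[b$i] & !mol$is_h[b$j]
    b <- b[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(mol$elem) - igraph::vcount(g)))
    g <- igraph::induced_subgraph(g, heavy_idx(mol))
  } else {
    g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(mol$elem) - igraph::vcount(g)))
  }
  g
}

validate_molecule <- function(mol) {
  g <- mol_graph(mol)
  if (igraph::components(g)$no != 1) stop("bond graph is not connected")
  if (any(mol$radius <= 0)) stop("non-positive vdW radius")
  invisible(TRUE)
}

## Neighbor lists as an adjacency index.
mol_neighbors <- function(mol) {
  n <- length(mol$elem)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

## Topological (bond-count) distances between all atoms.
bond_distances <- function(mol) {
  g <- mol_graph(mol)
  igraph::distances(g)
}
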