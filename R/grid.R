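## Receptor grids: trilinear-interpolable precomputation of the
## protein-ligand interaction terms over a cubic box (AutoDock convention,
## default spacing 0.375 A). One vdW and one hydrogen-bond channel per ligand
## atom class, plus electrostatic-potential and two desolvation channels.

## Ligand/receptor atom classes for grid purposes: element symbol, with
## hydrogens split into polar ("Hpol") and nonpolar ("H").
grid_atom_class <- function(elem, polar_h) {
  ifelse(elem == "H" & polar_h, "Hpol", elem)
}

receptor_polar_h <- function(prot) {
  ish <- prot$elem == "H"
  if (!any(ish)) return(logical(length(prot$elem)))
  out <- logical(length(prot$elem))
  don <- which(prot$elem %in% c("N", "O"))
  if (length(don) > 0) {
    for (i in which(ish)) {
      d2 <- rowSums((prot$coords[don, , drop = FALSE] -
                     matrix(prot$coords[i, ], length(don), 3, TRUE))^2)
      if (min(d2) < 1.25^2) out[i] <- TRUE
    }
  }
  out
}

is_hb_class_pair <- function(cl_a, cl_b) {
  (cl_a == "Hpol" & cl_b %in% c("N", "O")) |
  (cl_b == "Hpol" & cl_a %in% c("N", "O"))
}

#' Build receptor interaction grids
#'
#' Precomputes, on a cubic grid over the docking box, the receptor field for
#' each requested ligand atom class: a Lennard-Jones channel, a 12-10
#' hydrogen-bond channel (donor/acceptor pairs are moved out of the LJ
#' channel), an electrostatic potential channel (distance-dependent
#' dielectric; multiply by the ligand charge), and two desolvation channels
#' combined as `S_i*G_sv + V_i*G_ss`. Cofactor atoms are part of the rigid
#' receptor. Receptor atoms within `nb_cutoff` of a node contribute.
#'
#' @param prot a `ProteinStructure`
#' @param center box center (3-vector, Angstrom)
#' @param edge cubic box edge length (Angstrom, default 22.5)
#' @param spacing grid spacing (Angstrom, default 0.375)
#' @param classes ligand atom classes to precompute (default all supported)
#' @param cfg configuration
#' @return an object of class `ReceptorGrid`
#' @export
build_receptor_grid <- function(prot, center, edge = 22.5, spacing = 0.375,
                                classes = c("C", "N", "O", "S", "H", "Hpol",
                                            "F", "Cl"),
                                cfg = csalign_config()) {
  stopifnot(edge > 0, spacing > 0)
  cutoff <- cfg$energy$nb_cutoff
  half <- edge / 2
  origin <- center - half
  nx <- as.integer(floor(edge / spacing)) + 1L
  dims <- c(nx, nx, nx)
  ax <- origin[1] + spacing * (0:(nx - 1))
  ay <- origin[2] + spacing * (0:(nx - 1))
  az <- origin[3] + spacing * (0:(nx - 1))

  ## receptor atoms that can reach any node
  lo <- origin - cutoff; hi <- origin + edge + cutoff
  inreach <- prot$coords[, 1] >= lo[1] & prot$coords[, 1] <= hi[1] &
             prot$coords[, 2] >= lo[2] & prot$coords[, 2] <= hi[2] &
             prot$coords[, 3] >= lo[3] & prot$coords[, 3] <= hi[3]
  if (!any(inreach)) warning("no receptor atoms within reach of the box")
  rcoords <- prot$coords[inreach, , drop = FALSE]
  relem <- prot$elem[inreach]
  rq <- prot$charge[inreach]
  rpolh <- receptor_polar_h(prot)[inreach]
  rclass <- grid_atom_class(relem, rpolh)
  rnp <- nb_params(relem)
  rS <- rnp$asp + QASP * abs(rq)

  chan_names <- c(paste0("vdw_", classes), paste0("hb_", classes),
                  "elec", "sv", "ss")
  nchan <- length(chan_names)
  nxyz <- prod(dims)
  grid <- numeric(nxyz * nchan)
  chan_index <- stats::setNames(seq_along(chan_names) - 1L, chan_names)
  en <- cfg$energy
  lig_np <- nb_params(sub("pol$", "", classes))

  node_xyz_block <- function(j) {
    ## node indices within the cutoff cube of receptor atom j
    ix <- which(abs(ax - rcoords[j, 1]) <= cutoff)
    iy <- which(abs(ay - rcoords[j, 2]) <= cutoff)
    iz <- which(abs(az - rcoords[j, 3]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
    idx <- as.vector(outer(outer(ix - 1L, (iy - 1L) * nx, "+"),
                           (iz - 1L) * nx * nx, "+")) + 1L
    dx <- ax[ix] - rcoords[j, 1]
    dy <- ay[iy] - rcoords[j, 2]
    dz <- az[iz] - rcoords[j, 3]
    d2 <- as.vector(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    list(idx = idx, r = sqrt(d2))
  }

  for (j in seq_len(nrow(rcoords))) {
    blk <- node_xyz_block(j)
    if (is.null(blk)) next
    ok <- blk$r <= cutoff
    idx <- blk$idx[ok]
    r <- pmax(blk$r[ok], 0.75)
    inv2 <- 1 / (r * r); inv6 <- inv2^3; inv12 <- inv6^2; inv10 <- inv6 * inv2^2
    gauss <- exp(-r * r / (2 * DESOLV_SIGMA^2))
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      if (is_hb_class_pair(cl, rclass[j])) {
        A <- en$hb_eps * 5 * en$hb_r0^12
        B <- en$hb_eps * 6 * en$hb_r0^10
        ch <- chan_index[paste0("hb_", cl)]
        grid[ch * nxyz + idx] <- grid[ch * nxyz + idx] + A * inv12 - B * inv10
      } else {
        rm_ <- lig_np$rmin_half[ci] + rnp$rmin_half[j]
        eps <- sqrt(lig_np$epsilon[ci] * rnp$epsilon[j])
        ch <- chan_index[paste0("vdw_", cl)]
        grid[ch * nxyz + idx] <- grid[ch * nxyz + idx] +
          eps * rm_^12 * inv12 - 2 * eps * rm_^6 * inv6
      }
    }
    ch <- chan_index["elec"]
    grid[ch * nxyz + idx] <- grid[ch * nxyz + idx] +
      COULOMB_K * rq[j] / (ms_dielectric(r) * r)
    ch <- chan_index["sv"]
    grid[ch * nxyz + idx] <- grid[ch * nxyz + idx] + rnp$volume[j] * gauss
    ch <- chan_index["ss"]
    grid[ch * nxyz + idx] <- grid[ch * nxyz + idx] + rS[j] * gauss
  }

  structure(list(center = center, edge = edge, spacing = spacing,
                 origin = origin, dims = dims, grid = grid,
                 channels = chan_index, classes = classes,
                 cutoff = cutoff,
                 # an empty field leaves nothing to confine: the box wall
                 # only acts when receptor atoms are in reach
                 active = any(inreach)), class = "ReceptorGrid")
}

#' Protein-ligand energy of a pose
#'
#' Interpolates the receptor grids at the ligand atom positions, adds the
#' knowledge-based hooks (zero unless registered) and the ligand internal
#' energy. Ligand heavy atoms outside the box incur a quadratic wall penalty
#' (flagged in the breakdown) that keeps local minimization well-behaved.
#'
#' @param pose a `Pose`
#' @param grid a `ReceptorGrid`
#' @param weights energy weights
#' @param cfg configuration
#' @param spec optional precomputed [ligand_energy_spec()]
#' @param prot optional `ProteinStructure` passed to registered hooks
#' @return an `EnergyBreakdown`; `total` is the full docking energy
#' @export
protein_ligand_energy <- function(pose, grid,
                                  weights = csalign_config()$weights,
                                  cfg = csalign_config(), spec = NULL,
                                  prot = NULL) {
  mol <- pose$mol
  if (is.null(spec)) spec <- ligand_energy_spec(mol, cfg)
  pl <- pl_grid_terms(pose$coords, mol, spec, grid, cfg)
  eL <- ligand_internal_energy(pose, weights, cfg, spec)
  hm <- energy_hook_value("HM", pose, prot)
  ds <- energy_hook_value("DS", pose, prot)
  terms <- c(vdw_PL = pl$vdw, hb_PL = pl$hb, qq_PL = pl$qq,
             desolv_PL = pl$desolv, HM_PL = hm, DS_PL = ds,
             penalty_PL = pl$penalty, eL$terms)
  w <- weights
  total <- pl$vdw + w$w1 * pl$hb + w$w2 * pl$qq + w$w3 * pl$desolv +
    w$w9 * hm + w$w10 * ds + pl$penalty + eL$total
  structure(list(terms = terms, total = unname(total),
                 out_of_box = pl$penalty > 0),
            class = "EnergyBreakdown")
}

## Grid-interpolated PL terms + out-of-box wall penalty.
pl_grid_terms <- function(coords, mol, spec, grid, cfg) {
  cls <- grid_atom_class(mol$elem, spec$polar_h)
  known <- cls %in% grid$classes
  if (!all(known)) {
    warning("ligand classes without grids treated as C: ",
            paste(unique(cls[!known]), collapse = ", "))
    cls[!known] <- "C"
  }
  ch_vdw <- grid$channels[paste0("vdw_", cls)]
  ch_hb <- grid$channels[paste0("hb_", cls)]
  pts <- coords
  vals <- cpp_grid_interp(grid$grid, as.integer(grid$dims), grid$origin,
                          grid$spacing, pts,
                          as.integer(c(grid$channels["elec"],
                                       grid$channels["sv"],
                                       grid$channels["ss"])))
  ## per-atom channel interpolation for vdw/hb (channel differs per atom)
  vdw <- hb <- numeric(nrow(pts))
  for (u in unique(cls)) {
    rows <- which(cls == u)
    vv <- cpp_grid_interp(grid$grid, as.integer(grid$dims), grid$origin,
                          grid$spacing, pts[rows, , drop = FALSE],
                          as.integer(c(grid$channels[paste0("vdw_", u)],
                                       grid$channels[paste0("hb_", u)])))
    vdw[rows] <- vv[, 1]; hb[rows] <- vv[, 2]
  }
  qq <- mol$charge * vals[, 1]
  desolv <- spec$Si * vals[, 2] + spec$Vi * vals[, 3]
  ## wall penalty on heavy atoms leaving the box
  lo <- grid$origin; hi <- grid$origin + grid$edge
  hv <- heavy_idx(mol)
  over <- pmax(0, sweep(pts[hv, , drop = FALSE], 2, hi, "-")) +
          pmax(0, -sweep(pts[hv, , drop = FALSE], 2, lo, "-"))
  penalty <- if (isTRUE(grid$active))
    cfg$energy$out_of_box_k * sum(over^2) else 0
  list(vdw = sum(vdw), hb = sum(hb), qq = sum(qq), desolv = sum(desolv),
       penalty = penalty)
}

## Direct (grid-free) pairwise PL evaluation; the oracle the grids are
## checked against, and the route taken when a receptor is tiny.
protein_ligand_energy_direct <- function(pose, prot,
                                         weights = csalign_config()$weights,
                                         cfg = csalign_config(),
                                         spec = NULL) {
  mol <- pose$mol
  if (is.null(spec)) spec <- ligand_energy_spec(mol, cfg)
  en <- cfg$energy
  lpolh <- spec$polar_h
  lcls <- grid_atom_class(mol$elem, lpolh)
  rcls <- grid_atom_class(prot$elem, receptor_polar_h(prot))
  lnp <- nb_params(mol$elem); rnp <- nb_params(prot$elem)
  rS <- rnp$asp + QASP * abs(prot$charge)
  vdw <- hb <- qq <- desolv <- 0
  for (i in seq_along(mol$elem)) {
    d <- sqrt(rowSums((prot$coords -
                       matrix(pose$coords[i, ], nrow(prot$coords), 3,
                              TRUE))^2))
    ok <- d <= en$nb_cutoff
    if (!any(ok)) next
    r <- pmax(d[ok], 0.75)
    hbp <- is_hb_class_pair(lcls[i], rcls[ok])
    rm_ <- lnp$rmin_half[i] + rnp$rmin_half[ok]
    eps <- sqrt(lnp$epsilon[i] * rnp$epsilon[ok])
    e126 <- eps * rm_^12 / r^12 - 2 * eps * rm_^6 / r^6
    e1210 <- en$hb_eps * 5 * en$hb_r0^12 / r^12 -
             en$hb_eps * 6 * en$hb_r0^10 / r^10
    vdw <- vdw + sum(e126[!hbp])
    hb <- hb + sum(e1210[hbp])
    qq <- qq + sum(COULOMB_K * mol$charge[i] * prot$charge[ok] /
                   (ms_dielectric(r) * r))
    gauss <- exp(-r^2 / (2 * DESOLV_SIGMA^2))
    desolv <- desolv + sum((spec$Si[i] * rnp$volume[ok] +
                            spec$Vi[i] * rS[ok]) * gauss)
  }
  eL <- ligand_internal_energy(pose, weights, cfg, spec)
  w <- weights
  total <- vdw + w$w1 * hb + w$w2 * qq + w$w3 * desolv + eL$total
  structure(list(terms = c(vdw_PL = vdw, hb_PL = hb, qq_PL = qq,
                           desolv_PL = desolv, eL$terms),
                 total = unname(total)), class = "EnergyBreakdown")
}

#' Select the optimization energy for a run mode
#'
#' The compound energy entering the alignment objective: the ligand internal
#' energy for alignment runs, the full docking energy for alignment-docking
#' runs.
#'
#' @param mode `"csalign"` (ligand internal energy) or `"csalign_dock"`
#'   (docking energy; requires `grid`)
#' @param pose a `Pose`
#' @param grid a `ReceptorGrid` (dock mode only)
#' @param weights energy weights
#' @param cfg configuration
#' @param spec optional precomputed ligand energy spec
#' @return energy in kcal/mol
#' @export
select_energy <- function(mode = c("csalign", "csalign_dock"), pose,
                          grid = NULL, weights = csalign_config()$weights,
                          cfg = csalign_config(), spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "csalign") {
    ligand_internal_energy(pose, weights, cfg, spec)$total
  } else {
    if (is.null(grid)) stop("input error: dock mode requires a receptor grid")
    protein_ligand_energy(pose, grid, weights, cfg, spec)$total
  }
}
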