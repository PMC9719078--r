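## Ligand internal energy E_L: AutoDock4-style nonbonded terms (12-6
## Lennard-Jones, 12-10 hydrogen bond, distance-dependent-dielectric Coulomb,
## Gaussian-contact desolvation) over atom pairs separated by more than three
## bonds, the same terms over exactly-three-bond (1-4) pairs scaled by w8,
## and a torsional-strain bonded term over the rotatable bonds. Only torsions
## (and discrete ring states) change during sampling, so torsional strain is
## the discriminating bonded contribution; bond lengths and angles are frozen
## by the DOF parameterization.

COULOMB_K <- 332.0637
DESOLV_SIGMA <- 3.6
QASP <- 0.01097

## Mehler-Solmajer sigmoidal distance-dependent dielectric.
ms_dielectric <- function(r) {
  -8.5525 + 86.9525 / (1 + 7.7839 * exp(-0.003627 * 86.9525 * r))
}

## Polar hydrogens: H bonded to N or O.
polar_h_flags <- function(mol) {
  out <- logical(length(mol$elem))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$is_h[i] && mol$elem[j] %in% c("N", "O")) out[i] <- TRUE
    if (mol$is_h[j] && mol$elem[i] %in% c("N", "O")) out[j] <- TRUE
  }
  out
}

## Static pair-list + coefficient tables for a molecule; computed once.
ligand_energy_spec <- function(mol, cfg = csalign_config()) {
  en <- cfg$energy
  polh <- polar_h_flags(mol)
  sel <- which(!mol$is_h | polh)          # heavy + polar hydrogens
  bd <- bond_distances(mol)
  np <- nb_params(mol$elem)
  acceptor <- mol$elem %in% c("N", "O")
  Si <- np$asp + QASP * abs(mol$charge)

  pi_ <- integer(0); pj_ <- integer(0); is14 <- logical(0)
  if (length(sel) >= 2) {
    cmb <- utils::combn(sel, 2)
    sep <- bd[cbind(cmb[1, ], cmb[2, ])]
    keep <- sep >= 3
    pi_ <- cmb[1, keep]; pj_ <- cmb[2, keep]
    is14 <- sep[keep] == 3
  }
  ishb <- (polh[pi_] & acceptor[pj_]) | (polh[pj_] & acceptor[pi_])
  rm_ <- np$rmin_half[pi_] + np$rmin_half[pj_]
  eps <- sqrt(np$epsilon[pi_] * np$epsilon[pj_])
  ljA <- ifelse(ishb, en$hb_eps * 5 * en$hb_r0^12, eps * rm_^12)
  ljB <- ifelse(ishb, en$hb_eps * 6 * en$hb_r0^10, 2 * eps * rm_^6)
  qqc <- COULOMB_K * mol$charge[pi_] * mol$charge[pj_]
  dsc <- Si[pi_] * np$volume[pj_] + Si[pj_] * np$volume[pi_]

  ## torsional strain parameters per rotatable torsion
  hyb <- atom_hybridization(mol)
  tors <- mol$torsion_tree$torsions
  tV <- tn <- tphase <- tV1 <- numeric(length(tors))
  for (t in seq_along(tors)) {
    a <- tors[[t]]$a; b <- tors[[t]]$b
    if (hyb[a] == 2L && hyb[b] == 2L) {
      tV[t] <- en$torsion_barrier_conj; tn[t] <- 2; tphase[t] <- pi
    } else {
      tV[t] <- en$torsion_barrier_sp3; tn[t] <- 3; tphase[t] <- 0
      tV1[t] <- en$torsion_v1_sp3   # anti < gauche, united-atom convention
    }
  }
  list(pi = as.integer(pi_ - 1L), pj = as.integer(pj_ - 1L),
       ljA = ljA, ljB = ljB, is_hb = ishb, is_14 = is14,
       qqc = qqc, dsc = dsc,
       tV = tV, tn = tn, tphase = tphase, tV1 = tV1,
       Si = Si, Vi = np$volume, polar_h = polh)
}

## Torsional strain from measured dihedrals of the rotatable bonds.
torsion_strain <- function(mol, coords, spec) {
  tors <- mol$torsion_tree$torsions
  if (length(tors) == 0) return(0)
  e <- 0
  for (t in seq_along(tors)) {
    tt <- tors[[t]]
    phi <- cpp_dihedral(coords, tt$p - 1L, tt$a - 1L, tt$b - 1L, tt$q - 1L)
    e <- e + spec$tV[t] / 2 * (1 + cos(spec$tn[t] * phi - spec$tphase[t])) +
      spec$tV1[t] / 2 * (1 + cos(phi))
  }
  e
}

#' Ligand internal energy
#'
#' Computes the per-term energy breakdown of a pose: nonbonded terms over
#' pairs separated by more than three bonds, 1-4 terms over exactly-three-bond
#' pairs (scaled by `w8` in the total), and the torsional bonded term. The
#' total is the weighted sum
#' `w4*vdw + w5*hb + w6*qq + w7*desolv + w8*(...) + w11*bonded`.
#'
#' @param pose a `Pose`
#' @param weights energy weights (see [csalign_config()]`$weights`)
#' @param cfg full configuration (for functional-form constants)
#' @param spec precomputed [ligand_energy_spec()] (recomputed when NULL)
#' @return list of class `EnergyBreakdown` with `terms` and `total` (kcal/mol)
#' @export
ligand_internal_energy <- function(pose, weights = csalign_config()$weights,
                                   cfg = csalign_config(), spec = NULL) {
  mol <- pose$mol
  if (is.null(spec)) spec <- ligand_energy_spec(mol, cfg)
  sums <- cpp_pair_energy(pose$coords, spec$pi, spec$pj, spec$ljA, spec$ljB,
                          spec$is_hb, spec$is_14, spec$qqc, spec$dsc)
  bonded <- torsion_strain(mol, pose$coords, spec)
  terms <- c(vdw_L = sums[1], hb_L = sums[2], qq_L = sums[3],
             desolv_L = sums[4],
             vdw_14 = sums[5], hb_14 = sums[6], qq_14 = sums[7],
             desolv_14 = sums[8], bonded_L = bonded)
  w <- weights
  total <- w$w4 * terms["vdw_L"] + w$w5 * terms["hb_L"] +
    w$w6 * terms["qq_L"] + w$w7 * terms["desolv_L"] +
    w$w8 * (w$w4 * terms["vdw_14"] + w$w5 * terms["hb_14"] +
            w$w6 * terms["qq_14"] + w$w7 * terms["desolv_14"]) +
    w$w11 * terms["bonded_L"]
  structure(list(terms = terms, total = unname(total)),
            class = "EnergyBreakdown")
}

#' Register a knowledge-based energy hook
#'
#' The hydrophobic-match (`"HM"`) and pair-potential (`"DS"`) protein-ligand
#' terms are pluggable: their published parameter tables are not shipped, so
#' both default to zero (weights `w9`, `w10` are 0 as well). A registered
#' hook is called as `fn(pose, protein)` and must return kcal/mol.
#'
#' @param name `"HM"` or `"DS"`
#' @param fn function or NULL to unregister
#' @export
register_energy_hook <- function(name = c("HM", "DS"), fn) {
  name <- match.arg(name)
  if (is.null(.csalign_env$hooks)) .csalign_env$hooks <- list()
  .csalign_env$hooks[[name]] <- fn
  invisible(NULL)
}

energy_hook_value <- function(name, pose, prot) {
  h <- .csalign_env$hooks[[name]]
  if (is.null(h)) 0 else h(pose, prot)
}
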