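## End-to-end protocols: compound-to-compound alignment and alignment-based
## docking, plus report evaluation and output writing.

#' Align a query compound to a reference compound structure
#'
#' Globally optimizes the alignment energy (shape-match score combined with
#' the ligand internal energy) over the query's translational, rotational,
#' torsional and ring-state degrees of freedom with CSA. Returns the final
#' bank of 30 poses, ranked.
#'
#' @param query a `Molecule`
#' @param reference a `Pose` or `Molecule` (the reference 3D structure)
#' @param cfg configuration ([csalign_config()])
#' @param crystal optional crystal `Pose` of the query for per-pose RMSD
#' @return an `AlignmentReport`: ranked `poses`, summary `table`, run info
#' @export
csalign <- function(query, reference, cfg = csalign_config(),
                    crystal = NULL) {
  if (inherits(reference, "Molecule")) reference <- new_pose(reference)
  res <- run_csa(query, reference, mode = "csalign", cfg = cfg)
  build_report(query, reference, res, mode = "csalign", crystal = crystal,
               cfg = cfg)
}

#' Dock a query compound by alignment to a reference complex
#'
#' Same CSA machinery as [csalign()] with the docking objective: the energy
#' adds grid-interpolated protein-ligand interaction terms (cofactors inside
#' the box count as receptor). The docking box is cubic (default edge
#' 22.5 Angstrom) centered on the reference ligand's geometric center.
#'
#' @param query a `Molecule`
#' @param protein a `ProteinStructure`
#' @param ref_ligand reference ligand `Pose` (defines the box center)
#' @param cfg configuration
#' @param crystal optional crystal `Pose` of the query
#' @param grid optional prebuilt `ReceptorGrid` (built here when NULL)
#' @return an `AlignmentReport` with protein-ligand energies
#' @export
csalign_dock <- function(query, protein, ref_ligand, cfg = csalign_config(),
                         crystal = NULL, grid = NULL) {
  if (inherits(ref_ligand, "Molecule")) ref_ligand <- new_pose(ref_ligand)
  center <- colMeans(ref_ligand$coords[heavy_idx(ref_ligand$mol), ,
                                       drop = FALSE])
  edge <- cfg$dock$box_edge
  ext <- max(apply(query$coords[heavy_idx(query), , drop = FALSE], 2,
                   function(v) diff(range(v))))
  if (ext > edge) {
    if (isTRUE(cfg$dock$enlarge_box)) {
      edge <- ceiling(ext + 4)
      warning("ligand extent exceeds the box; box enlarged to ", edge, " A")
    } else {
      warning("ligand extent (", round(ext, 1),
              " A) exceeds the box edge; out-of-box poses are penalized")
    }
  }
  if (is.null(grid)) {
    spec <- ligand_energy_spec(query, cfg)
    classes <- unique(c(grid_atom_class(query$elem, spec$polar_h), "C"))
    grid <- build_receptor_grid(protein, center, edge = edge,
                                spacing = cfg$dock$grid_spacing,
                                classes = classes, cfg = cfg)
  }
  res <- run_csa(query, ref_ligand, mode = "csalign_dock", grid = grid,
                 cfg = cfg)
  build_report(query, ref_ligand, res, mode = "csalign_dock",
               crystal = crystal, cfg = cfg, grid = grid, protein = protein)
}

build_report <- function(query, reference, res, mode, crystal = NULL,
                         cfg = csalign_config(), grid = NULL,
                         protein = NULL) {
  bank <- res$bank
  tab <- data.frame(
    rank = seq_along(bank),
    Ealign = vapply(bank, function(m) m$objective, 1.0),
    Sshape = vapply(bank, function(m) m$shape, 1.0),
    Energy = vapply(bank, function(m) m$energy, 1.0))
  if (!is.null(crystal)) {
    tab$rmsd <- vapply(bank, function(m)
      symmetry_rmsd(query, m$coords, crystal$coords)$rmsd, 1.0)
  }
  structure(list(mode = mode, mol = query, reference = reference,
                 poses = bank, table = tab, history = res$history,
                 grid = grid, protein = protein, cfg = cfg),
            class = "AlignmentReport")
}

#' @export
print.AlignmentReport <- function(x, ...) {
  cat(sprintf("AlignmentReport (%s): %d ranked poses of '%s'\n",
              x$mode, length(x$poses), x$mol$name))
  print(utils::head(x$table, 5), row.names = FALSE)
  if (nrow(x$table) > 5) cat("...\n")
  invisible(x)
}

#' Evaluate an alignment report against a crystal pose
#'
#' Computes the symmetry-aware heavy-atom RMSD of the top-ranked pose and of
#' the best pose in the bank, and the success flags at the given cutoffs
#' (defaults 2.0 and 2.5 Angstrom).
#'
#' @param report an `AlignmentReport`
#' @param crystal crystal `Pose` of the same molecule
#' @param cutoffs RMSD success cutoffs in Angstrom
#' @return list with `top1_rmsd`, `best_rmsd`, `best_rank`, and a logical
#'   `success` vector named by cutoff
#' @export
evaluate_against_crystal <- function(report, crystal,
                                     cutoffs = c(2.0, 2.5)) {
  if (length(crystal$mol$elem) != length(report$mol$elem) ||
      any(crystal$mol$elem != report$mol$elem))
    stop("input error: crystal pose is a different molecule")
  rmsds <- vapply(report$poses, function(m)
    symmetry_rmsd(report$mol, m$coords, crystal$coords)$rmsd, 1.0)
  top1 <- rmsds[1]
  best <- min(rmsds)
  succ <- stats::setNames(top1 < cutoffs, paste0("<", cutoffs, "A"))
  list(top1_rmsd = top1, best_rmsd = best, best_rank = which.min(rmsds),
       success = succ, all_rmsd = rmsds)
}

#' Write an alignment report as a multi-record SDF
#'
#' One record per ranked pose with `<Ealign>`, `<Sshape>`, `<Energy>` and
#' `<Rank>` data tags.
#'
#' @param report an `AlignmentReport`
#' @param path output SDF path
#' @export
write_report <- function(report, path) {
  write_molecule(report$mol, path,
                 coords_list = lapply(report$poses, function(m) m$coords),
                 scores = report$table)
}
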