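#' Default run configuration
#'
#' One nested list drives every stage: shape-score parameters, energy weights,
#' CSA schedule, sampling, and docking-box defaults. Every value can be
#' overridden programmatically (`csalign_config(csa = list(n_iter = 20))`) or
#' from a YAML file via [read_config()].
#'
#' Key defaults and their provenance:
#' \itemize{
#'   \item `shape$radius_scale = 0.8` and `shape$cross_type_factor = 0.7`:
#'     the published shape-score constants (vdW radii scaled to emphasize core
#'     overlap; overlap between atoms of different type penalized).
#'   \item `weights`: the docking-energy term weights. The trained values of
#'     the original scoring function are not public; the shipped defaults are
#'     unit weights for the physics terms, 0 for the 1-4 scaling (a plain
#'     12-6 without dedicated 1-4 parameters over-repels at 1-4 distances, so
#'     the default follows the AutoDock4 convention of excluding them), and 0
#'     for the knowledge-based hydrophobic-match and pair-potential hooks,
#'     which are pluggable.
#'   \item `csa`: bank of 30, 50 iterations of 20 trials, early stop after 10
#'     improvement-free iterations, d-cut annealed from D_avg/2 to D_avg/5 by
#'     half the budget.
#'   \item `dock$box_edge = 22.5` A cubic box centered on the reference-ligand
#'     geometric center; `grid_spacing = 0.375` A.
#' }
#'
#' @param ... named overrides; nested lists are merged recursively
#' @return a list of class `csalign_config`
#' @export
csalign_config <- function(...) {
  base <- list(
    shape = list(
      radius_scale = 0.8,
      cross_type_factor = 0.7,
      heavy_atoms_only = TRUE,
      s_floor = 1e-6
    ),
    weights = list(
      w1 = 1, w2 = 1, w3 = 1,          # PL: hb, qq, desolv (vdw unweighted)
      w4 = 0.5, w5 = 0.5, w6 = 0.5, w7 = 0.5,  # L: vdw, hb, qq, desolv;
                # 0.5 keeps the internal nonbonded terms from outvoting the
                # shape match between conformers (calibrated on the synthetic
                # self-alignment/self-docking benchmarks, see vignette)
      w8 = 0,   # 1-4 nonbonded off by default: the plain 12-6 over-repels
                # at 1-4 range without special 1-4 parameters (AutoDock4
                # convention); torsional preference lives in the bonded term
      w9 = 0, w10 = 0,                 # HM / DS hooks (off by default)
      w11 = 1                          # ligand bonded (torsional strain)
    ),
    energy = list(
      nb_cutoff = 8.0,
      hb_r0 = 1.9, hb_eps = 5.0,
      torsion_barrier_sp3 = 3.0,       # kcal/mol, 3-fold
      torsion_v1_sp3 = 0.7,            # kcal/mol, 1-fold anti preference:
                                       # united-atom stand-in for the H-H
                                       # gauche repulsion heavy-atom models miss
      torsion_barrier_conj = 10.0,     # kcal/mol, 2-fold
      exclude_amide_torsions = TRUE,
      out_of_box_k = 10.0              # kcal/mol/A^2 quadratic wall
    ),
    sampling = list(
      rt = 0.593,                      # kcal/mol, 300 K
      p_ring = 0.3,
      mutation_magnitude = pi / 3,
      ring_embeddings = 200,
      ring_seed = 20201126L
    ),
    csa = list(
      bank_size = 30L,
      n_init_random = 30L,
      n_align_per_conf = 5L,
      n_iter = 50L,
      n_trials = 20L,
      early_stop = 10L,
      p_mutation = 0.4,
      minimize_maxit = 200L,
      dcut_init_frac = 0.5,            # D_avg/2
      dcut_floor_frac = 0.2            # D_avg/5
    ),
    rigidalign = list(
      k_alignments = 5L,
      top_m_pairs = 10L,
      triangle_tol = 1.0,              # A, mapped side-length difference
      dedup_rmsd = 0.25                # A, induced RMSD between transforms
    ),
    rmsd = list(
      automorphism_cap = 10000L
    ),
    dock = list(
      box_edge = 22.5,
      grid_spacing = 0.375,
      enlarge_box = FALSE
    ),
    seed = 1L,
    verbose = FALSE
  )
  modifyList(structure(base, class = "csalign_config"), list(...))
}

#' Read a YAML configuration file
#'
#' Values found in the file override the package defaults; everything else
#' keeps its default.
#'
#' @param path YAML file
#' @return a `csalign_config` list
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- csalign_config()
  utils::modifyList(cfg, user)
}
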