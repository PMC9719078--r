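## Parameter tables shipped as plain-text TSVs under inst/extdata.
## Loaded once per session into the package environment.

.csalign_env <- new.env(parent = emptyenv())

read_param_table <- function(name) {
  path <- system.file("extdata", name, package = "csalign")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

param_tables <- function() {
  if (is.null(.csalign_env$params)) {
    .csalign_env$params <- list(
      vdw    = read_param_table("vdw_radii.tsv"),
      nb     = read_param_table("nonbonded_params.tsv"),
      peoe   = read_param_table("gasteiger_params.tsv")
    )
  }
  .csalign_env$params
}

#' Van der Waals radius lookup
#'
#' Per-element radii from a single fixed table (Bondi 1964) shipped with the
#' package; unparameterized elements fall back to the carbon radius with a
#' warning.
#'
#' @param elements character vector of element symbols
#' @return numeric vector of radii in Angstrom
#' @export
vdw_radius <- function(elements) {
  tab <- param_tables()$vdw
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    warning("no vdW radius for element(s): ",
            paste(unique(elements[is.na(idx)]), collapse = ", "),
            "; using generic 1.70 A")
  }
  r <- tab$radius[idx]
  r[is.na(r)] <- 1.70
  r
}

## Lennard-Jones / desolvation parameters by element (AutoDock4-flavoured).
nb_params <- function(elements) {
  tab <- param_tables()$nb
  idx <- match(elements, tab$element)
  out <- tab[ifelse(is.na(idx), match("C", tab$element), idx), , drop = FALSE]
  if (anyNA(idx)) {
    warning("no nonbonded parameters for element(s): ",
            paste(unique(elements[is.na(idx)]), collapse = ", "),
            "; using carbon parameters")
  }
  rownames(out) <- NULL
  out
}
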