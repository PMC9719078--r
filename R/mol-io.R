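## Ligand and receptor file I/O. ChemmineR carries the SDF format, bio3d
## carries MOL2 and PDB; perception on top is ours.

#' Read a small molecule from SDF or MOL2
#'
#' Parses the connection table, checks that 3D coordinates are present and
#' runs full perception ([new_molecule()]). Formal charges are taken from
#' `M  CHG` lines (SDF) or summed partial charges (MOL2).
#'
#' @param path input file
#' @param format `"sdf"` or `"mol2"`; guessed from the extension by default
#' @return a `Molecule`
#' @export
read_molecule <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  if (format == "sdf") read_molecule_sdf(path) else read_molecule_mol2(path)
}

read_molecule_sdf <- function(path) {
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("SDF parse failure: ",
                                              conditionMessage(e)))
  if (length(sdfset) == 0) stop("SDF parse failure: no records in ", path)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  hdr <- ChemmineR::header(sdf)
  if (length(hdr) >= 2 && grepl("2D", hdr[2], fixed = TRUE))
    stop("input error: 2D coordinates (no 3D structure) in ", path)
  if (nrow(coords) > 4 && all(coords[, 3] == 0))
    stop("input error: flat z = 0 coordinates suggest a 2D structure in ", path)
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  formal <- sdf_formal_charges(path, length(elem))
  new_molecule(elem, coords, bonds,
               name = ChemmineR::sdfid(sdfset)[1], formal = formal)
}

## M  CHG lines of the first record (ChemmineR does not surface them).
sdf_formal_charges <- function(path, n_atoms) {
  lines <- readLines(path, warn = FALSE)
  end <- grep("^\\$\\$\\$\\$", lines)[1]
  if (!is.na(end)) lines <- lines[seq_len(end)]
  formal <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- scan(text = sub("^M  CHG", "", ln), quiet = TRUE)
    k <- f[1]
    for (m in seq_len(k)) {
      formal[f[2 * m]] <- as.integer(f[2 * m + 1])
    }
  }
  formal
}

read_molecule_mol2 <- function(path) {
  m2 <- tryCatch(bio3d::read.mol2(path),
                 error = function(e) stop("MOL2 parse failure: ",
                                          conditionMessage(e)))
  at <- m2$atom
  elem <- sub("\\..*$", "", at$elety)
  coords <- as.matrix(at[, c("x", "y", "z")])
  if (nrow(coords) > 4 && all(coords[, 3] == 0))
    stop("input error: flat z = 0 coordinates suggest a 2D structure in ", path)
  btype <- as.character(m2$bond$type)
  order <- ifelse(btype == "ar", 4L,
           ifelse(btype %in% c("am", "un", "nc", "du"), 1L,
                  suppressWarnings(as.integer(btype))))
  order[is.na(order)] <- 1L
  bonds <- data.frame(i = as.integer(m2$bond$origin),
                      j = as.integer(m2$bond$target), order = order)
  total_q <- round(sum(at$charge))
  formal <- integer(length(elem))
  if (length(formal) > 0) formal[1] <- as.integer(total_q)
  mol <- new_molecule(elem, coords, bonds,
                      name = if (!is.null(m2$name)) m2$name else basename(path),
                      formal = formal)
  mol
}

#' Write one or more poses as a multi-record SDF
#'
#' Each record carries the molecule's connection table with the pose's
#' coordinates and optional score fields as SDF data tags
#' (`<Ealign>`, `<Sshape>`, `<Energy>`, `<Rank>`).
#'
#' @param mol the `Molecule` (topology source)
#' @param path output file
#' @param coords_list list of N x 3 matrices; defaults to the molecule's own
#' @param scores optional data.frame with columns `Ealign`, `Sshape`,
#'   `Energy` (one row per record)
#' @export
write_molecule <- function(mol, path, coords_list = NULL, scores = NULL) {
  if (is.null(coords_list)) coords_list <- list(mol$coords)
  n <- length(mol$elem)
  nb <- nrow(mol$bonds)
  sdfs <- vector("list", length(coords_list))
  for (r in seq_along(coords_list)) {
    xyz <- coords_list[[r]]
    ab <- cbind(xyz, matrix(0, n, 13))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
    rownames(ab) <- paste(mol$elem, seq_len(n), sep = "_")
    bb <- cbind(mol$bonds$i, mol$bonds$j, mol$bonds$order, 0)
    colnames(bb) <- c("C1", "C2", "C3", "C4")
    rownames(bb) <- seq_len(nb)
    hdr <- c(Molecule_Name = mol$name, Source = "  csalign",
             Comment = "",
             Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                   n, nb))
    datab <- character(0)
    if (!is.null(scores)) {
      row <- scores[r, , drop = FALSE]
      datab <- c(Ealign = sprintf("%.6f", row$Ealign),
                 Sshape = sprintf("%.6f", row$Sshape),
                 Energy = sprintf("%.6f", row$Energy),
                 Rank = as.character(r))
    }
    sdfs[[r]] <- methods::new(
      methods::getClass("SDF", where = asNamespace("ChemmineR")),
      header = hdr, atomblock = ab, bondblock = bb, datablock = datab)
  }
  sdfset <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = sdfs, ID = paste0(mol$name, "_", seq_along(sdfs)))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Read a receptor structure from PDB
#'
#' Keeps the highest-occupancy alternate location per atom, drops waters,
#' assigns elements and coarse per-element partial charges, and flags HETATM
#' groups as cofactors unless their residue name matches
#' `reference_ligand_resid` (the reference ligand supplied by the caller,
#' which is handled separately).
#'
#' @param path PDB file
#' @param reference_ligand_resid residue name(s) of the reference ligand to
#'   exclude from the cofactor set
#' @return a `ProteinStructure`
#' @export
read_protein <- function(path, reference_ligand_resid = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_pdb_records(path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE)),
                  error = function(e) stop("PDB parse failure: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  ## alternate locations: keep the highest occupancy per atom site
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- !logical(nrow(at))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    best <- rows[which.max(occ[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[0-9 ]", "", at$elety[miss]), 1, 1)
  new_protein(
    elem = elem,
    coords = as.matrix(at[, c("x", "y", "z")]),
    resid = at$resid, resno = at$resno, chain = at$chain,
    is_cofactor = at$type == "HETATM" &
      !(at$resid %in% reference_ligand_resid),
    name = basename(path))
}

check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("PDB format error at line %d: unreadable coordinates", i))
  }
  invisible(TRUE)
}

#' Construct a ProteinStructure
#'
#' Rigid receptor atoms (optionally including cofactor atoms) with element,
#' atom-type label and partial charge. Charges default to a coarse
#' per-element scheme adequate for the grid electrostatics of toy systems.
#'
#' @param elem element symbols
#' @param coords N x 3 coordinates (Angstrom)
#' @param charge partial charges; per-element defaults when NULL
#' @param resid,resno,chain residue annotation
#' @param is_cofactor logical cofactor flags
#' @param name identifier
#' @return an object of class `ProteinStructure`
#' @export
new_protein <- function(elem, coords, charge = NULL, resid = "UNK",
                        resno = 1L, chain = "A", is_cofactor = FALSE,
                        name = "protein") {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite receptor coordinates")
  n <- length(elem)
  if (is.null(charge)) {
    defaults <- c(C = 0.0, N = -0.35, O = -0.40, S = -0.15, H = 0.15,
                  P = 0.40)
    charge <- unname(defaults[elem])
    charge[is.na(charge)] <- 0
  }
  structure(list(
    name = name, elem = elem, coords = coords,
    charge = as.numeric(charge), atype = elem,
    resid = rep_len(resid, n), resno = rep_len(as.integer(resno), n),
    chain = rep_len(chain, n),
    is_cofactor = rep_len(is_cofactor, n)
  ), class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("ProteinStructure '%s': %d atoms, %d residues, %d cofactor group(s)\n",
              x$name, length(x$elem),
              length(unique(paste(x$chain, x$resno)[!x$is_cofactor])),
              length(unique(paste(x$chain, x$resno)[x$is_cofactor]))))
  invisible(x)
}
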