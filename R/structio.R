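#' Bondi van der Waals radii
#'
#' Standard Bondi (1964) van der Waals radii for the elements that occur in
#' protein structures, in Angstroms. Used by [assign_radii()].
#'
#' @return Named numeric vector of radii (Angstrom), names are element symbols.
#' @export
bondi_radii <- function() {
  c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    Ne = 1.54, Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80,
    Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31, Ni = 1.63, Cu = 1.40,
    Zn = 1.39, Se = 1.90, Br = 1.85, I = 1.98, Fe = 2.00, Mn = 2.00)
}

#' Residue polarity classes
#'
#' The druggability criterion counts "polar residues" lining a pocket.  The
#' default classification is: polar = SER, THR, ASN, GLN, TYR, CYS, HIS, TRP;
#' charged = ASP, GLU, LYS, ARG; all remaining standard residues nonpolar.
#' The pocket polar-residue count treats polar and charged residues alike
#' (both can hydrogen-bond a ligand); both sets are configurable.
#'
#' @return Named list with character vectors `polar`, `charged`, `nonpolar`.
#' @export
residue_polarity_sets <- function() {
  list(
    polar    = c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS", "TRP"),
    charged  = c("ASP", "GLU", "LYS", "ARG"),
    nonpolar = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET")
  )
}

#' Classify a residue's side-chain chemistry
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @param sets Polarity classification, as from [residue_polarity_sets()].
#' @return Character vector with values "polar", "charged" or "nonpolar".
#'   Unknown residue names map to "nonpolar" with a warning.
#' @examples
#' classify_residue_polarity(c("SER", "LEU", "ASP"))
#' @export
classify_residue_polarity <- function(residue_name, sets = residue_polarity_sets()) {
  residue_name <- toupper(residue_name)
  out <- rep("nonpolar", length(residue_name))
  out[residue_name %in% sets$polar] <- "polar"
  out[residue_name %in% sets$charged] <- "charged"
  known <- c(sets$polar, sets$charged, sets$nonpolar)
  unk <- setdiff(unique(residue_name), known)
  if (length(unk) > 0) {
    warning("unknown residue name(s) classified nonpolar: ",
            paste(unk, collapse = ", "))
  }
  out
}

new_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "element", "x", "y", "z", "radius",
              "residue_name", "residue_seq", "chain_id", "is_heteroatom")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("empty structure: no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates")
  }
  structure(list(atoms = atoms, id = id), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d atoms, %d residues, chains: %s\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_seq))),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records from PDB-format text (via bio3d).  By default
#' heteroatoms (including waters) and hydrogens are excluded, only the first
#' MODEL is kept, and for alternate-location atoms the highest-occupancy
#' conformer is retained (ties broken by altloc letter order).
#'
#' @param path Path to a PDB-format text file.
#' @param model_policy "first" (default) keeps only the first MODEL.
#' @param keep_hetero Keep HETATM records (waters are always dropped).
#' @param keep_hydrogens Keep hydrogen atoms.
#' @param radii_table Named per-element van der Waals radii used to assign
#'   atomic radii; see [assign_radii()].
#' @return A `structure3d` object: a list with an `atoms` data frame
#'   (serial, element, x, y, z, radius, residue_name, residue_seq, chain_id,
#'   is_heteroatom) and an `id`.
#' @export
read_structure <- function(path, model_policy = c("first", "all"),
                           keep_hetero = FALSE, keep_hydrogens = FALSE,
                           radii_table = bondi_radii()) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (model_policy == "all"),
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  # bio3d with multi=FALSE already returns first-model atoms only
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  element <- at$elesy
  blank <- is.na(element) | element == ""
  if (any(blank)) element[blank] <- guess_element(at$elety[blank])
  element <- normalise_element(element)
  if (!keep_hydrogens) {
    keep <- element != "H"
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }
  if (nrow(at) == 0) stop("empty structure: no protein atoms in ", path)
  atoms <- data.frame(
    serial = at$eleno, element = element,
    x = at$x, y = at$y, z = at$z, radius = NA_real_,
    residue_name = at$resid, residue_seq = at$resno,
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    is_heteroatom = at$type == "HETATM",
    atom_name = at$elety,
    stringsAsFactors = FALSE
  )
  # altloc resolution: highest occupancy wins, ties by altloc letter order
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
    ord <- order(key, -occ, ifelse(is.na(alt) | alt == "", " ", alt))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain_id, atoms$residue_seq,
                                     atoms$atom_name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  s <- new_structure(atoms, id = sub("\\.pdb$", "", basename(path)))
  assign_radii(s, radii_table)
}

guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
         two, one)
}

normalise_element <- function(element) {
  e <- toupper(trimws(element))
  # canonical capitalisation: first letter upper, rest lower
  paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
}

#' Assign van der Waals radii to a structure's atoms
#'
#' Idempotent: radii are looked up from the table each time.  Elements not
#' in the table receive `default_radius` with a warning.
#'
#' @param structure A `structure3d`.
#' @param radii_table Named numeric vector, element symbol -> radius in
#'   Angstrom (default: Bondi set).
#' @param default_radius Radius for unlisted elements (default 1.50).
#' @return The structure with `atoms$radius` filled in.
#' @export
assign_radii <- function(structure, radii_table = bondi_radii(),
                         default_radius = 1.50) {
  el <- structure$atoms$element
  r <- unname(radii_table[el])
  if (anyNA(r)) {
    unk <- unique(el[is.na(r)])
    warning("no tabulated radius for element(s) ",
            paste(unk, collapse = ", "), "; using default ",
            default_radius, " Angstrom")
    r[is.na(r)] <- default_radius
  }
  structure$atoms$radius <- r
  structure
}

#' Write a structure to PDB-format text
#'
#' Fixed-width ATOM/HETATM records; coordinates to 3 decimals.  Round-trips
#' with [read_structure()].
#'
#' @param structure A `structure3d`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  name <- if ("atom_name" %in% names(a)) a$atom_name else a$element
  # PDB atom-name column convention: element right-justified in cols 13-14
  fmt_name <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name),
                     substr(name, 1, 4))
  rec <- ifelse(a$is_heteroatom, "HETATM", "ATOM  ")
  lines <- sprintf(
    "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$serial, fmt_name, a$residue_name, a$chain_id, a$residue_seq,
    a$x, a$y, a$z, 1.00, 0.00, toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
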