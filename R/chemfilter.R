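# Drug-likeness descriptors and the oral-therapeutic property filter.
#
# SMILES parsing and the MW / TPSA (Ertl fragment scheme) descriptors are
# delegated to OpenBabel via ChemmineR/ChemmineOB.  Hydrogen-bond counts
# follow the Lipinski convention: donors are N-H and O-H hydrogens
# (counted on the explicit-hydrogen molecular graph), acceptors are the
# nitrogen and oxygen atom count.

#' Compute drug-likeness descriptors for SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @param compound_id Optional ids (default CPD-001, ...).
#' @return Data frame: compound_id, smiles, mw (g/mol), tpsa (Angstrom^2),
#'   hbd, hba.  Unparseable SMILES raise an error naming the offender.
#' @examples
#' \dontrun{compute_descriptors("CCO")  # mw 46.07, tpsa 20.23, hbd 1, hba 1}
#' @export
compute_descriptors <- function(smiles,
                                compound_id = sprintf("CPD-%03d",
                                                      seq_along(smiles))) {
  stopifnot(length(smiles) >= 1, length(compound_id) == length(smiles))
  names(smiles) <- compound_id
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("SMILES parse error: ", conditionMessage(e))
  )
  natoms <- vapply(ChemmineR::atomcount(sdf), sum, numeric(1))
  if (any(natoms == 0)) {
    bad <- smiles[natoms == 0]
    stop("SMILES parse error: unparseable input '", bad[1], "'")
  }
  props <- ChemmineR::propOB(sdf)
  counts <- ChemmineR::atomcount(sdf)
  hba <- vapply(counts, function(ct) {
    sum(ct[names(ct) %in% c("N", "O")])
  }, numeric(1))
  hbd <- count_donor_hydrogens(smiles)
  data.frame(compound_id = compound_id, smiles = unname(smiles),
             mw = props$MW, tpsa = props$TPSA, hbd = hbd, hba = unname(hba),
             stringsAsFactors = FALSE)
}

# Lipinski donors: hydrogens bonded to N or O, counted on the
# explicit-hydrogen molecular graph produced by OpenBabel.
count_donor_hydrogens <- function(smiles) {
  txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(paste(smiles, collapse = "\n"), "\n"),
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
  sdfset <- ChemmineR::read.SDFset(
    ChemmineR::read.SDFstr(strsplit(txt, "\n", fixed = TRUE)[[1]]))
  vapply(ChemmineR::cid(sdfset), function(id) {
    mol <- sdfset[[id]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    el <- sub("_.*", "", rownames(ab))
    if (is.null(bb) || nrow(bb) == 0) return(0)
    i <- bb[, 1]; j <- bb[, 2]
    sum((el[i] == "H" & el[j] %in% c("N", "O")) |
          (el[j] == "H" & el[i] %in% c("N", "O")))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Apply the oral drug-likeness property filter
#'
#' Pass criteria: molecular weight between `mw_range[1]` and `mw_range[2]`
#' g/mol inclusive, TPSA strictly below `tpsa_max` Angstrom^2, fewer than
#' `hbd_max` donors and fewer than `hba_max` acceptors (bounds mirror the
#' screening filter: MW 160-480 inclusive, TPSA < 140, HBD < 5, HBA < 10).
#' Every failing criterion is recorded.
#'
#' @param records Data frame from [compute_descriptors()].
#' @param mw_range Inclusive molecular-weight window, g/mol.
#' @param tpsa_max Strict TPSA upper bound, Angstrom^2.
#' @param hbd_max Strict donor-count upper bound.
#' @param hba_max Strict acceptor-count upper bound.
#' @return `records` with `passes_filter` (logical) and `fail_reasons`
#'   (comma-joined among mw, tpsa, hbd, hba; "" when passing).
#' @export
apply_property_filter <- function(records, mw_range = c(160, 480),
                                  tpsa_max = 140, hbd_max = 5,
                                  hba_max = 10) {
  stopifnot(all(c("mw", "tpsa", "hbd", "hba") %in% names(records)))
  fails <- cbind(
    mw = records$mw < mw_range[1] | records$mw > mw_range[2],
    tpsa = records$tpsa >= tpsa_max,
    hbd = records$hbd >= hbd_max,
    hba = records$hba >= hba_max
  )
  records$passes_filter <- rowSums(fails) == 0
  records$fail_reasons <- apply(fails, 1, function(f) {
    paste(colnames(fails)[f], collapse = ",")
  })
  records
}

#' Read a SMILES library file
#'
#' One compound per line: SMILES optionally followed by whitespace and an
#' id.  Blank lines and lines starting with '#' are skipped.
#'
#' @param path File path.
#' @return Data frame: compound_id, smiles.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty SMILES file: ", path)
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("CPD-%03d", i)
  }, character(1))
  data.frame(compound_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Descriptor + filter pipeline for a compound library
#'
#' @param library Data frame with `compound_id` and `smiles` (e.g. from
#'   [read_smiles_file()] or [make_compound_library()]), or a character
#'   vector of SMILES.
#' @param ... Passed to [apply_property_filter()].
#' @return Data frame of descriptors with filter verdicts.
#' @export
filter_library <- function(library, ...) {
  if (is.character(library)) {
    library <- data.frame(compound_id = sprintf("CPD-%03d", seq_along(library)),
                          smiles = library, stringsAsFactors = FALSE)
  }
  rec <- compute_descriptors(library$smiles, library$compound_id)
  apply_property_filter(rec, ...)
}
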