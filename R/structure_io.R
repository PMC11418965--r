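# Atomic structure input (PDB / mmCIF via bio3d) and the element table.

.ELEMENTS <- c(
  "H" = 1, "D" = 1, "HE" = 2, "LI" = 3, "BE" = 4, "B" = 5, "C" = 6,
  "N" = 7, "O" = 8, "F" = 9, "NE" = 10, "NA" = 11, "MG" = 12, "AL" = 13,
  "SI" = 14, "P" = 15, "S" = 16, "CL" = 17, "AR" = 18, "K" = 19,
  "CA" = 20, "SC" = 21, "TI" = 22, "V" = 23, "CR" = 24, "MN" = 25,
  "FE" = 26, "CO" = 27, "NI" = 28, "CU" = 29, "ZN" = 30, "GA" = 31,
  "GE" = 32, "AS" = 33, "SE" = 34, "BR" = 35, "KR" = 36, "RB" = 37,
  "SR" = 38, "Y" = 39, "ZR" = 40, "MO" = 42, "RU" = 44, "RH" = 45,
  "PD" = 46, "AG" = 47, "CD" = 48, "IN" = 49, "SN" = 50, "SB" = 51,
  "TE" = 52, "I" = 53, "XE" = 54, "CS" = 55, "BA" = 56, "W" = 74,
  "RE" = 75, "OS" = 76, "IR" = 77, "PT" = 78, "AU" = 79, "HG" = 80,
  "TL" = 81, "PB" = 82, "U" = 92)

#' Element symbol to atomic number
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return Integer atomic numbers; errors on unknown symbols.
#' @export
elementToZ <- function(element) {
  z <- .ELEMENTS[toupper(trimws(element))]
  if (any(is.na(z)))
    stop("unresolvable element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  as.integer(z)
}

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses the file with bio3d (`read.pdb`/`read.cif`, chosen by extension),
#' resolves alternate conformers to the highest-occupancy one (ties go to
#' the first altloc in file order), derives atomic numbers from element
#' symbols, and optionally drops hydrogens and hetero atoms.  Waters are
#' always excluded when `include_hetero` is `FALSE`; when it is `TRUE`,
#' non-water hetero atoms are kept and waters still dropped.
#'
#' @param path a `.pdb` or `.cif`/`.mmcif` file.
#' @param include_hydrogens keep hydrogen (and deuterium) atoms? Default TRUE.
#' @param include_hetero keep non-water HETATM records? Default TRUE.
#' @return An [AtomicStructure-class].
#' @export
readStructure <- function(path, include_hydrogens = TRUE,
                          include_hetero = TRUE) {
  if (!file.exists(path)) stop("structure file does not exist: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- suppressWarnings(suppressMessages(
    if (is_cif) tryCatch(bio3d::read.cif(path, rm.alt = FALSE),
                         error = function(e) bio3d::read.cif(path))
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)))
  at <- pdb$atom
  elesy <- trimws(at$elesy)
  missing_el <- is.na(elesy) | elesy == ""
  if (any(missing_el)) {
    # fall back on the first letter of the atom name, standard PDB practice
    guess <- sub("^[0-9]*", "", trimws(at$elety[missing_el]))
    elesy[missing_el] <- substr(guess, 1, 1)
  }
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  if (!include_hydrogens) keep <- keep & !toupper(elesy) %in% c("H", "D")
  is_water <- toupper(trimws(at$resid)) %in% .WATER_RESID
  keep <- keep & !is_water
  if (!include_hetero) keep <- keep & at$type == "ATOM"
  if (!any(keep)) stop("no atoms selected from ", path)
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]; occ <- occ[keep]

  # altloc resolution: one atom per (chain, resno, insert, atom name),
  # keeping the highest occupancy; ties resolved to the first record.
  alt <- at$alt; alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               trimws(at$elety), sep = "|")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_along(key))
  first_of_key <- !duplicated(key[ord])
  sel <- sort(ord[first_of_key])
  at <- at[sel, , drop = FALSE]
  AtomicStructure(element = elesy[sel],
                  coords = cbind(at$x, at$y, at$z),
                  atomic_number = elementToZ(elesy[sel]),
                  occupancy = occ[sel],
                  id = basename(path))
}

#' Write an AtomicStructure as a minimal PDB file
#'
#' Emits plain ATOM records (one chain, poly-ALA residue naming when no
#' residue bookkeeping is attached) sufficient for round-tripping the
#' package's own fixtures through [readStructure()].
#'
#' @param structure an [AtomicStructure-class].
#' @param path output path.
#' @param atom_names optional atom-name column; defaults to element symbols.
#' @param resno optional residue numbers per atom.
#' @return Invisibly, `path`.
#' @export
writeStructurePDB <- function(structure, path, atom_names = NULL,
                              resno = NULL) {
  n <- nAtoms(structure)
  if (is.null(atom_names)) atom_names <- structure@element
  if (is.null(resno)) resno <- rep(1L, n)
  xyz <- structure@coords
  lines <- sprintf(
    "ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n) %% 100000L, substr(atom_names, 1, 4), resno %% 10000L,
    xyz[, 1], xyz[, 2], xyz[, 3], structure@occupancy, 0,
    toupper(structure@element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
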