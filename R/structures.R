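# Pocket extraction from PDB structures.

# Standard amino-acid residue names used for the default "protein" atom class.
.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP", "TIP3")

# Two-letter element symbols that plausibly appear in HETATM atom names when
# the element column is absent (metals, halogens and the like).
.TWO_LETTER_ELEMENTS <- c(
  "FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI", "CO", "SE",
  "CD", "HG", "PT", "AU", "AG", "MO", "AL", "SI", "AS", "LI", "RB", "CS",
  "SR", "BA", "TL", "PB"
)

#' Read atoms from a PDB structure
#'
#' Parses ATOM/HETATM records into a flat atom table. Element symbols are
#' taken from the element column (PDB columns 77-78) when present, otherwise
#' inferred from the atom name. When a structure contains alternate locations
#' for the same atom, only the highest-occupancy record is kept (ties resolved
#' in favour of the first record encountered).
#'
#' @param pdb Path to a PDB file, or a character scalar containing PDB text
#'   (detected by the presence of a newline).
#' @return A `structure_atoms` data frame with columns `element` (normalized,
#'   uppercase), `x`, `y`, `z` (orthogonal coordinates, Angstrom), `class`
#'   (one of `"protein"`, `"hetero"`, `"water"`), `resid`, `resno`, `chain`,
#'   `alt` and `occupancy`.
#' @export
read_structure <- function(pdb) {
  stopifnot(is.character(pdb), length(pdb) == 1L)
  path <- pdb
  if (grepl("\n", pdb, fixed = TRUE) || !file.exists(pdb)) {
    if (!grepl("\n", pdb, fixed = TRUE)) {
      stop("PDB file not found: ", pdb)
    }
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
  }
  parsed <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE),
    error = function(e) stop("unparseable PDB input: ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty structure: no ATOM/HETATM records found")
  }

  coords <- as.matrix(at[, c("x", "y", "z")])
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad) > 0L) {
    stop("unparseable coordinates in atom record ", bad[1L])
  }

  element <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  need <- element == ""
  if (any(need)) {
    element[need] <- .infer_element(at$elety[need], at$type[need])
  }
  if (any(element == "")) {
    stop("element symbol missing and not inferable in atom record ",
         which(element == "")[1L])
  }

  resid <- toupper(trimws(at$resid))
  cls <- ifelse(resid %in% .WATER_RESIDUES, "water",
                ifelse(at$type == "ATOM" & resid %in% .STANDARD_AA,
                       "protein", "hetero"))

  occ <- at$o
  occ[is.na(occ)] <- 1

  out <- data.frame(
    element = element,
    name = toupper(trimws(at$elety)),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    class = cls,
    resid = resid,
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occupancy = occ,
    stringsAsFactors = FALSE
  )
  out <- .collapse_altloc(out)
  class(out) <- c("structure_atoms", "data.frame")
  out
}

# Infer an element symbol from a PDB atom name. Protein atom names start with
# the element letter (CA is an alpha carbon, not calcium); two-letter symbols
# are only considered for HETATM records.
.infer_element <- function(name, rectype) {
  name <- toupper(gsub("[^A-Za-z]", "", name))
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- name[i]
    if (nchar(nm) == 0L) {
      out[i] <- ""
    } else if (rectype[i] == "HETATM" && nchar(nm) >= 2L &&
               substr(nm, 1L, 2L) %in% .TWO_LETTER_ELEMENTS) {
      out[i] <- substr(nm, 1L, 2L)
    } else {
      out[i] <- substr(nm, 1L, 1L)
    }
  }
  out
}

# Keep the highest-occupancy alternate-location record per atom site
# (same chain/residue/atom name); ties go to the record that appears first.
.collapse_altloc <- function(at) {
  if (!any(at$alt != "")) {
    return(at)
  }
  key <- paste(at$chain, at$resno, at$resid, at$name, sep = "|")
  ord <- order(-at$occupancy)  # stable: ties keep file order
  keep <- ord[!duplicated(key[ord])]
  out <- at[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pocket center from bound-ligand coordinates
#'
#' The binding-pocket cube is centered at the ligand, taken as the unweighted
#' centroid of the ligand's heavy atoms (hydrogens excluded).
#'
#' @param ligand_atoms A `structure_atoms` table (or any data frame with
#'   `element`, `x`, `y`, `z` columns) holding the ligand atoms.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
pocket_center <- function(ligand_atoms) {
  stopifnot(is.data.frame(ligand_atoms))
  heavy <- ligand_atoms[toupper(ligand_atoms$element) != "H", , drop = FALSE]
  if (nrow(heavy) == 0L) {
    stop("no heavy atoms: cannot define a pocket center")
  }
  c(x = mean(heavy$x), y = mean(heavy$y), z = mean(heavy$z))
}

#' Select protein atoms inside the pocket cube
#'
#' Returns the protein-class atoms lying in the half-open axis-aligned cube
#' `[center - side/2, center + side/2)` on every axis. Water is always
#' excluded; hetero atoms (cofactors, ions) are excluded by default.
#'
#' @param atoms A `structure_atoms` table.
#' @param center Numeric length-3 cube center (Angstrom).
#' @param side Cube side length in Angstrom (default 20).
#' @param include_hetero Include non-water HETATM atoms (default `FALSE`).
#' @return The selected subset, same columns as the input.
#' @export
select_pocket_atoms <- function(atoms, center, side = 20, include_hetero = FALSE) {
  stopifnot(is.data.frame(atoms), length(center) == 3L, is.finite(side), side > 0)
  keep_class <- atoms$class == "protein"
  if (include_hetero) keep_class <- keep_class | atoms$class == "hetero"
  lo <- center - side / 2
  hi <- center + side / 2
  inside <- atoms$x >= lo[1L] & atoms$x < hi[1L] &
            atoms$y >= lo[2L] & atoms$y < hi[2L] &
            atoms$z >= lo[3L] & atoms$z < hi[3L]
  out <- atoms[keep_class & inside, , drop = FALSE]
  class(out) <- c("structure_atoms", "data.frame")
  out
}
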