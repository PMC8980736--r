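# One-hot voxel encoding of a binding pocket.

#' Pocket voxel channel order
#'
#' Channel order of the pocket grid: index 0 marks an empty voxel, indices
#' 1-7 mark the presence of C, O, N, S, P, H and any other element.
#'
#' @return Character vector of length 8.
#' @export
pocket_channels <- function() {
  c("empty", "C", "O", "N", "S", "P", "H", "other")
}

#' Map an element symbol to its pocket grid channel
#'
#' @param element Character vector of normalized (uppercase, trimmed) element
#'   symbols.
#' @return Integer channel indices in 0..7 (0 is reserved for "no atom" and is
#'   never returned here): C=1, O=2, N=3, S=4, P=5, H=6, anything else 7.
#' @export
element_channel <- function(element) {
  element <- toupper(trimws(element))
  if (any(element == "" | is.na(element))) {
    stop("empty element symbol")
  }
  idx <- match(element, c("C", "O", "N", "S", "P", "H"))
  idx[is.na(idx)] <- 7L
  as.integer(idx)
}

#' Voxelize pocket atoms into a one-hot occupancy grid
#'
#' Discretizes the pocket cube into `side/resolution` voxels per axis
#' (10 voxels of 2 Angstrom for the canonical 20 Angstrom cube). Each voxel
#' carries 8 channels; a voxel containing at least one atom of element class
#' k has channel k set to 1 (the element-wise maximum over the one-hot
#' encodings of its atoms) and the "empty" channel cleared, while an
#' unoccupied voxel has only the "empty" channel set.
#'
#' Atoms are binned with half-open intervals: voxel index per axis is
#' `floor((coord - (center - side/2)) / resolution)`.
#'
#' @param atoms A `structure_atoms` table of atoms already restricted to the
#'   cube (see [select_pocket_atoms()]).
#' @param center Numeric length-3 cube center (Angstrom).
#' @param side Cube side length in Angstrom (default 20).
#' @param resolution Voxel edge length in Angstrom (default 2).
#' @return A `pocket_grid`: a `nv x nv x nv x 8` 0/1 array (nv =
#'   `side/resolution`) with attributes `center`, `side` and `resolution`.
#' @export
voxelize <- function(atoms, center, side = 20, resolution = 2) {
  stopifnot(is.data.frame(atoms), length(center) == 3L,
            side > 0, resolution > 0)
  nv <- side / resolution
  if (abs(nv - round(nv)) > 1e-9) {
    stop("side must be an integer multiple of resolution")
  }
  nv <- as.integer(round(nv))
  grid <- array(0, dim = c(nv, nv, nv, 8L))

  if (nrow(atoms) > 0L) {
    lo <- center - side / 2
    ix <- floor((atoms$x - lo[1L]) / resolution)
    iy <- floor((atoms$y - lo[2L]) / resolution)
    iz <- floor((atoms$z - lo[3L]) / resolution)
    out_of_cube <- ix < 0 | ix >= nv | iy < 0 | iy >= nv | iz < 0 | iz >= nv
    if (any(out_of_cube)) {
      stop("atom ", which(out_of_cube)[1L],
           " lies outside the pocket cube; apply select_pocket_atoms() first")
    }
    ch <- element_channel(atoms$element)
    grid[cbind(ix + 1L, iy + 1L, iz + 1L, ch + 1L)] <- 1
  }

  occ_mat <- matrix(grid[, , , 2:8], nrow = nv^3L)
  grid[, , , 1L] <- array(as.numeric(rowSums(occ_mat) == 0), dim = c(nv, nv, nv))

  structure(grid, center = as.numeric(center), side = side,
            resolution = resolution, class = c("pocket_grid", "array"))
}

#' Flatten a pocket grid to the model input vector
#'
#' @param grid A `pocket_grid`.
#' @return Numeric vector of length `prod(dim(grid))` (8000 for the canonical
#'   configuration), in column-major array order.
#' @export
flatten_pocket <- function(grid) {
  stopifnot(inherits(grid, "pocket_grid") || (is.array(grid) && length(dim(grid)) == 4L))
  as.vector(grid)
}

#' @export
print.pocket_grid <- function(x, ...) {
  d <- dim(x)
  occ <- sum(x[, , , 1L] == 0)
  cat(sprintf("pocket_grid: %dx%dx%dx%d, %.0f A cube at (%.2f, %.2f, %.2f), %d occupied voxels\n",
              d[1L], d[2L], d[3L], d[4L], attr(x, "side"),
              attr(x, "center")[1L], attr(x, "center")[2L], attr(x, "center")[3L], occ))
  invisible(x)
}

#' Featurize a protein-ligand PDB complex into a pocket grid
#'
#' Convenience wrapper: reads a structure, derives the pocket center from a
#' bound ligand residue name (or uses an explicit center, e.g. for apo
#' structures), selects protein atoms in the cube and voxelizes them.
#'
#' @param pdb PDB path or text (see [read_structure()]).
#' @param ligand_resname Residue name of the bound ligand used to center the
#'   pocket; ignored when `center` is given.
#' @param center Optional explicit pocket center (length-3, Angstrom).
#' @param side,resolution Cube geometry, see [voxelize()].
#' @param include_hetero Include non-water hetero atoms in the grid.
#' @return A `pocket_grid`.
#' @export
featurize_pocket <- function(pdb, ligand_resname = NULL, center = NULL,
                             side = 20, resolution = 2, include_hetero = FALSE) {
  atoms <- if (inherits(pdb, "structure_atoms")) pdb else read_structure(pdb)
  if (is.null(center)) {
    if (is.null(ligand_resname)) {
      stop("either a ligand residue name or an explicit center is required")
    }
    lig <- atoms[atoms$resid == toupper(ligand_resname), , drop = FALSE]
    if (nrow(lig) == 0L) {
      stop("no atoms with residue name ", ligand_resname)
    }
    center <- pocket_center(lig)
  }
  pocket <- select_pocket_atoms(atoms, center, side = side,
                                include_hetero = include_hetero)
  voxelize(pocket, center, side = side, resolution = resolution)
}
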