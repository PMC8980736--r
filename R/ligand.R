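# Fixed-size topology encoding of small molecules.

#' Construct a molecule graph
#'
#' A heavy-atom-only molecular topology: element symbols plus a bond table.
#' Hydrogens must already be removed.
#'
#' @param elements Character vector of heavy-atom element symbols, in atom
#'   order.
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices), integer `order` (1, 2 or 3) and logical `aromatic`
#'   (aromatic/conjugated flag). May have zero rows.
#' @return A `molecule_graph` object.
#' @export
molecule_graph <- function(elements, bonds = NULL) {
  elements <- toupper(trimws(elements))
  if (length(elements) == 0L) {
    stop("a molecule graph needs at least one heavy atom")
  }
  if (any(elements == "H")) {
    stop("hydrogens must be removed before building a molecule graph")
  }
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = integer(0), aromatic = logical(0))
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order),
                        aromatic = as.logical(bonds$aromatic))
    if (any(bonds$i < 1L | bonds$j < 1L |
            bonds$i > length(elements) | bonds$j > length(elements))) {
      stop("bond indices out of range")
    }
    if (any(bonds$i == bonds$j)) {
      stop("self-bonds are not allowed")
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")])) {
      stop("duplicate bonds between the same atom pair")
    }
    if (any(!bonds$order %in% 1:3)) {
      stop("bond order must be 1, 2 or 3")
    }
  }
  structure(list(elements = elements, bonds = bonds),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph: %d heavy atoms, %d bonds (%d aromatic/conjugated)\n",
              length(x$elements), nrow(x$bonds), sum(x$bonds$aromatic)))
  invisible(x)
}

#' Number of heavy atoms in a molecule graph
#' @param mol A `molecule_graph`.
#' @return Integer count.
#' @export
n_heavy_atoms <- function(mol) length(mol$elements)

#' Parse one SMILES record into a molecule graph
#'
#' Accepts a whitespace-separated line `SMILES [id [logP]]` (ZINC-style).
#' Parsing and aromaticity perception are delegated to Open Babel (via
#' ChemmineOB); hydrogens are not added, and any explicit hydrogens are
#' stripped. Unparseable records are reported via the `status` field rather
#' than raising an error, so that large library streams degrade gracefully.
#'
#' @param line A single SMILES record.
#' @return A list with fields `status` (`"ok"` or `"parse_error"`),
#'   `smiles`, `id`, `logp` (NA when absent), `mol` (a `molecule_graph`, or
#'   `NULL` on failure) and `reason`.
#' @export
parse_smiles <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(fields) == 0L || fields[1L] == "") {
    stop("empty SMILES line")
  }
  smiles <- fields[1L]
  id <- if (length(fields) >= 2L) fields[2L] else NA_character_
  logp <- if (length(fields) >= 3L) suppressWarnings(as.numeric(fields[3L])) else NA_real_

  rec <- list(status = "parse_error", smiles = smiles, id = id, logp = logp,
              mol = NULL, reason = "not parseable")
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", source = paste0(smiles, " mol\n")),
    error = function(e) ""
  )
  if (!nzchar(mol2) || !grepl("@<TRIPOS>ATOM", mol2, fixed = TRUE)) {
    return(rec)
  }
  g <- tryCatch(.mol2_to_graph(mol2), error = function(e) {
    rec$reason <<- conditionMessage(e)
    NULL
  })
  if (is.null(g)) {
    return(rec)
  }
  rec$status <- "ok"
  rec$mol <- g
  rec$reason <- ""
  rec
}

# Convert MOL2 text (one molecule) into a molecule_graph, dropping hydrogens.
.mol2_to_graph <- function(mol2_text) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1L]]
  mol_at <- which(trimws(lines) == "@<TRIPOS>MOLECULE")[1L]
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[mol_at + 2L]),
                                                 "[[:space:]]+")[[1L]]))
  if (length(counts) >= 2L && !is.na(counts[2L]) && counts[2L] == 0L) {
    # bond-free molecule: the bond-table reader cannot represent this, so
    # take the elements straight from the ATOM section
    at_start <- which(trimws(lines) == "@<TRIPOS>ATOM")[1L]
    atom_lines <- lines[(at_start + 1L):(at_start + counts[1L])]
    sybyl <- vapply(strsplit(trimws(atom_lines), "[[:space:]]+"),
                    `[[`, "", 6L)
    element <- toupper(sub("\\..*$", "", sybyl))
    element <- element[element != "H"]
    if (length(element) == 0L) stop("no heavy atoms")
    return(molecule_graph(element, NULL))
  }
  f <- tempfile(fileext = ".mol2")
  on.exit(unlink(f), add = TRUE)
  writeLines(mol2_text, f)
  m <- bio3d::read.mol2(f)
  if (is.null(m$atom) || nrow(m$atom) == 0L) {
    stop("no atoms")
  }
  element <- toupper(sub("\\..*$", "", m$atom$elety))
  keep <- element != "H"
  if (!any(keep)) {
    stop("no heavy atoms")
  }
  newidx <- cumsum(keep)
  bonds <- m$bond
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    bi <- as.integer(bonds$origin)
    bj <- as.integer(bonds$target)
    btype <- tolower(trimws(bonds$type))
    keep_bond <- keep[bi] & keep[bj] & btype != "nc"
    bi <- newidx[bi[keep_bond]]
    bj <- newidx[bj[keep_bond]]
    btype <- btype[keep_bond]
    aromatic <- btype == "ar"
    order <- suppressWarnings(as.integer(btype))
    order[btype == "am"] <- 1L   # amide: single formal order, not aromatic
    order[aromatic] <- 1L        # formal order unused when the flag is set
    if (any(is.na(order))) {
      stop("unsupported MOL2 bond type: ", btype[which(is.na(order))[1L]])
    }
    bonds <- data.frame(i = bi, j = bj, order = order, aromatic = aromatic)
  } else {
    bonds <- NULL
  }
  molecule_graph(element[keep], bonds)
}

#' Read a SMILES library file
#'
#' One molecule per line, `SMILES [id [logP]]`; blank lines and lines starting
#' with `#` are skipped. Each record is parsed independently; failures are
#' kept as flagged records.
#'
#' @param path Path to a `.smi` file.
#' @return A list of [parse_smiles()] records, one per retained line.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    stop("empty SMILES library: ", path)
  }
  recs <- lapply(lines, parse_smiles)
  for (k in seq_along(recs)) {
    if (is.na(recs[[k]]$id)) recs[[k]]$id <- sprintf("mol%06d", k)
  }
  recs
}

#' Ligand atom-type channel order
#' @return Character vector of length 7.
#' @export
ligand_atom_channels <- function() {
  c("none", "C", "N", "O", "F", "S", "other")
}

#' Ligand bond channel order
#' @return Character vector of length 5.
#' @export
ligand_bond_channels <- function() {
  c("none", "single", "double", "triple", "aromatic")
}

#' Map a heavy-atom element to its ligand channel
#'
#' @param element Character vector of element symbols (no hydrogens).
#' @return Integer channels in 1..6: C=1, N=2, O=3, F=4, S=5, other=6.
#'   Channel 0 is reserved for padding rows.
#' @export
atom_channel <- function(element) {
  element <- toupper(trimws(element))
  if (any(element == "" | is.na(element))) {
    stop("empty element symbol")
  }
  if (any(element == "H")) {
    stop("hydrogens must be removed before ligand encoding")
  }
  idx <- match(element, c("C", "N", "O", "F", "S"))
  idx[is.na(idx)] <- 6L
  as.integer(idx)
}

#' Map a bond to its adjacency channel
#'
#' The aromatic/conjugated flag takes precedence over the formal order, since
#' both are merged into a single channel.
#'
#' @param order Integer formal bond order (1, 2 or 3).
#' @param aromatic Logical aromatic/conjugated flag.
#' @return Integer channels in 1..4: single=1, double=2, triple=3,
#'   aromatic/conjugated=4. Channel 0 is reserved for "no bond".
#' @export
bond_channel <- function(order, aromatic = FALSE) {
  out <- ifelse(aromatic, 4L, as.integer(order))
  if (any(is.na(out) | (!aromatic & !order %in% 1:3))) {
    stop("unknown bond order: ", order[which(is.na(out) | !order %in% 1:3)[1L]])
  }
  as.integer(out)
}

#' Total bond order of each atom (or one atom)
#'
#' Sum over incident bonds of the bond's contribution: the formal order for
#' plain bonds, 1.5 for aromatic/conjugated bonds. This is the metric used to
#' decide which atoms to discard when pruning oversized molecules.
#'
#' @param mol A `molecule_graph`.
#' @param atom Optional single atom index; when omitted, the full per-atom
#'   vector is returned.
#' @return Numeric total bond order(s).
#' @export
total_bond_order <- function(mol, atom = NULL) {
  stopifnot(inherits(mol, "molecule_graph"))
  n <- length(mol$elements)
  contrib <- ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
  per_atom <- numeric(n)
  if (nrow(mol$bonds) > 0L) {
    sums_i <- tapply(contrib, mol$bonds$i, sum)
    sums_j <- tapply(contrib, mol$bonds$j, sum)
    per_atom[as.integer(names(sums_i))] <- per_atom[as.integer(names(sums_i))] + sums_i
    per_atom[as.integer(names(sums_j))] <- per_atom[as.integer(names(sums_j))] + sums_j
  }
  if (is.null(atom)) per_atom else {
    stopifnot(atom >= 1L, atom <= n)
    per_atom[atom]
  }
}

#' Prune a molecule to at most `max_atoms` heavy atoms
#'
#' Oversized molecules are reduced by iteratively deleting the atom with the
#' least total bond order (recomputed after every removal; ties broken by the
#' lowest original atom index), together with its bonds. This tends to strip
#' peripheral low-connectivity atoms first and preserve ring systems and
#' other load-bearing topology. Molecules already within the limit are
#' returned unchanged.
#'
#' @param mol A `molecule_graph`.
#' @param max_atoms Maximum heavy-atom count (default 36).
#' @return A `molecule_graph` with `min(n, max_atoms)` atoms. Surviving atoms
#'   keep their relative order; the original indices of the retained atoms are
#'   available in attribute `kept`.
#' @export
prune_ligand <- function(mol, max_atoms = 36L) {
  stopifnot(inherits(mol, "molecule_graph"), max_atoms >= 1L)
  kept <- seq_along(mol$elements)
  cur <- mol
  while (length(cur$elements) > max_atoms) {
    tbo <- total_bond_order(cur)
    victim <- which.min(tbo)  # first minimum = lowest original index
    keep <- setdiff(seq_along(cur$elements), victim)
    remap <- integer(length(cur$elements))
    remap[keep] <- seq_along(keep)
    b <- cur$bonds[cur$bonds$i != victim & cur$bonds$j != victim, , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    cur <- molecule_graph(cur$elements[keep], b)
    kept <- kept[keep]
  }
  attr(cur, "kept") <- kept
  cur
}

#' Encode a molecule graph as fixed-size ligand tensors
#'
#' Produces the `36 x 7` one-hot atom-type matrix and `36 x 36 x 5` one-hot
#' bond-adjacency tensor. Atoms occupy the first `n` rows in graph order;
#' remaining rows are padding ("no atom"), and every pair not joined by a
#' bond -- including the diagonal and all padding pairs -- carries the
#' "no bond" channel.
#'
#' @param mol A `molecule_graph` with at most `max_atoms` heavy atoms (see
#'   [prune_ligand()]).
#' @param max_atoms Encoded size (default 36).
#' @return A `ligand_graph`: list with `atom_types` (`max_atoms x 7`),
#'   `adjacency` (`max_atoms x max_atoms x 5`) and `n_atoms`.
#' @export
encode_ligand <- function(mol, max_atoms = 36L) {
  stopifnot(inherits(mol, "molecule_graph"))
  n <- length(mol$elements)
  if (n > max_atoms) {
    stop("molecule has ", n, " heavy atoms (> ", max_atoms,
         "); apply prune_ligand() first")
  }
  atom_types <- matrix(0, nrow = max_atoms, ncol = 7L,
                       dimnames = list(NULL, ligand_atom_channels()))
  ch <- atom_channel(mol$elements)
  atom_types[cbind(seq_len(n), ch + 1L)] <- 1
  if (n < max_atoms) {
    atom_types[(n + 1L):max_atoms, 1L] <- 1
  }

  adjacency <- array(0, dim = c(max_atoms, max_atoms, 5L))
  adjacency[, , 1L] <- 1
  if (nrow(mol$bonds) > 0L) {
    bc <- bond_channel(mol$bonds$order, mol$bonds$aromatic)
    i <- mol$bonds$i; j <- mol$bonds$j
    adjacency[cbind(i, j, 1L)] <- 0
    adjacency[cbind(j, i, 1L)] <- 0
    adjacency[cbind(i, j, bc + 1L)] <- 1
    adjacency[cbind(j, i, bc + 1L)] <- 1
  }

  structure(list(atom_types = atom_types, adjacency = adjacency,
                 n_atoms = n),
            class = "ligand_graph")
}

#' Flatten a ligand encoding to the model input vector
#'
#' @param lig A `ligand_graph`.
#' @return Numeric vector of length `36*7 + 36*36*5 = 6732` for the canonical
#'   size: atom-type matrix first (column-major), then the adjacency tensor.
#' @export
flatten_ligand <- function(lig) {
  stopifnot(inherits(lig, "ligand_graph"))
  c(as.vector(lig$atom_types), as.vector(lig$adjacency))
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("ligand_graph: %d/%d heavy atoms, %d bond cells set\n",
              x$n_atoms, nrow(x$atom_types),
              sum(x$adjacency[, , -1L]) / 2))
  invisible(x)
}
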