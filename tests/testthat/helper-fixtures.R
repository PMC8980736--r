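# Shared fixtures and independent brute-force oracles for the test suite.
# All fixtures are built in code; nothing is read from disk.

# Format one fixed-column PDB ATOM/HETATM record.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1.00, element = "", type = "ATOM", alt = " ") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, alt, resname, chain, resno,
          x, y, z, occ, 0, element)
}

pdb_text <- function(...) paste(c(..., "END"), collapse = "\n")

# A tiny well-formed protein + ligand + water complex. The ligand (resname
# LIG) heavy atoms are placed symmetrically about (1, 2, 3).
fixture_complex_pdb <- function() {
  pdb_text(
    pdb_line(1, "N",  "ALA", "A", 1, 0.5, 2.0, 3.0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0, element = "C"),
    pdb_line(3, "O",  "ALA", "A", 1, 1.5, 2.5, 3.5, element = "O"),
    pdb_line(4, "SG", "CYS", "A", 2, 5.0, 2.0, 3.0, element = "S"),
    pdb_line(5, "C1", "LIG", "A", 9, 0.0, 2.0, 3.0, occ = 1, element = "C",
             type = "HETATM"),
    pdb_line(6, "C2", "LIG", "A", 9, 2.0, 2.0, 3.0, occ = 1, element = "C",
             type = "HETATM"),
    pdb_line(7, "O",  "HOH", "A", 10, 1.0, 2.0, 3.0, element = "O",
             type = "HETATM")
  )
}

# Unbranched all-carbon chain graph (no hydrogens), n atoms.
linear_alkane_graph <- function(n) {
  bonds <- if (n > 1L) {
    data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L, aromatic = FALSE)
  } else NULL
  molecule_graph(rep("C", n), bonds)
}

# Benzene as a hand-built graph: 6 carbons, 6 aromatic ring bonds.
benzene_graph <- function() {
  molecule_graph(rep("C", 6L),
                 data.frame(i = 1:6, j = c(2:6, 1L), order = 1L,
                            aromatic = TRUE))
}

# Bare voxel values of a grid (drops class and geometry attributes).
grid_values <- function(g) array(as.vector(g), dim = dim(g))

# --- independent oracles ----------------------------------------------------

# Brute-force per-atom scatter voxelizer: explicit loops, no vectorized
# indexing, used to cross-check voxelize() on small inputs.
brute_voxelize <- function(atoms, center, side = 20, resolution = 2) {
  nv <- as.integer(side / resolution)
  g <- array(0, dim = c(nv, nv, nv, 8L))
  lo <- center - side / 2
  if (nrow(atoms) > 0L) {
    for (a in seq_len(nrow(atoms))) {
      i <- floor((atoms$x[a] - lo[1]) / resolution) + 1L
      j <- floor((atoms$y[a] - lo[2]) / resolution) + 1L
      k <- floor((atoms$z[a] - lo[3]) / resolution) + 1L
      ch <- element_channel(atoms$element[a]) + 1L
      g[i, j, k, ch] <- 1
    }
  }
  for (i in 1:nv) for (j in 1:nv) for (k in 1:nv) {
    g[i, j, k, 1L] <- as.numeric(sum(g[i, j, k, 2:8]) == 0)
  }
  g
}

# Brute-force seven summary statistics: sorting for the median, explicit
# sum loops for the moments.
brute_seven_stats <- function(x) {
  n <- length(x)
  mu <- 0; for (v in x) mu <- mu + v; mu <- mu / n
  m2 <- 0; m3 <- 0; m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  if (m2 < 1e-12) {
    c(mu, med, 0, xs[1], xs[n], 0, 0)
  } else {
    c(mu, med, sqrt(m2), xs[1], xs[n], m3 / m2^1.5, m4 / m2^2 - 3)
  }
}

# Explicit sum-formula Pearson correlation.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Invariant checks on a ligand encoding; returns TRUE or a message.
check_ligand_invariants <- function(lg) {
  at <- lg$atom_types; ad <- lg$adjacency; n <- lg$n_atoms
  if (!all(at %in% c(0, 1)) || !all(ad %in% c(0, 1))) return("non-binary entry")
  if (!all(rowSums(at) == 1)) return("atom rows not one-hot")
  if (n < nrow(at) && !all(at[(n + 1):nrow(at), 1] == 1)) return("bad padding rows")
  per_cell <- apply(ad, c(1, 2), sum)
  if (!all(per_cell == 1)) return("adjacency cells not one-hot")
  for (ch in 1:5) {
    if (!isTRUE(all.equal(ad[, , ch], t(ad[, , ch])))) return("asymmetric channel")
  }
  if (!all(diag(ad[, , 1]) == 1)) return("diagonal not no-bond")
  if (n < nrow(at)) {
    pad <- (n + 1):nrow(at)
    if (!all(ad[pad, , 1] == 1) || !all(ad[, pad, 1] == 1)) {
      return("padding pair not no-bond")
    }
  }
  TRUE
}

# Small deterministic stacked dataset for model tests (tiny and fast).
tiny_dataset <- function(n = 24, seed = 5, n_iter = 30) {
  make_dataset(n, seed = seed, n_iter = n_iter)
}
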