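# Synthetic docking oracle: generates pockets, ligands, per-iteration
# docking-energy samples and affinities from a known ground truth, so the
# whole featurize -> target -> train -> screen pipeline can be validated
# end to end without an external docking engine or curated datasets.

# Deterministic per-entity sub-seeds derived from one master seed, so any
# single stage (pockets, ligands, runs, affinities) is independently
# reproducible. Kept below 2^31 - 1.
.sub_seed <- function(master, stream, index = 0L) {
  sid <- match(stream, c("params", "pocket", "ligand", "run", "pk"))
  if (is.na(sid)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(master) * 48271 + sid * 1299709 + as.numeric(index) * 7919) %%
               2147483629)
}

#' Parameters of the synthetic docking oracle
#'
#' The oracle's ground-truth minimum `E_without_VDWR` is bilinear in the
#' encoded compositions: `E_min = -(c_p' W c_l)/s - v.b + mu0`, where `c_p`
#' counts occupied voxels per pocket element channel, `c_l` counts ligand
#' atoms per type channel and `b` counts bonds per class. Because the energy
#' is a function of the encoded tensors only, the information needed to
#' recover it demonstrably survives the featurization. Docking iterations
#' add nonnegative Gamma noise (the sample minimum is then a consistent
#' estimator of `E_min`, mimicking "best pose found"), and affinity is a
#' negatively sloped linear link `pK = clip(a - b_pk * E_min + eps, 0, 14)`.
#'
#' @param seed Master seed; all parameter draws derive from it.
#' @param nonlinear Use a mildly nonlinear distortion of the interaction
#'   term instead of the pure bilinear form (stress-testing variant).
#' @return An `oracle_params` list with fields `W` (7 x 6 interaction
#'   weights), `v` (length-4 bond-class weights), `s` (scale), `mu0`
#'   (offset, kcal/mol), Gamma noise `k` and `theta`, affine coefficients
#'   `alpha`/`beta`/`tau` for the secondary energy terms, and pK link
#'   `a`, `b_pk`, `sigma_pk`.
#' @export
oracle_params <- function(seed = 1L, nonlinear = FALSE) {
  set.seed(.sub_seed(seed, "params"))
  structure(list(
    W = matrix(stats::runif(7L * 6L, 0.5, 1.5), 7L, 6L,
               dimnames = list(pocket_channels()[-1L],
                               ligand_atom_channels()[-1L])),
    v = stats::runif(4L, 0.2, 0.8),
    s = 50,
    mu0 = -5,
    k = 2, theta = 2,
    alpha = stats::runif(7L, 0.3, 1.2),
    beta = stats::runif(7L, -10, 10),
    tau = 1,
    a = 1, b_pk = 0.08, sigma_pk = 0.3,
    nonlinear = isTRUE(nonlinear),
    seed = as.integer(seed)
  ), class = "oracle_params")
}

#' Generate a random synthetic pocket
#'
#' Atoms are placed uniformly in the canonical 20 Angstrom cube about the
#' origin, with elements drawn from a fixed protein-like composition over
#' (C, O, N, S, P, H, other).
#'
#' @param seed Seed for this pocket.
#' @param n_atoms Atom count; drawn uniformly from 30..120 when omitted.
#' @return A `structure_atoms` data frame (all atoms protein-class).
#' @export
make_pocket <- function(seed, n_atoms = NULL) {
  set.seed(seed)
  n <- if (is.null(n_atoms)) sample(30:120, 1L) else as.integer(n_atoms)
  elements <- sample(c("C", "O", "N", "S", "P", "H", "FE"), n, replace = TRUE,
                     prob = c(0.54, 0.12, 0.12, 0.03, 0.01, 0.16, 0.02))
  out <- data.frame(
    element = elements,
    name = elements,
    x = stats::runif(n, -10, 10),
    y = stats::runif(n, -10, 10),
    z = stats::runif(n, -10, 10),
    class = "protein",
    resid = "ALA", resno = seq_len(n), chain = "A", alt = "",
    occupancy = 1,
    stringsAsFactors = FALSE
  )
  class(out) <- c("structure_atoms", "data.frame")
  out
}

.VALENCE_CAPS <- c(C = 4, N = 3, O = 2, F = 1, S = 6, other = 4)

.cap_of <- function(element) {
  ch <- atom_channel(element)
  unname(.VALENCE_CAPS[c("C", "N", "O", "F", "S", "other")[ch]])
}

#' Generate a random synthetic molecule graph
#'
#' Builds a random spanning tree over the atoms (keeping tree degree at most
#' 4), assigns elements compatible with the realized degree, adds occasional
#' extra edges, then upgrades bond orders and flags some bonds as
#' aromatic/conjugated -- all without exceeding the per-element valence caps
#' (C 4, N 3, O 2, F 1, S 6, other 4; aromatic bonds count 1.5). Atom counts
#' up to 45 deliberately exceed the 36-atom encoding limit so that pruning
#' is exercised.
#'
#' @param seed Seed for this molecule.
#' @param n_atoms Heavy-atom count; drawn uniformly from 5..45 when omitted.
#' @param extra_edge_rate Expected fraction of atoms contributing an extra
#'   (cycle-forming) edge.
#' @param aromatic_rate Probability that an eligible single bond is flagged
#'   aromatic/conjugated.
#' @return A `molecule_graph`.
#' @export
make_ligand <- function(seed, n_atoms = NULL, extra_edge_rate = 0.08,
                        aromatic_rate = 0.15) {
  set.seed(seed)
  n <- if (is.null(n_atoms)) sample(5:45, 1L) else as.integer(n_atoms)
  stopifnot(n >= 1L)

  # spanning tree with tree degree capped at 4
  deg <- integer(n)
  parent <- integer(n)
  if (n > 1L) {
    for (kk in 2:n) {
      cand <- which(deg[seq_len(kk - 1L)] < 4L)
      parent[kk] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      deg[kk] <- deg[kk] + 1L
      deg[parent[kk]] <- deg[parent[kk]] + 1L
    }
  }

  # element assignment compatible with realized degree
  pool <- c("C", "N", "O", "F", "S", "CL")
  prob <- c(0.68, 0.12, 0.12, 0.03, 0.03, 0.02)
  caps <- c(4, 3, 2, 1, 6, 4)
  elements <- character(n)
  for (i in seq_len(n)) {
    ok <- caps >= max(deg[i], 1L)
    elements[i] <- sample(pool[ok], 1L, prob = prob[ok])
  }
  rem <- .cap_of(elements) - deg

  bonds <- if (n > 1L) {
    data.frame(i = parent[2:n], j = 2:n, order = 1L, aromatic = FALSE)
  } else {
    NULL
  }

  # occasional extra (cycle) edges
  n_extra <- stats::rbinom(1L, max(0L, n - 2L), extra_edge_rate)
  if (n_extra > 0L && n > 2L) {
    adj <- matrix(FALSE, n, n)
    if (!is.null(bonds)) adj[cbind(bonds$i, bonds$j)] <- adj[cbind(bonds$j, bonds$i)] <- TRUE
    for (e in seq_len(n_extra)) {
      cand <- which(rem >= 1)
      if (length(cand) < 2L) break
      pair <- sample(cand, 2L)
      i <- min(pair); j <- max(pair)
      if (adj[i, j]) next
      bonds <- rbind(bonds, data.frame(i = i, j = j, order = 1L, aromatic = FALSE))
      adj[i, j] <- adj[j, i] <- TRUE
      rem[c(i, j)] <- rem[c(i, j)] - 1L
    }
  }

  # bond-order upgrades and aromatic flags within remaining valence
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    for (bi in sample.int(nrow(bonds))) {
      i <- bonds$i[bi]; j <- bonds$j[bi]
      r <- stats::runif(1)
      if (r < 0.05 && rem[i] >= 2 && rem[j] >= 2) {
        bonds$order[bi] <- 3L
        rem[c(i, j)] <- rem[c(i, j)] - 2
      } else if (r < 0.25 && rem[i] >= 1 && rem[j] >= 1) {
        bonds$order[bi] <- 2L
        rem[c(i, j)] <- rem[c(i, j)] - 1
      } else if (stats::runif(1) < aromatic_rate && rem[i] >= 0.5 && rem[j] >= 0.5) {
        bonds$aromatic[bi] <- TRUE
        rem[c(i, j)] <- rem[c(i, j)] - 0.5
      }
    }
  }

  molecule_graph(elements, bonds)
}

#' Ground-truth minimum interaction energy of the synthetic oracle
#'
#' @param grid A `pocket_grid`.
#' @param ligand A `ligand_graph`.
#' @param params An [oracle_params()] object.
#' @return The true minimum `E_without_VDWR` (kcal/mol scale).
#' @export
oracle_energy <- function(grid, ligand, params) {
  stopifnot(inherits(params, "oracle_params"),
            inherits(ligand, "ligand_graph"))
  nv <- dim(grid)[1L]
  gm <- matrix(grid[, , , 2:8], nrow = nv^3L)
  c_p <- colSums(gm)                                   # occupied voxels per element channel
  c_l <- colSums(ligand$atom_types[, 2:7, drop = FALSE])  # atoms per type channel
  b <- vapply(2:5, function(ch) sum(ligand$adjacency[, , ch]) / 2, numeric(1))
  x <- as.numeric(c_p %*% params$W %*% c_l) / params$s + sum(params$v * b)
  if (params$nonlinear) {
    x <- x + 0.1 * x * log1p(abs(x)) / 4
  }
  -x + params$mu0
}

#' Simulate one docking run's per-iteration energy table
#'
#' `E_without_VDWR` iterates are `E_min + G_i` with `G_i ~ Gamma(k, theta)`
#' (nonnegative, so the sample minimum never undershoots the ground truth).
#' Seven further active terms are fixed affine transforms of the same
#' samples plus Gaussian noise, and five terms are identically zero,
#' mirroring the inactive components of typical force-field decompositions.
#'
#' @param E_min True minimum energy for this complex.
#' @param params An [oracle_params()].
#' @param n_iter Number of docking iterations (default 1000).
#' @param seed Seed for this run.
#' @return An `energy_samples` matrix (`n_iter` x 13) with the default term
#'   order and an `inactive` attribute.
#' @export
sample_docking_run <- function(E_min, params, n_iter = 1000L, seed = 1L) {
  stopifnot(n_iter >= 1L, is.finite(E_min))
  set.seed(seed)
  main <- E_min + stats::rgamma(n_iter, shape = params$k, scale = params$theta)
  terms <- default_energy_terms()
  m <- matrix(0, nrow = n_iter, ncol = length(terms),
              dimnames = list(NULL, terms))
  m[, 1L] <- main
  for (j in 1:7) {
    m[, 1L + j] <- params$alpha[j] * main + params$beta[j] +
      stats::rnorm(n_iter, 0, params$tau)
  }
  # columns 9..13 stay identically zero
  structure(m, inactive = apply(m == 0, 2L, all),
            class = c("energy_samples", "matrix"))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a complete synthetic training dataset
#'
#' Draws a pool of synthetic pockets (several complexes share a pocket, as
#' protein targets recur in curated affinity data), a ligand per complex,
#' simulates a docking run for each, builds the 92-long target vector with
#' [summarize_energies()] and [flatten_targets()], and links affinity to the
#' ground truth by `pK = clip(a - b_pk * E_min + eps, 0, 14)` with
#' `eps ~ N(0, sigma_pk^2)`.
#'
#' @param n Number of complexes.
#' @param seed Master seed.
#' @param params Optional [oracle_params()]; derived from `seed` when
#'   omitted.
#' @param n_iter Docking iterations per complex (default 1000).
#' @param n_proteins Size of the shared pocket pool (default `ceiling(n/5)`).
#' @return List with `examples` (training examples: `pocket`, `ligand`,
#'   `targets`, `protein_id`, `complex_id`) and `truth` (data frame of
#'   `complex_id`, `protein_id`, ground-truth `E_min` and noiseless
#'   `pk_true`).
#' @export
make_dataset <- function(n, seed = 1L, params = NULL, n_iter = 1000L,
                         n_proteins = NULL) {
  stopifnot(n >= 1L)
  if (is.null(params)) params <- oracle_params(seed)
  n_proteins <- n_proteins %||% max(1L, ceiling(n / 5))

  grids <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    atoms <- make_pocket(.sub_seed(seed, "pocket", p))
    grids[[p]] <- voxelize(atoms, c(0, 0, 0))
  }

  examples <- vector("list", n)
  truth <- data.frame(complex_id = character(n), protein_id = character(n),
                      E_min = numeric(n), pk_true = numeric(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pidx <- ((i - 1L) %% n_proteins) + 1L
    mol <- make_ligand(.sub_seed(seed, "ligand", i))
    lig <- encode_ligand(prune_ligand(mol))
    E_min <- oracle_energy(grids[[pidx]], lig, params)
    run <- sample_docking_run(E_min, params, n_iter = n_iter,
                              seed = .sub_seed(seed, "run", i))
    stats_m <- summarize_energies(run)
    pk_true <- .clip(params$a - params$b_pk * E_min, 0, 14)
    set.seed(.sub_seed(seed, "pk", i))
    pk <- .clip(params$a - params$b_pk * E_min + stats::rnorm(1, 0, params$sigma_pk),
                0, 14)
    examples[[i]] <- list(
      pocket = grids[[pidx]],
      ligand = lig,
      targets = flatten_targets(stats_m, pk),
      protein_id = sprintf("P%04d", pidx),
      complex_id = sprintf("CPX%05d", i)
    )
    truth$complex_id[i] <- examples[[i]]$complex_id
    truth$protein_id[i] <- examples[[i]]$protein_id
    truth$E_min[i] <- E_min
    truth$pk_true[i] <- pk_true
  }
  list(examples = examples, truth = truth, params = params)
}
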