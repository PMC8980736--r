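# Regression targets: summary statistics of docking energies plus pK.

#' Default docking energy term names
#'
#' Thirteen interaction-energy terms in the fixed column order used
#' throughout the package. `E_without_VDWR` (the interaction energy excluding
#' repulsive van der Waals contributions, the component best correlated with
#' experimental affinity) is always first and is required in any docking
#' table. The remaining names follow the style of force-field score
#' decompositions; the last five are terms that are identically zero in
#' typical runs and are kept so that the target layout stays full-width.
#'
#' @return Character vector of length 13.
#' @export
default_energy_terms <- function() {
  c("E_without_VDWR",
    "E_vdw_attr", "E_solv", "E_hbond_bb", "E_hbond_sc",
    "E_elec", "E_pi_stack", "E_entropy_sc",
    "E_vdw_rep0", "E_hbond_mix", "E_aro_sc", "E_constraint", "E_misc")
}

#' Summary statistic order
#' @return Character vector of the 7 statistics in target order.
#' @export
summary_stat_names <- function() {
  c("mean", "median", "sd", "min", "max", "skew", "kurtosis")
}

#' Interaction energy of a complex
#'
#' The interaction energy is the total energy of the protein-ligand complex
#' minus the energies of the isolated protein and ligand:
#' `E_int = E_PL - E_P - E_L`.
#'
#' @param e_complex,e_protein,e_ligand Finite numeric energies (kcal/mol);
#'   vectorized.
#' @return `e_complex - e_protein - e_ligand`.
#' @export
interaction_energy <- function(e_complex, e_protein, e_ligand) {
  if (!all(is.finite(e_complex), is.finite(e_protein), is.finite(e_ligand))) {
    stop("interaction_energy requires finite inputs")
  }
  e_complex - e_protein - e_ligand
}

#' Summary statistics of per-iteration docking energies
#'
#' For each energy term, computes the 7 summary statistics (mean, median,
#' standard deviation, minimum, maximum, skew, excess kurtosis) over the
#' docking iterations. Moments are population moments (divisor n):
#' skew `= m3 / m2^1.5`, kurtosis `= m4 / m2^2 - 3`. For (near-)constant
#' samples (`m2 < 1e-12`) the standard deviation, skew and kurtosis are
#' defined as 0, so single-iteration runs remain usable.
#'
#' @param samples An `energy_samples` matrix (iterations x terms, see
#'   [read_docking_table()]) or a plain numeric matrix/vector.
#' @return A terms x 7 numeric matrix (rows named by term, columns by
#'   statistic).
#' @export
summarize_energies <- function(samples) {
  if (is.numeric(samples) && is.null(dim(samples))) {
    samples <- matrix(samples, ncol = 1L, dimnames = list(NULL, "E"))
  }
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stop("summarize_energies requires at least one iteration per term")
  }
  if (!all(is.finite(samples))) {
    stop("non-finite energy sample")
  }
  out <- t(apply(samples, 2L, .seven_stats))
  colnames(out) <- summary_stat_names()
  out
}

.seven_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  d <- x - mu
  m2 <- sum(d^2) / n
  if (m2 < 1e-12) {
    return(c(mu, stats::median(x), 0, min(x), max(x), 0, 0))
  }
  m3 <- sum(d^3) / n
  m4 <- sum(d^4) / n
  c(mu, stats::median(x), sqrt(m2), min(x), max(x),
    m3 / m2^1.5, m4 / m2^2 - 3)
}

#' Convert a binding constant to pK
#'
#' `pK = -log10(K / 1 M)`: a dissociation or inhibition constant of 10 nM
#' corresponds to pK 8. K_D and K_I are treated identically.
#'
#' @param K Positive binding constant(s).
#' @param unit Unit of `K`: one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return Dimensionless pK value(s).
#' @export
pk_from_constant <- function(K, unit = "M") {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[match.arg(unit, c("M", "mM", "uM", "nM", "pM"))]]
  K <- K * scale
  if (any(!is.finite(K) | K <= 0)) {
    stop("binding constant must be positive and finite")
  }
  -log10(K)
}

#' Read a docking-run energy table
#'
#' Reads a CSV with one header row of energy-term names and one row per
#' docking iteration. The `E_without_VDWR` column is required. Columns that
#' are identically zero are flagged as inactive terms.
#'
#' @param csv Path to a CSV file, or CSV text (detected by an embedded
#'   newline).
#' @return An `energy_samples` numeric matrix (iterations x terms) with
#'   attribute `inactive`, a logical vector per term.
#' @export
read_docking_table <- function(csv) {
  stopifnot(is.character(csv), length(csv) == 1L)
  df <- tryCatch({
    if (grepl("\n", csv, fixed = TRUE)) {
      utils::read.csv(text = csv, check.names = FALSE)
    } else {
      utils::read.csv(csv, check.names = FALSE)
    }
  }, error = function(e) {
    stop("malformed docking table: ", conditionMessage(e), call. = FALSE)
  })
  if (nrow(df) < 1L) {
    stop("docking table has no iteration rows")
  }
  if (!"E_without_VDWR" %in% names(df)) {
    stop("docking table lacks the required E_without_VDWR column")
  }
  for (cn in names(df)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      if (any(is.na(vn))) {
        stop("non-numeric value in column '", cn, "', row ",
             which(is.na(vn))[1L])
      }
      df[[cn]] <- vn
    }
    if (any(is.na(df[[cn]]))) {
      stop("missing value in column '", cn, "', row ", which(is.na(df[[cn]]))[1L])
    }
  }
  m <- as.matrix(df)
  structure(m, inactive = apply(m == 0, 2L, all), class = c("energy_samples", "matrix"))
}

#' Read a binding-affinity table
#'
#' Tab-separated columns: complex id, K value, unit (`M`, `mM`, `uM`, `nM`,
#' `pM`) and kind (`Kd` or `Ki`, treated identically).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `complex_id`, `K`, `unit`, `kind`, `pk`.
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("complex_id", "K", "unit", "kind")
  df$pk <- mapply(pk_from_constant, df$K, df$unit)
  df
}

#' Flatten a statistics matrix and pK into the 92-long target vector
#'
#' Layout is terms-major: the 7 statistics of the first term, then the second
#' term, and so on (13 x 7 = 91 values), with pK appended last.
#'
#' @param stats_matrix Terms x 7 matrix from [summarize_energies()].
#' @param pk Scalar pK.
#' @return Named numeric vector of length `7 * nrow(stats_matrix) + 1`.
#' @export
flatten_targets <- function(stats_matrix, pk) {
  stopifnot(is.matrix(stats_matrix), ncol(stats_matrix) == 7L,
            length(pk) == 1L, is.finite(pk))
  v <- as.vector(t(stats_matrix))
  names(v) <- paste(rep(rownames(stats_matrix), each = 7L),
                    summary_stat_names(), sep = ".")
  c(v, pK = pk)
}

#' Index of one statistic of one term in the flattened target vector
#'
#' @param term Term name (must be present in `terms`).
#' @param stat One of [summary_stat_names()].
#' @param terms Term order (default [default_energy_terms()]).
#' @return Integer position in the flattened 92-vector.
#' @export
target_index <- function(term, stat, terms = default_energy_terms()) {
  ti <- match(term, terms)
  si <- match(stat, summary_stat_names())
  if (is.na(ti)) stop("unknown term: ", term)
  if (is.na(si)) stop("unknown statistic: ", stat)
  (ti - 1L) * 7L + si
}
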