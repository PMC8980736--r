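# Batch virtual screening: featurize a molecule library against one pocket,
# predict pK and energy statistics, filter by drug-likeness, rank.

#' Count Lipinski rule-of-five violations
#'
#' One violation for each of: molecular weight > 500 Da, logP > 5, hydrogen
#' bond donors > 5, hydrogen bond acceptors > 10. Boundary values are
#' compliant. Missing (`NA`) properties are not counted as violations; use
#' the return's `evaluable` attribute to see how many properties were
#' available per molecule.
#'
#' @param mw Molecular weight (Da).
#' @param logp Octanol-water partition coefficient.
#' @param donors Hydrogen-bond donor count.
#' @param acceptors Hydrogen-bond acceptor count.
#' @return Integer vector of violation counts (0-4) with attribute
#'   `evaluable` (number of non-missing properties per molecule, 0-4).
#' @export
lipinski_violations <- function(mw, logp, donors, acceptors) {
  props <- cbind(mw > 500, logp > 5, donors > 5, acceptors > 10)
  count <- as.integer(rowSums(props, na.rm = TRUE))
  structure(count, evaluable = as.integer(rowSums(!is.na(props))))
}

# Molecular properties (MW, logP, HBD, HBA) for parseable SMILES, via the
# chemistry toolkit. One batched call; returns a data frame aligned with
# `smiles`, NA rows where property calculation fails.
.molecule_properties <- function(smiles) {
  out <- data.frame(mw = rep(NA_real_, length(smiles)),
                    logp = NA_real_, donors = NA_real_, acceptors = NA_real_)
  if (length(smiles) == 0L) return(out)
  props <- tryCatch({
    names(smiles) <- sprintf("m%06d", seq_along(smiles))
    sdf <- ChemmineR::smiles2sdf(smiles)
    ChemmineR::propOB(sdf)
  }, error = function(e) NULL)
  if (is.null(props) || nrow(props) != length(smiles)) return(out)
  out$mw <- props$MW
  out$logp <- props$logP
  out$donors <- props$HBD
  out$acceptors <- props$HBA2
  out
}

#' Screen a molecule library against one pocket
#'
#' Parses, prunes, encodes and batch-predicts every molecule in the library
#' against the given pocket grid, then ranks parseable molecules by
#' predicted pK (descending; ties broken stably by input order).
#' Unparseable molecules are retained as flagged records with `NA`
#' predictions and are excluded from the ranking.
#'
#' @param model A trained `surrogate_model`.
#' @param pocket A `pocket_grid` for the target.
#' @param library A `.smi` path, a character vector of SMILES records
#'   (`SMILES [id [logP]]`), or a list of [parse_smiles()] records.
#' @param batch_size Molecules per prediction batch (default 256).
#' @param prune_oversized Prune molecules over 36 heavy atoms (default,
#'   matching the treatment of training data); when `FALSE` they are
#'   discarded with flag `"oversized"`.
#' @param properties Compute MW/logP/donor/acceptor properties and Lipinski
#'   violations (default `TRUE`). logP is taken from the library file when a
#'   third column is present, otherwise computed by the chemistry toolkit;
#'   the `logp_source` column records which.
#' @return A `screening_records` data frame with columns `rank`, `id`,
#'   `smiles`, `pred_pK`, `pred_min_E_without_VDWR`, `lipinski_violations`,
#'   `logp_source`, `status`, `pruned`, sorted by predicted pK descending
#'   (flagged failures last with `NA` rank).
#' @export
screen_library <- function(model, pocket, library, batch_size = 256L,
                           prune_oversized = TRUE, properties = TRUE) {
  stopifnot(inherits(model, "surrogate_model"))
  recs <- if (is.list(library) && length(library) > 0L &&
              inherits(library[[1L]], "molecule_graph")) {
    lapply(library, function(m) list(status = "ok", smiles = NA_character_,
                                     id = NA_character_, logp = NA_real_,
                                     mol = m, reason = ""))
  } else if (is.list(library) && !is.null(library[[1L]]$status)) {
    library
  } else if (length(library) == 1L && !grepl("[[:space:]]", library) &&
             file.exists(library)) {
    read_smiles_file(library)
  } else {
    lapply(as.character(library), parse_smiles)
  }
  n <- length(recs)
  if (n == 0L) stop("empty screening library")
  for (k in seq_len(n)) {
    if (is.na(recs[[k]]$id)) recs[[k]]$id <- sprintf("mol%06d", k)
  }

  status <- vapply(recs, function(r) r$status, character(1))
  pruned <- logical(n)
  enc <- vector("list", n)
  for (k in which(status == "ok")) {
    mol <- recs[[k]]$mol
    if (n_heavy_atoms(mol) > 36L) {
      if (!prune_oversized) {
        status[k] <- "oversized"
        next
      }
      mol <- prune_ligand(mol)
      pruned[k] <- TRUE
    }
    enc[[k]] <- flatten_ligand(encode_ligand(mol))
  }

  ok <- which(status == "ok")
  pred_pk <- rep(NA_real_, n)
  pred_min_e <- rep(NA_real_, n)
  if (length(ok) > 0L) {
    xp_row <- flatten_pocket(pocket)
    e_idx <- target_index("E_without_VDWR", "min", model$config$terms)
    pk_idx <- model$config$n_stats_out + 1L
    for (s in seq(1L, length(ok), by = batch_size)) {
      idx <- ok[s:min(s + batch_size - 1L, length(ok))]
      Xl <- do.call(rbind, enc[idx])
      Xp <- matrix(xp_row, nrow = length(idx), ncol = length(xp_row),
                   byrow = TRUE)
      Y <- predict(model, Xp, Xl)
      if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
      pred_pk[idx] <- Y[, pk_idx]
      pred_min_e[idx] <- Y[, e_idx]
    }
  }

  viol <- rep(NA_integer_, n)
  logp_source <- rep(NA_character_, n)
  smiles_all <- vapply(recs, function(r) r$smiles, character(1))
  if (properties && length(ok) > 0L && !all(is.na(smiles_all[ok]))) {
    smiles_ok <- smiles_all[ok]
    pr <- .molecule_properties(smiles_ok)
    file_logp <- vapply(recs[ok], function(r) r$logp, numeric(1))
    use_file <- !is.na(file_logp)
    pr$logp[use_file] <- file_logp[use_file]
    logp_source[ok] <- ifelse(use_file, "file",
                              ifelse(is.na(pr$logp), NA, "computed"))
    viol[ok] <- lipinski_violations(pr$mw, pr$logp, pr$donors, pr$acceptors)
  }

  out <- data.frame(
    rank = NA_integer_,
    id = vapply(recs, function(r) r$id, character(1)),
    smiles = vapply(recs, function(r) r$smiles, character(1)),
    pred_pK = pred_pk,
    pred_min_E_without_VDWR = pred_min_e,
    lipinski_violations = viol,
    logp_source = logp_source,
    status = status,
    pruned = pruned,
    stringsAsFactors = FALSE
  )
  ranked <- which(!is.na(out$pred_pK))
  ord <- ranked[order(-out$pred_pK[ranked], ranked)]  # stable tie-break
  out$rank[ord] <- seq_along(ord)
  out <- out[c(ord, setdiff(seq_len(n), ord)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_records", "data.frame")
  out
}

#' Top-k screening hits
#'
#' @param records A `screening_records` data frame from [screen_library()].
#' @param k Number of hits (default 100).
#' @return The first `min(k, n_ranked)` ranked records.
#' @export
top_k <- function(records, k = 100L) {
  stopifnot(k >= 1L)
  ranked <- records[!is.na(records$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  utils::head(ranked, k)
}

#' Write screening records to a ranked TSV
#'
#' @param records A `screening_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
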