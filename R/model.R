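# The docking surrogate: a three-subnetwork fully connected regression
# network (protein encoder, ligand encoder, affinity predictor) mapping the
# flattened pocket grid and ligand tensors to 13 x 7 energy summary
# statistics plus pK. Every dense layer carries spectral normalization,
# bias, LeakyReLU activation and dropout; shape-matched layers add an
# identity skip connection. Implemented directly on matrix operations with
# manual backpropagation and an Adam optimizer, so training is fully
# deterministic given a seed.

#' Model configuration
#'
#' @param n_blocks Number of fully connected layers per subnetwork (the
#'   reference architectures use 10 or 6).
#' @param hidden Hidden-layer width d (reference architectures: 2048, 1024,
#'   512, 256).
#' @param dropout Dropout rate applied after each hidden activation
#'   (default 0.2).
#' @param leaky_slope Negative slope of the LeakyReLU activation
#'   (default 0.3).
#' @param learning_rate Adam learning rate (default 1e-6; small synthetic
#'   problems train with larger rates such as 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 20); ignored when no validation set is supplied.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param pocket_dim,ligand_dim Flattened input lengths (defaults 8000 and
#'   6732 for the canonical encodings).
#' @param terms Energy term names defining the output layout (13 terms).
#' @return A `model_config` list.
#' @export
model_config <- function(n_blocks = 10L, hidden = 1024L, dropout = 0.2,
                         leaky_slope = 0.3, learning_rate = 1e-6,
                         batch_size = 64L, epochs = 100L, patience = 20L,
                         seed = 1L, pocket_dim = 8000L, ligand_dim = 6732L,
                         terms = default_energy_terms()) {
  stopifnot(n_blocks >= 1L, hidden >= 1L, dropout >= 0, dropout < 1,
            leaky_slope >= 0, learning_rate > 0, batch_size >= 1L,
            epochs >= 1L, pocket_dim >= 1L, ligand_dim >= 1L)
  structure(list(
    n_blocks = as.integer(n_blocks), hidden = as.integer(hidden),
    dropout = dropout, leaky_slope = leaky_slope,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed), pocket_dim = as.integer(pocket_dim),
    ligand_dim = as.integer(ligand_dim), terms = terms,
    n_stats_out = 7L * length(terms)
  ), class = "model_config")
}

# --- dense layer primitives ------------------------------------------------

# Uniform fan-based initialization; the spectral-norm power-iteration vector
# u is an auxiliary (non-trainable) state, not a parameter.
.make_layer <- function(n_in, n_out, skip = FALSE, linear = FALSE) {
  limit <- sqrt(6 / (n_in + n_out))
  W <- matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
  u <- stats::rnorm(n_in)
  u <- u / sqrt(sum(u^2))
  list(W = W, b = numeric(n_out), u = u,
       skip = skip, linear = linear, n_in = n_in, n_out = n_out)
}

# Spectral norm estimate from the stored u (read-only; used in eval mode).
.layer_sigma <- function(layer) {
  v <- crossprod(layer$W, layer$u)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(1)
  v <- v / nv
  sigma <- sum(layer$u * (layer$W %*% v))
  max(abs(sigma), 1e-12)
}

# One power-iteration update of u, returning the refreshed layer and sigma
# (used once per training step).
.layer_power_step <- function(layer) {
  v <- crossprod(layer$W, layer$u)
  v <- v / max(sqrt(sum(v^2)), 1e-12)
  u <- layer$W %*% v
  u <- as.vector(u) / max(sqrt(sum(u^2)), 1e-12)
  layer$u <- u
  layer$sigma <- max(abs(sum(u * (layer$W %*% v))), 1e-12)
  layer
}

.leaky <- function(Z, slope) pmax(Z, 0) + slope * pmin(Z, 0)

.add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward through one layer; returns output plus the cache needed for
# backpropagation. `sigma` must already be set on the layer.
.layer_forward <- function(layer, X, cfg, train) {
  Wn <- layer$W / layer$sigma
  Z <- .add_bias(X %*% Wn, layer$b)
  if (layer$linear) {
    return(list(out = Z, cache = list(X = X, Wn = Wn, D = NULL, M = NULL)))
  }
  D <- ifelse(Z > 0, 1, cfg$leaky_slope)
  A <- Z * D
  M <- NULL
  if (train && cfg$dropout > 0) {
    M <- (matrix(stats::runif(length(A)), nrow(A)) >= cfg$dropout) / (1 - cfg$dropout)
    A <- A * M
  }
  out <- if (layer$skip) X + A else A
  list(out = out, cache = list(X = X, Wn = Wn, D = D, M = M))
}

# Backward through one layer. Returns gradient w.r.t. the input plus
# parameter gradients (sigma treated as constant within the step).
.layer_backward <- function(layer, cache, dOut) {
  dA <- dOut
  if (!layer$linear) {
    if (!is.null(cache$M)) dA <- dA * cache$M
    dA <- dA * cache$D
  }
  dW <- crossprod(cache$X, dA) / layer$sigma
  db <- colSums(dA)
  dX <- tcrossprod(dA, cache$Wn)
  if (layer$skip && !layer$linear) dX <- dX + dOut
  list(dX = dX, dW = dW, db = db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.subnet_forward <- function(layers, X, cfg, train) {
  caches <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    fw <- .layer_forward(layers[[k]], X, cfg, train)
    X <- fw$out
    caches[[k]] <- fw$cache
  }
  list(out = X, caches = caches)
}

.subnet_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (k in rev(seq_along(layers))) {
    bk <- .layer_backward(layers[[k]], caches[[k]], dOut)
    grads[[k]] <- list(dW = bk$dW, db = bk$db)
    dOut <- bk$dX
  }
  list(dX = dOut, grads = grads)
}

.make_subnet <- function(n_in, d, n_blocks) {
  layers <- vector("list", n_blocks)
  layers[[1L]] <- .make_layer(n_in, d)
  if (n_blocks > 1L) {
    for (k in 2:n_blocks) layers[[k]] <- .make_layer(d, d, skip = TRUE)
  }
  layers
}

# --- model construction ----------------------------------------------------

#' Build the docking surrogate network
#'
#' Canonical wiring: the protein encoder maps the flattened pocket grid
#' (8000) to width d and applies `n_blocks - 1` further d-to-d layers with
#' identity skip connections; the ligand encoder does the same from the
#' flattened ligand tensors (6732). Their outputs are concatenated (2d) and
#' fed to the affinity predictor subnetwork, whose output feeds two linear
#' heads: a 91-output head for the energy summary statistics and a separate
#' 1-output head for pK. Initialization is a seeded uniform fan-based
#' scheme, so construction is fully reproducible.
#'
#' @param config A [model_config()].
#' @return A `surrogate_model` object.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  d <- config$hidden
  model <- list(
    config = config,
    protein = .make_subnet(config$pocket_dim, d, config$n_blocks),
    ligand = .make_subnet(config$ligand_dim, d, config$n_blocks),
    joint = .make_subnet(2L * d, d, config$n_blocks),
    stats_head = .make_layer(d, config$n_stats_out, linear = TRUE),
    pk_head = .make_layer(d, 1L, linear = TRUE)
  )
  class(model) <- "surrogate_model"
  model
}

.model_parts <- c("protein", "ligand", "joint")

#' Count trainable parameters
#'
#' Counts weights and biases of every dense layer; the spectral-norm
#' power-iteration vectors are auxiliary state and are excluded. The
#' reference parameter counts for this architecture family are quoted
#' without the pK head, so the head is excluded by default; including it
#' adds `hidden + 1` parameters.
#'
#' @param model A `surrogate_model`.
#' @param include_pk_head Count the pK head's parameters too (default
#'   `FALSE`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, include_pk_head = FALSE) {
  stopifnot(inherits(model, "surrogate_model"))
  layers <- c(unlist(lapply(.model_parts, function(p) model[[p]]), recursive = FALSE),
              list(model$stats_head))
  if (include_pk_head) layers <- c(layers, list(model$pk_head))
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Closed-form parameter count of the canonical architecture
#'
#' `N(n, d) = (3(n-1) + 2) d^2 + (8000 + 6732 + 91 + 3n) d + 91`, excluding
#' the pK head (which adds `d + 1`).
#'
#' @param n_blocks,hidden Architecture dimensions.
#' @param include_pk_head Add the pK head's `hidden + 1` parameters.
#' @return Numeric parameter count.
#' @export
parameter_count_formula <- function(n_blocks, hidden, include_pk_head = FALSE) {
  n <- n_blocks; d <- hidden
  out <- (3 * (n - 1) + 2) * d^2 + (8000 + 6732 + 91 + 3 * n) * d + 91
  if (include_pk_head) out <- out + d + 1
  out
}

# Refresh eval-mode sigma on every layer (no u update).
.set_eval_sigmas <- function(model) {
  for (p in .model_parts) {
    for (k in seq_along(model[[p]])) {
      model[[p]][[k]]$sigma <- .layer_sigma(model[[p]][[k]])
    }
  }
  model$stats_head$sigma <- .layer_sigma(model$stats_head)
  model$pk_head$sigma <- .layer_sigma(model$pk_head)
  model
}

.model_forward <- function(model, Xp, Xl, train = FALSE) {
  cfg <- model$config
  fp <- .subnet_forward(model$protein, Xp, cfg, train)
  fl <- .subnet_forward(model$ligand, Xl, cfg, train)
  H <- cbind(fp$out, fl$out)
  fj <- .subnet_forward(model$joint, H, cfg, train)
  fs <- .layer_forward(model$stats_head, fj$out, cfg, train)
  fk <- .layer_forward(model$pk_head, fj$out, cfg, train)
  list(Y = cbind(fs$out, fk$out),
       caches = list(protein = fp$caches, ligand = fl$caches,
                     joint = fj$caches, stats_head = fs$cache,
                     pk_head = fk$cache))
}

# --- prediction ------------------------------------------------------------

.as_input_matrix <- function(x, dim_expected, flattener) {
  if (is.matrix(x) && !inherits(x, "pocket_grid")) {
    if (ncol(x) != dim_expected) {
      stop("input matrix has ", ncol(x), " columns; expected ", dim_expected)
    }
    return(x)
  }
  if (is.list(x) && !inherits(x, "ligand_graph")) {
    rows <- lapply(x, flattener)
    return(do.call(rbind, rows))
  }
  v <- flattener(x)
  if (length(v) != dim_expected) {
    stop("flattened input has length ", length(v), "; expected ", dim_expected)
  }
  matrix(v, nrow = 1L)
}

#' Predict energy summary statistics and pK
#'
#' Evaluation-mode forward pass: dropout is disabled, so predictions are
#' deterministic, and batched evaluation gives exactly the same values as
#' one-at-a-time evaluation.
#'
#' @param object A `surrogate_model`.
#' @param pocket A `pocket_grid`, a list of them, or an `N x 8000` matrix of
#'   flattened grids.
#' @param ligand A `ligand_graph`, a list of them, or an `N x 6732` matrix.
#' @param ... Unused.
#' @return A named numeric vector of length 92 for a single input, or an
#'   `N x 92` matrix for batched input. The first 91 entries are the 7
#'   summary statistics per energy term (terms-major); the last is pK.
#' @export
predict.surrogate_model <- function(object, pocket, ligand, ...) {
  cfg <- object$config
  single <- inherits(pocket, "pocket_grid") ||
    (!is.matrix(pocket) && !is.list(pocket))
  Xp <- .as_input_matrix(pocket, cfg$pocket_dim, flatten_pocket)
  Xl <- .as_input_matrix(ligand, cfg$ligand_dim, flatten_ligand)
  if (nrow(Xp) != nrow(Xl)) {
    stop("pocket and ligand batches differ in size")
  }
  model <- .set_eval_sigmas(object)
  Y <- .model_forward(model, Xp, Xl, train = FALSE)$Y
  colnames(Y) <- c(paste(rep(cfg$terms, each = 7L), summary_stat_names(),
                         sep = "."), "pK")
  if (single && nrow(Y) == 1L) Y[1L, ] else Y
}

# --- training --------------------------------------------------------------

#' Stack training examples into input/target matrices
#'
#' @param examples List of training examples, each a list with `pocket`
#'   (`pocket_grid`), `ligand` (`ligand_graph`), `targets` (92-vector) and
#'   optionally `protein_id` / `complex_id`.
#' @return List with `Xp`, `Xl`, `Y` matrices and `protein_id` vector.
#' @export
stack_examples <- function(examples) {
  stopifnot(length(examples) >= 1L)
  Xp <- do.call(rbind, lapply(examples, function(e) flatten_pocket(e$pocket)))
  Xl <- do.call(rbind, lapply(examples, function(e) flatten_ligand(e$ligand)))
  Y <- do.call(rbind, lapply(examples, function(e) as.numeric(e$targets)))
  pid <- vapply(examples, function(e) e$protein_id %||% NA_character_,
                character(1))
  list(Xp = Xp, Xl = Xl, Y = Y, protein_id = pid)
}

.adam_init <- function(layer) {
  list(mW = array(0, dim(layer$W)), vW = array(0, dim(layer$W)),
       mb = numeric(length(layer$b)), vb = numeric(length(layer$b)))
}

.adam_step <- function(layer, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$mW <- beta1 * state$mW + (1 - beta1) * grad$dW
  state$vW <- beta2 * state$vW + (1 - beta2) * grad$dW^2
  state$mb <- beta1 * state$mb + (1 - beta1) * grad$db
  state$vb <- beta2 * state$vb + (1 - beta2) * grad$db^2
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  layer$W <- layer$W - lr * (state$mW / c1) / (sqrt(state$vW / c2) + eps)
  layer$b <- layer$b - lr * (state$mb / c1) / (sqrt(state$vb / c2) + eps)
  list(layer = layer, state = state)
}

# Mean over examples of the squared error summed across all 92 outputs.
.l2_loss <- function(Y, T) mean(rowSums((Y - T)^2))

#' Train the surrogate on stacked examples
#'
#' Minimizes the L2 loss (mean over examples of the squared differences
#' summed over all 92 outputs) with the Adam optimizer. One spectral-norm
#' power-iteration update is applied to every dense layer per training step.
#' Training is fully reproducible given the seed, which drives shuffling and
#' dropout masks.
#'
#' @param model A `surrogate_model` from [build_model()].
#' @param data Training data: a list of examples (see [stack_examples()]) or
#'   an already-stacked list with `Xp`, `Xl`, `Y`.
#' @param val_data Optional validation data in the same form; enables
#'   early stopping on validation loss.
#' @param epochs,batch_size,learning_rate,patience,seed Optional overrides of
#'   the model config.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained) and `history` (data frame of epoch,
#'   train and validation loss).
#' @export
train_surrogate <- function(model, data, val_data = NULL, epochs = NULL,
                            batch_size = NULL, learning_rate = NULL,
                            patience = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "surrogate_model"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  patience <- patience %||% cfg$patience
  seed <- seed %||% cfg$seed

  if (!is.null(data$Xp)) stacked <- data else stacked <- stack_examples(data)
  if (!is.null(val_data) && is.null(val_data$Xp)) val_data <- stack_examples(val_data)
  N <- nrow(stacked$Xp)
  stopifnot(N >= 1L, nrow(stacked$Y) == N)

  set.seed(seed)
  opt <- list()
  for (p in .model_parts) opt[[p]] <- lapply(model[[p]], .adam_init)
  opt$stats_head <- .adam_init(model$stats_head)
  opt$pk_head <- .adam_init(model$pk_head)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_model <- NULL; wait <- 0L; t_step <- 0L
  ns <- cfg$n_stats_out

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(N)
    starts <- seq(1L, N, by = batch_size)
    epoch_loss <- 0; seen <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, N)]
      Xp <- stacked$Xp[idx, , drop = FALSE]
      Xl <- stacked$Xl[idx, , drop = FALSE]
      Tm <- stacked$Y[idx, , drop = FALSE]

      # one power-iteration update per layer per step
      for (p in .model_parts) {
        for (k in seq_along(model[[p]])) {
          model[[p]][[k]] <- .layer_power_step(model[[p]][[k]])
        }
      }
      model$stats_head <- .layer_power_step(model$stats_head)
      model$pk_head <- .layer_power_step(model$pk_head)

      fw <- .model_forward(model, Xp, Xl, train = TRUE)
      loss <- .l2_loss(fw$Y, Tm)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      seen <- seen + length(idx)

      dY <- 2 * (fw$Y - Tm) / nrow(Tm)
      bs <- .layer_backward(model$stats_head, fw$caches$stats_head,
                            dY[, seq_len(ns), drop = FALSE])
      bk <- .layer_backward(model$pk_head, fw$caches$pk_head,
                            dY[, ns + 1L, drop = FALSE])
      bj <- .subnet_backward(model$joint, fw$caches$joint, bs$dX + bk$dX)
      d <- cfg$hidden
      bp <- .subnet_backward(model$protein, fw$caches$protein,
                             bj$dX[, seq_len(d), drop = FALSE])
      bl <- .subnet_backward(model$ligand, fw$caches$ligand,
                             bj$dX[, d + seq_len(d), drop = FALSE])

      t_step <- t_step + 1L
      for (p in .model_parts) {
        grads <- switch(p, protein = bp$grads, ligand = bl$grads,
                        joint = bj$grads)
        for (k in seq_along(model[[p]])) {
          upd <- .adam_step(model[[p]][[k]], grads[[k]], opt[[p]][[k]],
                            lr, t_step)
          model[[p]][[k]] <- upd$layer
          opt[[p]][[k]] <- upd$state
        }
      }
      upd <- .adam_step(model$stats_head, list(dW = bs$dW, db = bs$db),
                        opt$stats_head, lr, t_step)
      model$stats_head <- upd$layer; opt$stats_head <- upd$state
      upd <- .adam_step(model$pk_head, list(dW = bk$dW, db = bk$db),
                        opt$pk_head, lr, t_step)
      model$pk_head <- upd$layer; opt$pk_head <- upd$state
    }

    train_loss <- epoch_loss / seen
    val_loss <- NA_real_
    if (!is.null(val_data)) {
      meval <- .set_eval_sigmas(model)
      Yv <- .model_forward(meval, val_data$Xp, val_data$Xl, train = FALSE)$Y
      val_loss <- .l2_loss(Yv, val_data$Y)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    if (!is.null(val_data)) {
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_model <- model; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }

  list(model = best_model %||% model, history = history)
}

#' @export
print.surrogate_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "surrogate_model: %d blocks x %d hidden per subnetwork, %s trainable parameters (+%d pK head)\n",
    cfg$n_blocks, cfg$hidden,
    format(count_parameters(x), big.mark = ","), cfg$hidden + 1L))
  invisible(x)
}

# --- dataset split and evaluation ------------------------------------------

#' Shuffled train/validation split
#'
#' Shuffles the examples with the given seed and assigns
#' `floor(train_fraction * N)` of them to the training side. With
#' `protein_disjoint = TRUE`, whole protein-id groups are assigned to one
#' side (so no protein appears on both sides) and the training size
#' approximates the fraction.
#'
#' @param examples List of examples (each may carry `protein_id`).
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Shuffle seed.
#' @param protein_disjoint Keep protein-id groups intact (default `FALSE`).
#' @return List with `train` and `validation` example lists.
#' @export
split_dataset <- function(examples, train_fraction = 0.7, seed = 1L,
                          protein_disjoint = FALSE) {
  N <- length(examples)
  stopifnot(N >= 2L)
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  set.seed(seed)
  n_train <- floor(train_fraction * N)
  if (!protein_disjoint) {
    perm <- sample.int(N)
    return(list(train = examples[perm[seq_len(n_train)]],
                validation = examples[perm[-seq_len(n_train)]]))
  }
  pid <- vapply(examples, function(e) as.character(e$protein_id %||% NA_character_),
                character(1))
  if (any(is.na(pid))) stop("protein_disjoint requires protein_id on every example")
  groups <- sample(unique(pid))
  take <- character(0); size <- 0L
  for (g in groups) {
    if (size >= n_train) break
    take <- c(take, g)
    size <- size + sum(pid == g)
  }
  list(train = examples[pid %in% take],
       validation = examples[!pid %in% take])
}

#' Pearson correlation and least-squares fit of predictions vs reference
#'
#' @param predicted,reference Equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return List with `r` (Pearson correlation), `slope` and `intercept` of
#'   the ordinary least-squares fit of `predicted` on `reference`, and
#'   `p_value` of the correlation test.
#' @export
evaluate_correlation <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(predicted) >= 3L)
  if (stats::var(predicted) == 0 || stats::var(reference) == 0) {
    stop("zero variance: correlation undefined")
  }
  fit <- stats::lm(predicted ~ reference)
  ct <- stats::cor.test(predicted, reference)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = ct$p.value)
}

# --- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the serialized model next to a JSON sidecar holding the model
#' configuration and the data-schema dimensions. Reloading gives
#' bit-identical predictions.
#'
#' @param model A `surrogate_model`.
#' @param path Checkpoint path (an `.rds` file); the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  saveRDS(model, path)
  sidecar <- c(unclass(model$config),
               list(schema = list(pocket = c(10L, 10L, 10L, 8L),
                                  ligand_atoms = c(36L, 7L),
                                  ligand_bonds = c(36L, 36L, 5L),
                                  outputs = 7L * length(model$config$terms) + 1L)))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path previously passed to [save_checkpoint()].
#' @return The `surrogate_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "surrogate_model"))
  model
}
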