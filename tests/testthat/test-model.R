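# Surrogate network: construction, parameter accounting, prediction,
# training and evaluation utilities.

small_cfg <- function(...) {
  model_config(n_blocks = 2, hidden = 16, learning_rate = 1e-3,
               batch_size = 8, seed = 11, ...)
}

test_that("build_model wires 92 outputs and is seed-reproducible", {
  m <- build_model(small_cfg())
  g <- voxelize(make_pocket(1), c(0, 0, 0))
  lg <- encode_ligand(prune_ligand(make_ligand(2)))
  y <- predict(m, g, lg)
  expect_length(y, 92L)
  expect_true(all(is.finite(y)))
  expect_equal(names(y)[92], "pK")
  expect_equal(names(y)[4], "E_without_VDWR.min")

  m2 <- build_model(small_cfg())
  expect_identical(m$protein[[1]]$W, m2$protein[[1]]$W)
  expect_identical(predict(m2, g, lg), y)

  # minimal degenerate configuration still works
  m0 <- build_model(model_config(n_blocks = 1, hidden = 8, seed = 1))
  expect_true(all(is.finite(predict(m0, g, lg))))
})

test_that("parameter counts follow the closed-form architecture formula", {
  for (nd in list(c(2, 16), c(3, 32), c(1, 8))) {
    m <- build_model(model_config(n_blocks = nd[1], hidden = nd[2]))
    expect_equal(count_parameters(m), parameter_count_formula(nd[1], nd[2]))
    expect_equal(count_parameters(m, include_pk_head = TRUE),
                 parameter_count_formula(nd[1], nd[2]) + nd[2] + 1)
  }
  # strictly increasing in depth and width
  expect_true(parameter_count_formula(3, 64) > parameter_count_formula(2, 64))
  expect_true(parameter_count_formula(2, 128) > parameter_count_formula(2, 64))
})

test_that("prediction is deterministic, batch-consistent and shape-checked", {
  m <- build_model(small_cfg())
  g <- voxelize(make_pocket(3), c(0, 0, 0))
  lg <- encode_ligand(prune_ligand(make_ligand(4)))

  y1 <- predict(m, g, lg)
  y2 <- predict(m, g, lg)
  expect_identical(y1, y2)

  # batch of 3 copies: identical rows, equal to the single evaluation
  Xp <- matrix(rep(flatten_pocket(g), 3), nrow = 3, byrow = TRUE)
  Xl <- matrix(rep(flatten_ligand(lg), 3), nrow = 3, byrow = TRUE)
  Y <- predict(m, Xp, Xl)
  expect_equal(dim(Y), c(3L, 92L))
  expect_equal(unname(Y[1, ]), unname(y1))
  expect_equal(Y[1, ], Y[2, ])
  expect_equal(Y[2, ], Y[3, ])

  # all-empty pocket and padding-only ligand stay finite
  g0 <- voxelize(data.frame(element = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0)), c(0, 0, 0))
  lg0 <- structure(list(
    atom_types = cbind(1, matrix(0, 36, 6)),
    adjacency = { a <- array(0, c(36, 36, 5)); a[, , 1] <- 1; a },
    n_atoms = 0L), class = "ligand_graph")
  expect_true(all(is.finite(predict(m, g0, lg0))))

  expect_error(predict(m, matrix(0, 1, 100), Xl), "expected 8000|columns")
})

test_that("training reduces the loss on a trivially learnable problem", {
  ds <- tiny_dataset()
  st <- stack_examples(ds$examples)
  # constant targets: the net only has to learn a bias vector
  st$Y <- matrix(rep(c(rep(2, 91), 5), each = nrow(st$Y)), nrow = nrow(st$Y))
  m <- build_model(small_cfg(dropout = 0))
  fit <- train_surrogate(m, st, epochs = 30, learning_rate = 3e-3)
  h <- fit$history$train_loss
  expect_lt(h[length(h)], h[1] / 50)
  # early epochs trend downward
  expect_true(all(diff(h[1:10]) < 0))
})

test_that("training is bit-reproducible given the seed", {
  ds <- tiny_dataset()
  st <- stack_examples(ds$examples)
  f1 <- train_surrogate(build_model(small_cfg()), st, epochs = 3)
  f2 <- train_surrogate(build_model(small_cfg()), st, epochs = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$protein[[1]]$W, f2$model$protein[[1]]$W)
})

test_that("one training step moves parameters in all three subnetworks", {
  ds <- tiny_dataset(n = 4)
  st <- stack_examples(ds$examples)
  m0 <- build_model(small_cfg())
  m1 <- train_surrogate(m0, st, epochs = 1, batch_size = 4)$model
  for (part in c("protein", "ligand", "joint")) {
    moved <- any(vapply(seq_along(m0[[part]]), function(k) {
      any(m0[[part]][[k]]$W != m1[[part]][[k]]$W)
    }, logical(1)))
    expect_true(moved, label = paste("parameters moved in", part))
  }
  expect_true(any(m0$stats_head$W != m1$stats_head$W))
  expect_true(any(m0$pk_head$W != m1$pk_head$W))
})

test_that("the default learning rate is 1e-6", {
  expect_equal(model_config()$learning_rate, 1e-6)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  ds <- tiny_dataset(n = 8)
  st <- stack_examples(ds$examples)
  st$Y[1, 1] <- Inf
  m <- build_model(small_cfg())
  expect_error(train_surrogate(m, st, epochs = 5),
               "non-finite training loss")
})

test_that("split_dataset reproduces the 70/30 arithmetic and protein disjointness", {
  ex <- lapply(seq_len(3875), function(i) list(protein_id = sprintf("P%03d", i %% 400)))
  sp <- split_dataset(ex, train_fraction = 0.7, seed = 1)
  expect_length(sp$train, 2712L)
  expect_length(sp$validation, 1163L)

  ex10 <- lapply(1:10, function(i) list(protein_id = "p"))
  sp10 <- split_dataset(ex10, train_fraction = 0.7, seed = 2)
  expect_length(sp10$train, 7L)
  expect_length(sp10$validation, 3L)

  spd <- split_dataset(ex, train_fraction = 0.7, seed = 3, protein_disjoint = TRUE)
  tp <- unique(vapply(spd$train, `[[`, "", "protein_id"))
  vp <- unique(vapply(spd$validation, `[[`, "", "protein_id"))
  expect_length(intersect(tp, vp), 0L)
  expect_equal(length(spd$train) + length(spd$validation), 3875L)
  # group split approximates the fraction
  expect_gt(length(spd$train) / 3875, 0.6)
  expect_lt(length(spd$train) / 3875, 0.8)

  expect_error(split_dataset(ex10, train_fraction = 1.2), "between 0 and 1")
})

test_that("evaluate_correlation returns exact r and least-squares fit", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_correlation(2 * x + 1, x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)

  anti <- evaluate_correlation(-x, x)
  expect_equal(anti$r, -1)

  set.seed(12)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  expect_equal(evaluate_correlation(b, a)$r, brute_pearson(b, a),
               tolerance = 1e-12)

  expect_error(evaluate_correlation(rep(1, 5), x), "zero variance")
})

test_that("checkpoints reload to bit-identical predictions", {
  m <- build_model(small_cfg())
  g <- voxelize(make_pocket(6), c(0, 0, 0))
  lg <- encode_ligand(prune_ligand(make_ligand(7)))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$hidden, 16L)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m, g, lg), predict(m2, g, lg))
})
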