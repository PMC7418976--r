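# Model contracts: knn and forest baselines, autoencoder grafting,
# persistence, prediction-range invariants.

make_matrix_examples <- function(X, Y) {
  # wrap bare matrices as learning examples: one "gene" per column, T = 1
  stopifnot(nrow(X) == nrow(Y))
  ex <- lapply(seq_len(nrow(X)), function(i) {
    structure(list(
      source = structure(list(compound = paste0("c", i), dose = "high",
                              replicate = 1L, layout = "flat",
                              values = matrix(X[i, ], ncol = 1L)),
                         class = "encoded_instance"),
      target = structure(list(compound = paste0("c", i), dose = "high",
                              replicate = 1L, layout = "flat",
                              values = matrix(Y[i, ], ncol = 1L)),
                         class = "encoded_instance"),
      compound = paste0("c", i), dose = "high",
      source_replicate = 1L, target_replicate = 1L),
      class = "learning_example")
  })
  structure(ex, class = "learning_examples", n_times_source = 1L,
            n_times_target = 1L)
}

test_that("1-NN memorises its training examples exactly", {
  set.seed(3)
  X <- matrix(runif(40), 8, 5)
  Y <- matrix(runif(24), 8, 3)
  ex <- make_matrix_examples(X, Y)
  m <- fit_model(knn_spec(1L), ex)
  expect_equal(predict(m, X), Y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("2-NN with equidistant neighbours averages their targets", {
  X <- rbind(c(0, 0), c(2, 0), c(1, 5))
  Y <- rbind(c(0.2, 0.8), c(0.6, 0.4), c(0.9, 0.9))
  m <- fit_model(knn_spec(2L), make_matrix_examples(X, Y))
  # query at (1, 0): rows 1 and 2 tie at distance 1, row 3 is far
  pred <- predict(m, matrix(c(1, 0), 1, 2))
  expect_equal(pred[1, ], c(0.4, 0.6), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("doubling the training set maps k-NN predictions to k/2 behaviour", {
  set.seed(8)
  X <- matrix(runif(30, 0.1, 0.9), 6, 5)
  Y <- matrix(runif(18, 0.1, 0.9), 6, 3)
  ex <- make_matrix_examples(X, Y)
  doubled <- make_matrix_examples(rbind(X, X), rbind(Y, Y))
  q <- matrix(runif(10, 0.1, 0.9), 2, 5)
  expect_equal(predict(fit_model(knn_spec(4L), doubled), q),
               predict(fit_model(knn_spec(2L), ex), q), tolerance = 1e-12)
  expect_error(fit_model(knn_spec(7L), ex), "exceeds")
})

test_that("a single unlimited tree on one example predicts that target", {
  X <- matrix(runif(4), 1, 4)
  Y <- matrix(c(0.3, 0.7), 1, 2)
  m <- fit_model(rrf_spec(n_trees = 1L), make_matrix_examples(X, Y))
  pred <- predict(m, matrix(runif(8), 2, 4))
  expect_equal(pred, rbind(Y[1, ], Y[1, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a single deterministic tree is invariant to duplicated examples", {
  set.seed(5)
  X <- matrix(runif(50, 0.1, 0.9), 10, 5)
  Y <- matrix(runif(30, 0.1, 0.9), 10, 3)
  cfg <- quick_cfg(seed = 2L)
  m1 <- fit_model(rrf_spec(n_trees = 1L, mtry = 5L, min_node = 1L),
                  make_matrix_examples(X, Y), cfg)
  m2 <- fit_model(rrf_spec(n_trees = 1L, mtry = 5L, min_node = 1L),
                  make_matrix_examples(rbind(X, X), rbind(Y, Y)), cfg)
  q <- matrix(runif(15, 0.1, 0.9), 3, 5)
  expect_equal(predict(m1, q), predict(m2, q), tolerance = 1e-12)
})

test_that("forest learns structure and stays inside the target hull", {
  set.seed(6)
  X <- matrix(runif(300, 0, 1), 100, 3)
  Y <- cbind(0.2 + 0.5 * (X[, 1] > 0.5), 0.8 - 0.5 * (X[, 2] > 0.5))
  ex <- make_matrix_examples(X, Y)
  m <- fit_model(rrf_spec(n_trees = 30L), ex, quick_cfg(seed = 4L))
  q <- matrix(runif(60), 20, 3)
  pred <- predict(m, q)
  mean_pred <- matrix(colMeans(Y), 20, 2, byrow = TRUE)
  truth <- cbind(0.2 + 0.5 * (q[, 1] > 0.5), 0.8 - 0.5 * (q[, 2] > 0.5))
  expect_lt(mean(abs(pred - truth)), mean(abs(mean_pred - truth)) * 0.5)
  expect_gte(min(pred), min(Y) - 1e-12)
  expect_lte(max(pred), max(Y) + 1e-12)
  # seeded refit reproduces the same forest
  m2 <- fit_model(rrf_spec(n_trees = 30L), ex, quick_cfg(seed = 4L))
  expect_equal(predict(m2, q), pred, tolerance = 1e-15)
})

test_that("grafted weights equal the pre-trained halves bit for bit", {
  coh <- tiny_cohort(n_compounds = 3L, n_genes = 5L)
  ex <- tiny_examples(coh)
  cfg <- quick_cfg(epochs = 2L, seed = 10L)
  spec <- modified_autoencoder_spec(hidden = c(12L, 12L, 8L, 12L, 12L))
  graft <- pretrain_and_graft(ex, cfg, spec)
  for (i in 1:3) {
    expect_identical(graft$net$layers[[i]]$W, graft$source_ae$layers[[i]]$W)
    expect_identical(graft$net$layers[[i]]$b, graft$source_ae$layers[[i]]$b)
  }
  for (i in 4:6) {
    expect_identical(graft$net$layers[[i]]$W, graft$target_ae$layers[[i]]$W)
    expect_identical(graft$net$layers[[i]]$b, graft$target_ae$layers[[i]]$b)
  }
  # untrained autoencoders (epochs 0) graft their random initialisation
  spec0 <- modified_autoencoder_spec(hidden = c(12L, 12L, 8L, 12L, 12L),
                                     pretrain_epochs = 0L)
  graft0 <- pretrain_and_graft(ex, cfg, spec0)
  expect_identical(graft0$net$layers[[1L]]$W, graft0$source_ae$layers[[1L]]$W)
  # and those equal the seed-reproduced random init of the source AE
  set.seed(cfg$seed)
  ref <- txlate:::.net_init(txlate:::.apply_l1(txlate:::.build_dense_net(
    ncol(examples_source_matrix(ex)), ncol(examples_source_matrix(ex)),
    c(12L, 12L, 8L, 12L, 12L), c(2L, 3L, 4L)), cfg$l1_strength))
  expect_identical(graft0$source_ae$layers[[1L]]$W, ref$layers[[1L]]$W)
})

test_that("all model kinds emit finite predictions in [0, 1]", {
  coh <- tiny_cohort(n_compounds = 3L, n_genes = 8L)
  ex <- tiny_examples(coh)
  cfg <- quick_cfg(epochs = 2L, seed = 1L)
  specs <- list(naive_encoder_spec(hidden = c(16L, 8L, 4L, 8L, 16L)),
                modified_autoencoder_spec(hidden = c(10L, 10L, 6L, 10L, 10L)),
                cnn_spec(), knn_spec(3L), rrf_spec(n_trees = 3L))
  for (spec in specs) {
    pred <- predict(fit_model(spec, ex, cfg), ex[1:5])
    expect_true(all(is.finite(pred)))
    expect_gte(min(pred), 0)
    expect_lte(max(pred), 1)
    expect_equal(dim(pred), c(5L, 8L * 3L))
  }
  expect_error(fit_model(knn_spec(1L), ex[0]), "empty")
})

test_that("models round-trip through the JSON bundle", {
  coh <- tiny_cohort(n_compounds = 2L, n_genes = 8L)
  ex <- tiny_examples(coh)
  cfg <- quick_cfg(epochs = 2L, seed = 6L)
  specs <- list(naive_encoder_spec(hidden = c(8L, 6L, 4L, 6L, 8L)),
                modified_autoencoder_spec(hidden = c(8L, 8L, 6L, 8L, 8L)),
                cnn_spec(), knn_spec(2L), rrf_spec(n_trees = 2L))
  for (spec in specs) {
    m <- fit_model(spec, ex, cfg)
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    expect_lt(max(abs(predict(m, ex[1:3]) - predict(m2, ex[1:3]))), 1e-12)
  }
  expect_error(save_model(fit_model(custom_spec(identity), ex, cfg),
                          tempfile()), "cannot be saved")
})
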