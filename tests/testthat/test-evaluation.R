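# Error metric, BH adjustment, LOOCV aggregation, baseline comparison --
# each checked against an independent brute-force oracle where one exists.

brute_force_mae <- function(X, M) {
  s <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X)))
    s <- s + abs(X[i, j] - M[i, j])
  s / (nrow(X) * ncol(X))
}

# per-element enumeration of the step-up definition:
# adj for the i-th smallest p is min over k >= i of p_(k) * m / k, capped
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), 0)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

test_that("eq1_mae matches a brute-force double loop on random instances", {
  set.seed(123)
  for (rep in 1:100) {
    G <- sample(1:20, 1); Tn <- sample(2:5, 1)
    X <- matrix(runif(G * Tn), G, Tn)
    M <- matrix(runif(G * Tn), G, Tn)
    expect_lt(abs(eq1_mae(X, M) - brute_force_mae(X, M)), 1e-12)
  }
})

test_that("eq1_mae hand cases and degenerate inputs", {
  X <- matrix(c(0.2, 0.4), 1, 2)
  M <- matrix(c(0.3, 0.5), 1, 2)
  expect_equal(eq1_mae(X, M), 0.1)
  expect_equal(eq1_mae(X, X), 0)
  delta <- 0.07
  expect_equal(eq1_mae(X, X + delta), delta)
  expect_error(eq1_mae(matrix(0, 2, 2), matrix(0, 2, 3)), "shape mismatch")
  expect_error(eq1_mae(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("bh_adjust matches the textbook step-up on many random vectors", {
  set.seed(99)
  for (rep in 1:1000) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)                # rounded => frequent exact ties
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  # spot-check against the from-scratch oracle too (p.adjust independence)
  set.seed(100)
  for (rep in 1:50) {
    p <- runif(sample(1:6, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(bh_adjust(runif(10)) >= runif(0)))  # length-0 safe
  expect_length(bh_adjust(numeric(0)), 0L)
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("loocv with the oracle predictor is exact on a zero-noise cohort", {
  coh <- tiny_cohort(n_compounds = 3L, n_genes = 6L, noise = 0)
  ex <- tiny_examples(coh)
  spec <- oracle_predictor(coh, attr(ex, "target_scaling"))
  res <- run_loocv(spec, ex)
  expect_length(res$folds, 3L)
  expect_equal(vapply(res$folds, `[[`, 0, "mae"), rep(0, 3), tolerance = 1e-12)
  expect_equal(average_mae(res), 0, tolerance = 1e-12)
})

test_that("constant mean predictor's fold MAE equals the brute-force MAD", {
  coh <- tiny_cohort(n_compounds = 3L, n_genes = 5L)
  ex <- tiny_examples(coh)
  mean_of_training <- NULL
  spec <- custom_spec(function(examples)
    matrix(mean_of_training, length(examples), length(mean_of_training),
           byrow = TRUE))
  splits <- loco_splits(ex)
  res_folds <- numeric(length(splits))
  expected <- numeric(length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    mean_of_training <- colMeans(examples_target_matrix(sp$training))
    model <- fit_model(spec, sp$training)
    pred <- predict(model, sp$validation)
    meas <- examples_target_matrix(sp$validation)
    res_folds[i] <- mean(rowMeans(abs(meas - pred)))
    # independent brute force: mean absolute deviation of validation
    # targets from the training mean, averaged over examples
    devs <- vapply(seq_len(nrow(meas)), function(r)
      mean(abs(meas[r, ] - mean_of_training)), 0)
    expected[i] <- mean(devs)
  }
  expect_equal(res_folds, expected, tolerance = 1e-12)
})

test_that("per-compound fold results average into the overall score", {
  coh <- tiny_cohort(n_compounds = 4L, n_genes = 5L)
  ex <- tiny_examples(coh)
  res <- run_loocv(knn_spec(3L), ex)
  expect_length(res$folds, 4L)
  maes <- vapply(res$folds, `[[`, 0, "mae")
  expect_equal(average_mae(res), mean(maes))
  df <- as.data.frame(res)
  expect_equal(df$mae, maes)
  expect_equal(df$compound, coh$compounds)
  # per-gene errors average (over genes) back to something consistent:
  # both are means of |err| over the same entries, weighting equal
  pg <- res$folds[[1L]]$per_gene_mae
  expect_length(pg, 5L)
  expect_equal(mean(pg), res$folds[[1L]]$mae, tolerance = 1e-12)
})

test_that("paired comparison handles identical, better, and degenerate cases", {
  coh <- tiny_cohort(n_compounds = 5L, n_genes = 5L)
  ex <- tiny_examples(coh)
  base <- run_loocv(knn_spec(3L), ex)
  base$kind <- "rrf"
  # identical model: all differences zero -> degenerate t, p = 1
  rep0 <- compare_to_baseline(list(rrf = base, same = base), baseline = "rrf")
  expect_equal(rep0$p[rep0$model == "same"], 1)
  expect_false(rep0$significant[rep0$model == "same"])
  # strictly better by a fixed margin with tiny variance -> significant
  better <- base
  margin <- 0.01 + c(1e-6, -1e-6, 2e-6, -2e-6, 0)
  for (i in seq_along(better$folds))
    better$folds[[i]]$mae <- base$folds[[i]]$mae - margin[i]
  worse <- base
  for (i in seq_along(worse$folds))
    worse$folds[[i]]$mae <- base$folds[[i]]$mae + margin[i]
  rep1 <- compare_to_baseline(list(rrf = base, better = better, worse = worse),
                              baseline = "rrf")
  expect_lt(rep1$p_adj[rep1$model == "better"], 0.05)
  expect_true(rep1$significant[rep1$model == "better"])
  expect_false(rep1$significant[rep1$model == "worse"])  # worse, two-sided
  # agreement with stats::t.test as an independent reference
  d <- vapply(better$folds, `[[`, 0, "mae") - vapply(base$folds, `[[`, 0, "mae")
  ref <- stats::t.test(d)
  expect_equal(rep1$p[rep1$model == "better"], ref$p.value, tolerance = 1e-12)
  expect_equal(rep1$t[rep1$model == "better"], unname(ref$statistic),
               tolerance = 1e-12)
  # mismatched compound lists are rejected
  chopped <- base
  chopped$folds <- base$folds[c(2, 1, 3, 4, 5)]
  expect_error(compare_to_baseline(list(rrf = base, x = chopped)),
               "different compounds")
})

test_that("adjusted p-values never fall below raw p-values in reports", {
  set.seed(11)
  coh <- tiny_cohort(n_compounds = 4L, n_genes = 5L)
  ex <- tiny_examples(coh)
  res <- list(rrf = run_loocv(rrf_spec(n_trees = 3L), ex),
              knn = run_loocv(knn_spec(3L), ex),
              knn1 = run_loocv(knn_spec(1L), ex))
  res$knn1$kind <- "knn1"
  rep <- compare_to_baseline(res)
  nb <- rep$model != "rrf"
  expect_true(all(rep$p_adj[nb] >= rep$p[nb] - 1e-15))
})
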