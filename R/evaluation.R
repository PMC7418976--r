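# Leave-one-compound-out evaluation: the mean-absolute-error metric over
# genes and time points (used both as training loss and validation error),
# per-compound aggregation, and the paired-t / Benjamini-Hochberg model
# comparison against the random-regression-forest baseline.

#' Mean absolute error over genes and time points
#'
#' `MAE = 1/(G*T) * sum_i sum_j |X_ij - M_ij|` for a measured encoded
#' trajectory X and a model prediction M of identical shape.  Zero if and
#' only if the two agree exactly.
#'
#' @param X,M numeric matrices (G x T) or equal-length vectors.
#' @return Nonnegative scalar.
#' @export
eq1_mae <- function(X, M) {
  if (is.matrix(X) || is.matrix(M)) {
    if (!identical(dim(X), dim(M)))
      stop("shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
           paste(dim(M), collapse = "x"))
  } else if (length(X) != length(M)) {
    stop("length mismatch: ", length(X), " vs ", length(M))
  }
  mean(abs(X - M))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook step-up procedure: sort the m raw p-values ascending, compute
#' `p_(i) * m / i`, enforce monotonicity by a cumulative minimum from the
#' largest rank down, and cap at 1.  Adjusted values are always >= raw
#' values.
#'
#' @param p numeric vector of raw p-values.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Run leave-one-compound-out cross-validation
#'
#' For every compound: a fresh model is fitted on all other compounds'
#' examples and evaluated on the held-out compound's examples with
#' [eq1_mae()] in encoded space; the per-example errors are averaged into
#' one fold-level MAE per compound.  The overall score is the arithmetic
#' mean of the fold MAEs.
#'
#' @param spec a `model_spec` (any kind, including [custom_spec()]).
#' @param examples a [build_examples()] result covering >= 2 compounds.
#' @param cfg a [training_config()]; fold i trains with seed
#'   `cfg$seed + i - 1` so folds get independent initialisations while the
#'   whole run stays reproducible.
#' @param verbose print per-fold progress.
#' @return An object of class `loocv_result`: list of `fold_result`
#'   records (`compound`, `mae`, `per_gene_mae`, `n_examples`) with the
#'   model kind and overall mean attached.
#' @export
run_loocv <- function(spec, examples, cfg = training_config(),
                      verbose = FALSE) {
  splits <- loco_splits(examples)
  Tn <- attr(examples, "n_times_target")
  folds <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i - 1L
    model <- tryCatch(
      fit_model(spec, sp$training, fold_cfg),
      error = function(e) stop("fold '", sp$held_out_compound, "': ",
                               conditionMessage(e)))
    pred <- predict(model, sp$validation)
    meas <- examples_target_matrix(sp$validation)
    per_example <- rowMeans(abs(meas - pred))
    abs_err <- colMeans(abs(meas - pred))       # mean over examples, per entry
    per_gene <- if (!is.null(Tn))
      rowMeans(matrix(abs_err, ncol = Tn, byrow = TRUE)) else NULL
    folds[[i]] <- structure(
      list(compound = sp$held_out_compound, mae = mean(per_example),
           per_gene_mae = per_gene, n_examples = length(sp$validation)),
      class = "fold_result")
    if (verbose)
      message(sprintf("fold %d/%d (%s): MAE %.5f", i, length(splits),
                      sp$held_out_compound, folds[[i]]$mae))
  }
  structure(list(folds = folds, kind = spec$kind,
                 overall = mean(vapply(folds, `[[`, 0, "mae"))),
            class = "loocv_result")
}

#' @exportS3Method base::print
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: average MAE %.5f over %d compounds\n",
              x$kind, x$overall, length(x$folds)))
  invisible(x)
}

#' Per-compound fold errors as a data.frame
#'
#' @param x a `loocv_result`.
#' @param ... unused.
#' @return data.frame with columns `compound` and `mae`.
#' @export
as.data.frame.loocv_result <- function(x, ...) {
  data.frame(compound = vapply(x$folds, `[[`, "", "compound"),
             mae = vapply(x$folds, `[[`, 0, "mae"),
             stringsAsFactors = FALSE)
}

#' Average MAE of a cross-validation run
#'
#' @param result a `loocv_result`.
#' @return The arithmetic mean of the per-compound fold MAEs.
#' @export
average_mae <- function(result) {
  stopifnot(inherits(result, "loocv_result"))
  result$overall
}

# paired two-tailed t-test on per-compound differences; degenerate
# zero-variance differences report p = 1 (identical) or p = 0 (constant
# nonzero shift) rather than failing
.paired_t <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2L || s == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1L))
}

#' Compare models against the forest baseline
#'
#' Paired two-tailed t-tests on per-compound fold MAEs (model minus
#' baseline), Benjamini-Hochberg-adjusted across the model comparisons
#' within this gene set.  A model is flagged significantly better when its
#' mean MAE is below the baseline's and the adjusted p-value is below
#' `alpha`.
#'
#' @param results_by_model named list of `loocv_result` objects over
#'   identical compound lists, one of which is the baseline.
#' @param baseline name of the baseline entry (default `"rrf"`).
#' @param alpha significance level for the adjusted p-values.
#' @return An `evaluation_report` data.frame: one row per model with
#'   `mean_mae`, and for non-baseline rows `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
compare_to_baseline <- function(results_by_model, baseline = "rrf",
                                alpha = 0.05) {
  stopifnot(baseline %in% names(results_by_model))
  cmp_lists <- lapply(results_by_model, function(r)
    vapply(r$folds, `[[`, "", "compound"))
  for (nm in names(cmp_lists))
    if (!identical(cmp_lists[[nm]], cmp_lists[[baseline]]))
      stop("model '", nm, "' was evaluated on different compounds/order ",
           "than the baseline")
  mae_of <- function(r) vapply(r$folds, `[[`, 0, "mae")
  base_mae <- mae_of(results_by_model[[baseline]])
  models <- names(results_by_model)
  rows <- lapply(models, function(nm) {
    m <- mae_of(results_by_model[[nm]])
    if (nm == baseline)
      return(data.frame(model = nm, mean_mae = mean(m), t = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    tt <- .paired_t(m - base_mae)
    data.frame(model = nm, mean_mae = mean(m), t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  non_base <- report$model != baseline
  report$p_adj <- NA_real_
  report$p_adj[non_base] <- bh_adjust(report$p[non_base])
  report$significant <- !is.na(report$p_adj) & report$p_adj < alpha &
    report$mean_mae < report$mean_mae[report$model == baseline]
  class(report) <- c("evaluation_report", "data.frame")
  attr(report, "baseline") <- baseline
  attr(report, "alpha") <- alpha
  report
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> baseline: %s\n", attr(x, "baseline")))
  df <- as.data.frame(x)
  df$mean_mae <- sprintf("%.5f", df$mean_mae)
  star <- ifelse(!is.na(df$significant) & df$significant, " *", "")
  df$mean_mae <- paste0(df$mean_mae, star)
  print(df[, c("model", "mean_mae", "t", "p", "p_adj")], row.names = FALSE)
  invisible(x)
}
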