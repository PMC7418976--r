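# Rendering: models x gene-sets summary tables (best model emboldened,
# significant improvements over the baseline starred) and per-gene overlay
# plots of measured source, measured target (all replicates) and predicted
# trajectories.

#' Summary table across gene sets
#'
#' Combines per-gene-set [compare_to_baseline()] reports into one models x
#' gene-sets table of average MAEs.  The best (lowest) model per gene set
#' is wrapped in `**bold**` markers and models significantly better than
#' the baseline are starred, mirroring the usual presentation of such
#' benchmarks.
#'
#' @param reports_by_geneset named list of `evaluation_report` objects
#'   (names = gene-set labels), all covering the same models.
#' @param digits significant digits to print.
#' @return data.frame with one row per model, one column per gene set.
#' @export
summary_table <- function(reports_by_geneset, digits = 4L) {
  stopifnot(length(reports_by_geneset) >= 1L)
  models <- reports_by_geneset[[1L]]$model
  cols <- lapply(reports_by_geneset, function(rep) {
    stopifnot(identical(rep$model, models))
    val <- signif(rep$mean_mae, digits)
    txt <- format(val, trim = TRUE)
    txt[which.min(rep$mean_mae)] <- paste0("**", txt[which.min(rep$mean_mae)],
                                           "**")
    txt[rep$significant] <- paste0(txt[rep$significant], "*")
    txt
  })
  out <- data.frame(model = models, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("model", names(reports_by_geneset))
  out
}

#' @rdname summary_table
#' @param path TSV output path.
#' @export
write_summary_table <- function(reports_by_geneset, path, digits = 4L) {
  tab <- summary_table(reports_by_geneset, digits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# measured trajectories of every replicate for one compound-dose cell
.replicate_curves <- function(dataset, genes, compound, dose) {
  lapply(seq_len(dataset$design$n_replicates), function(r)
    extract_trajectory(dataset, genes, compound, dose, r))
}

#' Overlay plot of measured and predicted trajectories
#'
#' One panel per gene: the measured source-domain trajectories (red,
#' dashed), the measured target-domain replicates (blue) and the model
#' prediction (orange) against time.  With `decoded = TRUE` curves are
#' drawn in expression units (predictions decoded through the target
#' scaling); otherwise in encoded \[0, 1\] entries.
#'
#' @param model a `trained_model` fitted on examples carrying gene-set
#'   attributes.
#' @param source,target [domain_dataset()] objects.
#' @param examples the [build_examples()] result the model was fitted on
#'   (supplies gene sets and scalings).
#' @param compound,dose cell to visualise.
#' @param genes subset of target gene ids to draw (default: first 12).
#' @param decoded draw expression units rather than encoded entries.
#' @param file optional PDF path; when `NULL`, draws on the active device.
#' @return The file path (or `NULL`), invisibly.
#' @export
plot_overlays <- function(model, source, target, examples, compound, dose,
                          genes = NULL, decoded = TRUE, file = NULL) {
  src_genes <- attr(examples, "source_genes")
  tgt_genes <- attr(examples, "target_genes")
  src_scaling <- attr(examples, "source_scaling")
  tgt_scaling <- attr(examples, "target_scaling")
  if (is.null(genes)) genes <- utils::head(tgt_genes$gene_ids, 12L)
  gsel <- match(genes, tgt_genes$gene_ids)
  if (anyNA(gsel)) stop("genes not in the target gene set")
  src_curves <- .replicate_curves(source, src_genes, compound, dose)
  tgt_curves <- .replicate_curves(target, tgt_genes, compound, dose)
  raw_src <- src_curves[[1L]]
  enc_src <- encode_trajectory(raw_src, src_scaling, compound, dose, 1L)
  example <- structure(list(source = enc_src, compound = compound,
                            dose = dose), class = "learning_example")
  pred_enc <- predict_instance(model, example)
  t_src <- source$design$time_points_h
  t_tgt <- target$design$time_points_h
  if (decoded) {
    pred <- decode_trajectory(pred_enc, tgt_scaling)
  } else {
    pred <- to_matrix_layout(pred_enc)
    src_curves <- lapply(src_curves, function(m)
      to_matrix_layout(encode_trajectory(m, src_scaling)))
    tgt_curves <- lapply(tgt_curves, function(m)
      to_matrix_layout(encode_trajectory(m, tgt_scaling)))
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 2.2 * ceiling(length(gsel) / 4))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(length(gsel) / 4), min(4, length(gsel))),
                      mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (gi in seq_along(gsel)) {
    g <- gsel[gi]   # position in the ordered set; source set is
                    # position-aligned (possibly different identifiers)
    ylim <- range(unlist(lapply(src_curves, function(m) m[g, ])),
                  unlist(lapply(tgt_curves, function(m) m[g, ])), pred[g, ])
    graphics::plot(NA, xlim = range(c(t_src, t_tgt)), ylim = ylim,
                   xlab = "time (h)",
                   ylab = if (decoded) "expression" else "encoded",
                   main = genes[gi], cex.main = 0.9)
    for (m in src_curves)
      graphics::lines(t_src, m[g, ], col = "firebrick", lty = 2)
    for (m in tgt_curves)
      graphics::lines(t_tgt, m[g, ], col = "steelblue")
    graphics::lines(t_tgt, pred[g, ], col = "darkorange", lwd = 2)
  }
  invisible(file)
}

#' Render an evaluation report to files
#'
#' Writes the models x gene-sets summary table (TSV) and, when overlay
#' requests are supplied, one PDF of prediction overlays per request.
#'
#' @param reports_by_geneset named list of `evaluation_report` objects.
#' @param dir output directory (created if missing).
#' @param overlays optional list of requests, each a list with fields
#'   `model`, `source`, `target`, `examples`, `compound`, `dose` and
#'   optionally `genes`/`decoded`, passed to [plot_overlays()].
#' @return Character vector of the files written.
#' @export
render_report <- function(reports_by_geneset, dir, overlays = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "summary.tsv")
  write_summary_table(reports_by_geneset, files)
  for (i in seq_along(overlays)) {
    ov <- overlays[[i]]
    f <- file.path(dir, sprintf("overlay_%s_%s_%d.pdf", ov$compound,
                                ov$dose, i))
    plot_overlays(ov$model, ov$source, ov$target, ov$examples, ov$compound,
                  ov$dose, genes = ov$genes,
                  decoded = if (is.null(ov$decoded)) TRUE else ov$decoded,
                  file = f)
    files <- c(files, f)
  }
  files
}
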