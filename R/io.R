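# Portable on-disk model bundles: a JSON document holding the architecture
# description plus flattened weight arrays (networks), the memorised
# design matrices (knn) or the tree list (rrf).  Networks are rebuilt from
# their spec on load and re-filled from the parameter vector, so nothing
# binary or session-specific is stored.

#' Save or load a trained model
#'
#' @param model a `trained_model` (kind `custom` cannot be serialized).
#' @param path file path of the JSON bundle.
#' @return `save_model` returns the path invisibly; `load_model` a
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  if (model$kind == "custom")
    stop("custom predictors hold arbitrary functions and cannot be saved")
  bundle <- list(kind = model$kind,
                 spec = unclass(model$spec),
                 cfg = unclass(model$cfg),
                 meta = list(
                   n_times_target = model$meta$n_times_target,
                   target_gene_ids = model$meta$target_genes$gene_ids,
                   target_scaling = if (!is.null(model$meta$target_scaling))
                     unclass(model$meta$target_scaling)))
  bundle$spec$predict_fun <- NULL
  if (model$kind %in% c("naive_encoder", "modified_autoencoder", "cnn")) {
    bundle$params <- .net_get_params(model$fitted$net)
    bundle$history <- model$fitted$history
  } else if (model$kind == "knn") {
    bundle$knn <- list(X = model$fitted$X, Y = model$fitted$Y)
  } else if (model$kind == "rrf") {
    bundle$rrf <- model$fitted
  }
  writeLines(jsonlite::serializeJSON(bundle, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                            collapse = "\n"))
  spec <- structure(bundle$spec, class = "model_spec")
  cfg <- structure(bundle$cfg, class = "training_config")
  meta <- list(
    n_times_target = bundle$meta$n_times_target,
    target_genes = if (!is.null(bundle$meta$target_gene_ids))
      gene_set("loaded", bundle$meta$target_gene_ids),
    target_scaling = if (!is.null(bundle$meta$target_scaling))
      structure(bundle$meta$target_scaling, class = "scaling_params"))
  fitted <- switch(
    bundle$kind,
    knn = bundle$knn,
    rrf = bundle$rrf,
    {
      net <- .net_alloc(.apply_l1(.spec_to_net(spec), cfg$l1_strength))
      list(net = .net_set_params(net, bundle$params),
           history = bundle$history)
    })
  structure(list(spec = spec, kind = bundle$kind, fitted = fitted,
                 cfg = cfg, history = bundle$history, meta = meta),
            class = "trained_model")
}
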