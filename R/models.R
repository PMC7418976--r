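# The five translation models behind one fit/predict contract:
#   naive_encoder        dense bottleneck net 256-160-32-96-256
#   modified_autoencoder same-shape net 70-70-60-70-70, initialised by
#                        grafting pre-trained per-domain AE halves
#   cnn                  gene-axis convolutions 16@10 / 8@10 / 4@2 + pools,
#                        dense head 20-30-out
#   knn                  unweighted k-nearest-neighbour mean
#   rrf                  multi-output random regression forest
# Networks train with Adam on the mean absolute error of the encoded
# target; outputs pass through a sigmoid, so predictions stay in [0, 1].

#' Training configuration for the network models
#'
#' The study reports the optimizer (Adam) and loss (mean absolute error
#' over genes and time points) but no training hyperparameters; these
#' defaults are the package's own, chosen to be stable on cohorts of a few
#' hundred examples at a few hundred input dimensions.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param epochs number of passes over the training examples (>= 1; 0 is
#'   allowed and returns the untrained, seed-reproducible network).
#' @param batch_size mini-batch size.
#' @param l1_strength coefficient of the L1 activity penalty on the layers
#'   each architecture flags for it.
#' @param seed integer seed governing weight initialisation and batch
#'   shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-8, epochs = 200L, batch_size = 32L,
                            l1_strength = 1e-5, seed = 1L) {
  stopifnot(epochs >= 0, l1_strength >= 0, batch_size >= 1,
            learning_rate > 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 l1_strength = l1_strength, seed = as.integer(seed)),
            class = "training_config")
}

# NB: first parameter deliberately dot-prefixed so hyperparameter names
# passed through ... (like k) can never partially match it
.new_spec <- function(.kind, ...) {
  structure(c(list(kind = .kind), list(...)), class = "model_spec")
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s\n", x$kind))
  invisible(x)
}

#' Bottleneck feed-forward network specification
#'
#' Five dense hidden layers of 256, 160, 32, 96 and 256 nodes (ReLU), a
#' sigmoid output layer, and an L1 activity penalty on all five hidden
#' layers.  The 32-node bottleneck forces a compressed latent
#' representation of the source trajectory.
#'
#' @param input_dim,output_dim flat encoded dimensions (G*T per side);
#'   leave `NULL` to infer from the training examples at fit time.
#' @param hidden hidden-layer widths.
#' @return A `model_spec` of kind `"naive_encoder"`.
#' @export
naive_encoder_spec <- function(input_dim = NULL, output_dim = NULL,
                               hidden = c(256L, 160L, 32L, 96L, 256L)) {
  .new_spec("naive_encoder", input_dim = input_dim, output_dim = output_dim,
            hidden = as.integer(hidden))
}

#' Modified-autoencoder specification
#'
#' Same fit/predict contract as the other networks, but with hidden widths
#' 70, 70, 60, 70, 70 and a pre-training stage: one autoencoder per domain
#' (identical layout, input = output = that domain's instances) is trained
#' to reconstruct its own domain, then the prediction network is
#' initialised with the source autoencoder's encoder half (layers 1-3) and
#' the target autoencoder's decoder half (layers 4-5 plus output) before
#' fine-tuning on the paired examples.  L1 activity regularization applies
#' to the three middle hidden layers.
#'
#' @param input_dim,output_dim flat encoded dimensions, or `NULL` to infer.
#' @param hidden hidden-layer widths (encoder, bottleneck, decoder).
#' @param pretrain_epochs epochs for each autoencoder pre-training run;
#'   `NULL` reuses the fine-tuning epoch count.
#' @return A `model_spec` of kind `"modified_autoencoder"`.
#' @export
modified_autoencoder_spec <- function(input_dim = NULL, output_dim = NULL,
                                      hidden = c(70L, 70L, 60L, 70L, 70L),
                                      pretrain_epochs = NULL) {
  .new_spec("modified_autoencoder", input_dim = input_dim,
            output_dim = output_dim, hidden = as.integer(hidden),
            pretrain_epochs = pretrain_epochs)
}

#' Gene-axis convolutional network specification
#'
#' Consumes the G x T matrix layout.  Three convolution/max-pool blocks
#' slide along the gene axis only (16 filters with a 10x1 kernel, 8 with
#' 10x1, 4 with 2x1; pool size 2x1, floor division), with same-padding so
#' small gene panels remain valid; the pooled maps are flattened into a
#' dense head of 20 (with L1 activity penalty) and 30 ReLU nodes and a
#' sigmoid output layer.
#'
#' @param n_genes,n_times source-side panel size and time-point count;
#'   `NULL` to infer from the training examples.
#' @param output_dim flat target dimension, or `NULL` to infer.
#' @param filters,kernels per-block filter counts and kernel lengths.
#' @param dense widths of the two hidden dense head layers.
#' @return A `model_spec` of kind `"cnn"`.
#' @export
cnn_spec <- function(n_genes = NULL, n_times = NULL, output_dim = NULL,
                     filters = c(16L, 8L, 4L), kernels = c(10L, 10L, 2L),
                     dense = c(20L, 30L)) {
  stopifnot(length(filters) == length(kernels))
  .new_spec("cnn", n_genes = n_genes, n_times = n_times,
            output_dim = output_dim, filters = as.integer(filters),
            kernels = as.integer(kernels), dense = as.integer(dense))
}

#' k-nearest-neighbour baseline specification
#'
#' Euclidean distance on flat encoded source vectors; the prediction is the
#' unweighted mean of the k nearest training examples' target vectors.
#'
#' @param k neighbourhood size.
#' @return A `model_spec` of kind `"knn"`.
#' @export
knn_spec <- function(k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  .new_spec("knn", k = k)
}

#' Custom-predictor specification
#'
#' Wraps an arbitrary prediction function under the common fit/predict
#' contract, e.g. the synthetic cohort's noise-free oracle or a constant
#' predictor.  `predict_fun(examples)` must return an n x output_dim
#' matrix of encoded target values for a list of learning examples.
#'
#' @param predict_fun function of a list of learning examples.
#' @return A `model_spec` of kind `"custom"`.
#' @export
custom_spec <- function(predict_fun) {
  stopifnot(is.function(predict_fun))
  .new_spec("custom", predict_fun = predict_fun)
}

# ---- spec -> network construction ---------------------------------------

.build_dense_net <- function(input_dim, output_dim, hidden, l1_layers) {
  dims <- c(input_dim, hidden)
  layers <- lapply(seq_along(hidden), function(i)
    .layer_dense(dims[i], dims[i + 1L], "relu",
                 l1 = if (i %in% l1_layers) NA_real_ else 0))
  layers[[length(layers) + 1L]] <-
    .layer_dense(hidden[length(hidden)], output_dim, "sigmoid", l1 = 0)
  list(layers = layers)
}

.build_cnn_net <- function(spec) {
  G <- spec$n_genes; Tn <- spec$n_times
  if (G < 2L) stop("CNN needs at least 2 genes on the gene axis")
  layers <- list(.layer_fold_time(G, Tn))
  ch <- 1L
  g <- G
  for (i in seq_along(spec$filters)) {
    layers[[length(layers) + 1L]] <- .layer_conv(g, ch, spec$filters[i],
                                                 spec$kernels[i])
    ch <- spec$filters[i]
    layers[[length(layers) + 1L]] <- .layer_pool(g, ch)
    g <- g %/% 2L
    if (g < 1L) stop("gene axis exhausted by pooling; panel too small")
  }
  layers[[length(layers) + 1L]] <- .layer_flatten(g, ch, Tn)
  flat <- g * ch * Tn
  dims <- c(flat, spec$dense)
  for (i in seq_along(spec$dense))
    layers[[length(layers) + 1L]] <-
      .layer_dense(dims[i], dims[i + 1L], "relu",
                   l1 = if (i == 1L) NA_real_ else 0)
  layers[[length(layers) + 1L]] <-
    .layer_dense(spec$dense[length(spec$dense)], spec$output_dim,
                 "sigmoid", l1 = 0)
  list(layers = layers)
}

# substitute the configured L1 strength into flagged (NA) layers
.apply_l1 <- function(net, l1_strength) {
  net$layers <- lapply(net$layers, function(ly) {
    if (!is.null(ly$l1) && is.na(ly$l1)) ly$l1 <- l1_strength
    ly
  })
  net
}

.resolve_dims <- function(spec, X, Y, examples) {
  if (spec$kind == "cnn") {
    if (is.null(spec$n_times)) {
      spec$n_times <- attr(examples, "n_times_source")
      if (is.null(spec$n_times))
        stop("cnn_spec needs n_times (not inferable from these examples)")
    }
    if (is.null(spec$n_genes)) spec$n_genes <- ncol(X) / spec$n_times
    stopifnot(spec$n_genes * spec$n_times == ncol(X))
  } else {
    if (is.null(spec$input_dim)) spec$input_dim <- ncol(X)
    if (spec$input_dim != ncol(X))
      stop("spec input_dim ", spec$input_dim, " != data dimension ", ncol(X))
  }
  if (is.null(spec$output_dim)) spec$output_dim <- ncol(Y)
  if (spec$output_dim != ncol(Y))
    stop("spec output_dim ", spec$output_dim, " != data dimension ", ncol(Y))
  spec
}

.spec_to_net <- function(spec) {
  switch(spec$kind,
         naive_encoder = .build_dense_net(spec$input_dim, spec$output_dim,
                                          spec$hidden,
                                          seq_along(spec$hidden)),
         modified_autoencoder = .build_dense_net(spec$input_dim,
                                                 spec$output_dim, spec$hidden,
                                                 l1_layers = c(2L, 3L, 4L)),
         cnn = .build_cnn_net(spec),
         stop("not a network spec: ", spec$kind))
}

# ---- grafting -------------------------------------------------------------

#' Pre-train per-domain autoencoders and graft their halves
#'
#' Trains one autoencoder per domain to reconstruct that domain's encoded
#' instances, then initialises the prediction network by concatenating the
#' source autoencoder's encoder weights (layers 1-3) with the target
#' autoencoder's decoder weights (layers 4-5 and output).  The returned
#' network is *not* yet fine-tuned.
#'
#' @param examples a [build_examples()] result.
#' @param cfg a [training_config()]; pre-training uses `cfg` (with
#'   `pretrain_epochs` from the model specification, if set) and derived
#'   seeds.
#' @param spec a [modified_autoencoder_spec()].
#' @return List with the grafted `net`, both trained autoencoders, and the
#'   resolved `spec`.
#' @export
pretrain_and_graft <- function(examples, cfg, spec = modified_autoencoder_spec()) {
  stopifnot(spec$kind == "modified_autoencoder")
  X <- examples_source_matrix(examples)
  Y <- examples_target_matrix(examples)
  spec <- .resolve_dims(spec, X, Y, examples)
  pre_cfg <- cfg
  if (!is.null(spec$pretrain_epochs)) pre_cfg$epochs <- as.integer(spec$pretrain_epochs)
  # per-domain reconstruction autoencoders, same layout as the predictor
  src_ae <- .apply_l1(.build_dense_net(spec$input_dim, spec$input_dim,
                                       spec$hidden, c(2L, 3L, 4L)),
                      cfg$l1_strength)
  tgt_ae <- .apply_l1(.build_dense_net(spec$output_dim, spec$output_dim,
                                       spec$hidden, c(2L, 3L, 4L)),
                      cfg$l1_strength)
  src_cfg <- pre_cfg; src_cfg$seed <- cfg$seed
  tgt_cfg <- pre_cfg; tgt_cfg$seed <- cfg$seed + 1L
  src_fit <- .net_train(src_ae, X, X, src_cfg)
  tgt_fit <- .net_train(tgt_ae, Y, Y, tgt_cfg)
  net <- .apply_l1(.spec_to_net(spec), cfg$l1_strength)
  n_hidden <- length(spec$hidden)
  encoder_layers <- seq_len((n_hidden + 1L) %/% 2L)          # 1..3
  decoder_layers <- setdiff(seq_len(n_hidden + 1L), encoder_layers)
  for (i in encoder_layers) {
    net$layers[[i]]$W <- src_fit$net$layers[[i]]$W
    net$layers[[i]]$b <- src_fit$net$layers[[i]]$b
  }
  for (i in decoder_layers) {
    net$layers[[i]]$W <- tgt_fit$net$layers[[i]]$W
    net$layers[[i]]$b <- tgt_fit$net$layers[[i]]$b
  }
  list(net = net, source_ae = src_fit$net, target_ae = tgt_fit$net,
       spec = spec)
}

# ---- fit / predict --------------------------------------------------------

#' Fit a translation model
#'
#' Trains the model described by `spec` on paired learning examples.
#' Network models minimise the mean absolute error of the encoded target
#' (plus L1 activity penalties) with Adam; `knn` and `rrf` memorise /
#' ensemble the flat design matrices; `custom` stores its prediction
#' function.
#'
#' @param spec a `model_spec`.
#' @param examples a [build_examples()] result (or subset) to train on.
#' @param cfg a [training_config()] (ignored by `knn`, `rrf` and `custom`
#'   except for the seed used by `rrf`).
#' @return An object of class `trained_model`.
#' @export
fit_model <- function(spec, examples, cfg = training_config()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind != "custom" && length(examples) == 0L)
    stop("cannot fit on an empty training set")
  meta <- list(target_genes = attr(examples, "target_genes"),
               target_scaling = attr(examples, "target_scaling"),
               n_times_target = attr(examples, "n_times_target"))
  if (spec$kind == "custom") {
    return(structure(list(spec = spec, kind = "custom", meta = meta),
                     class = "trained_model"))
  }
  X <- examples_source_matrix(examples)
  Y <- examples_target_matrix(examples)
  spec <- .resolve_dims(spec, X, Y, examples)
  fitted <- switch(
    spec$kind,
    knn = {
      if (spec$k > nrow(X))
        stop("k = ", spec$k, " exceeds the training-set size ", nrow(X))
      list(X = X, Y = Y)
    },
    rrf = .fit_rrf(X, Y, spec, seed = cfg$seed),
    modified_autoencoder = {
      graft <- pretrain_and_graft(examples, cfg, spec)
      spec <- graft$spec
      ft_cfg <- cfg; ft_cfg$seed <- cfg$seed + 2L
      fit <- .net_train(graft$net, X, Y, ft_cfg, init = FALSE)
      .check_history(fit$history)
      c(fit, list(graft = graft))
    },
    {
      net <- .apply_l1(.spec_to_net(spec), cfg$l1_strength)
      fit <- .net_train(net, X, Y, cfg)
      .check_history(fit$history)
      fit
    })
  structure(list(spec = spec, kind = spec$kind, fitted = fitted, cfg = cfg,
                 history = fitted$history, meta = meta),
            class = "trained_model")
}

.check_history <- function(history) {
  if (length(history) && any(!is.finite(history)))
    stop("training diverged: non-finite loss at epoch ",
         which(!is.finite(history))[1L])
}

#' @exportS3Method base::print
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s", x$kind))
  if (!is.null(x$history) && length(x$history))
    cat(sprintf(": final training MAE %.5f after %d epochs",
                x$history[length(x$history)], length(x$history)))
  cat("\n")
  invisible(x)
}

#' Predict encoded target trajectories
#'
#' @param object a [fit_model()] result.
#' @param newdata a list of learning examples (their source side is used),
#'   a single `encoded_instance`, or an n x input_dim matrix of flat
#'   encoded source vectors.
#' @param ... unused.
#' @return n x output_dim matrix of encoded target values; network outputs
#'   are guaranteed to lie in \[0, 1\].
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (inherits(newdata, "encoded_instance"))
    newdata <- list(structure(list(source = newdata), class = "learning_example"))
  X <- if (is.matrix(newdata)) newdata else
    do.call(rbind, lapply(newdata, function(e) to_flat_layout(e$source)))
  pred <- switch(
    object$kind,
    custom = {
      if (is.matrix(newdata))
        stop("a custom predictor needs learning examples, not a bare matrix")
      object$spec$predict_fun(newdata)
    },
    knn = .predict_knn(object$fitted, X, object$spec$k),
    rrf = .predict_rrf(object$fitted, X),
    .net_predict(object$fitted$net, X))
  pred <- as.matrix(pred)
  if (!all(is.finite(pred))) stop("non-finite prediction")
  if (!object$kind %in% c("custom")) {
    # knn/rrf average observed encoded targets, networks end in a sigmoid;
    # either way predictions must stay in the encoded unit interval
    stopifnot(min(pred) >= 0, max(pred) <= 1)
  }
  pred
}

.predict_knn <- function(fitted, X, k) {
  tr <- fitted$X
  d2 <- outer(rowSums(X^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(X)), rowSums(tr^2)) - 2 * X %*% t(tr)
  t(apply(d2, 1L, function(dr) {
    nn <- order(dr)[seq_len(k)]              # ties broken by example order
    colMeans(fitted$Y[nn, , drop = FALSE])
  }))
}

#' Predict one instance as an encoded instance
#'
#' Convenience wrapper around [predict.trained_model()] that re-attaches
#' gene and layout structure so the result can be decoded or plotted.
#'
#' @param model a `trained_model` fitted on examples built with gene-set
#'   attributes.
#' @param example a `learning_example` (its source side is used).
#' @return An `encoded_instance` for the target domain.
#' @export
predict_instance <- function(model, example) {
  pred <- predict(model, list(example))
  Tn <- model$meta$n_times_target
  genes <- model$meta$target_genes$gene_ids
  values <- matrix(pred[1L, ], ncol = Tn, byrow = TRUE)
  rownames(values) <- genes
  colnames(values) <- c("level", sprintf("slope%d", seq_len(Tn - 1L)))
  structure(list(compound = example$compound, dose = example$dose,
                 replicate = NA_integer_, layout = "matrix", values = values),
            class = "encoded_instance")
}
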