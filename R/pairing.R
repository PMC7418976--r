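# Learning-example construction: pairwise replicate matching of encoded
# compound-dose trajectories across the two domains, and the
# leave-one-compound-out split machinery.

#' Randomly discard one replicate per compound-dose cell
#'
#' The in vivo arm carries three biological replicates where the in vitro
#' arms carry two; to keep the pairing combinatorics identical across
#' domain pairs, one of the three replicates is discarded uniformly at
#' random (seeded), independently for every compound-dose cell.  Remaining
#' replicates are renumbered 1..2.
#'
#' @param dataset a [domain_dataset()] with exactly 3 replicates.
#' @param seed integer seed for the discard pattern.
#' @return A [domain_dataset()] with 2 replicates.
#' @export
discard_in_vivo_replicate <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "domain_dataset"))
  if (dataset$design$n_replicates != 3L)
    stop("replicate discard expects a 3-replicate domain, got ",
         dataset$design$n_replicates)
  md <- dataset$metadata
  set.seed(seed)
  keep <- rep(TRUE, nrow(md))
  new_rep <- md$replicate
  for (cmp in unique(md$compound)) {
    for (dose in dataset$design$dose_levels) {
      cell <- md$compound == cmp & md$dose == dose
      drop_rep <- sample.int(3L, 1L)
      keep[cell & md$replicate == drop_rep] <- FALSE
      survivors <- sort(setdiff(1:3, drop_rep))
      new_rep[cell] <- match(md$replicate[cell], survivors)
    }
  }
  md$replicate <- new_rep
  md <- md[keep, , drop = FALSE]
  design <- dataset$design
  design$n_replicates <- 2L
  domain_dataset(design, dataset$gene_ids,
                 dataset$expression[, keep, drop = FALSE], md)
}

#' Build paired learning examples from two domains
#'
#' For every shared compound-dose combination, every source replicate is
#' paired with every target replicate (a 2 x 2 cross gives four examples
#' per combination), each side encoded with its own domain's scaling.
#' With 45 compounds and 4 dose levels this yields 720 examples.  Ordering
#' is deterministic: compound, then dose, then source replicate, then
#' target replicate.
#'
#' @param source,target [domain_dataset()] objects sharing compound and
#'   dose labels.
#' @param source_genes a [gene_set()] for the source domain.
#' @param target_genes a [gene_set()] for the target domain (defaults to
#'   `source_genes`, appropriate when both domains use the same
#'   identifiers).
#' @param source_scaling,target_scaling optional [fit_scaling()] results;
#'   by default fitted on each full dataset.
#' @return An object of class `learning_examples`: a list of
#'   `learning_example` records (fields `source`, `target`, `compound`,
#'   `dose`, `source_replicate`, `target_replicate`) carrying the gene sets
#'   and scalings as attributes.
#' @export
build_examples <- function(source, target, source_genes,
                           target_genes = source_genes,
                           source_scaling = NULL, target_scaling = NULL) {
  stopifnot(inherits(source, "domain_dataset"),
            inherits(target, "domain_dataset"))
  if (!setequal(source$compounds, target$compounds))
    stop("source and target must share the same compounds")
  if (!setequal(source$design$dose_levels, target$design$dose_levels))
    stop("source and target must share the same dose levels")
  if (is.null(source_scaling)) source_scaling <- fit_scaling(source, source_genes)
  if (is.null(target_scaling)) target_scaling <- fit_scaling(target, target_genes)
  compounds <- source$compounds
  doses <- source$design$dose_levels
  rs <- seq_len(source$design$n_replicates)
  rt <- seq_len(target$design$n_replicates)
  examples <- list()
  for (cmp in compounds) {
    for (dose in doses) {
      enc_s <- lapply(rs, function(r)
        encode_trajectory(extract_trajectory(source, source_genes, cmp, dose, r),
                          source_scaling, cmp, dose, r))
      enc_t <- lapply(rt, function(r)
        encode_trajectory(extract_trajectory(target, target_genes, cmp, dose, r),
                          target_scaling, cmp, dose, r))
      for (i in rs) for (j in rt) {
        examples[[length(examples) + 1L]] <- structure(
          list(source = enc_s[[i]], target = enc_t[[j]], compound = cmp,
               dose = dose, source_replicate = i, target_replicate = j),
          class = "learning_example")
      }
    }
  }
  structure(examples, class = "learning_examples",
            source_genes = source_genes, target_genes = target_genes,
            source_scaling = source_scaling, target_scaling = target_scaling,
            n_times_source = length(source$design$time_points_h),
            n_times_target = length(target$design$time_points_h))
}

#' @exportS3Method base::print
print.learning_examples <- function(x, ...) {
  cat(sprintf("<learning_examples> %d examples, %d compounds\n", length(x),
              length(unique(vapply(x, `[[`, "", "compound")))))
  invisible(x)
}

#' @export
`[.learning_examples` <- function(x, i) {
  out <- unclass(x)[i]
  attributes(out) <- c(attributes(out),
                       attributes(x)[setdiff(names(attributes(x)), "names")])
  out
}

#' Stack example sides into design matrices
#'
#' `examples_source_matrix()` / `examples_target_matrix()` return the
#' n x (G*T) flat-layout matrices the vector models consume (row order =
#' example order, column order = genes consecutive, T entries per gene).
#'
#' @param examples a [build_examples()] result (or subset).
#' @return Numeric matrix, one row per example.
#' @export
examples_source_matrix <- function(examples)
  do.call(rbind, lapply(examples, function(e) to_flat_layout(e$source)))

#' @rdname examples_source_matrix
#' @export
examples_target_matrix <- function(examples)
  do.call(rbind, lapply(examples, function(e) to_flat_layout(e$target)))

#' @rdname examples_source_matrix
#' @export
example_compounds <- function(examples)
  vapply(examples, `[[`, "", "compound")

#' Leave-one-compound-out splits
#'
#' One split per distinct compound: its examples form the validation block,
#' all other examples the training block.  With 720 examples over 45
#' compounds, each split trains on 704 and validates on 16 examples.
#'
#' @param examples a [build_examples()] result.
#' @return List of `loco_split` objects with fields `held_out_compound`,
#'   `training`, `validation`.
#' @export
loco_splits <- function(examples) {
  cmp <- example_compounds(examples)
  compounds <- unique(cmp)
  if (length(compounds) < 2L)
    stop("leave-one-compound-out needs at least 2 compounds")
  lapply(compounds, function(cc) {
    structure(list(held_out_compound = cc,
                   training = examples[cmp != cc],
                   validation = examples[cmp == cc]),
              class = "loco_split")
  })
}

#' @exportS3Method base::print
print.loco_split <- function(x, ...) {
  cat(sprintf("<loco_split> hold out %s: %d train / %d validation\n",
              x$held_out_compound, length(x$training), length(x$validation)))
  invisible(x)
}

#' Serialize learning examples
#'
#' Writes three TSVs sharing row order: the source design matrix, the
#' target design matrix, and a provenance table (compound, dose, source
#' and target replicate).
#'
#' @param examples a [build_examples()] result.
#' @param prefix path prefix; files get suffixes `_source.tsv`,
#'   `_target.tsv`, `_provenance.tsv`.
#' @return The three paths, invisibly.
#' @export
write_learning_examples <- function(examples, prefix) {
  paths <- paste0(prefix, c("_source.tsv", "_target.tsv", "_provenance.tsv"))
  utils::write.table(examples_source_matrix(examples), paths[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(examples_target_matrix(examples), paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prov <- data.frame(
    compound = example_compounds(examples),
    dose = vapply(examples, `[[`, "", "dose"),
    source_replicate = vapply(examples, function(e) e$source_replicate, 0L),
    target_replicate = vapply(examples, function(e) e$target_replicate, 0L))
  utils::write.table(prov, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
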