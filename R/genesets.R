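# Gene-set handling: literature sets from plain-text files, nested random
# sets (optionally within the ortholog universe), and the variance screen
# that rejects sets dominated by unresponsive genes.

#' Construct a gene set
#'
#' An ordered list of unique gene identifiers.  Order matters: it fixes the
#' layout of model input and output layers.  A set may record its parent in
#' a nested family; the parent's genes must be a subset and prefix-compatible
#' with the child's.
#'
#' @param name single character label.
#' @param gene_ids character vector; duplicates are dropped (first
#'   occurrence kept) with a warning.
#' @param parent optional parent `gene_set` for nested families.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, gene_ids, parent = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene ids in set '", name, "' dropped")
    gene_ids <- gene_ids[!duplicated(gene_ids)]
  }
  if (!is.null(parent)) {
    stopifnot(inherits(parent, "gene_set"))
    if (!all(parent$gene_ids %in% gene_ids))
      stop("parent gene set must be a subset of '", name, "'")
  }
  structure(list(name = name, gene_ids = gene_ids, parent = parent),
            class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes%s\n", x$name, length(x$gene_ids),
              if (is.null(x$parent)) "" else
                sprintf(" (nested in %s)", x$parent$name)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$gene_ids)

#' Load a gene set from a plain-text file
#'
#' One gene identifier per line; blank lines ignored; order preserved.
#'
#' @param path file path.
#' @param name set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
load_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("gene-set file is empty: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(name, ids)
}

#' Read an ortholog map
#'
#' Two-column TSV (`source_id`, `target_id`), one ortholog pair per line.
#' Duplicate source ids are not allowed: the restriction of a universe to
#' orthologs must be unambiguous.
#'
#' @param path file path.
#' @return A data.frame of class `ortholog_map` with columns `source_id`
#'   and `target_id`.
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("ortholog map needs two columns")
  names(map)[1:2] <- c("source_id", "target_id")
  ortholog_map(map$source_id, map$target_id)
}

#' @rdname read_ortholog_map
#' @param source_id,target_id paired gene-identifier vectors.
#' @export
ortholog_map <- function(source_id, target_id) {
  stopifnot(length(source_id) == length(target_id))
  if (anyDuplicated(source_id))
    stop("ortholog map has duplicate source ids")
  structure(data.frame(source_id = as.character(source_id),
                       target_id = as.character(target_id),
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' Restrict a gene universe to mapped orthologs
#'
#' @param universe character vector of source-domain gene ids.
#' @param map an [ortholog_map()].
#' @return The subset of `universe` that appears as a source id in `map`,
#'   order preserved.  Empty results are allowed but warned about.
#' @export
restrict_to_orthologs <- function(universe, map) {
  stopifnot(inherits(map, "ortholog_map"))
  out <- universe[universe %in% map$source_id]
  if (length(out) == 0L)
    warning("no genes of the universe are covered by the ortholog map")
  out
}

#' Translate a source-domain gene set through an ortholog map
#'
#' @param set a [gene_set()] of source-domain ids, all present in `map`.
#' @param map an [ortholog_map()].
#' @return A [gene_set()] of the paired target-domain ids, same order.
#' @export
map_gene_set <- function(set, map) {
  stopifnot(inherits(set, "gene_set"), inherits(map, "ortholog_map"))
  idx <- match(set$gene_ids, map$source_id)
  if (anyNA(idx))
    stop("gene ids missing from the ortholog map: ",
         paste(set$gene_ids[is.na(idx)], collapse = ", "))
  gene_set(paste0(set$name, "_target"), map$target_id[idx])
}

#' Generate a nested family of random gene sets
#'
#' Draws a random core set, then iteratively adds blocks of randomly chosen
#' genes (without replacement from the remaining universe), giving a strictly
#' nested family of increasing sets.  With the defaults the family sizes are
#' 20, 35, 50, 65, 80.  If a dataset and reference set are supplied, each
#' family is screened with [screen_variance()] and redrawn (fresh draws from
#' the same RNG stream) until it passes or `max_retries` is hit.
#'
#' @param universe character vector of candidate gene ids.
#' @param core_size size of the innermost set.
#' @param increment genes added per nesting level.
#' @param n_levels number of sets in the family.
#' @param seed integer seed; the same seed reproduces the same family.
#' @param dataset,reference,tolerance optional: a [domain_dataset()] and
#'   reference [gene_set()] for the variance screen (see
#'   [screen_variance()]).
#' @param max_retries redraw cap when screening (default 100).
#' @return List of `n_levels` [gene_set()] objects, each the parent of the
#'   next.
#' @export
generate_nested_random_sets <- function(universe, core_size = 20L,
                                        increment = 15L, n_levels = 5L,
                                        seed = 1L,
                                        dataset = NULL, reference = NULL,
                                        tolerance = 0.03,
                                        max_retries = 100L) {
  universe <- as.character(universe)
  core_size <- as.integer(core_size); increment <- as.integer(increment)
  n_levels <- as.integer(n_levels)
  stopifnot(core_size >= 1L, increment >= 1L || n_levels == 1L, n_levels >= 1L)
  top <- core_size + (n_levels - 1L) * increment
  if (top > length(universe))
    stop("universe too small: need ", top, " genes, have ", length(universe))
  screen <- !is.null(dataset) && !is.null(reference)
  set.seed(seed)
  for (attempt in seq_len(if (screen) max_retries else 1L)) {
    sets <- vector("list", n_levels)
    ids <- sample(universe, core_size)
    sets[[1L]] <- gene_set(sprintf("random_%d", core_size), ids)
    for (lev in seq_len(n_levels - 1L)) {
      extra <- sample(setdiff(universe, ids), increment)
      ids <- c(ids, extra)
      sets[[lev + 1L]] <- gene_set(sprintf("random_%d", length(ids)), ids,
                                   parent = sets[[lev]])
    }
    if (!screen) return(sets)
    ok <- vapply(sets, screen_variance, logical(1),
                 dataset = dataset, reference = reference,
                 tolerance = tolerance)
    if (all(ok)) return(sets)
  }
  stop("no nested family passed the variance screen within ", max_retries,
       " attempts")
}

# Mean over genes of the per-gene expression variance across all samples.
.set_variance <- function(gene_ids, dataset) {
  idx <- match(gene_ids, dataset$gene_ids)
  if (anyNA(idx))
    stop("genes missing from dataset: ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  mean(apply(dataset$expression[idx, , drop = FALSE], 1, stats::var))
}

#' Variance screen for candidate gene sets
#'
#' Unresponsive genes are trivially predictable, so random sets are screened
#' for sufficient expression variability.  The statistic is the mean over
#' genes of the per-gene variance across all samples of `dataset`; a
#' candidate passes when its statistic is at least `(1 - tolerance)` times
#' the reference set's (default tolerance 3%, boundary inclusive).  The
#' decision is invariant to rescaling all expression values by a constant.
#'
#' @param candidate,reference [gene_set()] objects present in `dataset`.
#' @param dataset a [domain_dataset()] (conventionally the source domain).
#' @param tolerance allowed fractional shortfall relative to the reference.
#' @return `TRUE` if the candidate passes the screen.
#' @export
screen_variance <- function(candidate, dataset, reference, tolerance = 0.03) {
  stopifnot(inherits(candidate, "gene_set"), inherits(reference, "gene_set"),
            inherits(dataset, "domain_dataset"), tolerance >= 0)
  v_cand <- .set_variance(candidate$gene_ids, dataset)
  v_ref <- .set_variance(reference$gene_ids, dataset)
  v_cand >= (1 - tolerance) * v_ref
}
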