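# Level-plus-slope trajectory encoding.
#
# A raw genes x time trajectory is re-encoded so that the first entry per
# gene is its scaled expression level at the first time point and the
# remaining T-1 entries are scaled slopes between consecutive time points.
# Slopes live in [-1, 1] after division by the global range and are mapped
# affinely into [0, 1] via (d + 1) / 2, so a sigmoid output layer can emit
# them.  The point of the encoding: a constant level shift changes only the
# first entry per gene, so the error metric favours getting the *pattern*
# of expression right over its absolute level.

#' Fit the global scaling of a domain
#'
#' Records the minimum and maximum expression over all selected genes and
#' all samples (compounds, doses, times, replicates) of a domain; the
#' encoding maps this range onto \[0, 1\].
#'
#' @param dataset a [domain_dataset()].
#' @param genes a [gene_set()] (or character vector) restricting the scan;
#'   subsetting to fewer genes never widens the range.
#' @return An object of class `scaling_params` with fields `global_min`,
#'   `global_max`, `domain_id`.
#' @export
fit_scaling <- function(dataset, genes) {
  stopifnot(inherits(dataset, "domain_dataset"))
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids else as.character(genes)
  idx <- match(ids, dataset$gene_ids)
  if (anyNA(idx))
    stop("genes missing from dataset: ", paste(ids[is.na(idx)], collapse = ", "))
  x <- dataset$expression[idx, , drop = FALSE]
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("degenerate scaling: all selected expression values are identical")
  structure(list(global_min = lo, global_max = hi,
                 domain_id = dataset$design$domain_id),
            class = "scaling_params")
}

#' @exportS3Method base::print
print.scaling_params <- function(x, ...) {
  cat(sprintf("<scaling_params> %s: [%.4g, %.4g]\n", x$domain_id,
              x$global_min, x$global_max))
  invisible(x)
}

#' Extract one raw trajectory from a domain dataset
#'
#' @param dataset a [domain_dataset()].
#' @param genes a [gene_set()] or character vector of gene ids (row order of
#'   the result).
#' @param compound,dose,replicate sample coordinates.
#' @return Numeric genes x time matrix in expression units.
#' @export
extract_trajectory <- function(dataset, genes, compound, dose, replicate) {
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids else as.character(genes)
  gidx <- match(ids, dataset$gene_ids)
  if (anyNA(gidx))
    stop("genes missing from dataset: ", paste(ids[is.na(gidx)], collapse = ", "))
  md <- dataset$metadata
  keep <- md$compound == compound & md$dose == dose & md$replicate == replicate
  if (!any(keep))
    stop("no samples for compound ", compound, ", dose ", dose,
         ", replicate ", replicate)
  md_sub <- md[keep, , drop = FALSE]
  ord <- order(md_sub$time_h)
  out <- dataset$expression[gidx, which(keep)[ord], drop = FALSE]
  dimnames(out) <- list(ids, sprintf("t%g", md_sub$time_h[ord]))
  out
}

#' Encode a raw trajectory as levels plus slopes
#'
#' Per gene: entry 1 is the scaled level at the first time point,
#' `(x1 - min) / (max - min)`; entries `k = 2..T` are scaled slopes
#' `d = (x_k - x_(k-1)) / (max - min)` stored as `(d + 1) / 2`.  All entries
#' lie in \[0, 1\] when the raw values lie within the fitted range; values
#' outside the range are clipped with a warning.
#'
#' @param raw numeric genes x time matrix (T >= 2), e.g. from
#'   [extract_trajectory()].
#' @param scaling a [fit_scaling()] result for the trajectory's domain.
#' @param compound,dose,replicate provenance labels carried on the instance.
#' @param layout `"flat"` (length G*T vector view, genes consecutive) or
#'   `"matrix"` (G x T view); see [to_flat_layout()].
#' @return An object of class `encoded_instance`.
#' @export
encode_trajectory <- function(raw, scaling, compound = NA_character_,
                              dose = NA_character_, replicate = NA_integer_,
                              layout = c("flat", "matrix")) {
  layout <- match.arg(layout)
  stopifnot(is.matrix(raw), inherits(scaling, "scaling_params"))
  if (ncol(raw) < 2L) stop("need at least 2 time points to encode slopes")
  if (!all(is.finite(raw))) stop("raw trajectory contains non-finite values")
  lo <- scaling$global_min; hi <- scaling$global_max
  if (any(raw < lo) || any(raw > hi)) {
    warning("raw values outside the fitted scaling range were clipped")
    raw <- pmin(pmax(raw, lo), hi)
  }
  rng <- hi - lo
  Tn <- ncol(raw)
  values <- matrix(NA_real_, nrow(raw), Tn)
  values[, 1L] <- (raw[, 1L] - lo) / rng
  if (Tn > 1L) {
    d <- (raw[, -1L, drop = FALSE] - raw[, -Tn, drop = FALSE]) / rng
    values[, -1L] <- (d + 1) / 2
  }
  rownames(values) <- rownames(raw)
  colnames(values) <- c("level", sprintf("slope%d", seq_len(Tn - 1L)))
  structure(list(compound = compound, dose = dose, replicate = replicate,
                 layout = layout, values = values),
            class = "encoded_instance")
}

#' @exportS3Method base::print
print.encoded_instance <- function(x, ...) {
  cat(sprintf("<encoded_instance> %s/%s rep %s: %d genes x %d entries (%s)\n",
              x$compound, x$dose, x$replicate, nrow(x$values),
              ncol(x$values), x$layout))
  invisible(x)
}

#' Decode an encoded instance back to expression units
#'
#' Exact inverse of [encode_trajectory()] for values within the fitted
#' range.
#'
#' @param enc an `encoded_instance` (or a bare numeric vector/matrix whose
#'   flat length is divisible by `n_times`).
#' @param scaling the [fit_scaling()] used to encode.
#' @param n_times required when `enc` is a bare vector.
#' @return Numeric genes x time matrix in expression units.
#' @export
decode_trajectory <- function(enc, scaling, n_times = NULL) {
  stopifnot(inherits(scaling, "scaling_params"))
  if (inherits(enc, "encoded_instance")) {
    values <- enc$values
  } else if (is.matrix(enc)) {
    values <- enc
  } else {
    if (is.null(n_times)) stop("n_times needed to decode a bare vector")
    if (length(enc) %% n_times != 0L)
      stop("flat length ", length(enc), " is not divisible by T = ", n_times)
    values <- matrix(enc, ncol = n_times, byrow = TRUE)
  }
  lo <- scaling$global_min
  rng <- scaling$global_max - lo
  Tn <- ncol(values)
  out <- matrix(NA_real_, nrow(values), Tn)
  out[, 1L] <- values[, 1L] * rng + lo
  if (Tn > 1L) {
    d <- (2 * values[, -1L, drop = FALSE] - 1) * rng
    for (k in 2:Tn) out[, k] <- out[, k - 1L] + d[, k - 1L]
  }
  rownames(out) <- rownames(values)
  out
}

#' Layout views of an encoded instance
#'
#' `to_matrix_layout()` returns the G x T array (genes x encoded entries);
#' `to_flat_layout()` returns the length-G*T vector with genes consecutive,
#' i.e. flat entry `(g - 1) * T + t` equals matrix entry `[g, t]`.  The two
#' views are lossless reshapes of each other.
#'
#' @param enc an `encoded_instance`.
#' @return A matrix or a numeric vector.
#' @export
to_matrix_layout <- function(enc) {
  stopifnot(inherits(enc, "encoded_instance"))
  enc$values
}

#' @rdname to_matrix_layout
#' @export
to_flat_layout <- function(enc) {
  stopifnot(inherits(enc, "encoded_instance"))
  v <- as.vector(t(enc$values))
  names(v) <- as.vector(t(outer(rownames(enc$values), colnames(enc$values),
                                paste, sep = ".")))
  v
}

#' Serialize encoded instances
#'
#' Writes the G x T value matrix as a TSV with a `#`-prefixed sidecar line
#' recording layout and provenance; `read_encoded_instance()` restores it.
#'
#' @param enc an `encoded_instance`.
#' @param path file path.
#' @return The path (write) or an `encoded_instance` (read).
#' @export
write_encoded_instance <- function(enc, path) {
  stopifnot(inherits(enc, "encoded_instance"))
  meta <- sprintf("# layout=%s compound=%s dose=%s replicate=%s",
                  enc$layout, enc$compound, enc$dose, enc$replicate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  df <- data.frame(gene_id = rownames(enc$values), enc$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encoded_instance
#' @export
read_encoded_instance <- function(path) {
  meta <- readLines(path, n = 1L)
  kv <- strsplit(sub("^#\\s*", "", meta), "\\s+")[[1L]]
  kv <- strsplit(kv, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  structure(list(compound = vals[["compound"]], dose = vals[["dose"]],
                 replicate = as.integer(vals[["replicate"]]),
                 layout = vals[["layout"]], values = m),
            class = "encoded_instance")
}
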