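# Synthetic paired-cohort generator.
#
# The generative model: each compound owns a smooth latent response curve
# z(t) (latent_dim coordinates, each a random combination of three smooth
# time basis functions).  Dose scales the amplitude of z (control = 0).
# Source expression mixes z through a gene-loading matrix; target expression
# mixes h(z) -- h the identity or tanh -- through its own loading matrix.
# Constant genes have zero loadings and carry baseline + replicate noise
# only.  All draws come from one seeded RNG stream whose prefix (the
# noise-free "truth") can be replayed, which is what the oracle does.

.latent_basis <- function(t)
  rbind(t / 24, sin(pi * t / 24), exp(-t / 8))

.compound_labels <- function(n) sprintf("compound_%02d", seq_len(n))

.gene_labels <- function(domain_id, n) sprintf("%s_g%03d", domain_id, seq_len(n))

# Draws everything except replicate noise.  Must be called under set.seed so
# that generate_cohort and oracle computations see identical values.
.draw_truth <- function(config) {
  G <- config$n_genes
  L <- config$latent_dim
  n_const <- round(config$frac_constant_genes * G)
  const_src <- sort(sample.int(G, n_const))
  const_tgt <- sort(sample.int(G, n_const))
  baseline_src <- stats::runif(G, 6, 12)
  baseline_tgt <- stats::runif(G, 6, 12)
  load_src <- matrix(stats::rnorm(G * L, sd = 0.45), G, L)
  load_tgt <- matrix(stats::rnorm(G * L, sd = 0.45), G, L)
  load_src[const_src, ] <- 0
  load_tgt[const_tgt, ] <- 0
  latent_coef <- lapply(seq_len(config$n_compounds), function(k)
    matrix(stats::rnorm(L * 3), L, 3))
  list(const_src = const_src, const_tgt = const_tgt,
       baseline_src = baseline_src, baseline_tgt = baseline_tgt,
       load_src = load_src, load_tgt = load_tgt,
       latent_coef = latent_coef)
}

.domain_transform <- function(z, kind)
  if (kind == "saturating") tanh(z) else z

# Noise-free gene x time mean for one compound-dose in one domain.
.mean_trajectory <- function(truth, config, compound_idx, dose_idx,
                             time_points, side = c("source", "target")) {
  side <- match.arg(side)
  phi <- .latent_basis(time_points)
  z <- config$dose_scaling[dose_idx] * (truth$latent_coef[[compound_idx]] %*% phi)
  if (side == "source") {
    truth$baseline_src + truth$load_src %*% z
  } else {
    truth$baseline_tgt +
      truth$load_tgt %*% .domain_transform(z, config$cross_domain_nonlinearity)
  }
}

.sample_metadata <- function(design, compounds) {
  md <- expand.grid(replicate = seq_len(design$n_replicates),
                    time_h = design$time_points_h,
                    dose = design$dose_levels,
                    compound = compounds,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md <- md[, c("compound", "dose", "time_h", "replicate")]
  md$sample_id <- sprintf("%s_%s_%s_t%g_r%d", design$domain_id, md$compound,
                          md$dose, md$time_h, md$replicate)
  md[, c("sample_id", "compound", "dose", "time_h", "replicate")]
}

.build_domain <- function(truth, config, design, compounds, side) {
  G <- config$n_genes
  md <- .sample_metadata(design, compounds)
  expr <- matrix(NA_real_, G, nrow(md))
  Tn <- length(design$time_points_h)
  R <- design$n_replicates
  block <- Tn * R
  col0 <- 0L
  for (k in seq_along(compounds)) {
    for (d in seq_along(design$dose_levels)) {
      mu <- .mean_trajectory(truth, config, k, d, design$time_points_h, side)
      # replicate-fastest ordering within the (compound, dose) block
      expr[, col0 + seq_len(block)] <- mu[, rep(seq_len(Tn), each = R)]
      col0 <- col0 + block
    }
  }
  expr <- expr + matrix(stats::rnorm(length(expr), sd = config$replicate_noise_sd),
                        G, ncol(expr))
  gene_ids <- .gene_labels(design$domain_id, G)
  rownames(expr) <- gene_ids
  colnames(expr) <- md$sample_id
  domain_dataset(design, gene_ids, expr, md)
}

#' Construct a domain dataset
#'
#' Bundles a genes x samples expression matrix with its sample metadata and
#' sampling design, checking the complete-crossing invariant: every
#' (compound, dose, time, replicate) cell of the design must be present
#' exactly once, and every expression value must be finite.
#'
#' @param design a [domain_design()].
#' @param gene_ids character vector of gene identifiers (row order of
#'   `expression`).
#' @param expression numeric matrix, genes x samples.
#' @param metadata data.frame with columns `sample_id`, `compound`, `dose`,
#'   `time_h`, `replicate`, one row per column of `expression`.
#' @return An object of class `domain_dataset`.
#' @export
domain_dataset <- function(design, gene_ids, expression, metadata) {
  stopifnot(inherits(design, "domain_design"), is.matrix(expression))
  gene_ids <- as.character(gene_ids)
  if (nrow(expression) != length(gene_ids))
    stop("expression must have one row per gene id")
  if (ncol(expression) != nrow(metadata))
    stop("metadata must have one row per expression column")
  need <- c("sample_id", "compound", "dose", "time_h", "replicate")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(expression))) stop("expression values must all be finite")
  compounds <- unique(metadata$compound)
  cells <- interaction(metadata$compound, metadata$dose, metadata$time_h,
                       metadata$replicate, drop = FALSE)
  expected <- length(compounds) * length(design$dose_levels) *
    length(design$time_points_h) * design$n_replicates
  if (nrow(metadata) != expected || anyDuplicated(cells))
    stop("incomplete crossing: every (compound, dose, time, replicate) cell ",
         "must appear exactly once")
  structure(list(design = design, gene_ids = gene_ids,
                 expression = expression, metadata = metadata,
                 compounds = compounds),
            class = "domain_dataset")
}

#' @exportS3Method base::print
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> %s: %d genes x %d samples (%d compounds)\n",
              x$design$domain_id, length(x$gene_ids), ncol(x$expression),
              length(x$compounds)))
  invisible(x)
}

#' Generate a paired two-domain synthetic cohort
#'
#' Simulates source- and target-domain expression matrices that share a
#' compound-dose latent response, on each domain's own time grid and
#' replicate count.  Identical `config$seed` gives bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param source_design,target_design [domain_design()] objects for the two
#'   domains.
#' @return An object of class `cohort`: a list with elements `source` and
#'   `target` (both [domain_dataset()]), plus the `config`, the designs and
#'   the internal noise-free truth used by [oracle_target()].
#' @examples
#' cfg <- simulation_config(n_compounds = 3, n_genes = 10, seed = 7)
#' coh <- generate_cohort(cfg, design_rat_invitro(), design_human_invitro())
#' dim(coh$source$expression)  # 10 x 72
#' @export
generate_cohort <- function(config, source_design, target_design) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(source_design, "domain_design"),
            inherits(target_design, "domain_design"))
  compounds <- .compound_labels(config$n_compounds)
  set.seed(config$seed)
  truth <- .draw_truth(config)
  # noise draws continue the same stream, after the truth prefix
  source <- .build_domain(truth, config, source_design, compounds, "source")
  target <- .build_domain(truth, config, target_design, compounds, "target")
  structure(list(source = source, target = target, config = config,
                 source_design = source_design, target_design = target_design,
                 compounds = compounds, truth = truth),
            class = "cohort")
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d compounds, seed %d\n  source: ",
              x$config$n_compounds, x$config$seed))
  print(x$source); cat("  target: "); print(x$target)
  invisible(x)
}

#' Noise-free target trajectory for a compound-dose combination
#'
#' Returns the target-domain mean expression trajectory that a perfect
#' translator would recover: the generative mean with no replicate noise.
#' With `replicate_noise_sd = 0` every generated replicate equals this
#' oracle exactly; with noise, the empirical replicate mean converges to it.
#'
#' @param cohort a [generate_cohort()] result.
#' @param compound compound label present in the cohort.
#' @param dose dose label present in the target design.
#' @return Numeric genes x time matrix (dimnames: gene ids, `t<h>`).
#' @export
oracle_target <- function(cohort, compound, dose) {
  stopifnot(inherits(cohort, "cohort"))
  k <- match(compound, cohort$compounds)
  if (is.na(k)) stop("unknown compound: ", compound)
  d <- match(dose, cohort$target_design$dose_levels)
  if (is.na(d)) stop("unknown dose: ", dose)
  mu <- .mean_trajectory(cohort$truth, cohort$config, k, d,
                         cohort$target_design$time_points_h, "target")
  dimnames(mu) <- list(cohort$target$gene_ids,
                       sprintf("t%g", cohort$target_design$time_points_h))
  mu
}

#' Read and write domain datasets as delimited text
#'
#' A domain dataset round-trips through two TSV files: a genes x samples
#' expression matrix (first column `gene_id`) and a sample-metadata table
#' with columns `sample_id`, `compound`, `dose`, `time_h`, `replicate`.
#' Dose-level order is taken from order of first appearance in the metadata.
#'
#' @param dataset a [domain_dataset()].
#' @param expression_path,metadata_path file paths for the two TSVs.
#' @param domain_id domain label to attach on read.
#' @return `write_domain_dataset` returns the paths invisibly;
#'   `read_domain_dataset` returns a [domain_dataset()].
#' @export
write_domain_dataset <- function(dataset, expression_path, metadata_path) {
  stopifnot(inherits(dataset, "domain_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$expression,
                   check.names = FALSE)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expression_path, metadata_path))
}

#' @rdname write_domain_dataset
#' @export
read_domain_dataset <- function(expression_path, metadata_path,
                                domain_id = "domain") {
  expr_df <- utils::read.delim(expression_path, check.names = FALSE)
  md <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  gene_ids <- as.character(expr_df$gene_id)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- gene_ids
  design <- domain_design(domain_id,
                          sort(unique(md$time_h)),
                          max(md$replicate),
                          unique(md$dose))
  domain_dataset(design, gene_ids, expr, md)
}
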