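#' Describe the sampling design of one expression domain
#'
#' A domain is one arm of a toxicogenomics study: a species/system (e.g. rat
#' hepatocytes in vitro, human hepatocytes in vitro, rat liver in vivo)
#' profiled on its own time grid with its own replicate count.  Dose levels
#' are categorical; the control is carried as an ordinary dose level so that
#' control arrays enter the learning problem like any other exposure.
#'
#' @param domain_id single character label, e.g. `"rat_invitro"`.
#' @param time_points_h strictly increasing numeric vector of sampling times
#'   in hours.
#' @param n_replicates integer number of biological replicates per
#'   compound-dose-time cell (must be >= 2).
#' @param dose_levels ordered character vector of dose labels; must contain
#'   `"control"`.
#' @return An object of class `domain_design`.
#' @examples
#' domain_design("rat_invitro", c(2, 8, 24), 2)
#' @export
domain_design <- function(domain_id, time_points_h, n_replicates,
                          dose_levels = c("control", "low", "middle", "high")) {
  stopifnot(is.character(domain_id), length(domain_id) == 1L)
  time_points_h <- as.numeric(time_points_h)
  if (length(time_points_h) < 2L || any(diff(time_points_h) <= 0))
    stop("time_points_h must be strictly increasing with at least 2 points")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("n_replicates must be an integer >= 2")
  dose_levels <- as.character(dose_levels)
  if (!"control" %in% dose_levels) stop("dose_levels must contain 'control'")
  if (anyDuplicated(dose_levels)) stop("dose_levels must be unique")
  structure(
    list(domain_id = domain_id, time_points_h = time_points_h,
         n_replicates = n_replicates, dose_levels = dose_levels),
    class = "domain_design")
}

#' @exportS3Method base::print
print.domain_design <- function(x, ...) {
  cat(sprintf("<domain_design> %s: t = {%s} h, %d replicates, doses: %s\n",
              x$domain_id, paste(x$time_points_h, collapse = ", "),
              x$n_replicates, paste(x$dose_levels, collapse = "/")))
  invisible(x)
}

#' Preset domain designs
#'
#' The three arms of the Open TG-GATEs subset this package targets: rat
#' hepatocytes in vitro and human hepatocytes in vitro are sampled at 2, 8
#' and 24 h with two biological replicates; rat liver in vivo at 3, 6, 9 and
#' 24 h with three biological replicates.  All three carry four dose levels
#' (control, low, middle, high).
#'
#' @return A `domain_design`.
#' @name design_presets
#' @examples
#' design_rat_invivo()
NULL

#' @rdname design_presets
#' @export
design_rat_invitro <- function()
  domain_design("rat_invitro", c(2, 8, 24), 2L)

#' @rdname design_presets
#' @export
design_human_invitro <- function()
  domain_design("human_invitro", c(2, 8, 24), 2L)

#' @rdname design_presets
#' @export
design_rat_invivo <- function()
  domain_design("rat_invivo", c(3, 6, 9, 24), 3L)

#' Configuration of the synthetic paired-cohort generator
#'
#' Captures every knob of the generative model behind [generate_cohort()]:
#' cohort size, gene panel size, the fraction of unresponsive (constant)
#' genes, replicate noise, the deterministic source-to-target latent
#' transform, and per-dose response multipliers.
#'
#' Defaults mirror the study design the package emulates: 45 compounds and a
#' 76-gene panel, with roughly log2-scale expression, a saturating
#' dose-response ladder and replicate noise of 0.15 expression units
#' (typical array-replicate disagreement on the RMA scale).
#'
#' @param n_compounds positive integer number of compounds.
#' @param n_genes positive integer number of genes per domain.
#' @param frac_constant_genes fraction in \[0, 1\] of genes that do not
#'   respond to any exposure (baseline + noise only).
#' @param replicate_noise_sd nonnegative standard deviation of i.i.d.
#'   Gaussian replicate noise, in expression units.
#' @param cross_domain_nonlinearity `"identity"` or `"saturating"`; the
#'   deterministic transform applied to the shared latent response before it
#'   is mixed into target-domain expression (`"saturating"` = elementwise
#'   `tanh`).
#' @param dose_scaling four nonnegative multipliers, control first and
#'   exactly zero, scaling the latent response amplitude per dose level.
#' @param latent_dim dimension of the shared compound-dose latent response.
#' @param seed integer seed governing all draws of the generator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 45L, n_genes = 76L,
                              frac_constant_genes = 0.2,
                              replicate_noise_sd = 0.15,
                              cross_domain_nonlinearity = c("identity", "saturating"),
                              dose_scaling = c(0, 0.3, 0.6, 1),
                              latent_dim = 5L,
                              seed = 1L) {
  n_compounds <- as.integer(n_compounds); n_genes <- as.integer(n_genes)
  if (is.na(n_compounds) || n_compounds < 1L) stop("n_compounds must be positive")
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be positive")
  if (frac_constant_genes < 0 || frac_constant_genes > 1)
    stop("frac_constant_genes must lie in [0, 1]")
  if (replicate_noise_sd < 0) stop("replicate_noise_sd must be nonnegative")
  cross_domain_nonlinearity <- match.arg(cross_domain_nonlinearity)
  dose_scaling <- as.numeric(dose_scaling)
  if (length(dose_scaling) != 4L || any(dose_scaling < 0))
    stop("dose_scaling must be 4 nonnegative multipliers")
  if (dose_scaling[1L] != 0)
    stop("dose_scaling must have value 0 for the control (first) level")
  latent_dim <- as.integer(latent_dim)
  if (is.na(latent_dim) || latent_dim < 1L) stop("latent_dim must be positive")
  structure(
    list(n_compounds = n_compounds, n_genes = n_genes,
         frac_constant_genes = frac_constant_genes,
         replicate_noise_sd = replicate_noise_sd,
         cross_domain_nonlinearity = cross_domain_nonlinearity,
         dose_scaling = dose_scaling, latent_dim = latent_dim,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' @exportS3Method base::print
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d compounds x %d genes ",
                     "(%.0f%% constant), noise sd %.3g, map %s, seed %d\n"),
              x$n_compounds, x$n_genes, 100 * x$frac_constant_genes,
              x$replicate_noise_sd, x$cross_domain_nonlinearity, x$seed))
  invisible(x)
}
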