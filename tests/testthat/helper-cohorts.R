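# Shared fixtures: all synthetic, built in code at test time.

tiny_cohort <- function(n_compounds = 3L, n_genes = 8L, noise = 0.15,
                        nonlinearity = "identity", seed = 11L,
                        frac_constant = 0.25,
                        target_design = design_human_invitro()) {
  cfg <- simulation_config(
    n_compounds = n_compounds, n_genes = n_genes,
    frac_constant_genes = frac_constant, replicate_noise_sd = noise,
    cross_domain_nonlinearity = nonlinearity, seed = seed)
  generate_cohort(cfg, design_rat_invitro(), target_design)
}

tiny_examples <- function(cohort = tiny_cohort()) {
  build_examples(cohort$source, cohort$target,
                 gene_set("src_panel", cohort$source$gene_ids),
                 gene_set("tgt_panel", cohort$target$gene_ids))
}

quick_cfg <- function(epochs = 3L, seed = 1L, ...)
  training_config(epochs = epochs, seed = seed, ...)

# encoded oracle predictor for a cohort: the noise-free target mean,
# encoded with the given scaling -- what a perfect translator returns
oracle_predictor <- function(cohort, target_scaling) {
  custom_spec(function(examples) {
    do.call(rbind, lapply(examples, function(e) {
      mu <- oracle_target(cohort, e$compound, e$dose)
      to_flat_layout(encode_trajectory(mu, target_scaling,
                                       e$compound, e$dose))
    }))
  })
}
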