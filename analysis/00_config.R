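# Shared study configuration for the analysis workflow.
#
# One synthetic "study": a 300-gene universe with three planted programs.
# Program 1 carries the strongest content signal (members push the trait
# up by 0.2 each); program 2 is the discordant one — its regulator path
# weight is negative (-0.5) while its member-content contribution is
# positive (+0.15), the pattern where program regulation and program
# content pull a trait in opposite directions. Burden-test noise and the
# shet coupling follow the generator defaults discussed in the vignette.

library(progtrait)

study_config <- function(seed = 42L) {
  sim_config(
    n_genes = 300L, n_programs = 3L,
    n_regulators_per_program = 20L, n_member_genes_per_program = 30L,
    regulator_effect_scale = 1,
    content_weight_per_program = c(0.2, 0.15, 0.1),
    regulator_path_weight_per_program = c(0.6, -0.5, 0.4),
    trait_noise_sd = 0.03, se_range = c(0.05, 0.25),
    shet_gamma_coupling = 0.3,
    n_cells_per_perturbation = 50L, n_nontargeting_cells = 500L,
    n_batches = 2L, mean_depth = 6000, mito_fraction_mean = 0.1,
    seed = seed)
}

data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
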