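# Shared fixtures, built in code.

# The reference study layout: 5x5 factorial + 5 center replicates.
ref_spec <- function(reps = 5L) hsa_design_spec(center_replicates = reps)

ref_design <- function(reps = 5L) build_design(ref_spec(reps))

# A small noiseless, latent-free dataset with known coefficients.
noiseless_dataset <- function(n_compounds = 20L, seed = 42L) {
  spec <- ref_spec()
  truth <- ground_truth(spec, n_compounds = n_compounds, seed = seed,
                        noise_sd = 0, n_latent = 0L)
  simulate_retention(spec, truth)
}

# Default-condition dataset (noise + one latent factor), small by default.
default_dataset <- function(n_compounds = 30L, seed = 42L, ...) {
  spec <- ref_spec()
  truth <- ground_truth(spec, n_compounds = n_compounds, seed = seed, ...)
  simulate_retention(spec, truth)
}

# A tiny single-factor design for hand calculations.
toy_one_factor <- function(levels = -1L:1L, terms = c("1", "x")) {
  design_spec(list(factor_spec("x", center = 0, step = 1,
                               coded_levels = levels)),
              model_terms = terms)
}
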