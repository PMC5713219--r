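# Shared setup for the analysis scripts: one seed, one pair of synthetic
# systems. The wild-type-like system plants stronger residue-residue
# coupling (AR(1) rho = 0.7) than the mutant-like system (rho = 0.5),
# emulating the weakening of the allosteric network on mutation; everything
# downstream is computed by the allodyn package.

library(allodyn)

SEED <- 42
RESULTS <- file.path("results", "analysis")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

config <- default_config(seed = SEED)

build_system <- function(name) {
  sc <- config$systems[[name]]
  chain <- make_chain(sc$n_res, sc$geometry)
  corr <- outer(seq_len(sc$n_res), seq_len(sc$n_res),
                function(i, j) sc$corr_rho^abs(i - j))
  idx <- match(name, names(config$systems))
  model <- planted_model(chain, corr, n_frames = sc$n_frames,
                         seed = SEED + idx - 1, amplitude = sc$amplitude)
  list(name = name, chain = chain, corr = corr,
       traj = sample_correlated_trajectory(model))
}
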