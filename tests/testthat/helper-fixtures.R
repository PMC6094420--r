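# small deterministic fixtures shared across tests

tiny_grid <- function(n_ex = 2, n_em = 2) {
  wavelength_grid(excitation = seq(240, by = 5, length.out = n_ex),
                  emission = seq(300, by = 10, length.out = n_em))
}

# cube with arbitrary values, sample i filled from `values[[i]]` (em x ex)
tiny_cube <- function(values, roles = NULL, conc = NULL, grid = NULL) {
  n_em <- nrow(values[[1]])
  n_ex <- ncol(values[[1]])
  if (is.null(grid)) grid <- tiny_grid(n_ex, n_em)
  if (is.null(roles)) roles <- rep("unknown", length(values))
  if (is.null(conc)) conc <- rep(NA_real_, length(values))
  samples <- lapply(seq_along(values), function(i) {
    eem_sample(sprintf("S%02d", i), values[[i]], role = roles[i],
               concentration = conc[i])
  })
  eem_cube(grid, samples)
}

random_cube <- function(n_samples, n_ex, n_em, seed = 1) {
  withr::with_seed(seed, {
    tiny_cube(lapply(seq_len(n_samples), function(i) {
      matrix(rnorm(n_em * n_ex), n_em, n_ex)
    }), grid = tiny_grid(n_ex, n_em))
  })
}

# noiseless bilinear design on a small grid for fast pipeline tests
small_bilinear_design <- function(concentrations, noise_sd = 0,
                                  interferents = FALSE, seed = 1,
                                  roles = NULL) {
  g <- wavelength_grid(seq(240, 264, by = 2), seq(300, 480, by = 4))
  interf <- if (interferents) {
    list(fluorophore(246, 10, 330, 30, 1), fluorophore(258, 8, 420, 40, 1))
  } else list()
  ranges <- if (interferents) list(c(10, 30), c(5, 15)) else list()
  simulation_design(g, fluorophore(251, 6, 362.5, 22, quantum_scale = 1e8),
                    concentrations = concentrations,
                    interferents = interf, interferent_ranges = ranges,
                    noise_sd = noise_sd, roles = roles, seed = seed)
}
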