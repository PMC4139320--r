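# Shared fixtures: all synthetic, generated in code.

# Small, fast MCMC settings for unit tests; acceptance tests use larger ones.
fast_mcmc <- function(seed = 1L) {
  mcmc_config(chains = 2L, adapt = 300L, warmup = 300L, kept = 800L,
              seed = seed)
}

# One-ethnicity nativity cohort, linkage complete so deaths are integers.
tiny_cohort <- function(seed = 42L, design = "nativity",
                        ethnicities = "Chinese", link_prob = 1,
                        sigma_strata = 0.1) {
  generate_cohort(generator_config(design = design,
                                   ethnicities = ethnicities,
                                   link_prob = link_prob,
                                   sigma_strata = sigma_strata,
                                   seed = seed))
}

# A hand-built 2-cell rate-draw matrix with named cells.
named_draws <- function(draws, cells) {
  m <- matrix(draws, ncol = length(cells))
  colnames(m) <- cells
  m
}

expect_quiet_fit <- function(expr) {
  # unit-test fits use few draws; convergence warnings there are expected
  suppressWarnings(expr)
}
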