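# Shared fixtures. Expensive objects are computed once per test run and
# cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

# Reference per-year turnover rates for cancellous bone (fraction/yr),
# intervals 0-1 .. 19-20: the values the tissue-level model is expected to
# reproduce.
ref_mineral <- c(1.217, 0.908, 0.786, 0.700, 0.629, 0.571, 0.527, 0.492,
                 0.462, 0.434, 0.407, 0.378, 0.349, 0.319, 0.289, 0.258,
                 0.227, 0.194, 0.158, 0.118)
ref_collagen <- c(1.474, 1.059, 0.892, 0.776, 0.682, 0.611, 0.558, 0.520,
                  0.489, 0.461, 0.432, 0.402, 0.370, 0.337, 0.302, 0.267,
                  0.231, 0.193, 0.151, 0.104)
ref_qp <- c(1.413, 1.134, 0.924, 0.771, 0.664, 0.590, 0.540, 0.507, 0.483,
            0.463, 0.441, 0.416, 0.386, 0.349, 0.306, 0.260, 0.213, 0.171,
            0.139, 0.124)

shared_qp <- function() {
  if (is.null(.fixture_cache$qp)) .fixture_cache$qp <- default_qp()
  .fixture_cache$qp
}

# canonical synthetic assemblage: 30 subadults, 0.3 permil scatter,
# truth t1 = 1, t2 = 3, E = 2.4, wnfood = 9.5 (adult mean 10)
shared_pop <- function() {
  if (is.null(.fixture_cache$pop)) {
    .fixture_cache$pop <- generate_population(
      synth_spec(n = 30, noise_sd = 0.3, seed = 11), shared_qp())
  }
  .fixture_cache$pop
}

# a well-converged fit of the canonical assemblage (enough stages for the
# posterior to concentrate)
shared_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$fit <- run_smc(
      shared_pop(),
      config = smc_config(n_particles = 2000, n_stages = 9, seed = 42))
  }
  .fixture_cache$fit
}

# build a minimal particle system by hand (for posterior-module unit tests)
fake_particle_system <- function(particles, weights = NULL) {
  n <- nrow(particles)
  colnames(particles) <- c("t1", "t2", "enrichment", "wnfood")
  structure(list(particles = particles,
                 weights = weights %||% rep(1 / n, n),
                 distances = rep(0, n),
                 tolerances = Inf),
            class = "particle_system")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
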