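# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# A reduced dose-gradient configuration: same module proportions and noise
# as the default, fewer genes, so DE-based tests stay fast.
small_cfg <- function(seed = 1L, ...) {
  sim_config(n_genes = 1500,
             module_sizes = c(shared = 300, ferro = 60, apopt = 60, flip = 15),
             seed = seed, ...)
}

small_sim <- function() {
  fixture("small_sim", function() simulate_dose_experiment(small_cfg()))
}

small_contrasts_24 <- function() {
  fixture("de24", function() {
    sim <- small_sim()
    dose_contrasts(sim$counts, sim$samples, 24)
  })
}

small_contrasts_6 <- function() {
  fixture("de6", function() {
    sim <- small_sim()
    dose_contrasts(sim$counts, sim$samples, 6,
                   contrasts = list(c("JB2", "JB6")))
  })
}

module_genes <- function(sim, mod) {
  sim$truth$modules$gene[sim$truth$modules$module == mod]
}

# Random named profile with unique values (tie-free unless asked otherwise).
random_profile <- function(n, seed) {
  set.seed(seed)
  stats::setNames(stats::rnorm(n), sprintf("g%03d", seq_len(n)))
}
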