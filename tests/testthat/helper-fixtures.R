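# Shared fixtures. Unit tests run on reduced worlds (fewer subjects/cycles,
# fewer restarts) -- they exercise machinery, not the stated default world,
# which is covered by test-acceptance.R.

mini_cfg <- function(seed = 7, ...) {
  default_ground_truth(seed = seed, n_subjects = 3, cycles_mean = 8,
                       cycles_sd = 1, ...)
}

# lazily computed, memoized across tests within a file run
.fixture_env <- new.env(parent = emptyenv())

fixture_extraction <- function() {
  if (is.null(.fixture_env$cs)) {
    cell <- generate_condition_cycles(mini_cfg(), 1, 3, 0)
    .fixture_env$cell <- cell
    .fixture_env$cs <- extract_cell(cell$cycles, restarts = 5, seed = 11)
  }
  list(cell = .fixture_env$cell, cs = .fixture_env$cs)
}

# deterministic non-negative random matrix
rand_nonneg <- function(m, n, seed) {
  set.seed(seed)
  matrix(runif(m * n), m, n)
}
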