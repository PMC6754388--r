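# shared fixtures: configurations kept small enough that converge-mode runs
# finish in milliseconds-to-seconds

default_kinetics <- function(...) kinetic_parameters(...)

# full-resolution grid (sensor spacing, 20 mm)
fine_grid <- function() grid_1d(spacing = 0.071, n_nodes = 283L)

# coarse grid over the full 20 mm depth; dt = 8 s keeps the stability
# number at 0.397 and makes converge-mode runs ~250x cheaper
coarse_grid <- function() grid_1d(spacing = 0.142, n_nodes = 142L)
coarse_dt <- 8

# half-depth coarse grid for the cheapest property loops
short_grid <- function() grid_1d(spacing = 0.142, n_nodes = 72L)

# a seeded family of random-but-plausible kinetic parameter sets
random_kinetics <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    kinetic_parameters(
      vmax_prod = runif(1, 0.5, 5),
      km_prod = runif(1, 200, 2000),
      vmax_resp = runif(1, 0.5, 5),
      km_resp = runif(1, 50, 500),
      par_surface = runif(1, 500, 2000)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
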