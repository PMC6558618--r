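# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

# The default study scenario (70 electrodes, SNR 7.5, seed 1).
get_scenario <- function() {
  if (is.null(.fixture_cache$scenario)) {
    .fixture_cache$scenario <- build_scenario(seed = 1)
  }
  .fixture_cache$scenario
}

# The four-variate degree-4 leadfield surrogate over skin/skull/gm/wm.
get_pce4 <- function() {
  if (is.null(.fixture_cache$pce4)) {
    .fixture_cache$pce4 <- build_leadfield_pce(get_scenario(),
                                               c("skin", "skull", "gm", "wm"))
  }
  .fixture_cache$pce4
}

# A cheap scenario for unit tests that only need plumbing, not accuracy.
get_small_scenario <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- build_scenario(seed = 3, n_electrodes = 24L,
                                           coarse_spacing = 14e-3,
                                           fine_extent = 8e-3,
                                           fine_spacing = 4e-3)
  }
  .fixture_cache$small
}

# Homogeneous and default 5-shell models used across forward tests.
homogeneous_shells <- function(radius = 0.092, sigma = 0.33) {
  shell_model(radius, sigma, "brain")
}

# Random unit vectors / surface points, reproducible.
random_surface_points <- function(n, radius, seed) {
  set.seed(seed)
  p <- matrix(stats::rnorm(3 * n), n, 3)
  p / sqrt(rowSums(p^2)) * radius
}
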