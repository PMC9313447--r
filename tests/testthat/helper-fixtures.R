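# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small cohort on a coarse grid: fast enough for unit tests, large enough
# that every territory is non-empty
test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(cohort_config(
      n_patients = 8L, grid_shape = c(24L, 24L, 12L), seed = 99L
    ))
  }
  .fixture_env$cohort
}

test_atlas <- function() test_cohort()$atlas

# cohort whose lesion always sits in m2, for planted-sign checks
test_cohort_m2 <- function() {
  if (is.null(.fixture_env$cohort_m2)) {
    .fixture_env$cohort_m2 <- simulate_cohort(cohort_config(
      n_patients = 14L, ht_fraction = 0.3, grid_shape = c(24L, 24L, 12L),
      lesion_territories = "m2", seed = 7L
    ))
  }
  .fixture_env$cohort_m2
}

# random test ROI: scattered mask plus Gaussian intensities
random_roi <- function(seed, dim = c(6L, 6L, 6L), fill = 0.5) {
  set.seed(seed)
  repeat {
    mask <- array(runif(prod(dim)) < fill, dim)
    if (sum(mask) >= 12) break
  }
  list(mask = mask, volume = array(rnorm(prod(dim), 100, 20), dim))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  stopifnot(length(actual) == length(expected))
  denom <- pmax(abs(expected), 1)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
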