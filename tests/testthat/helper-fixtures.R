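# Shared small fixtures, built once per test run.

tiny_gen_config <- function(seed = 11, ...) {
  generator_config(grid_shape = c(24, 28, 22), voxel_size_mm = c(4, 4, 4),
                   n_controls = 12, n_patients_by_subtype = c(AD = 4, FTD = 3),
                   seed = seed, ...)
}

# cached tiny cohort used by several files
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(tiny_gen_config())
    cache
  }
})

# a deterministic smooth test volume on a small grid
bump_volume <- function(d = c(12, 12, 12)) {
  x <- seq(-1, 1, length.out = d[1])
  y <- seq(-1, 1, length.out = d[2])
  z <- seq(-1, 1, length.out = d[3])
  outer(outer(exp(-x^2), exp(-y^2)), exp(-z^2)) + 0.5
}
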