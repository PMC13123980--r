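# Shared small fixtures, built once per test run.

# report every failure in a run instead of aborting at the default cap
options(testthat.progress.max_fails = 10000)

# two years of default-parameter synthetic climate
small_climate <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_climate(
        synthetic_config("2020-01-01", "2021-12-31", seed = 11L))
    cache
  }
})

small_hi <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- heat_index(small_climate())
    cache
  }
})

small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_features(small_hi())
    cache
  }
})

# deterministic noiseless series: hi is a smooth learnable function of the
# calendar, useful for interpolation-regime model checks
noiseless_config <- function(start = "2020-01-01", end = "2020-12-31",
                             seed = 5L) {
  synthetic_config(start, end, noise_sd = 0, rh_noise_sd = 0, seed = seed)
}
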