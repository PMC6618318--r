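# Shared fixtures: default parameters and common scenarios.

p_default <- deb_parameters()

env_baseline <- environment_spec(R_hat = 1.8)
env_d15 <- environment_spec(R_hat = 1.8, disturbance_days = 15)
env_d25 <- environment_spec(R_hat = 1.8, disturbance_days = 25)

# memoised fixed-mode baseline life with trajectory (used across files)
baseline_life <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_life(p_default, env_baseline, record = TRUE)
    cache
  }
})
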