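# Shared fixtures: small simulated cases, built once per test run.

small_case <- function(seed = 11L, dim_xyz = c(10L, 10L, 1L),
                       delay_range = c(0, 0), method = "osvd") {
  sim <- simulate_case(simulation_config(dim_xyz = dim_xyz,
                                         delay_range = delay_range,
                                         seed = seed))
  ctc <- signal_to_ctc(sim$series)
  maps <- maps_from_case(ctc, sim$aif, deconv_config(method = method))
  list(sim = sim, ctc = ctc, aif = sim$aif, maps = maps, id = sim$id)
}

# A deterministic nonlinear regression fixture: y is a smooth function of a
# few feature summaries, mimicking curve-shaped inputs.
toy_regression <- function(n = 200L, p = 10L, seed = 1L, noise_sd = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- X[, 1] + 0.5 * sin(2 * X[, 2]) + 0.25 * X[, 3]^2 +
      stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}
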