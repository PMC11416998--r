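# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small synthetic trial and its chemo-arm reconstructions.
fixture_sim <- function(n = 500, seed = 42) {
  cached(sprintf("sim_%d_%d", n, seed), {
    simulate_trial(trial_config(n_per_arm = n, seed = seed))
  })
}

fixture_chemo_km <- function(endpoint = "OS", n = 500, seed = 42) {
  cached(sprintf("km_%s_%d_%d", endpoint, n, seed), {
    sim <- fixture_sim(n, seed)
    km_with_risk_table(sim[sim$arm == "chemo" & sim$endpoint == endpoint, ])
  })
}

fixture_ipd <- function(endpoint = "OS", n = 500, seed = 42) {
  cached(sprintf("ipd_%s_%d_%d", endpoint, n, seed), {
    km <- fixture_chemo_km(endpoint, n, seed)
    reconstruct(km$curve, km$risk)
  })
}

# The full calibrated pipeline at the acceptance problem size (expensive;
# shared across acceptance blocks).
fixture_pipeline <- function(seed = 1) {
  cached(sprintf("pipe_%d", seed), {
    suppressWarnings(run_pipeline(config = list(), seed = seed))
  })
}

# Analytic survival models for cohort-engine tests.
manual_model <- function(family, params) {
  structure(list(family = family, params = params, loglik = 0,
                 n_params = length(params), aic = 0, knots = NULL),
            class = "surv_model")
}

exp_model <- function(rate) manual_model("exponential", c(rate = rate))

lnorm_model <- function(meanlog, sdlog) {
  manual_model("log_normal", c(meanlog = meanlog, sdlog = sdlog))
}

# Step-function sup-distance between two KM-style curves on a grid.
km_sup_dist <- function(t1, s1, t2, s2, grid) {
  f1 <- stats::stepfun(t1, c(1, s1))
  f2 <- stats::stepfun(t2, c(1, s2))
  max(abs(f1(grid) - f2(grid)))
}

# Minimal stand-in for a cea_result, for sensitivity-module oracles.
toy_cea <- function(d_cost, d_qaly) {
  structure(list(d_cost = d_cost, d_qaly = d_qaly,
                 icer_per_qaly = if (d_qaly > 0) d_cost / d_qaly else NA),
            class = "cea_result")
}
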