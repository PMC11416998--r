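toy_specs <- function() {
  structure(data.frame(
    name = c("a", "b", "c"),
    baseline = c(2, 1, 5),
    low = c(1, 0.5, 5),
    high = c(3, 2, 5),
    distribution = "fixed"), class = c("param_table", "data.frame"))
}

# ICER = 1000 * a / b; parameter c has no effect
toy_fn <- function(p) toy_cea(d_cost = 1000 * p$a, d_qaly = p$b)

test_that("one-way analysis matches a hand-computed toy model", {
  tor <- one_way(toy_fn, toy_specs())
  expect_s3_class(tor, "tornado")
  a_row <- tor[tor$name == "a", ]
  expect_equal(a_row$icer_at_low, 1000)   # a=1, b=1
  expect_equal(a_row$icer_at_high, 3000)  # a=3, b=1
  b_row <- tor[tor$name == "b", ]
  expect_equal(b_row$icer_at_low, 4000)   # a=2, b=0.5
  expect_equal(b_row$icer_at_high, 1000)  # a=2, b=2
  c_row <- tor[tor$name == "c", ]
  expect_equal(c_row$spread, 0)           # degenerate range kept
  expect_true(all(diff(tor$spread) <= 0)) # sorted by descending spread
})

test_that("moment-matched distributions honour the range rule", {
  specs <- default_parameters()
  # HR of OS: log-sd = (ln 0.58 - ln 0.38)/3.92
  d <- draw_params(specs, n = 20000, seed = 3)
  expect_equal(sd(log(d$hr_os)), (log(0.58) - log(0.38)) / 3.92,
               tolerance = 0.01)
  expect_equal(median(d$hr_os), 0.47, tolerance = 0.01)
  # beta utility: mean within +/-0.005 of 0.80 at 10,000+ draws
  expect_equal(mean(d$u_pfs[1:10000]), 0.80, tolerance = 0.005)
  # gamma cost keeps its mean; fixed stays fixed
  expect_equal(mean(d$cost_anemia), 4638, tolerance = 4638 * 0.02)
  expect_true(all(d$crcl == 70))
  expect_true(all(d$discount_annual == 0.03))
  # infeasible beta moment matching is refused by name
  bad <- toy_specs()
  bad$distribution <- c("beta", "fixed", "fixed")  # mean 2 outside (0,1)
  expect_error(draw_params(bad, 2), "infeasible for 'a'")
})

test_that("PSA is reproducible and collapses to the base case when fixed", {
  res1 <- psa(toy_fn, toy_specs(), n = 25, seed = 9)
  res2 <- psa(toy_fn, toy_specs(), n = 25, seed = 9)
  expect_identical(res1$draws, res2$draws)
  expect_true(all(res1$draws$d_cost == 2000))
  expect_true(all(res1$draws$d_qaly == 1))
})

test_that("CEAC equals brute-force enumeration over draws", {
  fake <- structure(list(draws = data.frame(
    d_cost = c(100, 200, 300, 400), d_qaly = c(1, 1, 1, 1)),
    n_draws = 4, seed = 1), class = "psa_result")
  cc <- ceac(fake, wtp_grid = c(0, 150, 250, 350, 1000))
  expect_equal(cc$prob_cost_effective, c(0, 0.25, 0.5, 0.75, 1))
  # identical draws: a step from 0 to 1 at the common ICER
  one <- structure(list(draws = data.frame(d_cost = 500, d_qaly = 2),
                        n_draws = 1, seed = 1), class = "psa_result")
  cs <- ceac(one, wtp_grid = c(200, 249, 251, 300))
  expect_equal(cs$prob_cost_effective, c(0, 0, 1, 1))
  # monotone whenever every draw gains QALYs
  expect_true(all(diff(cc$prob_cost_effective) >= 0))
})

test_that("price threshold solves the deterministic crossing", {
  specs <- structure(data.frame(
    name = "price_ev", baseline = 200, low = 150, high = 250,
    distribution = "fixed"), class = c("param_table", "data.frame"))
  fn <- function(p) toy_cea(d_cost = 1000 * p$price_ev, d_qaly = 1)
  # ICER = 1000 * price; at wtp 150,000 the crossing price is 150
  thr <- price_threshold(fn, specs, "price_ev", target_prob = 0.5,
                         wtp = 150000, n_draws = 1, seed = 1, tol = 0.5)
  expect_equal(thr, 150, tolerance = 0.5)
  # already cost-effective at baseline: the baseline price is returned
  thr2 <- price_threshold(fn, specs, "price_ev", target_prob = 0.5,
                          wtp = 300000, n_draws = 1, seed = 1)
  expect_equal(thr2, 200)
})

test_that("arm utilities drive the two-way grid in the expected direction", {
  os <- lnorm_model(log(16.9), 0.85)
  pf <- lnorm_model(log(6.3), 0.85)
  fn <- make_model_fn(os, pf, NULL, model_settings(horizon_years = 15))
  m <- two_way_utilities(fn, default_parameters(), n_grid = 4)
  expect_true(all(is.finite(m)))
  # raising the combination arm's utility weakly lowers the ICER
  expect_true(all(apply(m, 2, diff) <= 1e-6))
  expect_error(two_way_utilities(fn, default_parameters(), n_grid = 1),
               "n_grid")
})

test_that("the influential parameters of the calibrated base case have nonzero spread", {
  pipe <- fixture_pipeline(seed = 1)
  tor <- one_way(pipe$model_fn, default_parameters())
  influential <- c("discount_annual", "price_ev", "weight_kg",
                   "hr_os", "hr_pfs")
  expect_true(all(tor$spread[match(influential, tor$name)] > 0))
  # raising the EV unit price strictly increases the ICER
  ev <- tor[tor$name == "price_ev", ]
  expect_gt(ev$icer_at_high, ev$icer_at_low)
  expect_gt(pipe$base$icer_per_qaly, 150000)  # never cost-effective at WTP
})

test_that("subgroups re-run the pipeline and order by hazard ratio", {
  km_os <- fixture_chemo_km("OS", 500, 42)
  km_pf <- fixture_chemo_km("PFS", 500, 42)
  sg <- list(os_curve = km_os$curve, os_risk = km_os$risk,
             pfs_curve = km_pf$curve, pfs_risk = km_pf$risk)
  fams <- c("exponential", "weibull", "log_normal")
  res <- suppressWarnings(subgroup_run(
    list(eligible = c(sg, list(hr_os = 0.47, hr_pfs = 0.45)),
         ineligible = c(sg, list(hr_os = 0.38, hr_pfs = 0.38)),
         base = sg),
    default_parameters(), families = fams,
    settings = model_settings(horizon_years = 20)))
  # identical inputs reproduce the base-case ICER exactly
  expect_equal(res$base$icer_per_qaly, res$eligible$icer_per_qaly)
  # a stronger treatment effect lowers the ICER
  expect_lt(res$ineligible$icer_per_qaly, res$eligible$icer_per_qaly)
  expect_error(suppressWarnings(subgroup_run(
    list(bad = sg[c("os_curve", "os_risk")]), default_parameters())),
    "missing subgroup curves")
})
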