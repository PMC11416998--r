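pt70 <- patient()
pars <- param_baselines(default_parameters())

test_that("dose rules reproduce the protocol doses", {
  ev <- drug_component("ev", "mg_per_kg", 1.25, c(1, 8), 131.52)
  expect_equal(dose_mg(ev, pt70), 87.5)
  carbo <- drug_component("carboplatin", "auc_calvert", 4.5, 1, 0.072)
  expect_equal(dose_mg(carbo, pt70), 4.5 * (70 + 25))  # Calvert: 427.5 mg
  pem <- drug_component("pembrolizumab", "flat_mg", 200, 1, 55.73)
  expect_equal(dose_mg(pem, pt70), 200)
  gem <- drug_component("gemcitabine", "mg_per_m2", 1000, c(1, 8), 0.044)
  expect_equal(dose_mg(gem, pt70), 1860)
})

test_that("cycle drug cost honours schedules, caps and infusion fees", {
  arms <- build_arm_specs(pars)
  ev1 <- cycle_drug_cost(arms$ev_pemb$first_line, pt70, 1)
  # pembrolizumab 200 x 55.73 plus EV 2 x 87.5 x 131.52
  expect_equal(ev1$drug, 200 * 55.73 + 2 * 87.5 * 131.52)
  expect_equal(200 * 55.73, 11146)
  expect_equal(2 * 87.5 * 131.52, 23016)
  # two drugs on day 1 (one extra hour), EV alone on day 8
  expect_equal(ev1$admin, 144.39 + 31.10 + 144.39)

  ev36 <- cycle_drug_cost(arms$ev_pemb$first_line, pt70, 36)
  expect_equal(ev36$drug, 23016)  # pembrolizumab capped at 35 cycles
  expect_equal(ev36$admin, 2 * 144.39)

  ch <- cycle_drug_cost(arms$chemo$first_line, pt70, 1)
  expect_equal(ch$drug,
               2 * 1860 * 0.044 + 0.5 * 70 * 1.86 * 0.404 +
                 0.5 * 427.5 * 0.072)
  expect_equal(ch$admin, 144.39 + 31.10 + 144.39)
  # past the chemotherapy cap nothing is dispensed
  expect_equal(cycle_drug_cost(arms$chemo$first_line, pt70, 7)$total, 0)
  expect_error(cycle_drug_cost(arms$chemo$first_line, pt70, 0), ">= 1")
})

test_that("trace occupancy is conserved and degenerate cases behave", {
  st <- model_settings()
  ln <- lnorm_model(log(16.9), 0.85)
  tr <- build_trace(ln, lnorm_model(log(6.3), 0.85), default_life_table(), st)
  expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
  expect_true(all(tr$pfs >= 0 & tr$pd >= -1e-12 & tr$dead >= 0))
  expect_true(all(diff(tr$dead) >= -1e-12))

  # identical curves: the progressed state is never occupied
  tr2 <- build_trace(ln, ln, NULL, st)
  expect_true(all(tr2$pd == 0))

  # no mortality at all: everyone survives the horizon
  tr3 <- build_trace(exp_model(0), exp_model(0), NULL, st)
  expect_true(all(tr3$dead == 0))
  expect_error(model_settings(horizon_years = 0.01), "shorter than one cycle")
})

test_that("trace life-years match the closed-form exponential mean", {
  st <- model_settings(discount_annual = 0, horizon_years = 40)
  lam <- 0.0411  # per month; mean 1/lambda = 24.33 months
  m <- exp_model(lam)
  tr <- build_trace(m, m, NULL, st)
  arm <- list(first_line = regimen(list()), second_line = regimen(list()),
              utilities = c(pfs = 1, pd = 1), ae = NULL, bsc_per_cycle = 0)
  acc <- accrue_arm(tr, arm, pt70)
  expect_equal(acc$ly, (1 / lam) / 12, tolerance = 0.005)
  expect_equal(acc$qaly, acc$ly)  # utilities of 1, no AE decrement
})

test_that("background-mortality floor can only shorten life expectancy", {
  st <- model_settings(discount_annual = 0)
  ln <- lnorm_model(log(16.9), 0.85)
  arm <- list(first_line = regimen(list()), second_line = regimen(list()),
              utilities = c(pfs = 1, pd = 1), ae = NULL, bsc_per_cycle = 0)
  ly_floor <- accrue_arm(build_trace(ln, ln, default_life_table(), st),
                         arm, pt70)$ly
  ly_free <- accrue_arm(build_trace(ln, ln, NULL, st), arm, pt70)$ly
  expect_lte(ly_floor, ly_free)
})

test_that("one-time adverse-event burdens equal the incidence-weighted sums", {
  arms <- build_arm_specs(pars)
  ae <- arms$chemo$ae
  expect_equal(sum(ae$incidence * ae$disutility), 0.11212)
  expect_equal(sum(ae$incidence * ae$cost), 18654.58)
  ae_ev <- arms$ev_pemb$ae
  expect_equal(sum(ae_ev$incidence * ae_ev$disutility),
               0.048 * 0.150 + 0.077 * 0.032 + 0.050 * 0.140)
})

test_that("discounted totals are non-increasing in the discount rate", {
  ln <- lnorm_model(log(16.9), 0.85)
  pf <- lnorm_model(log(6.3), 0.85)
  vals <- lapply(c(0, 0.03, 0.08), function(r) {
    st <- model_settings(discount_annual = r)
    tr <- build_trace(ln, pf, default_life_table(), st)
    accrue_arm(tr, build_arm_specs(pars)$chemo, pt70)
  })
  expect_true(all(diff(vapply(vals, `[[`, numeric(1), "cost")) < 0))
  expect_true(all(diff(vapply(vals, `[[`, numeric(1), "qaly")) < 0))
})

test_that("half-cycle correction averages the start- and end-of-cycle schemes", {
  st <- model_settings()
  tr <- build_trace(lnorm_model(log(16.9), 0.85),
                    lnorm_model(log(6.3), 0.85), default_life_table(), st)
  arm <- build_arm_specs(pars)$chemo
  half <- accrue_arm(tr, arm, pt70, scheme = "half_cycle")
  st_s <- accrue_arm(tr, arm, pt70, scheme = "start")
  en <- accrue_arm(tr, arm, pt70, scheme = "end")
  one_cycle_ly <- st$cycle_months / 12
  expect_lt(abs(half$ly - (st_s$ly + en$ly) / 2), one_cycle_ly)
  expect_lt(abs(half$qaly - (st_s$qaly + en$qaly) / 2), one_cycle_ly)
  # within one cycle's maximal accrual for costs as well
  max_cycle_cost <- cycle_drug_cost(arm$first_line, pt70, 1)$total +
    arm$bsc_per_cycle + 2e4
  expect_lt(abs(half$cost - (st_s$cost + en$cost) / 2), max_cycle_cost)
})

test_that("costs decompose additively across categories", {
  ln <- lnorm_model(log(16.9), 0.85)
  pf <- lnorm_model(log(6.3), 0.85)
  st <- model_settings()
  tr <- build_trace(ln, pf, default_life_table(), st)
  zero <- function(p, what) {
    q <- p
    if ("drugs" %in% what)
      q[grep("^price_", names(q))] <- lapply(q[grep("^price_", names(q))],
                                             function(x) 0)
    if ("admin" %in% what) q$admin_first_hour <- q$admin_additional_hour <- 0
    if ("bsc" %in% what) q$bsc_per_cycle <- 0
    if ("ae" %in% what) q[grep("^cost_", names(q))] <-
        lapply(q[grep("^cost_", names(q))], function(x) 0)
    q
  }
  total <- function(p) accrue_arm(tr, build_arm_specs(p)$chemo, pt70)$cost
  full <- total(pars)
  parts <- total(zero(pars, c("admin", "bsc", "ae"))) +       # drugs only
    total(zero(pars, c("drugs", "bsc", "ae"))) +              # admin only
    total(zero(pars, c("drugs", "admin", "ae"))) +            # bsc only
    total(zero(pars, c("drugs", "admin", "bsc")))             # ae only
  expect_equal(full, parts, tolerance = 1e-9)
  # with zero drug prices only admin/BSC/AE differences remain
  expect_equal(total(zero(pars, "drugs")),
               full - total(zero(pars, c("admin", "bsc", "ae"))),
               tolerance = 1e-9)
})

test_that("a duration cap can only reduce second-line cost", {
  ln <- lnorm_model(log(16.9), 0.85)
  pf <- lnorm_model(log(6.3), 0.85)
  tr <- build_trace(ln, pf, default_life_table(), model_settings())
  arm <- build_arm_specs(pars)$chemo
  capped <- accrue_arm(tr, arm, pt70)$breakdown[["second_line"]]
  arm$second_line$max_cycles <- Inf
  uncapped <- accrue_arm(tr, arm, pt70)$breakdown[["second_line"]]
  expect_lte(capped, uncapped + 1e-9)
  expect_gt(capped, 0)
})

test_that("icer computes increments, ratios and dominance", {
  expect_equal(icer(list(ly = 2, qaly = 2, cost = 100),
                    list(ly = 1, qaly = 1, cost = 50))$icer_per_qaly, 50)
  tie <- icer(list(ly = 1, qaly = 1, cost = 100),
              list(ly = 1, qaly = 1, cost = 50))
  expect_equal(tie$status, "dominated")
  expect_true(is.na(tie$icer_per_qaly))
  dom <- icer(list(ly = 2, qaly = 2, cost = 10),
              list(ly = 1, qaly = 1, cost = 50))
  expect_equal(dom$status, "dominant")
  expect_error(accrue_arm(
    build_trace(exp_model(0.1), exp_model(0.1), NULL, model_settings()),
    list(first_line = regimen(list()), second_line = NULL,
         utilities = c(pfs = 1, pd = 1)), pt70), "second-line")
})
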