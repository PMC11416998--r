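test_that("exponential MLE and log-likelihood match the closed form", {
  set.seed(1)
  tt <- rexp(10, 0.2)
  ipd <- data.frame(time = tt, event = 1)
  fit <- fit_survival(ipd, "exponential")
  expect_equal(unname(fit$params[["rate"]]), 10 / sum(tt), tolerance = 1e-6)
  # independent likelihood evaluation: sum of log densities at the MLE
  lam <- fit$params[["rate"]]
  ll_manual <- sum(stats::dexp(tt, lam, log = TRUE))
  expect_equal(fit$loglik, ll_manual, tolerance = 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
})

test_that("log-normal fit recovers generating parameters at n = 2000", {
  set.seed(7)
  ipd <- data.frame(time = rlnorm(2000, 2.5, 0.95), event = 1)
  fit <- fit_survival(ipd, "log_normal")
  expect_equal(unname(fit$params[["meanlog"]]), 2.5, tolerance = 0.07)
  expect_equal(unname(fit$params[["sdlog"]]), 0.95, tolerance = 0.07)
})

test_that("every family yields a valid survival and hazard function", {
  ipd <- fixture_ipd("OS", 500, 42)
  fits <- suppressWarnings(fit_candidates(ipd))
  expect_gte(length(fits), 6)
  grid <- seq(0.05, 120, by = 0.05)
  for (fit in fits) {
    s <- surv_prob(fit, grid)
    expect_equal(surv_prob(fit, 0), 1)
    expect_true(all(diff(s) <= 1e-12), info = fit$family)
    expect_true(all(hazard_fn(fit, grid) >= 0), info = fit$family)
    # numerical hazard -d log S / dt vs analytic
    ok <- s > 1e-6 & grid > 1 & grid < 60
    h <- 1e-4
    num <- -(log(surv_prob(fit, grid[ok] + h)) -
               log(surv_prob(fit, grid[ok] - h))) / (2 * h)
    ana <- hazard_fn(fit, grid[ok])
    expect_lt(max(abs(num - ana) / pmax(ana, 1e-8)), 1e-4)
  }
})

test_that("AIC selection prefers parsimony on exponential data", {
  set.seed(11)
  ipd <- data.frame(time = rexp(2000, 0.1), event = 1)
  fits <- suppressWarnings(
    lapply(c("exponential", "gen_gamma"), function(f) fit_survival(ipd, f)))
  sel <- select_by_aic(fits)
  expect_equal(sel$family, "exponential")
  expect_equal(nrow(attr(sel, "aic_ranking")), 2L)
})

test_that("AIC selection handles singletons, ties and empty input", {
  set.seed(2)
  m <- fit_survival(data.frame(time = rexp(50, 1) + 0.01, event = 1),
                    "exponential")
  expect_identical(select_by_aic(list(m))$family, "exponential")

  a <- manual_model("exponential", c(rate = 1)); a$loglik <- -10; a$aic <- 22
  b <- manual_model("weibull", c(shape = 1, scale = 1))
  b$loglik <- -10; b$n_params <- 2; b$aic <- 22  # tie: fewer params wins
  expect_equal(select_by_aic(list(b, a))$family, "exponential")
  expect_error(select_by_aic(list()), "no converged")
})

test_that("AIC ordering is invariant to the time unit", {
  ipd <- fixture_ipd("OS", 500, 42)
  ipd_days <- transform(ipd, time = time * 30.4375)
  fams <- c("exponential", "weibull", "log_logistic", "log_normal",
            "gompertz")
  f1 <- suppressWarnings(fit_candidates(ipd, fams))
  f2 <- suppressWarnings(fit_candidates(ipd_days, fams))
  shared <- intersect(names(f1), names(f2))
  a1 <- vapply(f1[shared], `[[`, numeric(1), "aic")
  a2 <- vapply(f2[shared], `[[`, numeric(1), "aic")
  expect_equal(names(sort(a1)), names(sort(a2)))
  # AIC gaps are exactly invariant up to the Jacobian constant d*log(c)
  expect_equal(unname(a1 - min(a1)), unname(a2 - min(a2)), tolerance = 0.05)
})

test_that("hazard-ratio scaling obeys its closed forms and inverse identity", {
  m <- exp_model(0.2)
  expect_equal(surv_prob(apply_hr(m, 1), 5), surv_prob(m, 5))
  # exponential rate lambda scaled by 0.5 is exponential rate lambda/2
  expect_equal(surv_prob(apply_hr(m, 0.5), 7), pexp(7, 0.1, lower.tail = FALSE))
  # S = 0.25 scaled by hr = 0.5 gives 0.5
  t_quarter <- -log(0.25) / 0.2
  expect_equal(surv_prob(apply_hr(m, 0.5), t_quarter), 0.5, tolerance = 1e-12)

  ln <- lnorm_model(2.8, 0.9)
  back <- apply_hr(apply_hr(ln, 0.47), 1 / 0.47)
  tg <- c(0.5, 3, 17, 80)
  expect_equal(surv_prob(back, tg), surv_prob(ln, tg), tolerance = 1e-10)
  expect_error(apply_hr(ln, 0), "positive")
})

test_that("interval survival is the conditional probability across the cycle", {
  m <- exp_model(0.1)
  expect_equal(interval_survival(m, 0, 0.75), exp(-0.075), tolerance = 1e-12)
  expect_equal(interval_survival(m, 10, 10 + 1e-9), 1, tolerance = 1e-6)
  # telescoping across consecutive cycles
  ln <- lnorm_model(2.8, 0.9)
  cuts <- seq(2, 12, by = 0.69)
  prod_cond <- prod(vapply(seq_len(length(cuts) - 1), function(i)
    interval_survival(ln, cuts[i], cuts[i + 1]), numeric(1)))
  expect_equal(prod_cond, interval_survival(ln, cuts[1], cuts[length(cuts)]),
               tolerance = 1e-10)
  expect_error(interval_survival(m, 5, 5), "t_start < t_end")
})

test_that("mixture-cure fit recovers a cured fraction", {
  set.seed(21)
  n <- 1500
  cured <- runif(n) < 0.25
  tt <- ifelse(cured, Inf, rweibull(n, 1.4, 10))
  cens <- runif(n, 30, 60)
  ipd <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens))
  fit <- fit_survival(ipd, "mixture_cure")
  expect_lt(abs(fit$params[["cure_prob"]] - 0.25), 0.04)
  expect_lt(abs(fit$params[["shape"]] - 1.4), 0.2)
})
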