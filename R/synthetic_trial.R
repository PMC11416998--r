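#' Configuration for the synthetic two-arm trial emulator
#'
#' Defines the data-generating process for an EV-302-like randomized trial:
#' a chemotherapy arm with log-normal overall survival (OS) and a
#' log-logistic latent progression process, and a combination arm obtained
#' by raising the chemotherapy survival functions to the power of the
#' hazard ratio (proportional hazards on both endpoints). Uniform accrual
#' plus a fixed data cut-off induce administrative right-censoring.
#'
#' The default medians (OS 16.9 months, PFS 6.3 months) and hazard ratios
#' (OS 0.47, PFS 0.45) are the chemotherapy-arm medians and treatment
#' effects of the emulated trial. Both chemotherapy-arm marginals are
#' log-normal: OS with sigma `os_shape`, PFS with sigma `pfs_shape`. The
#' latent progression process is derived as the survival ratio
#' `S_PFS(t) / S_OS(t)`, which is a valid distribution whenever the PFS
#' hazard dominates the OS hazard (it does throughout the modelled range
#' for the defaults; the generator enforces monotonicity numerically).
#' The sigmas are not published; the defaults are calibrated once so that
#' the lifetime discounted projections of the downstream cohort model
#' land near the published base case (see the methods vignette).
#'
#' @param n_per_arm Number of subjects per arm (>= 2).
#' @param chemo_os_median Median OS in the chemotherapy arm, months.
#' @param chemo_pfs_median Marginal median PFS in the chemotherapy arm,
#'   months. Must not exceed `chemo_os_median`.
#' @param os_shape Log-normal sigma of the chemotherapy OS marginal.
#' @param pfs_shape Log-normal sigma of the chemotherapy PFS marginal.
#' @param hr_os,hr_pfs Hazard ratios (combination vs chemotherapy) applied
#'   to OS and PFS.
#' @param accrual_months Uniform accrual window, months.
#' @param followup_months Data cut-off after start of accrual, months.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 2000L,
                         chemo_os_median = 16.9,
                         chemo_pfs_median = 6.3,
                         os_shape = 0.85,
                         pfs_shape = 1.00,
                         hr_os = 0.47,
                         hr_pfs = 0.45,
                         accrual_months = 20,
                         followup_months = 24,
                         seed = 1L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 2)
    stop("`n_per_arm` must be at least 2", call. = FALSE)
  if (chemo_os_median <= 0 || chemo_pfs_median <= 0)
    stop("medians must be positive", call. = FALSE)
  if (chemo_pfs_median > chemo_os_median)
    stop("`chemo_pfs_median` must not exceed `chemo_os_median`", call. = FALSE)
  if (hr_os <= 0 || hr_pfs <= 0)
    stop("hazard ratios must be positive", call. = FALSE)
  if (os_shape <= 0 || pfs_shape <= 0)
    stop("shape parameters must be positive", call. = FALSE)
  if (accrual_months < 0 || followup_months <= 0)
    stop("accrual/follow-up must be non-negative/positive", call. = FALSE)
  structure(
    list(n_per_arm = as.integer(n_per_arm),
         chemo_os_median = chemo_os_median,
         chemo_pfs_median = chemo_pfs_median,
         os_shape = os_shape, pfs_shape = pfs_shape,
         hr_os = hr_os, hr_pfs = hr_pfs,
         accrual_months = accrual_months,
         followup_months = followup_months,
         seed = as.integer(seed)),
    class = "trial_config")
}

# Baseline survival functions of the chemotherapy arm implied by a config:
# log-normal OS and PFS marginals. The latent progression process used for
# the min-coupling has log-survival
#   log S_prog(t) = log S_PFS(t) - log S_OS(t),
# valid (non-increasing) wherever the PFS hazard dominates the OS hazard.
chemo_baseline <- function(config) {
  mu_os <- log(config$chemo_os_median)
  mu_pfs <- log(config$chemo_pfs_median)
  sig_os <- config$os_shape
  sig_pfs <- config$pfs_shape
  list(mu_os = mu_os, sig_os = sig_os, mu_pfs = mu_pfs, sig_pfs = sig_pfs,
       s_os = function(t) plnorm(t, mu_os, sig_os, lower.tail = FALSE),
       s_pfs = function(t) plnorm(t, mu_pfs, sig_pfs, lower.tail = FALSE),
       log_s_os = function(t) plnorm(t, mu_os, sig_os, lower.tail = FALSE,
                                     log.p = TRUE),
       log_s_pfs = function(t) plnorm(t, mu_pfs, sig_pfs, lower.tail = FALSE,
                                      log.p = TRUE))
}

# Inverse of S(t) = u for the combination-arm latent progression process,
# S_prog_ev(t) = S_os(t)^(hr_pfs - hr_os) * S_prog(t)^hr_pfs, by monotone
# interpolation on a log-time grid.
invert_on_grid <- function(log_s_fn, u, t_max = 5000) {
  grid <- c(0, exp(seq(log(1e-3), log(t_max), length.out = 4096)))
  s <- exp(log_s_fn(grid))
  s <- cummin(pmin(s, 1))  # enforce monotonicity against numerical noise
  keep <- !duplicated(s)   # flat stretches invert to their earliest time
  out <- approx(x = rev(s[keep]), y = rev(grid[keep]), xout = u,
                rule = 2)$y
  out[u >= s[1]] <- 0
  out
}

#' Simulate an EV-302-like two-arm trial
#'
#' Draws per-subject OS and progression times in each arm, couples PFS as
#' `min(OS, progression)` so that PFS never exceeds OS within a subject,
#' and applies administrative censoring from uniform accrual with a fixed
#' data cut-off. The combination arm is generated under proportional
#' hazards: its marginal OS and PFS survival functions equal the
#' chemotherapy-arm functions raised to `hr_os` and `hr_pfs`.
#'
#' The two arms share common random numbers: each arm transforms the same
#' per-subject uniforms through its own survival inversion. This leaves
#' every marginal distribution untouched while sharply reducing the Monte
#' Carlo variance of between-arm contrasts (the estimated hazard ratios),
#' and makes the two arms exactly identical when both hazard ratios are 1.
#'
#' @param config A [trial_config()].
#' @return A data frame of survival records with columns `id`, `arm`
#'   (`"chemo"` or `"ev_pemb"`), `endpoint` (`"OS"` or `"PFS"`), `time`
#'   (months) and `event` (1 = event, 0 = censored).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  base <- chemo_baseline(config)
  set.seed(config$seed)
  n <- config$n_per_arm

  u_os <- runif(n)
  u_prog <- runif(n)
  u_entry <- runif(n)

  draw_arm <- function(arm, hr_os, hr_pfs) {
    # OS: S_os(t)^hr = u  =>  S_os(t) = u^(1/hr)
    t_os <- qlnorm(u_os^(1 / hr_os), base$mu_os, base$sig_os,
                   lower.tail = FALSE)
    # latent progression under proportional hazards on both endpoints:
    # S_prog(t) = S_pfs(t)^hr_pfs / S_os(t)^hr_os, so that the marginal
    # of min(OS, progression) is exactly S_pfs^hr_pfs
    log_s <- function(t) hr_pfs * base$log_s_pfs(t) -
      hr_os * base$log_s_os(t)
    t_prog <- invert_on_grid(log_s, u_prog)
    t_pfs <- pmin(t_os, t_prog)
    entry <- u_entry * config$accrual_months
    cens <- pmax(config$followup_months - entry, 0)
    id <- sprintf("%s_%04d", arm, seq_len(n))
    rbind(
      data.frame(id = id, arm = arm, endpoint = "OS",
                 time = pmin(t_os, cens), event = as.integer(t_os <= cens)),
      data.frame(id = id, arm = arm, endpoint = "PFS",
                 time = pmin(t_pfs, cens), event = as.integer(t_pfs <= cens)))
  }

  out <- rbind(draw_arm("chemo", 1, 1),
               draw_arm("ev_pemb", config$hr_os, config$hr_pfs))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curve with a number-at-risk table
#'
#' Computes the product-limit estimate for one stratum of survival records
#' and reports the number at risk on a requested time grid, i.e. the pair
#' of objects a published KM figure provides and that pseudo-IPD
#' reconstruction consumes.
#'
#' @param records Data frame with columns `time` and `event` (one stratum:
#'   filter to a single arm and endpoint first).
#' @param at_risk_times Ascending time grid (months), starting at 0, at
#'   which the number at risk is reported.
#' @return A list with `curve` (a [digitized_curve()]: coordinates at time
#'   0 and every event time) and `risk` (a [risk_table()]).
#' @export
km_with_risk_table <- function(records, at_risk_times = seq(0, 24, by = 3)) {
  if (NROW(records) == 0) stop("no survival records supplied", call. = FALSE)
  if (is.unsorted(at_risk_times) || at_risk_times[1] != 0)
    stop("`at_risk_times` must be ascending and start at 0", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  drop <- fit$n.event > 0
  curve <- digitized_curve(times = c(0, fit$time[drop]),
                           surv = c(1, fit$surv[drop]))
  sm <- summary(fit, times = at_risk_times, extend = TRUE)
  risk <- risk_table(times = at_risk_times, n_at_risk = sm$n.risk)
  list(curve = curve, risk = risk)
}

#' Synthetic Gompertz-like background life table
#'
#' Builds an age-indexed table of annual death probabilities growing
#' geometrically with age, a synthetic stand-in for a national life table
#' used as the background-mortality floor of the cohort model.
#'
#' @param base_prob Annual death probability at `base_age`, in (0, 1).
#' @param growth Multiplicative increase per year of age.
#' @param age_range Strictly increasing integer ages.
#' @param base_age Age at which `base_prob` applies (default: first age).
#' @return A data frame of class `life_table` with columns `age` and
#'   `annual_death_prob` (capped at 1).
#' @export
make_life_table <- function(base_prob, growth, age_range,
                            base_age = min(age_range)) {
  if (base_prob <= 0 || base_prob >= 1)
    stop("`base_prob` must be in (0, 1)", call. = FALSE)
  if (growth <= 0) stop("`growth` must be positive", call. = FALSE)
  if (any(diff(age_range) <= 0))
    stop("`age_range` must be strictly increasing", call. = FALSE)
  q <- pmin(1, base_prob * growth^(age_range - base_age))
  structure(data.frame(age = age_range, annual_death_prob = q),
            class = c("life_table", "data.frame"))
}

#' Default synthetic US-style background life table
#'
#' Annual death probability 0.009 at age 60 growing 8.8% per year of age,
#' over ages 40-110; a synthetic approximation to general-population
#' mortality around the cohort's start age of 69.
#' @return A `life_table`.
#' @export
default_life_table <- function() {
  make_life_table(base_prob = 0.009, growth = 1.088,
                  age_range = 40:110, base_age = 60)
}
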