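#' Global settings of the cohort model
#'
#' Three-week cycles, lifetime horizon, 3% annual discounting of both
#' costs and health outcomes, half-cycle correction, a cohort starting age
#' of 69 years, and a willingness-to-pay threshold of $150,000 per QALY.
#' Time is measured in months internally; one 21-day cycle is
#' 21 / 30.4375 = 0.690 months.
#'
#' @param cycle_days Cycle length in days.
#' @param discount_annual Annual discount rate (>= 0) applied to costs,
#'   LYs and QALYs.
#' @param horizon_years Model horizon in years (lifetime approximation).
#' @param start_age Cohort age at model start, years; drives the
#'   background-mortality floor as the cohort ages.
#' @param wtp Willingness-to-pay threshold, $/QALY.
#' @param half_cycle Apply half-cycle correction (trapezoidal averaging of
#'   adjacent state occupancies for all accruals)? If `FALSE`,
#'   start-of-cycle occupancies are used.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_days = 21, discount_annual = 0.03,
                           horizon_years = 40, start_age = 69,
                           wtp = 150000, half_cycle = TRUE) {
  if (discount_annual < 0) stop("discount must be >= 0", call. = FALSE)
  if (horizon_years <= 0) stop("horizon must be positive", call. = FALSE)
  cm <- cycle_days / DAYS_PER_MONTH
  if (horizon_years * 12 < cm)
    stop("horizon shorter than one cycle", call. = FALSE)
  structure(list(cycle_days = cycle_days, cycle_months = cm,
                 discount_annual = discount_annual,
                 horizon_years = horizon_years, start_age = start_age,
                 wtp = wtp, half_cycle = isTRUE(half_cycle)),
            class = "model_settings")
}

#' Reference patient for dose calculations
#' @param weight Body weight, kg.
#' @param bsa Body surface area, m^2.
#' @param crcl Creatinine clearance, mL/min (Calvert carboplatin dosing).
#' @return An object of class `patient`.
#' @export
patient <- function(weight = 70, bsa = 1.86, crcl = 70) {
  if (weight <= 0 || bsa <= 0 || crcl <= 0)
    stop("patient characteristics must be positive", call. = FALSE)
  structure(list(weight = weight, bsa = bsa, crcl = crcl),
            class = "patient")
}

#' A drug within a regimen
#'
#' @param name Drug name.
#' @param dose_rule One of `"flat_mg"`, `"mg_per_kg"`, `"mg_per_m2"`,
#'   `"auc_calvert"` (Calvert formula: dose = AUC x (CrCl + 25)).
#' @param dose_value Dose in the rule's unit (mg, mg/kg, mg/m^2, or AUC in
#'   mg/mL/min).
#' @param schedule_days Days within the 21-day cycle on which the drug is
#'   given.
#' @param unit_price $ per mg.
#' @param max_cycles Last cycle in which the drug is given (e.g. 35 for
#'   pembrolizumab); `Inf` for no cap.
#' @param weight Fraction of the cohort receiving this component (e.g. 0.5
#'   each for the cisplatin/carboplatin split).
#' @param doses_per_cycle Average number of administrations per cycle
#'   (default: one per scheduled day; fractional values express schedules
#'   that do not align with the cycle, e.g. 1.5 for every-2-week dosing).
#' @return An object of class `drug_component`.
#' @export
drug_component <- function(name, dose_rule, dose_value, schedule_days,
                           unit_price, max_cycles = Inf, weight = 1,
                           doses_per_cycle = length(schedule_days)) {
  dose_rule <- match.arg(dose_rule,
                         c("flat_mg", "mg_per_kg", "mg_per_m2", "auc_calvert"))
  if (dose_value <= 0) stop("doses must be positive", call. = FALSE)
  if (unit_price < 0) stop("unit price must be >= 0", call. = FALSE)
  if (any(schedule_days < 1 | schedule_days > 21))
    stop("schedule days must lie within the cycle", call. = FALSE)
  structure(list(name = name, dose_rule = dose_rule, dose_value = dose_value,
                 schedule_days = schedule_days, unit_price = unit_price,
                 max_cycles = max_cycles, weight = weight,
                 doses_per_cycle = doses_per_cycle),
            class = "drug_component")
}

#' A treatment regimen (list of drug components with an optional cap)
#' @param components List of [drug_component()]s.
#' @param max_cycles Regimen-level cap on treatment cycles (`Inf` = until
#'   leaving the state).
#' @return An object of class `regimen`.
#' @export
regimen <- function(components, max_cycles = Inf) {
  stopifnot(all(vapply(components, inherits, logical(1), "drug_component")))
  structure(list(components = components, max_cycles = max_cycles),
            class = "regimen")
}

#' Dose in mg for one administration
#' @param component A [drug_component()].
#' @param pt A [patient()].
#' @return Dose in mg.
#' @export
dose_mg <- function(component, pt) {
  switch(component$dose_rule,
         flat_mg = component$dose_value,
         mg_per_kg = component$dose_value * pt$weight,
         mg_per_m2 = component$dose_value * pt$bsa,
         auc_calvert = component$dose_value * (pt$crcl + 25))
}

#' Drug and administration cost of one cycle of a regimen
#'
#' Drug cost sums dose x unit price over components still active at
#' `cycle_index` (components past their cap contribute zero). Infusion
#' cost follows the Medicare two-rate schedule: the first-hour fee per
#' infusion visit, plus the additional-hour fee for each drug beyond the
#' first given on the same day.
#'
#' @param reg A [regimen()].
#' @param pt A [patient()].
#' @param cycle_index Cycle number, starting at 1.
#' @param admin_first,admin_additional Medicare infusion fees, $ for the
#'   first hour and each additional hour.
#' @return List with `drug`, `admin` and `total` ($ per cycle).
#' @export
cycle_drug_cost <- function(reg, pt, cycle_index,
                            admin_first = 144.39, admin_additional = 31.10) {
  if (cycle_index < 1) stop("`cycle_index` must be >= 1", call. = FALSE)
  drug <- 0
  day_w <- numeric(0)
  if (cycle_index <= reg$max_cycles) {
    for (comp in reg$components) {
      if (cycle_index > comp$max_cycles) next
      drug <- drug + comp$weight * dose_mg(comp, pt) * comp$unit_price *
        comp$doses_per_cycle
      per_day <- comp$weight * comp$doses_per_cycle /
        length(comp$schedule_days)
      for (d in as.character(comp$schedule_days))
        day_w[d] <- (if (is.na(day_w[d])) 0 else day_w[d]) + per_day
    }
  }
  admin <- sum(admin_first * pmin(day_w, 1) +
                 admin_additional * pmax(day_w - 1, 0))
  list(drug = drug, admin = admin, total = drug + admin)
}

# Per-cycle cost vectors over cycles 1..K. Regimen costs are piecewise
# constant between component caps, so evaluate once per segment.
cycle_cost_vectors <- function(reg, pt, K, admin_first, admin_additional) {
  caps <- c(vapply(reg$components, `[[`, numeric(1), "max_cycles"),
            reg$max_cycles)
  brk <- sort(unique(pmin(caps[is.finite(caps)], K)))
  starts <- c(1, brk[brk < K] + 1)
  drug <- numeric(K); admin <- numeric(K)
  for (s in starts) {
    cc <- cycle_drug_cost(reg, pt, s, admin_first, admin_additional)
    seg_end <- min(c(brk[brk >= s], K))
    drug[s:seg_end] <- cc$drug
    admin[s:seg_end] <- cc$admin
  }
  list(drug = drug, admin = admin)
}

#' Build the three-state cohort trace from OS and PFS curves
#'
#' Partitioned-survival occupancy: at each cycle boundary,
#' progression-free = S_PFS(t), dead = 1 - S_OS(t), progressed =
#' S_OS(t) - S_PFS(t). Each cycle's conditional death probability (for
#' both curves) is floored at the background life-table mortality for the
#' cohort's current age, and PFS occupancy is clipped to OS occupancy if
#' fitted-curve noise makes it exceed it.
#'
#' @param os_model,pfs_model Fitted or HR-scaled survival curves.
#' @param life_table A [make_life_table()] result (or `NULL` to disable
#'   the floor).
#' @param settings A [model_settings()].
#' @return A data frame of class `cohort_trace` with columns `cycle`,
#'   `t_months`, `pfs`, `pd`, `dead`; rows at cycle boundaries 0..K.
#' @export
build_trace <- function(os_model, pfs_model, life_table, settings) {
  K <- floor(settings$horizon_years * 12 / settings$cycle_months)
  tgrid <- (0:K) * settings$cycle_months
  s_os <- surv_prob(os_model, tgrid)
  s_pfs <- surv_prob(pfs_model, tgrid)
  if (max(s_pfs - s_os) > 0.02)
    warning(sprintf("PFS curve exceeds OS curve by up to %.3f; clipping",
                    max(s_pfs - s_os)), call. = FALSE)
  build_trace_from_surv(s_os, s_pfs, tgrid, life_table, settings)
}

#' @rdname build_trace
#' @param s_os,s_pfs Survival probabilities evaluated on the cycle grid
#'   (length K + 1, starting at 1).
#' @param tgrid Cycle-boundary times in months.
#' @export
build_trace_from_surv <- function(s_os, s_pfs, tgrid, life_table, settings) {
  K <- length(tgrid) - 1
  if (K < 1) stop("horizon shorter than one cycle", call. = FALSE)
  cm <- settings$cycle_months
  q_bg <- if (is.null(life_table)) rep(0, K) else {
    age <- settings$start_age + tgrid[1:K] / 12
    qx <- approx(life_table$age, life_table$annual_death_prob,
                 xout = age, rule = 2)$y
    1 - (1 - qx)^(cm / 12)
  }
  cond_with_floor <- function(s) {
    q_mod <- ifelse(s[1:K] > 0, 1 - s[2:(K + 1)] / s[1:K], 1)
    q <- pmax(pmin(q_mod, 1), q_bg)
    cumprod(c(1, 1 - q))
  }
  os <- cond_with_floor(s_os)
  pfs <- pmin(cond_with_floor(s_pfs), os)
  structure(data.frame(cycle = 0:K, t_months = tgrid, pfs = pfs,
                       pd = os - pfs, dead = 1 - os),
            class = c("cohort_trace", "data.frame"), settings = settings)
}

# Occupancy used for accrual in each cycle: trapezoid of adjacent cycle
# boundaries under half-cycle correction, else the start-of-cycle value.
accrual_weights <- function(x, settings, scheme = NULL) {
  K <- length(x) - 1
  if (is.null(scheme))
    scheme <- if (settings$half_cycle) "half_cycle" else "start"
  switch(scheme,
         half_cycle = (x[1:K] + x[2:(K + 1)]) / 2,
         start = x[1:K],
         end = x[2:(K + 1)])
}

# Expected fraction of the cohort on a duration-capped second-line drug at
# each cycle boundary: entrants to PD per cycle, carried forward at most
# `cap` cycles, decayed by the overall-survival ratio; never exceeding PD
# occupancy.
capped_pd_occupancy <- function(trace, cap) {
  K <- nrow(trace) - 1
  os <- trace$pfs + trace$pd
  e <- pmax(0, trace$pfs[1:K] - trace$pfs[2:(K + 1)])
  out <- numeric(K + 1)
  for (k in seq_len(K)) {
    j <- seq(max(1, k - cap + 1), k)
    out[k + 1] <- sum(e[j] * os[k + 1] / pmax(os[j], 1e-12))
  }
  pmin(out, trace$pd)
}

#' Accrue discounted costs, life-years and QALYs for one arm
#'
#' First-line drug and administration costs are weighted by
#' progression-free occupancy while on treatment; an optional maintenance
#' rule pays a fraction of progression-free occupants after first-line
#' chemotherapy ends; progressed occupancy accrues second-line drug cost
#' (with an optional per-patient cycle cap) and per-cycle best supportive
#' care; adverse-event costs and QALY decrements are applied once at
#' cycle 1 as incidence-weighted sums; utilities weight life-years into
#' QALYs; everything is discounted at the annual rate on the cycle grid.
#'
#' @param trace A [build_trace()] result.
#' @param arm An arm specification: list with `first_line` ([regimen()]),
#'   `second_line` ([regimen()]), optional `maintenance` (list with
#'   `regimen`, `fraction`, `after_cycle`), `utilities` (named vector
#'   `pfs`, `pd`), `ae` (data frame with `incidence`, `cost`,
#'   `disutility`), `bsc_per_cycle`, optional `admin_first`,
#'   `admin_additional`.
#' @param pt A [patient()].
#' @param scheme Accrual scheme override (`"half_cycle"`, `"start"`,
#'   `"end"`); default follows the settings.
#' @param detail Also return `per_cycle`, a data frame of discounted
#'   accruals by cycle (occupancy-weighted cost by category, LY, QALY)?
#' @return List with `ly`, `qaly`, `cost` and a named `breakdown` of cost
#'   categories (all discounted); with `detail = TRUE` also `per_cycle`.
#' @export
accrue_arm <- function(trace, arm, pt, scheme = NULL, detail = FALSE) {
  settings <- attr(trace, "settings")
  if (is.null(arm$second_line))
    stop("missing second-line regimen for arm", call. = FALSE)
  K <- nrow(trace) - 1
  cm <- settings$cycle_months
  af <- if (!is.null(arm$admin_first)) arm$admin_first else 144.39
  aa <- if (!is.null(arm$admin_additional)) arm$admin_additional else 31.10

  w_pfs <- accrual_weights(trace$pfs, settings, scheme)
  w_pd <- accrual_weights(trace$pd, settings, scheme)
  w_os <- w_pfs + w_pd
  t_acc <- accrual_weights(trace$t_months, settings, scheme)
  disc <- (1 + settings$discount_annual)^(-t_acc / 12)
  dt_years <- cm / 12

  ly <- sum(w_os * dt_years * disc)
  u <- arm$utilities
  ae_qaly <- if (is.null(arm$ae)) 0 else sum(arm$ae$incidence * arm$ae$disutility)
  ae_cost <- if (is.null(arm$ae)) 0 else sum(arm$ae$incidence * arm$ae$cost)
  qaly <- sum((w_pfs * u[["pfs"]] + w_pd * u[["pd"]]) * dt_years * disc) -
    ae_qaly

  fl <- cycle_cost_vectors(arm$first_line, pt, K, af, aa)
  cost_first <- sum(w_pfs * (fl$drug + fl$admin) * disc)

  cost_maint <- 0
  if (!is.null(arm$maintenance)) {
    m <- arm$maintenance
    mc <- cycle_drug_cost(m$regimen, pt, 1, af, aa)
    on_maint <- as.numeric(seq_len(K) > m$after_cycle)
    cost_maint <- sum(m$fraction * w_pfs * on_maint * mc$total * disc)
  }

  sl_cost <- cycle_drug_cost(arm$second_line, pt, 1, af, aa)
  sl_cap <- arm$second_line$max_cycles
  w_sl <- if (is.finite(sl_cap)) {
    accrual_weights(capped_pd_occupancy(trace, sl_cap), settings, scheme)
  } else w_pd
  cost_second <- sum(w_sl * sl_cost$total * disc)

  bsc <- if (is.null(arm$bsc_per_cycle)) 0 else arm$bsc_per_cycle
  cost_bsc <- sum(w_pd * bsc * disc)

  breakdown <- c(first_line = cost_first, maintenance = cost_maint,
                 second_line = cost_second, bsc = cost_bsc, ae = ae_cost)
  out <- list(ly = ly, qaly = qaly, cost = sum(breakdown),
              breakdown = breakdown)
  if (detail) {
    mcyc <- if (!is.null(arm$maintenance))
      arm$maintenance$fraction * w_pfs *
        (seq_len(K) > arm$maintenance$after_cycle) *
        cycle_drug_cost(arm$maintenance$regimen, pt, 1, af, aa)$total * disc
    else 0
    ae_cyc <- c(ae_cost, rep(0, K - 1))
    out$per_cycle <- data.frame(
      cycle = seq_len(K),
      t_months = trace$t_months[-1],
      pfs = trace$pfs[-1], pd = trace$pd[-1], dead = trace$dead[-1],
      disc_cost_first_line = w_pfs * (fl$drug + fl$admin) * disc,
      disc_cost_maintenance = mcyc,
      disc_cost_second_line = w_sl * sl_cost$total * disc,
      disc_cost_bsc = w_pd * bsc * disc,
      disc_cost_ae = ae_cyc,
      disc_ly = w_os * dt_years * disc,
      disc_qaly = (w_pfs * u[["pfs"]] + w_pd * u[["pd"]]) * dt_years *
        disc - c(ae_qaly, rep(0, K - 1)))
  }
  out
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' @param a Accrual result ([accrue_arm()]) of the intervention arm.
#' @param b Accrual result of the comparator arm.
#' @param labels Character vector of the two arm names.
#' @return An object of class `cea_result`: per-arm LY/QALY/cost,
#'   increments, `icer_per_qaly`, `icer_per_ly`, and a `status` of
#'   `"ok"`, `"dominated"` (less effect, more cost) or `"dominant"`.
#'   ICERs are `NA` when the QALY increment is zero or negative.
#' @export
icer <- function(a, b, labels = c("ev_pemb", "chemo")) {
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  d_ly <- a$ly - b$ly
  status <- if (d_qaly <= 0 && d_cost >= 0) "dominated"
            else if (d_qaly >= 0 && d_cost <= 0) "dominant"
            else "ok"
  structure(list(
    arms = data.frame(arm = labels,
                      ly = c(a$ly, b$ly), qaly = c(a$qaly, b$qaly),
                      cost = c(a$cost, b$cost)),
    breakdown = rbind(a$breakdown, b$breakdown),
    d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
    icer_per_qaly = if (d_qaly > 0) d_cost / d_qaly else NA_real_,
    icer_per_ly = if (d_ly > 0) d_cost / d_ly else NA_real_,
    status = status),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  print(render_base_table(x))
  invisible(x)
}
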