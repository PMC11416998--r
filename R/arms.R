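#' Treatment-arm specifications from a parameter list
#'
#' Encodes the trial's treatment rules. Combination arm: pembrolizumab
#' 200 mg flat on day 1 for at most 35 cycles plus enfortumab vedotin
#' 1.25 mg/kg on days 1 and 8 with no cap, followed after progression by
#' platinum-based chemotherapy. Chemotherapy arm: gemcitabine
#' 1000 mg/m^2 on days 1 and 8 plus cisplatin 70 mg/m^2 or carboplatin
#' AUC 4.5 (Calvert) on day 1 (a 50/50 cohort split), for at most 6
#' cycles; afterwards 30.2% of progression-free patients receive
#' avelumab maintenance (800 mg every 2 weeks, i.e. 1.5 doses per 3-week
#' cycle); after progression, pembrolizumab for at most 35 cycles. Both
#' arms accrue best supportive care while progressed, and one-time
#' adverse-event costs and disutilities.
#'
#' @param pars Named list of parameter values (see
#'   [default_parameters()]); typically [param_baselines()] or a PSA
#'   draw.
#' @param chemo_max_cycles First-line chemotherapy cap (cycles).
#' @param maintenance_fraction Fraction of the chemotherapy arm's
#'   progression-free occupants on avelumab maintenance.
#' @return Named list with elements `ev_pemb` and `chemo`, each an arm
#'   specification consumed by [accrue_arm()].
#' @export
build_arm_specs <- function(pars, chemo_max_cycles = 6,
                            maintenance_fraction = 0.302) {
  chemo_reg <- function(max_cycles) regimen(list(
    drug_component("gemcitabine", "mg_per_m2", 1000, c(1, 8),
                   pars$price_gemcitabine),
    drug_component("cisplatin", "mg_per_m2", 70, 1,
                   pars$price_cisplatin, weight = 0.5),
    drug_component("carboplatin", "auc_calvert", 4.5, 1,
                   pars$price_carboplatin, weight = 0.5)),
    max_cycles = max_cycles)

  ev_first <- regimen(list(
    drug_component("pembrolizumab", "flat_mg", 200, 1,
                   pars$price_pembrolizumab, max_cycles = 35),
    drug_component("enfortumab_vedotin", "mg_per_kg", 1.25, c(1, 8),
                   pars$price_ev)))

  pembro_2l <- regimen(list(
    drug_component("pembrolizumab", "flat_mg", 200, 1,
                   pars$price_pembrolizumab)),
    max_cycles = 35)

  avelumab <- regimen(list(
    drug_component("avelumab", "flat_mg", 800, c(1, 11),
                   pars$price_avelumab, doses_per_cycle = 1.5)))

  u_ev <- c(pfs = if (!is.null(pars$u_pfs_ev)) pars$u_pfs_ev else pars$u_pfs,
            pd = pars$u_pd)
  u_ch <- c(pfs = if (!is.null(pars$u_pfs_chemo)) pars$u_pfs_chemo
                  else pars$u_pfs,
            pd = pars$u_pd)

  ae_ev <- data.frame(
    name = c("neutropenia", "maculopapular_rash", "hyperglycemia"),
    incidence = c(pars$inc_ev_neutropenia, pars$inc_ev_rash,
                  pars$inc_ev_hyperglycemia),
    cost = c(pars$cost_neutropenia, pars$cost_rash,
             pars$cost_hyperglycemia),
    disutility = c(pars$disut_neutropenia, pars$disut_rash,
                   pars$disut_hyperglycemia))
  ae_ch <- data.frame(
    name = c("anemia", "neutropenia", "thrombocytopenia",
             "decreased_neutrophil_count"),
    incidence = c(pars$inc_chemo_anemia, pars$inc_chemo_neutropenia,
                  pars$inc_chemo_thrombocytopenia,
                  pars$inc_chemo_neutrophil_count),
    cost = c(pars$cost_anemia, pars$cost_neutropenia,
             pars$cost_thrombocytopenia, pars$cost_neutrophil_count),
    disutility = c(pars$disut_anemia, pars$disut_neutropenia,
                   pars$disut_thrombocytopenia,
                   pars$disut_neutrophil_count))

  common <- list(admin_first = pars$admin_first_hour,
                 admin_additional = pars$admin_additional_hour,
                 bsc_per_cycle = pars$bsc_per_cycle)
  list(
    ev_pemb = c(list(first_line = ev_first, second_line = chemo_reg(Inf),
                     maintenance = NULL, utilities = u_ev, ae = ae_ev),
                common),
    chemo = c(list(first_line = chemo_reg(chemo_max_cycles),
                   second_line = pembro_2l,
                   maintenance = list(regimen = avelumab,
                                      fraction = maintenance_fraction,
                                      after_cycle = chemo_max_cycles),
                   utilities = u_ch, ae = ae_ch),
              common))
}

#' Build a deterministic model function over the parameter space
#'
#' Returns a closure mapping a named parameter list to a [icer()] result:
#' the chemotherapy-arm survival curves stay fixed at their fitted
#' shapes, the combination arm is derived by hazard-ratio scaling
#' (`hr_os`, `hr_pfs` from the parameters), and all cost/utility
#' parameters are rebuilt per call. This is the single evaluation path
#' shared by the base case, one-way/two-way sensitivity analysis and PSA.
#'
#' @param os_model,pfs_model Fitted chemotherapy-arm survival models.
#' @param life_table Background life table (or `NULL`).
#' @param settings A [model_settings()].
#' @return `function(pars) -> cea_result`.
#' @export
make_model_fn <- function(os_model, pfs_model, life_table,
                          settings = model_settings()) {
  K <- floor(settings$horizon_years * 12 / settings$cycle_months)
  tgrid <- (0:K) * settings$cycle_months
  # chemo-arm curves are fixed across parameter draws: precompute log S
  log_s_os <- log(pmax(surv_prob(os_model, tgrid), 1e-300))
  log_s_pfs <- log(pmax(surv_prob(pfs_model, tgrid), 1e-300))

  function(pars) {
    st <- settings
    if (!is.null(pars$discount_annual))
      st$discount_annual <- pars$discount_annual
    pt <- patient(weight = pars$weight_kg, bsa = pars$bsa, crcl = pars$crcl)
    tr_ch <- build_trace_from_surv(exp(log_s_os), exp(log_s_pfs), tgrid,
                                   life_table, st)
    tr_ev <- build_trace_from_surv(exp(pars$hr_os * log_s_os),
                                   exp(pars$hr_pfs * log_s_pfs), tgrid,
                                   life_table, st)
    arms <- build_arm_specs(pars)
    icer(accrue_arm(tr_ev, arms$ev_pemb, pt),
         accrue_arm(tr_ch, arms$chemo, pt))
  }
}
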