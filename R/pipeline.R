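#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates the stages end to end: synthetic trial generation, KM
#' curves with risk tables per endpoint, pseudo-IPD reconstruction,
#' candidate-family fitting with AIC selection for the chemotherapy arm,
#' hazard-ratio scaling of the combination arm, the lifetime cohort
#' model, and the requested sensitivity analyses. All randomness fans
#' out from the single `seed`. When `outdir` is given, every artifact
#' is written as CSV/JSON together with a run manifest (MD5 of the
#' configuration, seed, package version, AIC rankings and the defaults
#' in effect).
#'
#' @param config List of options; unset entries take defaults:
#'   `trial` (arguments to [trial_config()]), `risk_grid`,
#'   `families`, `settings` (arguments to [model_settings()]),
#'   `params` (a `param_table`), `life_table`, `analyses` (character
#'   subset of `"owsa"`, `"twsa"`, `"psa"`), `n_psa`, `wtp_grid`,
#'   `total_events_adjust`, `subgroups`.
#' @param seed Integer master seed.
#' @param outdir Optional output directory.
#' @return List with the stage outputs: `sim`, `km`, `ipd`, `fits`,
#'   `os_model`, `pfs_model`, `base` (a `cea_result`), and any of
#'   `owsa`, `twsa`, `psa`, `ceac`, `subgroups` requested.
#' @export
run_pipeline <- function(config = list(), seed = 1L, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (check the stage's %s)",
                   name, conditionMessage(e), "inputs and configuration"),
           call. = FALSE)
    })
  }
  trial_args <- config$trial %||% list()
  trial_args$seed <- trial_args$seed %||% seed
  cfg <- stage("simulate", do.call(trial_config, trial_args))
  sim <- stage("simulate", simulate_trial(cfg))
  grid <- config$risk_grid %||% seq(0, cfg$followup_months, by = 3)
  families <- config$families %||% surv_families
  params <- config$params %||% default_parameters()
  lt <- config$life_table %||% default_life_table()
  settings <- stage("settings",
                    do.call(model_settings, config$settings %||% list()))
  analyses <- config$analyses %||% character(0)

  km <- stage("km", {
    one <- function(ep) {
      r <- sim[sim$arm == "chemo" & sim$endpoint == ep, ]
      km_with_risk_table(r, grid)
    }
    list(OS = one("OS"), PFS = one("PFS"))
  })

  tot_ev <- NULL
  ipd <- stage("reconstruct", lapply(km, function(k)
    reconstruct(k$curve, k$risk,
                total_events = if (isTRUE(config$total_events_adjust))
                  tot_ev else NULL)))

  fits <- stage("fit", suppressWarnings(
    lapply(ipd, fit_candidates, families = families)))
  os_model <- stage("select", select_by_aic(fits$OS))
  pfs_model <- stage("select", select_by_aic(fits$PFS))

  model_fn <- make_model_fn(os_model, pfs_model, lt, settings)
  baselines <- param_baselines(params)
  base <- stage("cohort", model_fn(baselines))

  traces <- stage("cohort", list(
    ev_pemb = build_trace(apply_hr(os_model, baselines$hr_os),
                          apply_hr(pfs_model, baselines$hr_pfs),
                          lt, settings),
    chemo = build_trace(os_model, pfs_model, lt, settings)))

  out <- list(config = config, seed = seed, trial_config = cfg, sim = sim,
              km = km, ipd = ipd, fits = fits, os_model = os_model,
              pfs_model = pfs_model, settings = settings,
              model_fn = model_fn, base = base, traces = traces,
              baselines = baselines)

  if ("owsa" %in% analyses)
    out$owsa <- stage("owsa", one_way(model_fn, params))
  if ("twsa" %in% analyses)
    out$twsa <- stage("twsa", two_way_utilities(model_fn, params))
  if ("psa" %in% analyses) {
    n_psa <- config$n_psa %||% 1000
    out$psa <- stage("psa", psa(model_fn, params, n = n_psa,
                                seed = seed + 1000L))
    out$ceac <- stage("psa", ceac(out$psa,
                                  config$wtp_grid %||% seq(0, 1e6, 1e4)))
  }
  if (!is.null(config$subgroups))
    out$subgroups <- stage("subgroups",
                           subgroup_run(config$subgroups, params, lt,
                                        settings, families))

  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write.csv(out$sim, p("survival_records.csv"), row.names = FALSE)
  for (ep in names(out$km)) {
    write_curve_csv(out$km[[ep]]$curve, p(sprintf("km_%s.csv", ep)))
    write_risk_csv(out$km[[ep]]$risk, p(sprintf("risk_%s.csv", ep)))
    write_ipd_csv(out$ipd[[ep]], p(sprintf("ipd_%s.csv", ep)))
  }
  write_model_json(out$os_model, p("os_model.json"))
  write_model_json(out$pfs_model, p("pfs_model.json"))
  write_fitted_curve_csv(out$os_model, p("fitted_os.csv"))
  write_fitted_curve_csv(out$pfs_model, p("fitted_pfs.csv"))
  pt <- patient(weight = out$baselines$weight_kg, bsa = out$baselines$bsa,
                crcl = out$baselines$crcl)
  arms <- build_arm_specs(out$baselines)
  for (arm in names(out$traces)) {
    acc <- accrue_arm(out$traces[[arm]], arms[[arm]], pt, detail = TRUE)
    write.csv(acc$per_cycle, p(sprintf("trace_%s.csv", arm)),
              row.names = FALSE)
  }
  writeLines(render_base_table(out$base), p("base_case.txt"))
  jsonlite::write_json(
    list(arms = out$base$arms, d_cost = out$base$d_cost,
         d_qaly = out$base$d_qaly, d_ly = out$base$d_ly,
         icer_per_qaly = out$base$icer_per_qaly,
         icer_per_ly = out$base$icer_per_ly, status = out$base$status),
    p("base_case.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(out$owsa))
    write.csv(out$owsa, p("tornado.csv"), row.names = FALSE)
  if (!is.null(out$psa))
    write.csv(out$psa$draws, p("psa_draws.csv"), row.names = FALSE)
  if (!is.null(out$ceac))
    write.csv(out$ceac, p("ceac.csv"), row.names = FALSE)
  manifest <- list(
    seed = out$seed,
    package_version = as.character(utils::packageVersion("evpcea")),
    settings = unclass(out$settings),
    trial_config = unclass(out$trial_config),
    aic_ranking_os = attr(out$os_model, "aic_ranking"),
    aic_ranking_pfs = attr(out$pfs_model, "aic_ranking"),
    defaults = list(chemo_max_cycles = 6, maintenance_fraction = 0.302,
                    second_line_pembro_cap = 35,
                    bsc_state = "progressed_disease",
                    cis_carbo_split = 0.5,
                    risk_grid_months = 3))
  mf <- p("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  man <- jsonlite::read_json(mf)
  man$config_hash <- unname(tools::md5sum(mf))
  jsonlite::write_json(man, mf, auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Render the base-case results table
#'
#' Formats a [icer()] result the way base-case tables are published:
#' rows for LYs, QALYs, cost and the two ICERs; arms as columns with the
#' increments last; three decimals for LYs/QALYs, whole dollars with
#' thousands separators for costs.
#'
#' @param cea A `cea_result`.
#' @return Character matrix (one row per outcome) with a printed ICER of
#'   `"dominated"`/`"dominant"` instead of a number when the QALY
#'   increment is not positive.
#' @export
render_base_table <- function(cea) {
  dollars <- function(x) formatC(x, format = "f", digits = 0,
                                 big.mark = ",")
  num3 <- function(x) formatC(x, format = "f", digits = 3)
  a <- cea$arms
  icer_q <- if (is.na(cea$icer_per_qaly)) cea$status
            else dollars(cea$icer_per_qaly)
  icer_l <- if (is.na(cea$icer_per_ly)) cea$status
            else dollars(cea$icer_per_ly)
  m <- rbind(
    LYs = c(num3(a$ly[1]), num3(a$ly[2]), num3(cea$d_ly)),
    QALYs = c(num3(a$qaly[1]), num3(a$qaly[2]), num3(cea$d_qaly)),
    `Cost, US $` = c(dollars(a$cost[1]), dollars(a$cost[2]),
                     dollars(cea$d_cost)),
    `ICER, US $/LY` = c("", "", icer_l),
    `ICER, US $/QALY` = c("", "", icer_q))
  colnames(m) <- c(a$arm[1], a$arm[2], "Incremental")
  m
}
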