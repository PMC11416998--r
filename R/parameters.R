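#' Model parameters: baselines, ranges and sampling distributions
#'
#' The full parameter set of the cost-effectiveness model from the US
#' payer perspective (2023 USD): grade >= 3 adverse-event incidences per
#' arm, health-state utilities, adverse-event disutilities and management
#' costs, patient characteristics, per-milligram drug prices, Medicare
#' infusion fees, best-supportive-care cost per 3-week cycle, and the
#' EV-302 hazard ratios (OS 0.47, 95% CI 0.38-0.58; PFS 0.45, 0.38-0.54).
#' Ranges are +/-20% of baseline or the 95% CI; `distribution` names the
#' sampling family used in probabilistic sensitivity analysis. The
#' discount rate is included for one-way sensitivity analysis but held
#' fixed in PSA.
#'
#' @return A data frame of class `param_table` with columns `name`,
#'   `baseline`, `low`, `high`, `distribution`.
#' @export
default_parameters <- function() {
  tab <- read.csv(text = '
name,baseline,low,high,distribution
inc_chemo_anemia,0.314,0.251,0.377,beta
inc_chemo_neutropenia,0.300,0.240,0.360,beta
inc_chemo_thrombocytopenia,0.194,0.156,0.233,beta
inc_chemo_neutrophil_count,0.090,0.072,0.108,beta
inc_ev_neutropenia,0.048,0.038,0.058,beta
inc_ev_rash,0.077,0.062,0.092,beta
inc_ev_hyperglycemia,0.050,0.040,0.060,beta
u_pfs,0.800,0.770,0.820,beta
u_pd,0.750,0.700,0.790,beta
disut_anemia,0.120,0.096,0.144,beta
disut_neutrophil_count,0.090,0.072,0.108,beta
disut_hyperglycemia,0.140,0.112,0.168,beta
disut_neutropenia,0.150,0.120,0.180,beta
disut_rash,0.032,0.026,0.039,beta
disut_thrombocytopenia,0.110,0.088,0.132,beta
cost_anemia,4638,3710.4,5565.6,gamma
cost_neutrophil_count,36106,28884.8,43327.2,gamma
cost_hyperglycemia,255.506,204.405,306.607,gamma
cost_neutropenia,17181,13744.8,20617.2,gamma
cost_rash,15709,12567.2,18850.8,gamma
cost_thrombocytopenia,45332,36265.6,54398.4,gamma
weight_kg,70,60,140,gamma
price_ev,131.52,116.36,174.54,gamma
price_pembrolizumab,55.73,46.893,70.339,gamma
price_carboplatin,0.072,0.058,0.086,gamma
price_cisplatin,0.404,0.323,0.485,gamma
price_gemcitabine,0.044,0.035,0.053,gamma
price_avelumab,9.236,7.389,11.083,gamma
admin_first_hour,144.39,115.512,173.268,gamma
admin_additional_hour,31.10,24.880,37.320,gamma
bsc_per_cycle,1213,970.4,1455.6,gamma
crcl,70,70,70,fixed
bsa,1.86,1.456,2.184,normal
hr_os,0.47,0.38,0.58,log_normal
hr_pfs,0.45,0.38,0.54,log_normal
discount_annual,0.03,0.024,0.036,fixed
', stringsAsFactors = FALSE, strip.white = TRUE)
  structure(tab, class = c("param_table", "data.frame"))
}

#' Read a parameter table from CSV
#'
#' @param path CSV with columns `name`, `baseline`, `low`, `high`,
#'   `distribution` (see `inst/extdata/model_parameters.csv` for the
#'   default set).
#' @return A `param_table`.
#' @export
read_parameters <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("name", "baseline", "low", "high", "distribution")
  if (!all(need %in% names(tab)))
    stop("parameter file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- tab$low > tab$baseline | tab$baseline > tab$high
  if (any(bad))
    stop("low <= baseline <= high violated for: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  structure(tab[need], class = c("param_table", "data.frame"))
}

#' Baseline values of a parameter table as a named list
#' @param params A `param_table`.
#' @return Named list of baseline values.
#' @export
param_baselines <- function(params) {
  as.list(setNames(params$baseline, params$name))
}
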