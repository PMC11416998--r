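#' One-way (tornado) sensitivity analysis
#'
#' Each parameter is set to its low and high value in turn with all
#' others at baseline, and the ICER per QALY is recorded; entries are
#' sorted by descending spread.
#'
#' @param model_fn Deterministic model function (see [make_model_fn()]).
#' @param specs A `param_table` ([default_parameters()]).
#' @return Data frame of class `tornado` with columns `name`,
#'   `icer_at_low`, `icer_at_high`, `spread`, sorted by descending
#'   spread.
#' @export
one_way <- function(model_fn, specs) {
  base <- param_baselines(specs)
  eval_at <- function(name, value) {
    p <- base; p[[name]] <- value
    model_fn(p)$icer_per_qaly
  }
  lo <- mapply(eval_at, specs$name, specs$low)
  hi <- mapply(eval_at, specs$name, specs$high)
  out <- data.frame(name = specs$name, icer_at_low = lo, icer_at_high = hi,
                    spread = abs(hi - lo), row.names = NULL)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"))
}

#' Two-way sensitivity analysis of the arms' progression-free utilities
#'
#' The progression-free utility of each arm is varied on a Cartesian
#' grid from 50% of baseline up to 1 and the ICER per QALY is evaluated
#' at every combination.
#'
#' @param model_fn Model function accepting `u_pfs_ev` / `u_pfs_chemo`
#'   overrides (as produced by [make_model_fn()]).
#' @param specs A `param_table` (supplies the remaining baselines).
#' @param n_grid Grid points per axis (>= 2).
#' @param grid_lo,grid_hi Utility range; defaults: half the baseline
#'   progression-free utility up to 1.
#' @return Matrix of ICERs with EV-arm utility on rows and
#'   chemotherapy-arm utility on columns (dimnames give the utilities).
#' @export
two_way_utilities <- function(model_fn, specs, n_grid = 11,
                              grid_lo = NULL, grid_hi = 1) {
  if (n_grid < 2) stop("`n_grid` must be >= 2", call. = FALSE)
  base <- param_baselines(specs)
  if (is.null(grid_lo)) grid_lo <- 0.5 * base$u_pfs
  u <- seq(grid_lo, grid_hi, length.out = n_grid)
  out <- matrix(NA_real_, n_grid, n_grid,
                dimnames = list(ev = sprintf("%.3f", u),
                                chemo = sprintf("%.3f", u)))
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    p <- base
    p$u_pfs_ev <- u[i]
    p$u_pfs_chemo <- u[j]
    out[i, j] <- model_fn(p)$icer_per_qaly
  }
  out
}

# Distribution parameters implied by (baseline, low, high) under the
# moment rule sd = (high - low) / 3.92 (range read as a 95% interval).
spec_distribution <- function(name, baseline, low, high, distribution) {
  sd <- (high - low) / 3.92
  switch(distribution,
    fixed = list(r = function(n) rep(baseline, n)),
    normal = list(r = function(n) rnorm(n, baseline, sd)),
    beta = {
      m <- baseline; v <- sd^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m))
        stop(sprintf("beta moment matching infeasible for '%s'", name),
             call. = FALSE)
      nu <- m * (1 - m) / v - 1
      list(r = function(n) rbeta(n, m * nu, (1 - m) * nu))
    },
    gamma = {
      if (baseline <= 0)
        stop(sprintf("gamma moment matching infeasible for '%s'", name),
             call. = FALSE)
      if (sd == 0) list(r = function(n) rep(baseline, n))
      else list(r = function(n) rgamma(n, shape = (baseline / sd)^2,
                                       rate = baseline / sd^2))
    },
    log_normal = {
      sdlog <- (log(high) - log(low)) / 3.92
      list(r = function(n) rlnorm(n, log(baseline), sdlog))
    },
    stop(sprintf("unknown distribution '%s' for '%s'", distribution, name),
         call. = FALSE))
}

#' Draw parameter sets from their sensitivity distributions
#'
#' Beta and gamma parameters are moment-matched to the baseline mean and
#' sd = (high - low)/3.92; normal parameters use that sd directly;
#' hazard ratios are log-normal with log-mean `log(baseline)` and log-sd
#' `(log(high) - log(low))/3.92`; `fixed` parameters stay at baseline.
#'
#' @param specs A `param_table`.
#' @param n Number of draws.
#' @param seed Optional seed for reproducibility.
#' @return Data frame with `n` rows, one column per parameter.
#' @export
draw_params <- function(specs, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    d <- spec_distribution(specs$name[i], specs$baseline[i], specs$low[i],
                           specs$high[i], specs$distribution[i])
    d$r(n)
  })
  setNames(as.data.frame(cols), specs$name)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets with all distributions varied simultaneously
#' and evaluates the model per draw, recording incremental cost and
#' incremental QALYs.
#'
#' @param model_fn Model function (see [make_model_fn()]).
#' @param specs A `param_table`.
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Seed; the same seed reproduces the PSA exactly.
#' @return An object of class `psa_result`: `draws` (data frame with
#'   `d_cost`, `d_qaly`, `icer`), `n_draws`, `seed`.
#' @export
psa <- function(model_fn, specs, n = 1000, seed = 1L) {
  pars <- draw_params(specs, n, seed = seed)
  d_cost <- numeric(n); d_qaly <- numeric(n)
  for (i in seq_len(n)) {
    res <- model_fn(as.list(pars[i, , drop = FALSE]))
    d_cost[i] <- res$d_cost
    d_qaly[i] <- res$d_qaly
  }
  structure(list(draws = data.frame(d_cost = d_cost, d_qaly = d_qaly,
                                    icer = ifelse(d_qaly > 0,
                                                  d_cost / d_qaly, NA)),
                 n_draws = n, seed = seed, params = pars),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of
#' cost-effectiveness is the fraction of PSA draws with positive
#' incremental net monetary benefit, `wtp * d_qaly - d_cost > 0`.
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid Willingness-to-pay grid, $/QALY (default $0 to $1M in
#'   $10k steps).
#' @return Data frame of class `ceac` with columns `wtp`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 1e6, by = 1e4)) {
  if (psa_result$n_draws == 0) stop("empty PSA", call. = FALSE)
  d <- psa_result$draws
  p <- vapply(wtp_grid,
              function(l) mean(l * d$d_qaly - d$d_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = p),
            class = c("ceac", "data.frame"))
}

#' Price threshold for a target probability of cost-effectiveness
#'
#' Bisects the unit price of a drug until the probability of
#' cost-effectiveness at the given willingness-to-pay (the CEAC value
#' under the PSA distributions, common random numbers across candidate
#' prices) crosses the target. With all distributions `fixed` this
#' reduces to the price at which the deterministic ICER equals the
#' threshold.
#'
#' @param model_fn Model function.
#' @param specs A `param_table`.
#' @param drug Parameter name of the unit price to vary (e.g.
#'   `"price_ev"`).
#' @param target_prob Target probability of cost-effectiveness.
#' @param wtp Willingness-to-pay, $/QALY.
#' @param n_draws PSA draws per candidate price.
#' @param seed Seed (shared across candidate prices).
#' @param lower Lower price bracket, $/mg.
#' @param tol Price tolerance, $/mg.
#' @return Threshold unit price, $/mg (the baseline price if the target
#'   is already met there).
#' @export
price_threshold <- function(model_fn, specs, drug = "price_ev",
                            target_prob = 0.5, wtp = 150000,
                            n_draws = 1000, seed = 1L, lower = 0,
                            tol = 0.5) {
  i <- match(drug, specs$name)
  if (is.na(i)) stop("unknown drug parameter: ", drug, call. = FALSE)
  prob_at <- function(price) {
    sp <- specs
    # scale the price distribution (baseline and range) to the candidate
    f <- price / specs$baseline[i]
    sp$baseline[i] <- price
    sp$low[i] <- specs$low[i] * f
    sp$high[i] <- specs$high[i] * f
    res <- psa(model_fn, sp, n = n_draws, seed = seed)
    mean(wtp * res$draws$d_qaly - res$draws$d_cost > 0)
  }
  upper <- specs$baseline[i]
  p_hi <- prob_at(upper)
  if (p_hi >= target_prob) return(upper)
  p_lo <- prob_at(max(lower, tol / 2))
  if (p_lo < target_prob)
    stop("target probability not reachable within the price bracket",
         call. = FALSE)
  lo <- max(lower, tol / 2); hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (prob_at(mid) >= target_prob) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Re-run the cost-effectiveness pipeline for patient subgroups
#'
#' Each subgroup supplies its own chemotherapy-arm OS and PFS curves
#' (digitized coordinates plus risk tables) and hazard ratios; the same
#' reconstruction / fitting / cohort pipeline is applied per subgroup.
#'
#' @param subgroups Named list; each element a list with `os_curve`,
#'   `os_risk`, `pfs_curve`, `pfs_risk`, `hr_os`, `hr_pfs`.
#' @param specs A `param_table` for the remaining baselines.
#' @param life_table,settings As in [make_model_fn()].
#' @param families Candidate families for fitting.
#' @return Named list of `cea_result`s.
#' @export
subgroup_run <- function(subgroups, specs, life_table = default_life_table(),
                         settings = model_settings(),
                         families = surv_families) {
  lapply(subgroups, function(sg) {
    need <- c("os_curve", "os_risk", "pfs_curve", "pfs_risk")
    miss <- need[!need %in% names(sg)]
    if (length(miss) > 0)
      stop("missing subgroup curves: ", paste(miss, collapse = ", "),
           call. = FALSE)
    os <- select_by_aic(fit_candidates(
      reconstruct(sg$os_curve, sg$os_risk), families))
    pfs <- select_by_aic(fit_candidates(
      reconstruct(sg$pfs_curve, sg$pfs_risk), families))
    fn <- make_model_fn(os, pfs, life_table, settings)
    pars <- param_baselines(specs)
    if (!is.null(sg$hr_os)) pars$hr_os <- sg$hr_os
    if (!is.null(sg$hr_pfs)) pars$hr_pfs <- sg$hr_pfs
    fn(pars)
  })
}
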