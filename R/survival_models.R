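#' @rdname fit_survival
#' @format NULL
#' @export
surv_families <- c("exponential", "weibull", "log_logistic", "log_normal",
                   "gompertz", "gen_gamma", "spline", "mixture_cure")

flexsurv_dist <- c(exponential = "exp", weibull = "weibull",
                   log_logistic = "llogis", log_normal = "lnorm",
                   gompertz = "gompertz", gen_gamma = "gengamma")

new_surv_model <- function(family, params, loglik, n_params, knots = NULL) {
  structure(list(family = family, params = params, loglik = loglik,
                 n_params = n_params, aic = -2 * loglik + 2 * n_params,
                 knots = knots),
            class = "surv_model")
}

#' Fit a parametric survival model to (pseudo) individual patient data
#'
#' Maximum-likelihood fit with right censoring for one of eight candidate
#' families: exponential, Weibull, log-logistic, log-normal, Gompertz,
#' generalized gamma, a Royston-Parmar spline on the log cumulative
#' hazard, and a mixture-cure model (cure fraction plus Weibull latency).
#' Standard families and the spline are fitted with \pkg{flexsurv}; the
#' mixture-cure likelihood is maximized directly with multiple restarts.
#'
#' @param ipd Data frame with columns `time` (> 0) and `event` (0/1),
#'   e.g. a [reconstruct()] result.
#' @param family One of `surv_families`.
#' @param spline_knots Number of internal knots for the spline family
#'   (placed at log-time quantiles of the event times).
#' @return A `surv_model` with elements `family`, `params` (natural
#'   scale), `loglik`, `n_params` and `aic`; or `NULL` with a warning if
#'   the fit fails to converge (such models are excluded from selection).
#' @export
fit_survival <- function(ipd, family = surv_families, spline_knots = 1) {
  family <- match.arg(family)
  ipd <- as.data.frame(ipd)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  ipd <- ipd[ipd$time > 0, , drop = FALSE]
  n_ev <- sum(ipd$event)
  min_ev <- if (family == "exponential") 1 else 2
  if (n_ev < min_ev)
    stop(sprintf("family '%s' needs at least %d events", family, min_ev),
         call. = FALSE)
  if (family == "mixture_cure") return(fit_mixture_cure(ipd))

  fml <- survival::Surv(ipd$time, ipd$event) ~ 1
  fit_one <- function(inits = NULL) {
    tryCatch({
      f <- if (family == "spline") {
        flexsurv::flexsurvspline(fml, data = ipd, k = spline_knots,
                                 scale = "hazard")
      } else if (is.null(inits)) {
        flexsurv::flexsurvreg(fml, data = ipd, dist = flexsurv_dist[[family]])
      } else {
        flexsurv::flexsurvreg(fml, data = ipd, dist = flexsurv_dist[[family]],
                              inits = inits)
      }
      if (!is.finite(f$loglik)) NULL else f
    }, error = function(e) NULL, warning = function(w) NULL)
  }
  fit <- withCallingHandlers(fit_one(),
                             warning = function(w) invokeRestart("muffleWarning"))
  if (family == "gen_gamma" && !is.null(fit)) {
    # multi-modal likelihood: restart from perturbed initial values
    base <- fit$res[, "est"]
    for (f in c(0.7, 1.4)) {
      alt <- withCallingHandlers(
        fit_one(inits = base * c(1, f, 1) + c(0, 0, (f - 1))),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(alt) && alt$loglik > fit$loglik) fit <- alt
    }
  }
  if (is.null(fit)) {
    warning(sprintf("fit of family '%s' did not converge; excluded", family),
            call. = FALSE)
    return(NULL)
  }
  new_surv_model(family,
                 params = setNames(fit$res[, "est"], rownames(fit$res)),
                 loglik = fit$loglik,
                 n_params = fit$npars,
                 knots = if (family == "spline") fit$knots else NULL)
}

# Mixture-cure MLE: S(t) = pi + (1 - pi) * S_weibull(t), fitted on
# (logit pi, log shape, log scale) with three starts.
fit_mixture_cure <- function(ipd) {
  t <- ipd$time; d <- ipd$event
  nll <- function(par) {
    pi <- plogis(par[1]); sh <- exp(par[2]); sc <- exp(par[3])
    ll <- suppressWarnings(
      d * (log1p(-pi) + dweibull(t, sh, sc, log = TRUE)) +
        (1 - d) * log(pi + (1 - pi) * pweibull(t, sh, sc,
                                               lower.tail = FALSE)))
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  # anchor the latency start at a Weibull fit of the event times
  wb <- tryCatch(flexsurv::flexsurvreg(
    survival::Surv(ipd$time, ipd$event) ~ 1, data = ipd, dist = "weibull"),
    error = function(e) NULL)
  w0 <- if (is.null(wb)) c(0, log(median(t))) else log(wb$res[, "est"])
  starts <- list(c(qlogis(0.1), w0), c(qlogis(0.3), w0 + 0.3),
                 c(qlogis(0.02), w0 - 0.3))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, nll, method = "BFGS",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    warning("fit of family 'mixture_cure' did not converge; excluded",
            call. = FALSE)
    return(NULL)
  }
  par <- unname(best$par)
  params <- c(cure_prob = plogis(par[1]), shape = exp(par[2]),
              scale = exp(par[3]))
  new_surv_model("mixture_cure", params = params, loglik = -best$value,
                 n_params = 3L)
}

#' Fit all candidate families
#'
#' @param ipd As in [fit_survival()].
#' @param families Character vector of families to try.
#' @param ... Passed to [fit_survival()].
#' @return Named list of `surv_model`s (failed fits dropped).
#' @export
fit_candidates <- function(ipd, families = surv_families, ...) {
  fits <- lapply(families, function(f)
    tryCatch(fit_survival(ipd, f, ...), error = function(e) {
      warning(sprintf("family '%s': %s", f, conditionMessage(e)),
              call. = FALSE)
      NULL
    }))
  names(fits) <- families
  fits[!vapply(fits, is.null, logical(1))]
}

#' Select the best-fitting model by AIC
#'
#' Minimum-AIC selection over converged candidates; ties within 1e-9 are
#' broken in favour of fewer parameters. The full ranking is attached as
#' attribute `"aic_ranking"`.
#'
#' @param models List of `surv_model`s (`NULL` entries allowed, dropped).
#' @return The selected `surv_model`.
#' @export
select_by_aic <- function(models) {
  models <- models[!vapply(models, is.null, logical(1))]
  if (length(models) == 0) stop("no converged models to select from",
                                call. = FALSE)
  aic <- vapply(models, `[[`, numeric(1), "aic")
  np <- vapply(models, `[[`, numeric(1), "n_params")
  ord <- order(aic, np)
  rank_tab <- data.frame(
    family = vapply(models, `[[`, character(1), "family"),
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    n_params = np, aic = aic, row.names = NULL)[ord, ]
  best <- ord[1]
  for (j in ord[-1]) {
    if (abs(aic[j] - aic[best]) < 1e-9 && np[j] < np[best]) best <- j
  }
  sel <- models[[best]]
  attr(sel, "aic_ranking") <- rank_tab
  sel
}

#' Survival probability S(t) of a fitted model
#' @param model A `surv_model` or HR-scaled curve.
#' @param t Times (months), vectorized.
#' @return S(t) in \[0, 1\], with S(0) = 1.
#' @export
surv_prob <- function(model, t) UseMethod("surv_prob")

#' @export
surv_prob.surv_model <- function(model, t) {
  p <- model$params
  s <- switch(model$family,
    exponential = pexp(t, p[["rate"]], lower.tail = FALSE),
    weibull = pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    log_logistic = flexsurv::pllogis(t, p[["shape"]], p[["scale"]],
                                     lower.tail = FALSE),
    log_normal = plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]],
                                   lower.tail = FALSE),
    gen_gamma = flexsurv::pgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]],
                                    lower.tail = FALSE),
    spline = flexsurv::psurvspline(t, gamma = p, knots = model$knots,
                                   scale = "hazard", lower.tail = FALSE),
    mixture_cure = p[["cure_prob"]] + (1 - p[["cure_prob"]]) *
      pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    stop("unknown family: ", model$family))
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Hazard function h(t) of a fitted model
#' @inheritParams surv_prob
#' @return h(t) >= 0.
#' @export
hazard_fn <- function(model, t) UseMethod("hazard_fn")

#' @export
hazard_fn.surv_model <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = flexsurv::hexp(t, p[["rate"]]),
    weibull = flexsurv::hweibull(t, p[["shape"]], p[["scale"]]),
    log_logistic = flexsurv::hllogis(t, p[["shape"]], p[["scale"]]),
    log_normal = flexsurv::hlnorm(t, p[["meanlog"]], p[["sdlog"]]),
    gompertz = flexsurv::hgompertz(t, p[["shape"]], p[["rate"]]),
    gen_gamma = flexsurv::hgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]]),
    spline = flexsurv::hsurvspline(t, gamma = p, knots = model$knots,
                                   scale = "hazard"),
    mixture_cure = {
      pi <- p[["cure_prob"]]
      s <- pi + (1 - pi) * pweibull(t, p[["shape"]], p[["scale"]],
                                    lower.tail = FALSE)
      (1 - pi) * dweibull(t, p[["shape"]], p[["scale"]]) / pmax(s, 1e-300)
    },
    stop("unknown family: ", model$family))
}

#' Scale a survival curve by a hazard ratio
#'
#' Under proportional hazards, the comparator curve is obtained by
#' multiplying the baseline hazard by `hr`, equivalently raising the
#' baseline survival function to the power `hr`:
#' `S'(t) = S(t)^hr`, `h'(t) = hr * h(t)`.
#'
#' @param model A `surv_model` (or an already-scaled curve, in which case
#'   the ratios compose, so `apply_hr(apply_hr(m, h), 1/h)` is exactly
#'   `m`'s curve).
#' @param hr Hazard ratio, > 0.
#' @return An object of class `hr_surv_model` supporting [surv_prob()],
#'   [hazard_fn()] and [interval_survival()].
#' @export
apply_hr <- function(model, hr) {
  if (hr <= 0) stop("`hr` must be positive", call. = FALSE)
  if (inherits(model, "hr_surv_model")) {
    base <- model$base
    hr <- hr * model$hr
  } else base <- model
  structure(list(base = base, hr = hr,
                 family = paste0(base$family, "_hr")),
            class = c("hr_surv_model"))
}

#' @export
surv_prob.hr_surv_model <- function(model, t) {
  surv_prob(model$base, t)^model$hr
}

#' @export
hazard_fn.hr_surv_model <- function(model, t) {
  model$hr * hazard_fn(model$base, t)
}

#' Conditional survival across a cycle
#'
#' @param model A fitted or HR-scaled survival curve.
#' @param t_start,t_end Cycle boundaries in months, `0 <= t_start < t_end`;
#'   `S(t_start)` must be positive.
#' @return `S(t_end) / S(t_start)`, the probability of surviving the cycle
#'   given being alive at its start.
#' @export
interval_survival <- function(model, t_start, t_end) {
  if (any(t_start < 0) || any(t_start >= t_end))
    stop("need 0 <= t_start < t_end", call. = FALSE)
  s0 <- surv_prob(model, t_start)
  if (any(s0 <= 0)) stop("S(t_start) must be positive", call. = FALSE)
  surv_prob(model, t_end) / s0
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("<surv_model> family=%s  loglik=%.3f  k=%d  AIC=%.3f\n",
              x$family, x$loglik, x$n_params, x$aic))
  print(x$params)
  invisible(x)
}
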