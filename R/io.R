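#' Read and write pipeline CSV artifacts
#'
#' Plain-CSV interchange for the pipeline's data objects: survival
#' records (`time,event,arm,endpoint`), digitized curves
#' (`time,survival`), risk tables (`time,n_at_risk`), pseudo-IPD
#' (`time,event`) and life tables (`age,qx`).
#'
#' @param x Object to write.
#' @param path File path.
#' @return `read_*` return the corresponding package object; `write_*`
#'   return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_curve_csv <- function(x, path) {
  write.csv(data.frame(time = x$times, survival = x$surv), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_curve_csv <- function(path) {
  d <- read.csv(path)
  digitized_curve(d$time, d$survival)
}

#' @rdname pipeline_io
#' @export
write_risk_csv <- function(x, path) {
  write.csv(data.frame(time = x$times, n_at_risk = x$n_at_risk), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_risk_csv <- function(path) {
  d <- read.csv(path)
  risk_table(d$time, d$n_at_risk)
}

#' @rdname pipeline_io
#' @export
write_ipd_csv <- function(x, path) {
  write.csv(as.data.frame(x)[c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ipd_csv <- function(path) {
  d <- read.csv(path)
  structure(d[c("time", "event")], class = c("pseudo_ipd", "data.frame"))
}

#' @rdname pipeline_io
#' @export
write_life_table_csv <- function(x, path) {
  write.csv(data.frame(age = x$age, qx = x$annual_death_prob), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_life_table_csv <- function(path) {
  d <- read.csv(path)
  structure(data.frame(age = d$age, annual_death_prob = d$qx),
            class = c("life_table", "data.frame"))
}

#' Export a fitted curve as CSV (time, survival, hazard)
#' @param model A fitted or HR-scaled survival curve.
#' @param path Output path.
#' @param t_max,by Time grid in months.
#' @return `path`, invisibly.
#' @export
write_fitted_curve_csv <- function(model, path, t_max = 480, by = 1) {
  t <- seq(0, t_max, by = by)
  write.csv(data.frame(t = t, S = surv_prob(model, t),
                       h = hazard_fn(model, t)), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted survival model to JSON
#' @param model A `surv_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(family = model$family, params = as.list(model$params),
         loglik = model$loglik, n_params = model$n_params,
         aic = model$aic, knots = model$knots),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
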