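#' Digitized Kaplan-Meier curve
#'
#' Container for published-curve coordinates: non-decreasing times and the
#' survival probability read off the curve at each time. Small
#' monotonicity violations from digitization noise are tolerated here and
#' repaired by [repair_monotonicity()] before reconstruction.
#'
#' @param times Non-decreasing times (months).
#' @param surv Survival probabilities in \[0, 1\], nominally non-increasing.
#' @return A data frame of class `digitized_curve` with columns `times`,
#'   `surv`.
#' @export
digitized_curve <- function(times, surv) {
  if (length(times) != length(surv))
    stop("`times` and `surv` must have the same length", call. = FALSE)
  if (length(times) == 0) stop("empty curve", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be non-decreasing", call. = FALSE)
  if (any(surv < 0 | surv > 1)) stop("`surv` must lie in [0, 1]", call. = FALSE)
  structure(data.frame(times = times, surv = surv),
            class = c("digitized_curve", "data.frame"))
}

#' Number-at-risk table accompanying a digitized curve
#'
#' @param times Ascending times (months) at which the number at risk is
#'   printed under a KM figure.
#' @param n_at_risk Non-increasing, non-negative integer counts.
#' @return A data frame of class `risk_table` with columns `times`,
#'   `n_at_risk`.
#' @export
risk_table <- function(times, n_at_risk) {
  if (length(times) != length(n_at_risk))
    stop("`times` and `n_at_risk` must have the same length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("risk-table times must be strictly increasing", call. = FALSE)
  if (any(n_at_risk < 0) || any(n_at_risk != round(n_at_risk)))
    stop("`n_at_risk` must be non-negative integers", call. = FALSE)
  if (any(diff(n_at_risk) > 0))
    stop(sprintf("number at risk increases at interval %d",
                 which(diff(n_at_risk) > 0)[1]), call. = FALSE)
  structure(data.frame(times = times, n_at_risk = as.integer(n_at_risk)),
            class = c("risk_table", "data.frame"))
}

#' Repair digitization noise in a KM curve
#'
#' Applies a running minimum to the survival coordinates and collapses
#' duplicated time points, keeping the last (lowest, post-running-minimum)
#' value at each time.
#'
#' @param curve A [digitized_curve()] or data frame with `times`, `surv`.
#' @return A strictly valid `digitized_curve` (non-increasing survival,
#'   unique times).
#' @export
repair_monotonicity <- function(curve) {
  s <- cummin(pmin(curve$surv, 1))
  t <- curve$times
  keep <- !duplicated(t, fromLast = TRUE)
  digitized_curve(times = t[keep], surv = s[keep])
}

# Step-function lookup of a repaired curve: right-continuous value of S at
# time x (the value after any drop located exactly at x).
curve_step_fun <- function(curve) {
  function(x) approx(curve$times, curve$surv, xout = x,
                     method = "constant", f = 0, rule = 2)$y
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Inverts the product-limit construction: within each interval between
#' consecutive number-at-risk times, the numbers of events (placed at the
#' digitized step times) and censorings (spread uniformly over the
#' interval) are estimated iteratively so that the KM estimate of the
#' output tracks the input curve and the implied number at risk matches
#' the printed table at every risk time. Subjects still at risk after the
#' last digitized time are censored there. If the total number of events
#' is known (e.g. reported in the publication), the event count in the
#' final interval is adjusted to match it.
#'
#' @param curve A [digitized_curve()].
#' @param risk A [risk_table()]; refusing to reconstruct without one is
#'   deliberate, since guessing the censoring pattern is the principal
#'   failure mode of naive digitization. The curve must span the risk
#'   times.
#' @param total_events Optional total event count for the final
#'   adjustment; default `NULL` (off).
#' @return A data frame of class `pseudo_ipd` with columns `time`, `event`
#'   (1 = event, 0 = censored); one row per reconstructed subject, so the
#'   number of rows equals the first number at risk.
#' @export
reconstruct <- function(curve, risk, total_events = NULL) {
  if (missing(risk) || is.null(risk))
    stop("a number-at-risk table is required for reconstruction",
         call. = FALSE)
  curve <- repair_monotonicity(curve)
  if (!inherits(risk, "risk_table"))
    risk <- risk_table(risk$times, risk$n_at_risk)
  if (risk$n_at_risk[1] < 1)
    stop("first number at risk must be at least 1", call. = FALSE)
  if (curve$times[1] > risk$times[1])
    curve <- digitized_curve(c(risk$times[1], curve$times),
                             c(1, curve$surv))
  sfun <- curve_step_fun(curve)
  tt <- curve$times
  ss <- curve$surv
  Tn <- risk$times
  Nn <- risk$n_at_risk
  I <- length(Tn)
  t_end <- max(tt[length(tt)], Tn[I])

  ev_times <- numeric(0); ev_counts <- integer(0); cen_times <- numeric(0)
  km_hat <- 1            # running KM of the reconstruction
  n_cur <- Nn[1]

  # Walk the clicks of one interval for a candidate number of censorings.
  # Clicks at the interval's right boundary belong to the interval (events
  # at a printed risk time are taken to precede the at-risk reading).
  walk_interval <- function(idx, n_in, km_in, ncen, t_lo, t_hi, last = FALSE) {
    c_times <- if (ncen > 0) t_lo + (seq_len(ncen) - 0.5) / ncen * (t_hi - t_lo)
               else numeric(0)
    d <- integer(length(idx)); n_risk <- n_in; km <- km_in
    used_cen <- 0
    for (j in seq_along(idx)) {
      k <- idx[j]
      n_c <- sum(c_times <= tt[k]) - used_cen
      used_cen <- used_cen + n_c
      n_risk <- n_risk - n_c
      if (km > 0 && n_risk > 0) {
        dj <- round(n_risk * (1 - ss[k] / km))
        dj <- max(0L, min(as.integer(dj), n_risk))
      } else dj <- 0L
      if (dj > 0) {
        km <- km * (1 - dj / n_risk)
        n_risk <- n_risk - dj
      }
      d[j] <- dj
    }
    n_risk <- n_risk - (ncen - used_cen)
    list(d = d, c_times = c_times, n_out = n_risk, km_out = km)
  }

  for (i in seq_len(I)) {
    t_lo <- Tn[i]
    t_hi <- if (i < I) Tn[i + 1] else t_end
    idx <- which(tt > t_lo & tt <= t_hi)
    if (i < I) {
      n_next <- Nn[i + 1]
      sr <- if (sfun(t_lo) > 0) sfun(t_hi) / sfun(t_lo) else 0
      ncen <- max(0L, min(n_cur, as.integer(round(n_cur * sr - n_next))))
      best <- NULL; tried <- integer(0)
      for (iter in 1:60) {
        res <- walk_interval(idx, n_cur, km_hat, ncen, t_lo, t_hi)
        diff <- res$n_out - n_next
        if (is.null(best) || abs(diff) < abs(best$diff))
          best <- c(res, list(ncen = ncen, diff = diff))
        if (diff == 0) break
        tried <- c(tried, ncen)
        ncen <- max(0L, min(n_cur, ncen + diff))
        if (ncen %in% tried) break
      }
      res <- best
      if (res$diff > 0) {
        # censor the surplus just before the next risk time
        extra <- rep(t_hi - 1e-9 * max(1, t_hi), res$diff)
        res$c_times <- c(res$c_times, extra)
        res$n_out <- res$n_out - res$diff
      } else if (res$diff < 0) {
        stop(sprintf(paste0("risk table inconsistent with curve in interval ",
                            "%d [%g, %g]: curve drops below what the ",
                            "remaining number at risk permits"),
                     i, t_lo, t_hi), call. = FALSE)
      }
      ev_times <- c(ev_times, tt[idx]); ev_counts <- c(ev_counts, res$d)
      cen_times <- c(cen_times, res$c_times)
      n_cur <- res$n_out; km_hat <- res$km_out
    } else {
      res <- walk_interval(idx, n_cur, km_hat, 0L, t_lo, t_hi, last = TRUE)
      if (!is.null(total_events)) {
        gap <- total_events - (sum(ev_counts) + sum(res$d))
        if (length(res$d) > 0) {
          j <- length(res$d)
          avail <- res$n_out
          adj <- max(-res$d[j], min(gap, avail))
          res$d[j] <- res$d[j] + adj
          res$n_out <- res$n_out - max(0, adj)
        }
      }
      ev_times <- c(ev_times, tt[idx]); ev_counts <- c(ev_counts, res$d)
      n_cur <- res$n_out
    }
  }

  out <- data.frame(
    time = c(rep(ev_times, ev_counts), cen_times, rep(t_end, n_cur)),
    event = c(rep(1L, sum(ev_counts)), rep(0L, length(cen_times) + n_cur)))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pseudo_ipd", "data.frame"), n0 = Nn[1])
}
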