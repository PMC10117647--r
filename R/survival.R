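#' A right-censored sample of recurrence times
#'
#' @param time Non-negative event or censoring times (months for clinical
#'   data, model time units for in-silico cohorts; the fitting calibration
#'   equates the two).
#' @param event Logical (or 0/1): `TRUE` when recurrence was observed,
#'   `FALSE` when the observation is right-censored.
#' @param patient_id Optional identifiers; generated when missing.
#' @return An object of class `survival_sample` (a data frame with columns
#'   `patient_id`, `time`, `event`).
#' @examples
#' survival_sample(c(2, 5, 9, 12), c(TRUE, TRUE, FALSE, TRUE))
#' @export
survival_sample <- function(time, event, patient_id = NULL) {
  if (length(time) == 0) stop("empty sample")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and >= 0")
  event <- as.logical(event)
  if (anyNA(event)) stop("event flags must be TRUE/FALSE (or 0/1)")
  if (is.null(patient_id))
    patient_id <- sprintf("P%04d", seq_along(time))
  structure(data.frame(patient_id = as.character(patient_id),
                       time = as.numeric(time), event = event,
                       stringsAsFactors = FALSE),
            class = c("survival_sample", "data.frame"))
}

#' Kaplan-Meier estimate of the recurrence-free survival function
#'
#' Standard product-limit estimator with right censoring, computed with
#' [survival::survfit()].
#'
#' @param sample A [survival_sample()].
#' @return An object of class `km_curve`: a list with `time` (event times),
#'   `surv` (survival probabilities after each), `n_risk`, `n_event` and
#'   the sample size `n`.
#' @examples
#' km_estimate(survival_sample(c(2, 5, 9, 12), rep(TRUE, 4)))
#' @export
km_estimate <- function(sample) {
  if (!inherits(sample, "survival_sample"))
    sample <- survival_sample(sample$time, sample$event, sample$patient_id)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = as.data.frame(sample), conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = nrow(sample)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve from %d observations (%d distinct times)\n",
              x$n, length(x$time)))
  invisible(x)
}

#' Percentile grid of recurrence times from a Kaplan-Meier curve
#'
#' For each quantile `q` on the grid 0%, `step`%, 2*`step`%, ..., 100%,
#' returns the first time at which the cumulative recurrence fraction
#' `1 - S(t)` reaches `q`. The 0% point maps to time 0 by convention;
#' quantiles the curve never reaches (because of censoring) are `NA`.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param step Grid spacing in percent. Default 4 (a 26-point grid).
#' @return A data frame of class `percentile_grid` with columns `quantile`
#'   (percent) and `time`.
#' @examples
#' pg <- percentile_times(km_estimate(
#'   survival_sample(c(2, 5, 9, 12), rep(TRUE, 4))))
#' pg[pg$quantile == 50, ]
#' @export
percentile_times <- function(curve, step = 4) {
  stopifnot(inherits(curve, "km_curve"))
  qs <- seq(0, 100, by = step)
  cuminc <- 1 - curve$surv
  times <- vapply(qs, function(q) {
    if (q == 0) return(0)
    # numeric tolerance so e.g. 3/4 reached counts as the 75% quantile
    hit <- which(cuminc >= q / 100 - 1e-9)
    if (length(hit) == 0) NA_real_ else curve$time[hit[1]]
  }, numeric(1))
  structure(data.frame(quantile = qs, time = times),
            class = c("percentile_grid", "data.frame"))
}

#' Mean squared logarithmic residual between two percentile grids
#'
#' The fitting objective: the mean over shared usable quantiles of
#' `(log(t_sim) - log(t_clin))^2`, where a quantile is usable when both
#' grids reach it with a strictly positive time (the 0% point, at time 0,
#' is always excluded). Natural logarithms are used; the choice of base
#' rescales the objective by a constant and does not move the argmin. The
#' companion sum of squared residuals (log-SSR) is also returned.
#'
#' @param sim,clin `percentile_grid` data frames on the same quantile grid.
#' @return A list with `log_msr`, `log_ssr` and `n_quantiles` (the number
#'   of quantiles compared).
#' @examples
#' g1 <- data.frame(quantile = c(4, 8), time = c(2, 4))
#' g2 <- data.frame(quantile = c(4, 8), time = c(1, 8))
#' log_msr(g1, g2)$log_msr  # log(2)^2
#' @export
log_msr <- function(sim, clin) {
  m <- merge(as.data.frame(sim), as.data.frame(clin), by = "quantile",
             suffixes = c("_sim", "_clin"))
  use <- !is.na(m$time_sim) & !is.na(m$time_clin) &
    m$time_sim > 0 & m$time_clin > 0
  if (!any(use))
    stop("no shared usable quantile with strictly positive times")
  res2 <- (log(m$time_sim[use]) - log(m$time_clin[use]))^2
  list(log_msr = mean(res2), log_ssr = sum(res2), n_quantiles = sum(use))
}

#' Mantel-Cox (log-rank) test between two survival samples
#'
#' Wraps [survival::survdiff()] with `rho = 0`.
#'
#' @param a,b [survival_sample()] objects.
#' @return A list with `statistic` (chi-square, 1 df) and `p`.
#' @examples
#' s1 <- survival_sample(1:10, rep(TRUE, 10))
#' s2 <- survival_sample(101:110, rep(TRUE, 10))
#' logrank_test(s1, s2)$p  # < 0.001
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("both samples must be non-empty")
  if (!any(a$event) && !any(b$event))
    stop("degenerate comparison: no events in either sample")
  df <- data.frame(time = c(a$time, b$time),
                   event = c(a$event, b$event),
                   arm = rep(c("a", "b"), c(nrow(a), nrow(b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = df,
                           rho = 0)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), p = p)
}

#' Build an in-silico recurrence cohort by repeated full simulations
#'
#' Each run contributes its recurrence time as an event; runs whose
#' recurrence phase is censored contribute a censored time at `max_time`,
#' and runs in which cancer never initiated contribute a censored time at
#' `max_time` as well. Under the fitting calibration one model time unit is
#' one month, so the cohort is directly comparable to clinical
#' disease-free-survival tables.
#'
#' @param params A [model_params()].
#' @param engine `"well_mixed"` or `"spatial"`.
#' @param n_runs Number of simulated patients (>= 1).
#' @param seed Optional integer seed.
#' @return A [survival_sample()] of `n_runs` observations.
#' @export
in_silico_cohort <- function(params, engine = c("well_mixed", "spatial"),
                             n_runs, seed = NULL) {
  engine <- match.arg(engine)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- if (engine == "well_mixed") run_full else simulate_spatial
  time <- numeric(n_runs)
  event <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    out <- sim(params)
    if (out$detected) {
      time[i] <- out$t_recur
      event[i] <- out$recurred
    } else {
      time[i] <- params$max_time
      event[i] <- FALSE
    }
  }
  survival_sample(time, event)
}

#' Write a Kaplan-Meier curve or percentile grid as CSV
#'
#' @param x A `km_curve` or `percentile_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(x, path) {
  df <- if (inherits(x, "km_curve"))
    data.frame(time = x$time, surv = x$surv, n_risk = x$n_risk,
               n_event = x$n_event)
  else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
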