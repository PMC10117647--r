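#' Sampling ranges for the fitted model parameters
#'
#' The calibration fits seven parameters: the premalignant fitnesses `r1`
#' and `rS1`, the malignant birth/death rates `rS` and `dS`, and the three
#' mutation probabilities (sampled log-uniformly, so their bounds are given
#' in log10). Structural values (`N`, `r0 = 1`, `d`, thresholds) are fixed
#' by the base parameter set. Defaults bracket the fitted profiles shipped
#' with the package.
#'
#' @param r1,rS1,rS,dS Length-2 numeric `c(lower, upper)` bounds.
#' @param log10_mu1,log10_muS1,log10_muS Length-2 bounds on log10 of each
#'   mutation probability.
#' @return An object of class `parameter_ranges` (named list of bounds).
#' @examples
#' parameter_ranges(rS = c(2, 9))
#' @export
parameter_ranges <- function(r1 = c(0.85, 1.15), rS1 = c(0.85, 1.15),
                             rS = c(2, 9), dS = c(1, 4.5),
                             log10_mu1 = c(-5, -2),
                             log10_muS1 = c(-5, -2),
                             log10_muS = c(-5, -2)) {
  rg <- list(r1 = r1, rS1 = rS1, rS = rS, dS = dS,
             log10_mu1 = log10_mu1, log10_muS1 = log10_muS1,
             log10_muS = log10_muS)
  for (nm in names(rg)) {
    b <- rg[[nm]]
    if (length(b) != 2 || anyNA(b)) stop("bounds for ", nm,
                                         " must be c(lower, upper)")
    if (b[1] > b[2]) stop("inverted bounds for ", nm)
  }
  structure(rg, class = "parameter_ranges")
}

#' Draw one candidate parameter set from the sampling ranges
#'
#' Fitnesses and rates are drawn uniformly within their bounds; mutation
#' probabilities are drawn log-uniformly (uniform in log10).
#'
#' @param ranges A [parameter_ranges()].
#' @param base A [model_params()] supplying the fixed structural values.
#' @return A [model_params()] with the sampled values substituted.
#' @export
sample_parameters <- function(ranges, base) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  draw <- function(b) stats::runif(1, b[1], b[2])
  p <- base
  p$r1 <- draw(ranges$r1)
  p$rS1 <- draw(ranges$rS1)
  p$rS <- draw(ranges$rS)
  p$dS <- draw(ranges$dS)
  p$mu1 <- 10^draw(ranges$log10_mu1)
  p$muS1 <- 10^draw(ranges$log10_muS1)
  p$muS <- 10^draw(ranges$log10_muS)
  suppressWarnings(validate_params(p))
  p
}

#' Objective value of one candidate parameter set
#'
#' Simulates an in-silico cohort at the candidate parameters, takes its
#' Kaplan-Meier percentile grid and returns the mean squared logarithmic
#' residual against the clinical grid. Candidates whose cohorts yield no
#' usable shared quantile (for example because cancer never initiates
#' within `max_time`) receive a large penalty value instead of an error so
#' that random search remains total.
#'
#' @param params Candidate [model_params()].
#' @param clinical_grid A `percentile_grid` from the clinical sample.
#' @param engine `"well_mixed"` or `"spatial"`.
#' @param n_runs Cohort size per evaluation (>= 25 so the percentile grid
#'   is populated).
#' @param step Percentile grid spacing (percent).
#' @param penalty Objective value assigned to unusable candidates.
#' @return The log-MSR objective (or `penalty`).
#' @export
evaluate_candidate <- function(params, clinical_grid,
                               engine = c("well_mixed", "spatial"),
                               n_runs = 200, step = 4, penalty = 1e6) {
  engine <- match.arg(engine)
  if (n_runs < 25) stop("n_runs must be >= 25 to populate the grid")
  cohort <- in_silico_cohort(params, engine, n_runs)
  if (!any(cohort$event)) return(penalty)
  grid <- percentile_times(km_estimate(cohort), step = step)
  obj <- tryCatch(log_msr(grid, clinical_grid)$log_msr,
                  error = function(e) penalty)
  obj
}

#' Random-search calibration against a clinical disease-free-survival sample
#'
#' Draws `n_samples` candidate parameter sets from `ranges`, scores each
#' with [evaluate_candidate()] and returns the minimizer. The accepted fit
#' is additionally checked with a Mantel-Cox log-rank test between the
#' clinical sample and a fresh cohort simulated at the best parameters
#' (agreement corresponds to p above 0.05).
#'
#' @param clinical A [survival_sample()] of disease-free-survival times in
#'   months.
#' @param ranges A [parameter_ranges()].
#' @param base A [model_params()] with the fixed structural values (tissue
#'   size, turnover `d`, thresholds; one model time unit is one month).
#' @param n_samples Number of candidates to evaluate.
#' @param n_runs Cohort size per candidate evaluation.
#' @param engine `"well_mixed"` or `"spatial"`.
#' @param step Percentile grid spacing (percent).
#' @param seed Optional integer seed.
#' @param verbose Print progress every 50 candidates.
#' @return A list of class `fit_result`: `best` (the fitted
#'   [model_params()]), `SQ_msr` and `SQ_ssr` (objective at the optimum, in
#'   mean and sum form), `logrank_p`, `n_samples`, and `audit` (a data
#'   frame of every candidate and its objective).
#' @export
random_search <- function(clinical, ranges, base, n_samples = 1000,
                          n_runs = 200, engine = c("well_mixed", "spatial"),
                          step = 4, seed = NULL, verbose = FALSE) {
  engine <- match.arg(engine)
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  clin_grid <- percentile_times(km_estimate(clinical), step = step)
  audit <- data.frame(sample = seq_len(n_samples), r1 = NA_real_,
                      rS1 = NA_real_, rS = NA_real_, dS = NA_real_,
                      mu1 = NA_real_, muS1 = NA_real_, muS = NA_real_,
                      objective = NA_real_)
  best <- NULL
  best_obj <- Inf
  for (i in seq_len(n_samples)) {
    cand <- sample_parameters(ranges, base)
    obj <- evaluate_candidate(cand, clin_grid, engine, n_runs, step)
    audit[i, c("r1", "rS1", "rS", "dS", "mu1", "muS1", "muS")] <-
      c(cand$r1, cand$rS1, cand$rS, cand$dS, cand$mu1, cand$muS1, cand$muS)
    audit$objective[i] <- obj
    if (obj < best_obj) { best <- cand; best_obj <- obj }
    if (verbose && i %% 50 == 0)
      message(sprintf("candidate %d/%d, best objective %.4f",
                      i, n_samples, best_obj))
  }
  if (!is.finite(best_obj) || best_obj >= 1e6)
    stop("search failed: every candidate was penalized ",
         "(no candidate produced recurrences)")
  check <- in_silico_cohort(best, engine, n_runs = max(n_runs,
                                                       nrow(clinical)))
  lr <- logrank_test(clinical, check)
  best_grid <- percentile_times(km_estimate(
    in_silico_cohort(best, engine, n_runs)), step = step)
  sq <- log_msr(best_grid, clin_grid)
  structure(list(best = best, SQ_msr = best_obj, SQ_ssr = sq$log_ssr,
                 logrank_p = lr$p, n_samples = n_samples, audit = audit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("random-search fit over %d candidates\n", x$n_samples))
  cat(sprintf("  best objective (log-MSR) = %.4f, log-rank p = %.4f\n",
              x$SQ_msr, x$logrank_p))
  cat(sprintf("  r1 = %.3f, rS1 = %.3f, rS = %.3f, dS = %.3f\n",
              b$r1, b$rS1, b$rS, b$dS))
  cat(sprintf("  log10 mu = (%.3f, %.3f, %.3f)\n",
              log10(b$mu1), log10(b$muS1), log10(b$muS)))
  invisible(x)
}

#' Generate a synthetic disease-free-survival cohort at known parameters
#'
#' Simulates `n_patients` full initiation-surgery-recurrence courses at the
#' true parameters and emits their recurrence times as a clinical-style
#' sample. Two censoring mechanisms mirror real disease-free-survival
#' tables: every patient is administratively censored at the end of the
#' follow-up window (`follow_up` months, as in registry exports where
#' follow-up ends long before the model's own time cap), and a random
#' `censor_fraction` of the remaining event patients are lost to follow-up
#' at a uniform time below their event time. Used for download-free fitting
#' tests and parameter-recovery studies.
#'
#' @param true_params A [model_params()].
#' @param n_patients Cohort size (>= 1).
#' @param censor_fraction Fraction of event patients to censor early, in
#'   `[0, 1)`.
#' @param follow_up End of the follow-up window in months; later event and
#'   censoring times are censored there. Default 150 (a typical registry
#'   horizon); `Inf` disables it.
#' @param engine `"well_mixed"` or `"spatial"`.
#' @param seed Optional integer seed.
#' @return A [survival_sample()].
#' @export
synthesize_cohort <- function(true_params, n_patients, censor_fraction = 0,
                              follow_up = 150,
                              engine = c("well_mixed", "spatial"),
                              seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(n_patients >= 1, censor_fraction >= 0, censor_fraction < 1,
            follow_up > 0)
  if (!is.null(seed)) set.seed(seed)
  cohort <- in_silico_cohort(true_params, engine, n_patients)
  beyond <- cohort$time > follow_up
  cohort$time[beyond] <- follow_up
  cohort$event[beyond] <- FALSE
  if (censor_fraction > 0) {
    ev <- which(cohort$event)
    n_cens <- floor(censor_fraction * length(ev))
    if (n_cens > 0) {
      pick <- sample(ev, n_cens)
      cohort$time[pick] <- stats::runif(n_cens) * cohort$time[pick]
      cohort$event[pick] <- FALSE
    }
  }
  cohort
}

#' Integrated mutation rate of a carcinogenic profile
#'
#' The integrated mutation rate is the product of the per-step mutation
#' probabilities, `mu1 * muS1 * muS`; on the log10 scale it is the sum of
#' the three per-step log10 rates. A small integrated rate is a proxy for
#' many mutational hits being required for carcinogenesis.
#'
#' @param profile A one-row data frame (or list) with `log10_mu1`,
#'   `log10_muS1`, `log10_muS`.
#' @return log10 of the integrated mutation rate.
#' @examples
#' integrated_mutation_rate(
#'   list(log10_mu1 = -3.212, log10_muS1 = -3.979, log10_muS = -3.006))
#' @export
integrated_mutation_rate <- function(profile) {
  vals <- c(profile$log10_mu1, profile$log10_muS1, profile$log10_muS)
  if (length(vals) != 3 || anyNA(vals))
    stop("profile must provide all three per-step log10 mutation rates")
  sum(vals)
}

#' Tissue turnover cycles per month implied by a profile
#'
#' Under the fitting calibration one model time unit is one month, so the
#' fitted malignant death rate `dS` is read directly as the tissue-specific
#' turnover rate per month.
#'
#' @param profile A list or one-row data frame with a `dS` element.
#' @return Turnover cycles per month.
#' @export
turnover_per_month <- function(profile) {
  if (is.null(profile$dS)) stop("profile must provide dS")
  as.numeric(profile$dS)
}

#' Regression of required mutational hits on the integrated mutation rate
#'
#' Ordinary least squares of published driver-hit counts against log10
#' integrated mutation rates across cancer types, with the slope
#' significance p value; the fitted line predicts hit counts for cancer
#' types without published estimates.
#'
#' @param log10_muI Numeric vector of log10 integrated mutation rates.
#' @param hits Numeric vector of published mutational-hit counts.
#' @return A list with `slope`, `intercept`, `p` (slope t-test), `r_squared`
#'   and `predict`, a function mapping new log10 muI values to predicted
#'   hit counts.
#' @examples
#' fit <- hits_regression(c(-10, -9, -8), c(3, 4, 5))
#' fit$slope      # 1
#' fit$predict(-9.5)
#' @export
hits_regression <- function(log10_muI, hits) {
  if (length(log10_muI) != length(hits)) stop("length mismatch")
  if (length(log10_muI) < 3) stop("need at least 3 pairs")
  if (stats::sd(log10_muI) == 0) stop("constant predictor: cannot regress")
  fit <- stats::lm(hits ~ log10_muI)
  co <- summary(fit)$coefficients
  p <- if (nrow(co) < 2 || ncol(co) < 4) NA_real_ else co[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = p,
       r_squared = summary(fit)$r.squared,
       predict = function(x)
         unname(stats::coef(fit)[1] + stats::coef(fit)[2] * x))
}

#' Format a fit result as a profile-table row
#'
#' @param fit A `fit_result` from [random_search()].
#' @param code Short cancer-type code for the row.
#' @param name Cancer-type name.
#' @param source Data source annotation.
#' @return A one-row data frame matching the bundled profile table layout.
#' @export
fit_to_profile_row <- function(fit, code = "FIT", name = "", source = "") {
  b <- fit$best
  row <- data.frame(code = code, cancer_type = name, source = source,
                    SQ = fit$SQ_ssr, r1 = b$r1, rS1 = b$rS1, rS = b$rS,
                    dS = b$dS, log10_mu1 = log10(b$mu1),
                    log10_muS1 = log10(b$muS1), log10_muS = log10(b$muS),
                    log10_muI = NA_real_, p_value = fit$logrank_p,
                    stringsAsFactors = FALSE)
  row$log10_muI <- integrated_mutation_rate(row)
  row
}
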