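#' Tissue composition of the Moran compartment
#'
#' @param X0,X1,XS1 Non-negative integer counts of Type 0, Type 1 and
#'   Type S-1 cells. Their sum is the tissue size `N` and is conserved by
#'   every turnover step.
#' @return An object of class `tissue_state` (named integer vector).
#' @examples
#' tissue_state(990, 8, 2)
#' @export
tissue_state <- function(X0, X1, XS1) {
  x <- c(X0 = as.integer(X0), X1 = as.integer(X1), XS1 = as.integer(XS1))
  if (anyNA(x) || any(x < 0)) stop("cell counts must be non-negative integers")
  if (sum(x) < 2) stop("tissue must contain at least 2 cells")
  class(x) <- "tissue_state"
  x
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("tissue (N = %d): X0 = %d, X1 = %d, XS1 = %d\n",
              sum(x), x[["X0"]], x[["X1"]], x[["XS1"]]))
  invisible(x)
}

#' Mean waiting time between simulation events
#'
#' The hybrid simulation interleaves three event channels: tissue turnover
#' (rate `d * N`), malignant birth (rate `rS * XS`) and malignant death
#' (rate `dS * XS`). The mean time to the next event is the reciprocal of
#' the total rate, and the simulation clock advances by this amount at each
#' step.
#'
#' @param params A [model_params()] object.
#' @param XS Current malignant cell count (>= 0).
#' @return The mean waiting time `1 / (d*N + rS*XS + dS*XS)`.
#' @examples
#' waiting_time(model_params(N = 1000, d = 1), XS = 0)   # 0.001
#' @export
waiting_time <- function(params, XS) {
  stopifnot(XS >= 0)
  total <- params$d * params$N + (params$rS + params$dS) * XS
  if (total <= 0)
    stop("frozen system: all event rates are zero")
  1 / total
}

#' Probabilities of the three Gillespie event channels
#'
#' @inheritParams waiting_time
#' @return Named numeric vector `c(turnover, S_birth, S_death)`, each equal
#'   to its rate times the mean waiting time; the three sum to 1.
#' @examples
#' event_channel_probabilities(model_params(N = 1000, rS = 1.5, dS = 1), 1000)
#' @export
event_channel_probabilities <- function(params, XS) {
  dt <- waiting_time(params, XS)
  c(turnover = params$d * params$N * dt,
    S_birth = params$rS * XS * dt,
    S_death = params$dS * XS * dt)
}

#' Division-outcome distribution for refilling a vacancy
#'
#' When a tissue cell dies, the vacancy is refilled by a fitness-weighted
#' draw over dividing cells, with mutation routing the daughter to the next
#' type. With `F = r0*X0 + r1*X1 + rS1*XS1`, the four outcomes have
#' probabilities:
#' \itemize{
#'   \item Type 0 daughter: `r0*X0*(1 - mu1) / F`
#'   \item Type 1 daughter: `(r1*X1*(1 - muS1) + r0*X0*mu1) / F`
#'   \item Type S-1 daughter: `(rS1*XS1*(1 - muS) + r1*X1*muS1) / F`
#'   \item malignant (Type S) birth: `rS1*XS1*muS / F`
#' }
#' The malignant branch does not fill the vacancy: the simulation increments
#' the off-tissue tumor count and redraws until a tissue daughter appears.
#'
#' @param state A [tissue_state()].
#' @param params A [model_params()].
#' @return Named numeric vector
#'   `c(daughter0, daughter1, daughterS1, S_birth)` summing to 1.
#' @examples
#' p <- model_params(N = 1000, r1 = 1.2, rS1 = 0.8,
#'                   mu1 = 0.01, muS1 = 0.01, muS = 0.001)
#' division_distribution(tissue_state(500, 300, 200), p)
#' @export
division_distribution <- function(state, params) {
  X0 <- state[["X0"]]; X1 <- state[["X1"]]; XS1 <- state[["XS1"]]
  F <- params$r0 * X0 + params$r1 * X1 + params$rS1 * XS1
  if (F <= 0) stop("no cell can divide: total division weight F is zero")
  c(daughter0 = params$r0 * X0 * (1 - params$mu1) / F,
    daughter1 = (params$r1 * X1 * (1 - params$muS1) +
                   params$r0 * X0 * params$mu1) / F,
    daughterS1 = (params$rS1 * XS1 * (1 - params$muS) +
                    params$r1 * X1 * params$muS1) / F,
    S_birth = params$rS1 * XS1 * params$muS / F)
}

#' One Moran turnover event (well-mixed)
#'
#' A cell is chosen uniformly to die and the vacancy is refilled by a draw
#' from [division_distribution()] computed on the pre-death composition.
#' Every malignant draw adds one malignant cell and the vacancy draw
#' repeats (so a single turnover can spawn several malignant cells); the
#' number of redraws is capped to guard `muS` near 1.
#'
#' @param state A [tissue_state()].
#' @param params A [model_params()].
#' @return A list with the updated `state` and `s_births`, the number of
#'   malignant cells born during this event.
#' @export
turnover_step <- function(state, params) {
  N <- sum(state)
  dying <- sample.int(3L, 1L, prob = as.numeric(state) / N)
  pr <- division_distribution(state, params)
  s_births <- 0L
  daughter <- NA_integer_
  for (k in seq_len(params$redraw_cap + 1L)) {
    out <- sample.int(4L, 1L, prob = pr)
    if (out == 4L) { s_births <- s_births + 1L; next }
    daughter <- out
    break
  }
  if (is.na(daughter))
    stop("redraw cap exceeded while refilling a vacancy (muS too close to 1)")
  x <- as.integer(state)
  x[dying] <- x[dying] - 1L
  x[daughter] <- x[daughter] + 1L
  list(state = tissue_state(x[1], x[2], x[3]), s_births = s_births)
}

#' Deterministic tumor expansion time
#'
#' Once the malignant population is much larger than the tissue (by default
#' `2 * N` cells), its growth is well approximated by deterministic
#' exponential expansion at net rate `rS - dS`, and the remaining time to
#' the detection threshold is
#' `log(threshold / (2 * N)) / (rS - dS)`.
#'
#' @param rS,dS Malignant birth and death rates; requires `rS > dS`.
#' @param N Tissue size.
#' @param threshold Detection threshold (>= `2 * N`).
#' @param hybrid_switch Multiple of `N` at which growth became
#'   deterministic. Default 2.
#' @return Time from the switch point to detection.
#' @examples
#' deterministic_growth_time(1.5, 1.0, 1000, 1e9)  # 2 * log(5e5)
#' @export
deterministic_growth_time <- function(rS, dS, N, threshold,
                                      hybrid_switch = 2) {
  if (rS <= dS) stop("no net growth: rS must exceed dS")
  start <- hybrid_switch * N
  if (threshold < start) stop("threshold must be at least hybrid_switch * N")
  log(threshold / start) / (rS - dS)
}

run_phase_engine <- function(state, XS, params) {
  cpp_run_phase(state[["X0"]], state[["X1"]], state[["XS1"]], XS,
                params$N, params$d, params$r0, params$r1, params$rS1,
                params$rS, params$dS, params$mu1, params$muS1, params$muS,
                params$detection_threshold, params$hybrid_switch,
                params$max_time, params$redraw_cap)
}

#' Simulate cancer initiation up to first detection
#'
#' Starting from a tissue of `N` Type 0 cells (or a supplied composition),
#' the hybrid Moran/branching process runs until the malignant count reaches
#' the detection threshold or `max_time` elapses (a censored run). Tumor
#' growth is stochastic while small and deterministic beyond
#' `hybrid_switch * N` cells, during which interval tissue turnover
#' continues to be simulated.
#'
#' @param params A [model_params()].
#' @param initial Optional starting [tissue_state()]; default all Type 0.
#' @param seed Optional integer seed set before simulating.
#' @return A list with `detected` (flag), `t_detect` (detection time, or the
#'   censoring time `max_time`), `composition` (the [tissue_state()] at
#'   detection/censoring) and `seed`.
#' @examples
#' \donttest{
#' simulate_to_detection(model_params(N = 50, mu1 = 0.05, muS1 = 0.05,
#'                                    muS = 0.05), seed = 1)
#' }
#' @export
simulate_to_detection <- function(params, initial = NULL, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) initial <- tissue_state(params$N, 0, 0)
  if (sum(initial) != params$N)
    stop("initial composition must sum to N")
  res <- run_phase_engine(initial, 0, params)
  list(detected = res$detected,
       t_detect = res$t,
       composition = tissue_state(res$X0, res$X1, res$XS1),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Surgical resection of the malignant compartment
#'
#' Surgery removes every malignant cell and nothing else: the tissue
#' composition (including premalignant Type 1 and Type S-1 cells — the
#' cancerized field) and the simulation clock are untouched.
#'
#' @param tumor A list with at least an `XS` element (malignant count).
#' @return The same list with `XS = 0`.
#' @examples
#' apply_surgery(list(XS = 1e9, t = 42))
#' @export
apply_surgery <- function(tumor) {
  tumor$XS <- 0
  tumor
}

#' Simulate one full initiation-surgery-recurrence course
#'
#' Runs initiation to first detection, applies surgery (malignant cells
#' removed, tissue preserved), then continues from the preserved tissue
#' until the tumor re-reaches the detection threshold. The elapsed time
#' between surgery and second detection is the recurrence time. Each phase
#' is censored at `max_time`; a censored initiation skips the recurrence
#' phase.
#'
#' @param params A [model_params()].
#' @param seed Optional integer seed.
#' @return A list of class `simulation_outcome`: `t_detect`,
#'   `composition_at_surgery`, `t_recur`, `detected`, `recurred`, `seed`.
#' @examples
#' \donttest{
#' run_full(model_params(N = 50, mu1 = 0.05, muS1 = 0.05, muS = 0.05),
#'          seed = 1)
#' }
#' @export
run_full <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  init <- tissue_state(params$N, 0, 0)
  first <- run_phase_engine(init, 0, params)
  out <- list(t_detect = first$t,
              composition_at_surgery =
                tissue_state(first$X0, first$X1, first$XS1),
              t_recur = NA_real_,
              detected = first$detected,
              recurred = FALSE,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (first$detected) {
    # surgery: malignant count to zero, tissue preserved
    second <- run_phase_engine(out$composition_at_surgery, 0, params)
    out$t_recur <- second$t
    out$recurred <- second$detected
  }
  class(out) <- "simulation_outcome"
  out
}

#' @export
print.simulation_outcome <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("detected at t = %.3f; tissue at surgery: (%d, %d, %d)\n",
                x$t_detect, x$composition_at_surgery[["X0"]],
                x$composition_at_surgery[["X1"]],
                x$composition_at_surgery[["XS1"]]))
    if (x$recurred)
      cat(sprintf("recurred %.3f time units after surgery\n", x$t_recur))
    else
      cat(sprintf("no recurrence by t = %.0f (censored)\n", x$t_recur))
  } else {
    cat(sprintf("no cancer detected by t = %.0f (censored)\n", x$t_detect))
  }
  invisible(x)
}

#' Bin the premalignant Type S-1 proportion at surgery
#'
#' Bins the Type S-1 count into `small` (`XS1 <= 0.1 N`), `intermediate`
#' (`0.1 N < XS1 <= 0.9 N`) and `large` (`XS1 > 0.9 N`).
#'
#' @param composition A [tissue_state()].
#' @param N Tissue size; defaults to `sum(composition)`.
#' @return One of `"small"`, `"intermediate"`, `"large"`.
#' @examples
#' proportion_bin(tissue_state(450, 450, 100))  # small
#' @export
proportion_bin <- function(composition, N = sum(composition)) {
  xs1 <- composition[["XS1"]]
  if (xs1 <= 0.1 * N) "small"
  else if (xs1 <= 0.9 * N) "intermediate"
  else "large"
}

#' Write a batch of simulation outcomes as tab-separated text
#'
#' @param outcomes A list of `simulation_outcome` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(
    run_id = seq_along(outcomes),
    seed = vapply(outcomes, function(o) o$seed, integer(1)),
    t_detect = vapply(outcomes, function(o) o$t_detect, numeric(1)),
    X0 = vapply(outcomes, function(o) o$composition_at_surgery[["X0"]],
                integer(1)),
    X1 = vapply(outcomes, function(o) o$composition_at_surgery[["X1"]],
                integer(1)),
    XS1 = vapply(outcomes, function(o) o$composition_at_surgery[["XS1"]],
                 integer(1)),
    t_recur = vapply(outcomes, function(o) o$t_recur, numeric(1)),
    detected = vapply(outcomes, function(o) o$detected, logical(1)),
    recurred = vapply(outcomes, function(o) o$recurred, logical(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
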