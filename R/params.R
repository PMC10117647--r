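#' Model parameters for the hybrid Moran/branching recurrence model
#'
#' Bundles every rate and size of the multistage initiation/recurrence model:
#' a fixed-size tissue of `N` cells turning over at rate `d` (Moran process),
#' three tissue cell types (normal Type 0, premalignant Type 1 and Type S-1)
#' with division fitnesses `r0`, `r1`, `rS1` and per-division mutation
#' probabilities `mu1` (0 to 1), `muS1` (1 to S-1) and `muS` (S-1 to
#' malignant), and an off-tissue malignant compartment growing as a branching
#' process with birth rate `rS` and death rate `dS` per cell.
#'
#' Detection (and surgery) is triggered when the malignant count reaches
#' `detection_threshold` cells; once the tumor exceeds `hybrid_switch * N`
#' cells its growth is treated as deterministic exponential expansion at net
#' rate `rS - dS`. Runs that never reach detection by `max_time` are censored.
#'
#' @param N Tissue size (number of tissue cells), integer >= 2.
#' @param d Tissue turnover rate (turnover events per cell per unit time; the
#'   whole tissue turns over at rate `d * N`).
#' @param r0,r1,rS1 Division fitness of Type 0 / Type 1 / Type S-1 cells
#'   (dimensionless weights; Type 0 is conventionally 1).
#' @param rS Malignant cell birth rate (per cell per unit time).
#' @param dS Malignant cell death rate (per cell per unit time). Net growth
#'   `rS - dS` must be positive for detection to occur; a warning is issued
#'   otherwise.
#' @param mu1,muS1,muS Per-division mutation probabilities, each in `[0, 1]`.
#' @param detection_threshold Malignant cell count triggering detection and
#'   surgery. Default `1e9` (roughly a 1 cm^3 tumor).
#' @param hybrid_switch Multiple of `N` above which tumor growth becomes
#'   deterministic. Default 2.
#' @param max_time Simulation-time cap per phase; runs not detected by then
#'   are censored. Default `1e4` model time units.
#' @param I,J Optional lattice dimensions for the spatial engine; must
#'   satisfy `I * J == N`. When only `N` is given a near-square lattice is
#'   derived on demand.
#' @param redraw_cap Maximum number of vacancy redraws in a single turnover
#'   event (guards pathological `muS` near 1). Default `1e4`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(N = 1000, r1 = 1.1, muS1 = 1e-4)
#' p$N
#' @export
model_params <- function(N = 1000, d = 1, r0 = 1, r1 = 1, rS1 = 1,
                         rS = 1.5, dS = 1, mu1 = 0.001, muS1 = 0.001,
                         muS = 0.001, detection_threshold = 1e9,
                         hybrid_switch = 2, max_time = 1e4,
                         I = NULL, J = NULL, redraw_cap = 1e4) {
  p <- list(N = as.integer(N), d = d, r0 = r0, r1 = r1, rS1 = rS1, rS = rS,
            dS = dS, mu1 = mu1, muS1 = muS1, muS = muS,
            detection_threshold = detection_threshold,
            hybrid_switch = hybrid_switch, max_time = max_time,
            I = if (is.null(I)) NULL else as.integer(I),
            J = if (is.null(J)) NULL else as.integer(J),
            redraw_cap = as.integer(redraw_cap))
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (is.na(p$N) || p$N < 2) stop("N must be an integer >= 2")
  rates <- c(d = p$d, r0 = p$r0, r1 = p$r1, rS1 = p$rS1, rS = p$rS,
             dS = p$dS)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and fitnesses must be finite and >= 0")
  mus <- c(mu1 = p$mu1, muS1 = p$muS1, muS = p$muS)
  if (any(!is.finite(mus)) || any(mus < 0) || any(mus > 1))
    stop("mutation probabilities must lie in [0, 1]")
  if (p$detection_threshold <= p$hybrid_switch * p$N)
    stop("detection_threshold must exceed hybrid_switch * N")
  if (p$max_time <= 0) stop("max_time must be positive")
  if (p$rS <= p$dS)
    warning("rS <= dS: malignant net growth is non-positive; ",
            "detection will never occur once growth is deterministic",
            call. = FALSE)
  if (xor(is.null(p$I), is.null(p$J)))
    stop("provide both lattice dims I and J, or neither")
  if (!is.null(p$I) && p$I * p$J != p$N)
    stop("lattice dims must satisfy I * J == N")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Multistage initiation/recurrence model parameters\n")
  cat(sprintf("  tissue: N = %d, d = %g, fitness (r0, r1, rS1) = (%g, %g, %g)\n",
              x$N, x$d, x$r0, x$r1, x$rS1))
  cat(sprintf("  tumor: rS = %g, dS = %g (net %g), detect at %.3g cells\n",
              x$rS, x$dS, x$rS - x$dS, x$detection_threshold))
  cat(sprintf("  mutation: mu1 = %g, muS1 = %g, muS = %g\n",
              x$mu1, x$muS1, x$muS))
  if (!is.null(x$I))
    cat(sprintf("  lattice: %d x %d\n", x$I, x$J))
  invisible(x)
}

#' Derive square-ish lattice dimensions for a tissue of N cells
#'
#' Used by the spatial engine when explicit `I`, `J` are not supplied:
#' returns the most square factorization `I x J = N` (error when `N` is
#' prime and larger than a ribbon would make sense is left to the caller;
#' a `1 x N` ribbon is still a valid lattice).
#'
#' @param N Tissue size.
#' @return Integer vector `c(I, J)` with `I * J == N`.
#' @export
lattice_dims <- function(N) {
  N <- as.integer(N)
  i <- as.integer(floor(sqrt(N)))
  while (i >= 1L && N %% i != 0L) i <- i - 1L
  c(I = i, J = N %/% i)
}

#' Read model parameters from a flat key: value config file
#'
#' The config dialect is one `key: value` pair per line (comments with `#`,
#' blank lines ignored). Recognized keys are the `model_params()` arguments
#' `N, d, r0, r1, rS1, rS, dS, mu1, muS1, muS, detection_threshold,
#' hybrid_switch, max_time, I, J` plus an optional `seed`.
#'
#' @param path Path to the config file.
#' @return A list with elements `params` (a `model_params`) and `seed`
#'   (integer or `NULL`).
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric config value for key: ", keys[is.na(vals)][1])
  allowed <- c("N", "d", "r0", "r1", "rS1", "rS", "dS", "mu1", "muS1",
               "muS", "detection_threshold", "hybrid_switch", "max_time",
               "I", "J", "seed")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  args <- as.list(vals)
  names(args) <- keys
  seed <- args$seed
  args$seed <- NULL
  list(params = do.call(model_params, args),
       seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Write model parameters to a flat key: value config file
#'
#' @param params A `model_params` object.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path, seed = NULL) {
  validate_params(params)
  keys <- c("N", "d", "r0", "r1", "rS1", "rS", "dS", "mu1", "muS1", "muS",
            "detection_threshold", "hybrid_switch", "max_time")
  lines <- vapply(keys, function(k)
    sprintf("%s: %.15g", k, as.numeric(params[[k]])), "")
  if (!is.null(params$I))
    lines <- c(lines, sprintf("I: %d", params$I), sprintf("J: %d", params$J))
  if (!is.null(seed)) lines <- c(lines, sprintf("seed: %d", as.integer(seed)))
  writeLines(lines, path)
  invisible(path)
}
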