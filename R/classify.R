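#' Pattern labels for tissue composition at detection
#'
#' @format Character vector of the nine possible labels: single-type
#'   dominance (`DOM_0`, `DOM_1`, `DOM_S1`), pairwise co-dominance
#'   (`CODOM_0_1`, `CODOM_0_S1`, `CODOM_1_S1`), triple co-dominance
#'   (`CODOM_0_1_S1`), `OTHER` for compositions matching no rule, and
#'   `NO_CANCER` for censored runs.
#' @export
pattern_labels <- c("DOM_0", "DOM_1", "DOM_S1",
                    "CODOM_0_1", "CODOM_0_S1", "CODOM_1_S1",
                    "CODOM_0_1_S1", "OTHER", "NO_CANCER")

#' Classify tissue composition at cancer detection
#'
#' Applies the dominance/co-dominance rules: a single cell type with a
#' strict majority above 90% of the tissue is *dominant*; failing that, two
#' types each strictly above 40% are *co-dominant*, or all three strictly
#' above 30% are triply co-dominant. Thresholds are strict (`>`), so a type
#' at exactly 90% is not dominant. Precedence is dominance, then pairwise,
#' then triple co-dominance; compositions matching no rule are labeled
#' `OTHER`.
#'
#' @param composition A [tissue_state()] (or integer vector of the three
#'   counts).
#' @param N Tissue size; defaults to the sum of the counts.
#' @return A single label from [pattern_labels].
#' @examples
#' classify_pattern(tissue_state(25, 950, 25))    # DOM_1
#' classify_pattern(tissue_state(100, 450, 450))  # CODOM_1_S1
#' @export
classify_pattern <- function(composition, N = sum(composition)) {
  f <- as.numeric(composition) / N
  type <- c("0", "1", "S1")
  if (any(f > 0.9))
    return(paste0("DOM_", type[which.max(f)]))
  pair <- which(f > 0.4)
  if (length(pair) == 2)
    return(paste0("CODOM_", paste(type[pair], collapse = "_")))
  if (all(f > 0.3))
    return("CODOM_0_1_S1")
  "OTHER"
}

#' Parameter-grid scan of cancer-initiation patterns
#'
#' Runs the chosen engine to first detection over the Cartesian product of
#' the supplied parameter values, classifying the tissue composition at
#' detection for each replicate. Censored runs (no malignant detection by
#' `max_time`) are labeled `NO_CANCER`.
#'
#' @param engine `"well_mixed"` or `"spatial"`.
#' @param grid Named list of parameter value vectors (names must be
#'   [model_params()] arguments, e.g. `r1`, `rS1`, `muS1`, `muS`).
#' @param base A [model_params()] supplying every parameter not scanned.
#' @param replicates Number of independent runs per parameter combination.
#' @return A data frame with one row per (combination, replicate): the
#'   scanned parameter values, `replicate`, `detected`, `t_detect`, the
#'   composition counts and `pattern`.
#' @examples
#' \donttest{
#' base <- model_params(N = 100, max_time = 500)
#' set.seed(1)
#' scan <- grid_scan("well_mixed", list(muS1 = c(1e-3, 1e-2)), base,
#'                   replicates = 2)
#' table(scan$pattern)
#' }
#' @export
grid_scan <- function(engine = c("well_mixed", "spatial"), grid, base,
                      replicates = 1) {
  engine <- match.arg(engine)
  stopifnot(length(grid) > 0, replicates >= 1)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  sim <- if (engine == "well_mixed") simulate_to_detection
         else simulate_spatial_to_detection
  rows <- vector("list", nrow(combos) * replicates)
  idx <- 1L
  for (ci in seq_len(nrow(combos))) {
    p <- base
    for (nm in names(combos)) p[[nm]] <- combos[[nm]][ci]
    validate_params(p)
    for (rep in seq_len(replicates)) {
      res <- sim(p)
      comp <- res$composition
      rows[[idx]] <- data.frame(
        combos[ci, , drop = FALSE],
        replicate = rep,
        detected = res$detected,
        t_detect = res$t_detect,
        X0 = comp[["X0"]], X1 = comp[["X1"]], XS1 = comp[["XS1"]],
        pattern = if (res$detected) classify_pattern(comp) else "NO_CANCER",
        row.names = NULL)
      idx <- idx + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The published initiation-pattern scan grid
#'
#' The fitness/mutation grid used for the pattern panels: `r1` and `rS1`
#' in \{0.75, 1.00, 1.25\}, `muS1` in \{1e-6, ..., 1e-2\} (decades) and
#' `muS` in \{1e-3, 1e-2\}, with `r0 = 1`, `rS = 1.5`, `d = dS = 1` fixed.
#' The Type 0 to Type 1 mutation rate `mu1` does not affect the patterns
#' and is held at its default.
#'
#' @return A named list of parameter value vectors for [grid_scan()].
#' @export
pattern_scan_grid <- function() {
  list(r1 = c(0.75, 1.00, 1.25),
       rS1 = c(0.75, 1.00, 1.25),
       muS1 = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
       muS = c(1e-3, 1e-2))
}

#' Write a grid-scan result as tab-separated text
#'
#' @param scan A data frame from [grid_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
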