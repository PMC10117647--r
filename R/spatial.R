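#' A 2D lattice tissue
#'
#' The spatial refinement of the Moran tissue: an `I x J` grid in which
#' every site holds exactly one tissue cell (Type 0, 1 or S-1, coded 0, 1,
#' 2). Division is restricted to the 4-neighborhood of a dying cell and the
#' lattice has wall boundaries (no wraparound), so corner sites have 2
#' neighbors and edge sites 3. Malignant cells are never placed on the
#' lattice; they are tracked as an off-lattice count.
#'
#' @param I,J Lattice dimensions (positive integers).
#' @param fill Cell-type code used to initialize every site. Default 0.
#' @param grid Optional `I x J` integer matrix of codes in `{0, 1, 2}`
#'   overriding `fill`.
#' @return An object of class `lattice_tissue`: a list with `I`, `J` and
#'   `grid` (an integer matrix).
#' @examples
#' lat <- lattice_tissue(10, 10)
#' lattice_composition(lat)
#' @export
lattice_tissue <- function(I, J, fill = 0L, grid = NULL) {
  I <- as.integer(I); J <- as.integer(J)
  if (I < 1L || J < 1L) stop("lattice dims must be positive")
  if (is.null(grid)) {
    grid <- matrix(as.integer(fill), nrow = I, ncol = J)
  } else {
    grid <- matrix(as.integer(grid), nrow = I, ncol = J)
  }
  if (!all(grid %in% 0:2))
    stop("grid codes must be 0 (Type 0), 1 (Type 1) or 2 (Type S-1)")
  structure(list(I = I, J = J, grid = grid), class = "lattice_tissue")
}

#' @export
print.lattice_tissue <- function(x, ...) {
  comp <- lattice_composition(x)
  cat(sprintf("%d x %d lattice tissue: X0 = %d, X1 = %d, XS1 = %d\n",
              x$I, x$J, comp[["X0"]], comp[["X1"]], comp[["XS1"]]))
  invisible(x)
}

#' Tissue composition of a lattice
#'
#' @param lattice A [lattice_tissue()].
#' @return The derived [tissue_state()] with `N = I * J`.
#' @export
lattice_composition <- function(lattice) {
  g <- lattice$grid
  tissue_state(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

#' 4-neighborhood of a lattice site under wall boundaries
#'
#' @param pos Integer vector `c(i, j)`, 0-based row-major coordinates.
#' @param dims Integer vector `c(I, J)`.
#' @return A matrix with one `(i, j)` row per in-bounds neighbor (2 at
#'   corners, 3 on edges, 4 in the interior; no wraparound).
#' @examples
#' neighbors(c(0, 0), c(50, 50))   # 2 rows
#' @export
neighbors <- function(pos, dims) {
  i <- pos[1]; j <- pos[2]; I <- dims[1]; J <- dims[2]
  if (i < 0 || j < 0 || i >= I || j >= J)
    stop("position out of bounds")
  cand <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
  keep <- cand[, 1] >= 0 & cand[, 1] < I & cand[, 2] >= 0 & cand[, 2] < J
  m <- cand[keep, , drop = FALSE]
  colnames(m) <- c("i", "j")
  m
}

#' Division-outcome distribution restricted to a dying cell's neighbors
#'
#' Identical in form to [division_distribution()] but with global counts
#' replaced by the type counts among the dying cell's in-bounds neighbors,
#' and `F` by the fitness-weighted sum over those neighbors.
#'
#' @param lattice A [lattice_tissue()].
#' @param dead_pos 0-based `c(i, j)` coordinate of the dying cell.
#' @param params A [model_params()].
#' @return Named numeric vector
#'   `c(daughter0, daughter1, daughterS1, S_birth)` summing to 1.
#' @export
local_division_distribution <- function(lattice, dead_pos, params) {
  nb <- neighbors(dead_pos, c(lattice$I, lattice$J))
  codes <- lattice$grid[cbind(nb[, 1] + 1L, nb[, 2] + 1L)]
  n0 <- sum(codes == 0L); n1 <- sum(codes == 1L); nS1 <- sum(codes == 2L)
  F <- params$r0 * n0 + params$r1 * n1 + params$rS1 * nS1
  if (F <= 0) stop("no neighbor can divide: local division weight F is zero")
  c(daughter0 = params$r0 * n0 * (1 - params$mu1) / F,
    daughter1 = (params$r1 * n1 * (1 - params$muS1) +
                   params$r0 * n0 * params$mu1) / F,
    daughterS1 = (params$rS1 * nS1 * (1 - params$muS) +
                    params$r1 * n1 * params$muS1) / F,
    S_birth = params$rS1 * nS1 * params$muS / F)
}

#' One spatial Moran turnover event
#'
#' The death site is chosen uniformly over all `I * J` sites; the vacancy
#' is refilled via [local_division_distribution()], with the same
#' malignant-redraw semantics as the well-mixed [turnover_step()].
#'
#' @param lattice A [lattice_tissue()].
#' @param params A [model_params()].
#' @return A list with the updated `lattice` and `s_births`.
#' @export
spatial_turnover_step <- function(lattice, params) {
  n <- lattice$I * lattice$J
  site <- sample.int(n, 1L) - 1L
  pos <- c(site %/% lattice$J, site %% lattice$J)
  pr <- local_division_distribution(lattice, pos, params)
  s_births <- 0L
  daughter <- NA_integer_
  for (k in seq_len(params$redraw_cap + 1L)) {
    out <- sample.int(4L, 1L, prob = pr)
    if (out == 4L) { s_births <- s_births + 1L; next }
    daughter <- out - 1L
    break
  }
  if (is.na(daughter))
    stop("redraw cap exceeded while refilling a vacancy (muS too close to 1)")
  lattice$grid[pos[1] + 1L, pos[2] + 1L] <- daughter
  list(lattice = lattice, s_births = s_births)
}

run_phase_spatial_engine <- function(lattice, XS, params) {
  # engine works on a row-major flat vector of codes
  flat <- as.integer(t(lattice$grid))
  res <- cpp_run_phase_spatial(flat, lattice$I, lattice$J, XS,
                               params$d, params$r0, params$r1, params$rS1,
                               params$rS, params$dS, params$mu1, params$muS1,
                               params$muS, params$detection_threshold,
                               params$hybrid_switch, params$max_time,
                               params$redraw_cap)
  res$lattice <- lattice_tissue(lattice$I, lattice$J,
                                grid = matrix(res$grid, nrow = lattice$I,
                                              byrow = TRUE))
  res
}

spatial_dims <- function(params) {
  if (!is.null(params$I)) return(c(params$I, params$J))
  dims <- lattice_dims(params$N)
  c(dims[["I"]], dims[["J"]])
}

#' Simulate a full course on the 2D lattice
#'
#' Same initiation-surgery-recurrence protocol as [run_full()], with tissue
#' turnover on the lattice. The lattice persists through surgery (only the
#' off-lattice malignant count is reset) so the spatial arrangement of the
#' cancerized field carries over into the recurrence phase.
#'
#' @param params A [model_params()]; lattice dims are taken from `I`, `J`
#'   or derived as the most square factorization of `N`.
#' @param seed Optional integer seed.
#' @param keep_lattice Return the final lattice as well. Default `FALSE`.
#' @return A `simulation_outcome` (see [run_full()]); with
#'   `keep_lattice = TRUE`, also `lattice_at_surgery`.
#' @examples
#' \donttest{
#' p <- model_params(N = 100, I = 10, J = 10,
#'                   mu1 = 0.05, muS1 = 0.05, muS = 0.05)
#' simulate_spatial(p, seed = 1)
#' }
#' @export
simulate_spatial <- function(params, seed = NULL, keep_lattice = FALSE) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  dims <- spatial_dims(params)
  lat <- lattice_tissue(dims[1], dims[2], fill = 0L)
  first <- run_phase_spatial_engine(lat, 0, params)
  out <- list(t_detect = first$t,
              composition_at_surgery =
                tissue_state(first$X0, first$X1, first$XS1),
              t_recur = NA_real_,
              detected = first$detected,
              recurred = FALSE,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (keep_lattice) out$lattice_at_surgery <- first$lattice
  if (first$detected) {
    second <- run_phase_spatial_engine(first$lattice, 0, params)
    out$t_recur <- second$t
    out$recurred <- second$detected
  }
  class(out) <- "simulation_outcome"
  out
}

#' Simulate initiation only on the 2D lattice
#'
#' Spatial counterpart of [simulate_to_detection()].
#'
#' @inheritParams simulate_spatial
#' @return A list with `detected`, `t_detect`, `composition`, `lattice`
#'   and `seed`.
#' @export
simulate_spatial_to_detection <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  dims <- spatial_dims(params)
  lat <- lattice_tissue(dims[1], dims[2], fill = 0L)
  res <- run_phase_spatial_engine(lat, 0, params)
  list(detected = res$detected,
       t_detect = res$t,
       composition = tissue_state(res$X0, res$X1, res$XS1),
       lattice = res$lattice,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Write a lattice snapshot as a plain-text integer grid
#'
#' One row of space-separated type codes per lattice row.
#'
#' @param lattice A [lattice_tissue()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lattice <- function(lattice, path) {
  writeLines(apply(lattice$grid, 1, paste, collapse = " "), path)
  invisible(path)
}

#' Read a lattice snapshot written by [write_lattice()]
#'
#' @param path Input path.
#' @return A [lattice_tissue()].
#' @export
read_lattice <- function(path) {
  rows <- strsplit(readLines(path, warn = FALSE), " +")
  m <- do.call(rbind, lapply(rows, as.integer))
  lattice_tissue(nrow(m), ncol(m), grid = m)
}
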